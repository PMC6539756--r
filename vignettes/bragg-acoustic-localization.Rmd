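---
title: "Methods: thermoacoustic simulation and acoustic localization of the proton Bragg peak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermoacoustic simulation and acoustic localization of the proton Bragg peak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggloc)
```

## The problem

Proton radiotherapy concentrates dose at the Bragg peak, the sharp maximum
of energy deposition at the end of the proton range. Anatomical and
positioning uncertainties translate directly into range uncertainty, so an
independent, online measurement of where the peak actually sits is
valuable. A pulsed beam (millions of protons within a microsecond) heats
the peak region almost instantaneously; thermal expansion then launches a
pressure transient — a thermoacoustic (ionoacoustic) pulse — that acoustic
sensors around the target can record. Localizing the acoustic source
localizes the Bragg peak.

`braggloc` implements this chain end to end in water: an analytical depth-
dose model, a Kirchhoff-integral forward acoustic model, time-difference-
of-arrival (TDOA) estimation by cross-correlation, and Gauss–Newton
multilateration, together with seeded study drivers that emulate a
four-sensor cube simulation study and a 12-position water-tank experiment.

## Depth-dose model

The Bragg curve uses the standard analytical stopping model in water. The
range–energy relation is the power law

$$R_0 = \alpha E_0^{\,p}, \qquad \alpha = 2.2\times 10^{-3}\ \mathrm{cm\,MeV}^{-p},\quad p = 1.77,$$

fitted for beam energies of roughly 10–250 MeV. The residual energy at
depth $z$ is $E(z) = \alpha^{-1/p}(R_0 - z)^{1/p}$, and nuclear
interactions remove protons from the beam linearly with residual range,

$$\Phi(z) = \Phi_0\,\frac{1 + \beta (R_0 - z)}{1 + \beta R_0},
\qquad \beta = 0.012\ \mathrm{cm}^{-1}.$$

(The package adopts this standard form of the fluence factor; the source
publication's rendering of the same equation is typographically garbled.)
The dose deposited per unit fluence is

$$\hat D(z) = -\frac{1}{\rho}\!\left(\Phi \frac{dE}{dz}
  + \gamma E \frac{d\Phi}{dz}\right)
 = \frac{(R_0 - z)^{1/p - 1}/p + (\beta/p + \gamma\beta)(R_0-z)^{1/p}}
        {\rho\,(1+\beta R_0)\,\alpha^{1/p}},$$

where $\gamma$ is the fraction of nuclear-interaction energy absorbed
locally. Range straggling replaces every proton's sharp stopping point by
a Gaussian of width $\sigma = 0.012\,R_0^{0.935}$ cm. The Gaussian
convolution of $\hat D$ has a closed form in parabolic cylinder functions
$D_\nu$:

$$D(z) = \Phi_0\,
 \frac{e^{-\zeta^2/4}\,\sigma^{1/p}\,\Gamma(1/p)}
      {\sqrt{2\pi}\,\rho\, p\, \alpha^{1/p} (1+\beta R_0)}
 \left[\frac{1}{\sigma} D_{-1/p}(-\zeta)
   + \Bigl(\frac{\beta}{p} + \gamma\beta + \frac{\epsilon}{R_0}\Bigr)
     D_{-1/p-1}(-\zeta)\right],
 \qquad \zeta = \frac{R_0 - z}{\sigma}.$$

This expression was re-derived here from the convolution integral (the
printed rendering is ambiguous about the prefactor and the exponent's
sign); the test suite checks it against a brute-force numerical
convolution of $\hat D$ to better than 1% relative $L_2$ error. Note the
closed form convolves the stopping curve continued analytically across
the entrance plane (an infinite-medium convention); differences against a
half-space convolution are confined to a few $\sigma$ of the surface.

### Parabolic cylinder evaluation

No pre-installed R package provides $D_\nu$, so the package evaluates the
Gaussian-scaled combination $f_\nu(\zeta) = e^{-\zeta^2/4} D_\nu(-\zeta)$
(the only form needed, stable at all depths) with three branches:

* $-5 < \zeta \le 30$: Kummer confluent-hypergeometric series (the two
  $_1F_1$ terms have positive coefficients here, so no intra-series
  cancellation);
* $\zeta \le -5$ (deep tail): generalized Gauss–Laguerre quadrature of the
  integral representation, whose weight $s^{-\nu-1}e^{-s}$ is treated
  exactly — the Kummer form cancels catastrophically on this side;
* $\zeta > 30$ (entrance plateau): large-argument asymptotic series, whose
  leading term recovers the unconvolved power law.

The branches are validated against frozen values from two independent
external special-function libraries (which agree with each other to
$10^{-10}$) and against adaptive quadrature of the integral definition.

### Energy bookkeeping and $\gamma$

With $\gamma = 1$ and $\beta \ge 0$ the depth integral of $\rho\hat D$
equals $\Phi_0 E_0$ exactly — all stopping energy is deposited — and the
tests assert this through the package's own quadrature. With the default
$\gamma = 0.6$ (the conventional choice; no measured value exists) the
deposited fraction is $0.9786$ for 100 MeV: about 2% of the beam energy
leaves with non-local nuclear secondaries. The source-field builder
therefore conserves the *profile's* energy, not blindly $N E_0$; the
frozen ratio is itself a test. $\epsilon$ (peak fluence fraction) defaults
to 0 and is exposed as a parameter.

## Thermoacoustic forward model

Rapid heating with volumetric expansion coefficient $\alpha'$ obeys the
thermoacoustic wave equation; its retarded-time (Kirchhoff) solution for a
separable source $\epsilon(\mathbf r, t) = \epsilon_s(\mathbf r)\,H(t)$,
with $H$ the cumulative time profile of the heating, is

$$p(\mathbf r, t) = \frac{\alpha'}{4\pi C_p}
  \int \frac{dV'}{|\mathbf r - \mathbf r'|}\,
  \epsilon_s(\mathbf r')\,
  \ddot H\!\left(t - \tfrac{|\mathbf r - \mathbf r'|}{c_s}\right).$$

$\ddot H$ is the first derivative of the Gaussian heating *rate* — applied
analytically, never by numerical double differentiation — which is why a
Gaussian pulse radiates the characteristic bipolar (compression–
rarefaction) waveform. A dose of 1 Gy raises water by
$1/C_p = 239\ \mu\mathrm{K}$ with $C_p = 4186$ J kg$^{-1}$K$^{-1}$.

The discrete source is a voxel grid: Bragg depth profile times a
transverse Gaussian of the beam width, truncated at $5\sigma$ laterally
(<10⁻⁵ of the mass) and resolved by voxels no coarser than a quarter of
the smaller of the lateral and straggling widths (the builder refuses
coarser voxels). Per-voxel arrival times are deposited on the output time
grid by linear binning — algebraically identical to linear interpolation
of the smooth kernel derivative between samples — after which the sum
collapses to a single FFT convolution. The point-source closed form, the
$1/r$ far-field law, superposition in the proton number, and stability
under voxel halving (<1%) are all asserted in the tests.

Water constants live in one registry: $c_s = 1492$ m/s (the tank-
calibrated sound speed), $C_p = 4186$, $\rho = 1000$,
$\alpha' = 2.07\times10^{-4}$ K$^{-1}$ (≈20 °C; the source work prints no
value). No physical constant is restated anywhere else in the code. The
absolute pressure scale is asserted nowhere — no printed reference value
exists — only shape, timing and scaling laws are.

## Delay estimation

TDOAs come from generalized cross-correlation computed on zero-padded
FFTs (no circular wrap-around). Plain weighting — the default, and
provably identical to time-domain cross-correlation, which the suite
checks against a brute-force oracle — is used throughout the studies;
PHAT and SCOT whitenings are available, as is an optional zero-phase
band-pass prefilter applied identically to both channels (the experiment's
actual filters are unpublished, so none is applied by default). The TOA is
the correlation argmax with three-point parabolic sub-sample refinement;
ties are broken deterministically toward the smaller lag by the argmax
scan order, boundary peaks are flagged unreliable, and each estimate
carries a peak-to-secondary quality ratio.

## Localization

With sensor positions $\mathbf x_i$, reference sensor 1 and measured
$\tau_{i1}$, the residuals
$f_i(\mathbf x) = (d_i - d_1) - c\,\tau_{i1}$ vanish at the source. The
Jacobian row is the difference of unit vectors toward the two sensors.
The damped Gauss–Newton update $\mathbf x \leftarrow \mathbf x - s\,J^+ f$
(SVD pseudo-inverse; exactly determined for 4 sensors, least squares for
more — the update sign corrects an obvious typo in the printed iteration)
halves $s$ up to 10 times when the residual norm fails to decrease, stops
on a step norm below `tol` (default $10^{-6}$ m, `max_iter` 100), and
reports convergence honestly: singular Jacobians, stalls and iteration
overruns all yield `converged = FALSE` rather than an exception.

When no starting point is given, the solver starts from the sensor
centroid nudged by 5% of the array span and, if that fails, retries from
a small deterministic set of axis-offset starts, keeping the converged
solution with the smallest residual. The nudge and restarts exist because
coplanar four-sensor groups (common in the tank layout) put the exact
centroid on the array's symmetry plane, where the Jacobian is singular
and a single iteration track can run away along a hyperboloid asymptote.
Coplanar groups also possess genuine mirror-image solutions with exactly
zero residual; the solver then reports whichever branch it reaches —
the experimental study this package emulates shows the same multi-
centimetre offsets for exactly those groups. A user-supplied start
disables the multi-start, which is what the convergence study uses to
probe single-start behaviour.

## The synthetic world

The tank surrogate emulates the acquisition chain: 10 MS/s sampling,
500 µs records, the known emitted pulse (the simulated waveform for the
100 MeV, 1 µs, $3.4\times10^6$-proton reference spill, computed 40 mm
from the peak — the printed sensor configuration), per-channel delays
applied as exact band-limited fractional-sample shifts, $1/r$ amplitude
scaling, and white Gaussian noise. The per-channel SNR is defined against
the clean channel's RMS over its effective support (samples above 1% of
the peak magnitude); defining it over the whole 500 µs record would make
the SNR depend on the record length rather than on the pulse. All
randomness descends from one integer seed; identical seeds give
bit-identical records.

The cube study adds noise at the TOA level instead, because the printed
study does not state its noise model: Gaussian jitter with
$\sigma$ = one sample period at 10 MS/s (0.1 µs ≈ 0.15 mm of range),
followed by quantization to the sampling grid. This choice is consistent
with the printed sub-millimetre-to-few-millimetre error scales and is
exposed as a parameter; it was fixed before the acceptance values were
computed and has not been revisited.

What a green test does and does not establish: the surrogate contains no
transducer response, no hydrophone positioning error, no tank
reverberation, no sound-speed miscalibration and no medium heterogeneity.
That is why the 12-sensor surrogate localizes to ~0.01 mm where the real
experiment reports sub-millimetre: the bound is met, but the margin
reflects the absence of experimental systematics, not superiority of the
method. Conversely the cube study's few-millimetre maxima are driven
almost entirely by the assumed jitter model.

## Numerical choices

* Internal units are SI everywhere except the dose module, which keeps
  cm/MeV to match the $\alpha, \beta$ fit constants; conversion happens
  once, at the source-builder boundary.
* "1 µs temporal profile" is ambiguous (σ vs FWHM); the default reads it
  as the Gaussian σ, switchable via `width_convention`, and recorded in
  outputs.
* The dose grid defaults to $[0, R_0 + 6\sigma]$ with step
  $\min(\sigma/10, 0.01\ \mathrm{cm})$, resolving the peak at all
  energies in scope; the unconvolved curve's integrable endpoint
  singularity is mapped to 0 at the measure-zero point $z = R_0$.
* Correlation ties break toward the smallest lag deterministically;
  sub-sample refinement is skipped when the three-point curvature is not
  concave.
* The solver treats a singular-value ratio below $10^{-12}$ as singular;
  `residual_tol` (default 1 cm) guards against declaring convergence at a
  stalled point far from any solution.
* Degenerate inputs error early with specific messages: all-zero signals,
  mismatched sample rates, records too short for the geometry, voxels too
  coarse, sensors inside the source, coincident sensors, sources on a
  sensor.

## Limitations

Homogeneous, lossless, isotropic water only; no attenuation, dispersion,
reflections or transducer response; no closed-form TDOA initializers; no
Monte-Carlo transport; reference-relative TDOAs only (all pairwise pairs
are not used). Wall-clock timing is reported by `run_timing_study()` but
never asserted. The printed experiment's means and SDs are not
reproduced numerically — its noise realization and waveforms are
unavailable — and are replaced by the property-based acceptance suite.
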