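# braggloc — acoustic localization of the proton Bragg peak

Proton therapy delivers most of its dose at the Bragg peak, the sharp
maximum of energy deposition at the end of the proton range, so knowing
*where* that peak actually lands inside the patient is the central range-
verification problem. A pulsed beam (millions of protons within ~1 µs)
heats the peak region fast enough to launch a measurable pressure
transient — a thermoacoustic pulse — and an array of acoustic sensors can
triangulate its origin.

`braggloc` is an R package for medical physicists and signal-processing
researchers that implements this chain end to end in water:

1. **Bragg curve** — the analytical depth-dose model
   `R0 = α E0^p` (α = 2.2·10⁻³ cm MeV⁻ᵖ, p = 1.77), linear nuclear
   fluence loss (β = 0.012 cm⁻¹), and range straggling
   (σ = 0.012 R0^0.935 cm) via the closed-form Gaussian convolution in
   parabolic cylinder functions `D_ν`.
2. **Thermoacoustics** — the Kirchhoff retarded-time integral
   `p(r,t) = α′/(4πC_p) Σ_v E_v/|r−r_v| · ġ(t − |r−r_v|/c_s)`
   over a voxelized source, with the Gaussian heating-rate kernel `g`
   differentiated analytically (bipolar waveform).
3. **TDOA estimation** — generalized cross-correlation (plain/PHAT/SCOT)
   on zero-padded FFTs, correlation-argmax TOA with parabolic sub-sample
   refinement.
4. **Multilateration** — damped Gauss–Newton on the range-difference
   residuals `f_i = (d_i − d_1) − c·τ_i1` with an analytic Jacobian,
   honest convergence reporting and a deterministic multi-start fallback.
5. **Study drivers** — seeded reproductions of a four-sensor cube
   simulation study (volumes 27–343 litres) and a full signal-level
   surrogate of a 12-sensor water-tank experiment (10 MS/s, 500 µs
   records, c = 1492 m/s), plus a solver-convergence study and a timing
   harness.

## Worked example

```r
library(braggloc)

beam <- beam_pulse(energy_mev = 100, n_protons = 3.4e6)  # 1 mm beam, 1 us pulse
prof <- dose_profile(beam)
prof
#> <depth_dose_profile> E0 = 100 MeV, R0 = 7.628 cm, sigma = 0.08021 cm, straggling on, 1011 depths
prof$z[which.max(prof$dose)]       # Bragg peak depth: 7.556 cm, just short of R0
temperature_rise(1) * 1e6          # 238.9 uK per Gy in water

src <- build_source(prof, beam)
src
#> <source_field> 1010000 voxels of 0.201 mm, total 5.331e-05 J, sigma_t = 1 us
p <- kirchhoff_pressure(src, bragg_peak_position(prof) + c(0, 0, 0.04),
                        seq(0, 6e-5, by = 1e-7))
p
#> <pressure_signal> 601 samples @ 10 MS/s, t0 = 0 us, peak |p| = 0.1219 Pa
```

The 0.12 Pa bipolar pulse arrives around 26.8 µs = 0.04 m / 1492 m s⁻¹.
The full tank surrogate — synthesize all 12 channels at 20 dB SNR,
estimate TOAs by correlation, localize — recovers the source position
(54.0, 53.0, 38.0) cm:

```r
run_tank_study(groups = list(all12 = 1:12), n_repeats = 20, seed = 1)
#> <study_result> tank study, seed 1
#>   group n_sensors                    sensors x_cm   x_sd_cm y_cm   y_sd_cm z_cm
#> 1 all12        12 1,2,3,4,5,6,7,8,9,10,11,12   54 0.0006333   53 0.0003633   38
#>     z_sd_cm n_converged n_repeats median_err_mm max_err_mm
#> 1 0.0008822          20        20      0.007273    0.02981
```

The median 3-D error (0.007 mm) sits far below the sub-millimetre
experimental figure because the surrogate carries no hydrophone-
positioning or calibration systematics — see the methods vignette
(`vignettes/bragg-acoustic-localization.Rmd`) for what the synthetic
world does and does not emulate.

## Command line

```sh
Rscript -e 'braggloc::cli_main()' bragg-curve --energy-mev 100 --protons 3.4e6 --out curve.csv
Rscript -e 'braggloc::cli_main()' bragg-pressure --energy-mev 100 --sensor 0,0,0.115 --out pulse.csv
Rscript -e 'braggloc::cli_main()' bragg-toa --emitted a.csv --received b.csv
Rscript -e 'braggloc::cli_main()' bragg-localize --geometry sensors.csv --tdoa tdoas.csv --c 1492
Rscript -e 'braggloc::cli_main()' bragg-study --kind cube --H 300,400,500,600,700 --seed 42 --out results/
```

(A launcher script is installed at `inst/cli/braggloc`.) Every run writes
a `run_manifest.json` — package version, parameters, seed, input digests —
sufficient to reproduce it exactly.

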