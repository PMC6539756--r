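#' Pulsed proton beam description
#'
#' A single beam spill: initial energy, number of protons, transverse
#' Gaussian width, and a Gaussian temporal profile. The central (on-axis)
#' fluence of the Gaussian pencil beam, \eqn{\Phi_0 = N / (2\pi\sigma^2)}
#' in protons/cm^2, is derived and stored.
#'
#' The reference configuration is a 100 MeV spill of
#' \eqn{3.4\times 10^6} protons, 1 mm beam size and a 1 us temporal
#' profile. Whether a printed "1 us" means the Gaussian sigma or the
#' FWHM is a convention; it is selectable and recorded.
#'
#' @param energy_mev Initial proton energy, MeV (model fitted for 10-250).
#' @param n_protons Protons per pulse (>= 0).
#' @param lateral_sigma_mm Transverse Gaussian sigma, mm (> 0).
#' @param pulse_width_us Temporal width parameter, us (> 0).
#' @param width_convention Either `"sigma"` (default: the width is the
#'   Gaussian sigma) or `"fwhm"`.
#' @return Object of class `beam_pulse` with fields `energy_mev`,
#'   `n_protons`, `lateral_sigma_mm`, `pulse_width_us`,
#'   `width_convention`, `sigma_t` (temporal sigma, s) and `phi0`
#'   (central fluence, protons/cm^2).
#' @export
#' @examples
#' beam_pulse()           # the 100 MeV reference spill
beam_pulse <- function(energy_mev = 100, n_protons = 3.4e6,
                       lateral_sigma_mm = 1, pulse_width_us = 1,
                       width_convention = c("sigma", "fwhm")) {
  width_convention <- match.arg(width_convention)
  stopifnot(is.numeric(energy_mev), length(energy_mev) == 1L, energy_mev > 0,
            is.numeric(n_protons), length(n_protons) == 1L, n_protons >= 0,
            is.numeric(lateral_sigma_mm), lateral_sigma_mm > 0,
            is.numeric(pulse_width_us), pulse_width_us > 0)
  sigma_t <- pulse_width_us * 1e-6
  if (width_convention == "fwhm") sigma_t <- sigma_t / (2 * sqrt(2 * log(2)))
  sigma_cm <- lateral_sigma_mm * MM_TO_M / CM_TO_M
  structure(list(
    energy_mev = energy_mev,
    n_protons = n_protons,
    lateral_sigma_mm = lateral_sigma_mm,
    pulse_width_us = pulse_width_us,
    width_convention = width_convention,
    sigma_t = sigma_t,
    phi0 = if (n_protons > 0) n_protons / (2 * pi * sigma_cm^2) else 0
  ), class = "beam_pulse")
}

#' @export
print.beam_pulse <- function(x, ...) {
  cat(sprintf("<beam_pulse> %g MeV, %g protons, lateral sigma %g mm, pulse %g us (%s)\n",
              x$energy_mev, x$n_protons, x$lateral_sigma_mm,
              x$pulse_width_us, x$width_convention))
  invisible(x)
}
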