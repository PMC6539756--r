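#' Acoustic/thermal properties of the propagation medium
#'
#' @param c_s Speed of sound, m/s (water default: the tank-calibrated
#'   1492 m/s).
#' @param C_p Specific heat capacity, J kg^-1 K^-1.
#' @param rho Mass density, kg/m^3.
#' @param alpha_exp Volumetric thermal expansion coefficient, K^-1.
#' @return Object of class `acoustic_medium`.
#' @export
#' @examples
#' medium_water()
acoustic_medium <- function(c_s = WATER_SOUND_SPEED, C_p = WATER_C_P,
                            rho = WATER_RHO, alpha_exp = WATER_ALPHA_EXP) {
  stopifnot(c_s > 0, C_p > 0, rho > 0, alpha_exp > 0)
  structure(list(c_s = c_s, C_p = C_p, rho = rho, alpha_exp = alpha_exp),
            class = "acoustic_medium")
}

#' @rdname acoustic_medium
#' @export
medium_water <- function() acoustic_medium()

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> c_s = %g m/s, C_p = %g J/kg/K, rho = %g kg/m^3, alpha' = %g /K\n",
              x$c_s, x$C_p, x$rho, x$alpha_exp))
  invisible(x)
}

#' Temperature rise from absorbed dose
#'
#' For rapid energy deposition (no heat diffusion) the temperature rise
#' is \eqn{\Delta T = D / C_p} with the dose \eqn{D} in gray (J/kg). In
#' water, 1 Gy gives about 240 uK.
#'
#' @param dose_gy Absorbed dose, Gy (vectorized, >= 0).
#' @param medium An [acoustic_medium()]; default water.
#' @return Temperature rise, K.
#' @export
#' @examples
#' temperature_rise(1) * 1e6   # ~239 uK per Gy in water
temperature_rise <- function(dose_gy, medium = medium_water()) {
  stopifnot(inherits(medium, "acoustic_medium"), is.numeric(dose_gy))
  if (any(dose_gy < 0)) stop("dose must be non-negative")
  dose_gy / medium$C_p
}
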