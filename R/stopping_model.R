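#' Range-energy stopping model for protons in water
#'
#' Parameter set of the analytical depth-dose model: the power-law
#' range-energy relation \eqn{R_0 = \alpha E_0^p}, the linear fluence-loss
#' slope \eqn{\beta} describing removal of protons by nuclear interactions,
#' the locally absorbed fraction \eqn{\gamma} of the energy released in
#' those interactions, and the small fluence fraction \eqn{\epsilon}
#' deposited in the peak by secondaries.
#'
#' Defaults are the water best-fit values \eqn{\alpha = 2.2\times10^{-3}}
#' cm MeV\eqn{^{-p}}, \eqn{p = 1.77}, \eqn{\beta = 0.012} cm\eqn{^{-1}}.
#' \eqn{\gamma} is not pinned down by measurements; 0.6 is the conventional
#' choice. The model is fitted for beam energies of roughly 10-250 MeV.
#'
#' @param alpha Range-energy coefficient, cm MeV^(-p). Must be > 0.
#' @param p Range-energy exponent, dimensionless, in (1, 2).
#' @param beta Fluence-loss slope, cm^-1, >= 0.
#' @param gamma Locally absorbed fraction of nuclear-interaction energy,
#'   in \[0, 1\].
#' @param epsilon_peak Fraction of the primary fluence deposited in the
#'   peak, >= 0 (default 0).
#' @return Object of class `stopping_model`.
#' @export
#' @examples
#' m <- stopping_model()
#' range_from_energy(100, m)
stopping_model <- function(alpha = 2.2e-3, p = 1.77, beta = 0.012,
                           gamma = 0.6, epsilon_peak = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(p), length(p) == 1L, p > 1, p < 2,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
            is.numeric(epsilon_peak), length(epsilon_peak) == 1L,
            epsilon_peak >= 0)
  structure(list(alpha = alpha, p = p, beta = beta, gamma = gamma,
                 epsilon_peak = epsilon_peak),
            class = "stopping_model")
}

#' @export
print.stopping_model <- function(x, ...) {
  cat("<stopping_model>  R0 = alpha * E0^p\n")
  cat(sprintf("  alpha = %g cm/MeV^p, p = %g, beta = %g /cm, gamma = %g, epsilon_peak = %g\n",
              x$alpha, x$p, x$beta, x$gamma, x$epsilon_peak))
  invisible(x)
}

#' Proton range in water from beam energy
#'
#' Power-law range-energy relation \eqn{R_0 = \alpha E_0^p}.
#'
#' @param E0 Initial proton energy, MeV (vectorized, >= 0).
#' @param model A [stopping_model()].
#' @return Range(s) in cm.
#' @export
range_from_energy <- function(E0, model = stopping_model()) {
  stopifnot(inherits(model, "stopping_model"), is.numeric(E0))
  if (any(E0 < 0)) stop("E0 must be non-negative (got negative energy)")
  model$alpha * E0^model$p
}

#' Beam energy from proton range (inverse range-energy relation)
#'
#' @param R0 Range, cm (vectorized, >= 0).
#' @param model A [stopping_model()].
#' @return Energy in MeV.
#' @export
energy_from_range <- function(R0, model = stopping_model()) {
  stopifnot(inherits(model, "stopping_model"), is.numeric(R0))
  if (any(R0 < 0)) stop("R0 must be non-negative (got negative range)")
  (R0 / model$alpha)^(1 / model$p)
}

#' Residual proton energy at depth
#'
#' Energy left at depth `z` of a proton of range `R0`:
#' \eqn{E(z) = \alpha^{-1/p} (R_0 - z)^{1/p}}. Depths beyond the range
#' return 0 (the proton has stopped); the returned vector carries a
#' logical attribute `stopped` marking those entries.
#'
#' @param z Depth, cm (vectorized, >= 0).
#' @param R0 Range, cm.
#' @param model A [stopping_model()].
#' @return Residual energy in MeV with attribute `stopped`.
#' @export
residual_energy <- function(z, R0, model = stopping_model()) {
  stopifnot(inherits(model, "stopping_model"), is.numeric(z),
            is.numeric(R0), length(R0) == 1L, R0 >= 0)
  if (any(z < 0)) stop("depth z must be non-negative")
  stopped <- z > R0
  E <- (pmax(R0 - z, 0) / model$alpha)^(1 / model$p)
  attr(E, "stopped") <- stopped
  E
}

#' Proton fluence at depth
#'
#' Linear fluence reduction by nuclear interactions,
#' \eqn{\Phi(z) = \Phi_0 (1 + \beta (R_0 - z)) / (1 + \beta R_0)}:
#' equal to \eqn{\Phi_0} at the surface and non-increasing with depth.
#'
#' @param z Depth, cm (vectorized, 0 <= z <= R0).
#' @param phi0 Primary fluence, protons/cm^2.
#' @param model A [stopping_model()].
#' @param R0 Range, cm.
#' @return Fluence at each depth, protons/cm^2.
#' @export
fluence_at_depth <- function(z, phi0, model = stopping_model(), R0) {
  stopifnot(inherits(model, "stopping_model"), is.numeric(z),
            is.numeric(phi0), length(phi0) == 1L, phi0 >= 0,
            is.numeric(R0), length(R0) == 1L, R0 >= 0)
  if (any(z < 0) || any(z > R0)) stop("depth z must lie in [0, R0]")
  phi0 * (1 + model$beta * (R0 - z)) / (1 + model$beta * R0)
}

#' Range-straggling width
#'
#' Gaussian spread of stopping depths, \eqn{\sigma = 0.012 R_0^{0.935}}
#' (both in cm), for protons in water.
#'
#' @param R0 Range, cm (vectorized, >= 0).
#' @return Straggling sigma, cm.
#' @export
straggling_sigma <- function(R0) {
  stopifnot(is.numeric(R0))
  if (any(R0 < 0)) stop("R0 must be non-negative")
  0.012 * R0^0.935
}
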