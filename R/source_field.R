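# Voxelized thermoacoustic source: the separable deposited-energy density
#   eps(r) = N * Lambda(z) * G2(x, y; sigma_lat)        [J/m^3 * m^3 = J]
# with Lambda(z) the linear energy deposition per proton (from the depth
# dose) and G2 a unit-mass transverse Gaussian. The time structure is a
# normalized Gaussian heating-rate kernel handled analytically by the
# Kirchhoff solver.

#' Build a voxelized thermoacoustic source from a depth-dose profile
#'
#' Assembles the 3-D deposited-energy field for a beam entering the
#' medium at the origin and travelling along +z: depth profile from the
#' Bragg curve, transverse Gaussian of the beam's lateral sigma,
#' truncated at `trunc_sigma` lateral sigmas (< 1e-5 of the Gaussian
#' mass discarded at the default 5). The voxel energies are rescaled so
#' that their sum equals the 1-D quadrature of the deposited energy,
#' removing voxelization bias.
#'
#' @param profile A [dose_profile()] (straggling on recommended).
#' @param beam The [beam_pulse()] (supplies protons per pulse, lateral
#'   width and the temporal kernel width).
#' @param medium An [acoustic_medium()].
#' @param voxel_size Voxel edge, m. Must resolve both the lateral sigma
#'   and the straggling sigma: `voxel_size <= min(lateral, straggle)/4`.
#'   Default: exactly that bound.
#' @param trunc_sigma Lateral truncation, in sigmas (default 5).
#' @return Object of class `source_field`: voxel `centers` (N x 3
#'   matrix, m), `energy_j` (J per voxel), `voxel_size`, `sigma_t` (s),
#'   `total_energy_j`, `medium`.
#' @export
build_source <- function(profile, beam = profile$beam,
                         medium = medium_water(),
                         voxel_size = NULL, trunc_sigma = 5) {
  stopifnot(inherits(profile, "depth_dose_profile"),
            inherits(beam, "beam_pulse"),
            inherits(medium, "acoustic_medium"))
  lat_m <- beam$lateral_sigma_mm * MM_TO_M
  str_m <- profile$sigma_straggle * CM_TO_M
  vmax <- min(lat_m, str_m) / 4
  if (is.null(voxel_size)) voxel_size <- vmax
  if (voxel_size > vmax * (1 + 1e-12))
    stop(sprintf(paste("voxel_size %.3g m too coarse: must be <= min(lateral sigma %.3g m,",
                       "straggling sigma %.3g m)/4 = %.3g m"),
                 voxel_size, lat_m, str_m, vmax))

  # linear energy deposition per proton along depth, J/m
  lambda_j_per_m <- profile$rho * profile$dose_per_fluence * MEV_TO_J / CM_TO_M

  z_m <- profile$z * CM_TO_M
  zv <- seq(voxel_size / 2, max(z_m), by = voxel_size)
  lam_v <- stats::approx(z_m, lambda_j_per_m, xout = zv, rule = 2)$y

  half <- trunc_sigma * lat_m
  xv <- seq(-half, half, by = voxel_size)
  gx <- exp(-xv^2 / (2 * lat_m^2))
  gx <- gx / sum(gx)                      # unit-mass transverse weights

  nx <- length(xv); nz <- length(zv)
  centers <- cbind(
    x = rep(xv, times = nx * nz),
    y = rep(rep(xv, each = nx), times = nz),
    z = rep(zv, each = nx * nx)
  )
  wxy <- as.numeric(outer(gx, gx))        # length nx^2, sums to 1
  energy <- as.numeric(outer(wxy, beam$n_protons * lam_v * voxel_size))

  # rescale to the 1-D quadrature of the deposited energy (trapezoid)
  e_total <- beam$n_protons *
    sum(diff(z_m) * (head(lambda_j_per_m, -1) + tail(lambda_j_per_m, -1)) / 2)
  s <- sum(energy)
  if (s > 0) energy <- energy * (e_total / s)

  structure(list(
    centers = centers,
    energy_j = energy,
    voxel_size = voxel_size,
    sigma_t = beam$sigma_t,
    total_energy_j = e_total,
    medium = medium,
    beam = beam
  ), class = "source_field")
}

#' @export
print.source_field <- function(x, ...) {
  cat(sprintf("<source_field> %d voxels of %.3g mm, total %.4g J, sigma_t = %g us\n",
              nrow(x$centers), x$voxel_size / MM_TO_M, x$total_energy_j,
              x$sigma_t * 1e6))
  invisible(x)
}

#' Position of the Bragg peak of a source field
#'
#' Depth (m, along +z from the entrance plane, on the beam axis x=y=0)
#' of the maximum of the depth-dose profile used to build the source.
#'
#' @param profile A [dose_profile()].
#' @return 3-vector (m) of the peak position in source coordinates.
#' @export
bragg_peak_position <- function(profile) {
  stopifnot(inherits(profile, "depth_dose_profile"))
  c(0, 0, profile$z[which.max(profile$dose_per_fluence)] * CM_TO_M)
}
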