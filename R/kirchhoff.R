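# Kirchhoff-integral solution of the thermoacoustic wave equation for a
# voxelized source with a separable Gaussian heating-rate kernel g(t):
#   p(r, t) = alpha'/(4 pi C_p) * sum_v  E_v / |r - r_v| *
#             gdot(t - |r - r_v|/c_s)
# where gdot is the time derivative of the normalized heating rate (the
# second derivative of the cumulative deposited-energy time profile), so
# a Gaussian heating pulse yields the characteristic bipolar waveform.

# normalized Gaussian heating rate centred at t = 0 and its derivative
gauss_rate <- function(t, sigma_t) {
  exp(-t^2 / (2 * sigma_t^2)) / (sigma_t * sqrt(2 * pi))
}
gauss_rate_deriv <- function(t, sigma_t) {
  -t / sigma_t^2 * gauss_rate(t, sigma_t)
}

# full linear convolution via FFT
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nfft <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(a, numeric(nfft - length(a)))) *
                  stats::fft(c(b, numeric(nfft - length(b)))),
                inverse = TRUE))[seq_len(n)] / nfft
}

#' Thermoacoustic pressure at a sensor (Kirchhoff integral)
#'
#' Evaluates the retarded-time Kirchhoff sum over the source voxels on a
#' uniform time grid. Per-voxel arrival times are deposited onto the
#' time grid by linear binning, which is exactly equivalent to linear
#' interpolation of the (smooth, analytic) kernel derivative between
#' samples; the sum then reduces to one linear convolution.
#'
#' @param source A [build_source()] result.
#' @param sensor_pos Sensor position, 3-vector, m (source frame: beam
#'   enters at the origin along +z).
#' @param t_grid Uniform time grid, s; t = 0 is the centre of the
#'   heating pulse, so a point at distance d contributes around
#'   t = d / c_s.
#' @param medium An [acoustic_medium()]; defaults to the source's.
#' @return A [pressure_signal()] (Pa).
#' @export
kirchhoff_pressure <- function(source, sensor_pos, t_grid,
                               medium = source$medium) {
  stopifnot(inherits(source, "source_field"), length(sensor_pos) == 3L,
            is.numeric(t_grid), length(t_grid) >= 2L,
            inherits(medium, "acoustic_medium"))
  dt <- diff(t_grid[1:2])
  if (any(abs(diff(t_grid) - dt) > 1e-9 * dt))
    stop("t_grid must be uniform")

  n <- length(t_grid)
  nv <- nrow(source$centers)
  chunk <- 2e6
  tau <- numeric(nv); amp <- numeric(nv)
  for (i0 in seq(1L, nv, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nv)
    dx <- source$centers[i0:i1, 1] - sensor_pos[1]
    dy <- source$centers[i0:i1, 2] - sensor_pos[2]
    dz <- source$centers[i0:i1, 3] - sensor_pos[3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    if (any(d < source$voxel_size))
      stop("sensor lies inside the source region (distance < voxel_size): singular kernel")
    tau[i0:i1] <- d / medium$c_s
    amp[i0:i1] <- source$energy_j[i0:i1] / d
  }
  amp <- amp * medium$alpha_exp / (4 * pi * medium$C_p)

  # linear binning of (tau, amp) onto a dt grid anchored at min(tau)
  tau0 <- min(tau)
  pos <- (tau - tau0) / dt
  i0b <- floor(pos)
  frac <- pos - i0b
  nb <- max(i0b) + 2L
  h <- numeric(nb)
  acc <- rowsum(c(amp * (1 - frac), amp * frac),
                group = c(i0b + 1L, i0b + 2L))
  h[as.integer(rownames(acc))] <- acc[, 1]

  # kernel-derivative samples at every needed lag
  q <- seq.int(-(nb - 1L), n - 1L)
  g2 <- gauss_rate_deriv(t_grid[1] - tau0 + q * dt, source$sigma_t)
  p <- conv_full(h, g2)[seq.int(nb, nb + n - 1L)]
  pressure_signal(p, fs = 1 / dt, t0 = t_grid[1])
}
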