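# Time-delay estimation by (generalized) cross-correlation. The
# correlation is computed in the frequency domain on zero-padded
# transforms (no circular wrap-around); plain weighting is standard
# cross-correlation, PHAT and SCOT whiten the cross-spectrum.

#' Generalized cross-correlation of two signals
#'
#' Computes \eqn{R(\tau) = \mathcal{F}^{-1}[\varphi(f)\,\hat G_{x_j x_i}(f)]}
#' where \eqn{\hat G} is the cross-spectrum estimate and \eqn{\varphi}
#' the weighting. With `weighting = "plain"`, \eqn{\varphi = 1} and the
#' result equals time-domain cross-correlation. A positive-lag maximum
#' means `x_j` lags `x_i`.
#'
#' @param x_i,x_j [pressure_signal()]s with equal sample rates.
#' @param weighting `"plain"` (default), `"phat"` (1/|G|) or `"scot"`
#'   (1/sqrt(Gxx Gyy)).
#' @param prefilter_band Optional `c(f_lo, f_hi)` in Hz: a zero-phase
#'   band-pass mask applied identically to both spectra (peak location
#'   preserving). Default none.
#' @return Object of class `correlation_function`: `lags` (s, symmetric
#'   about 0), `values`, `weighting`, `prefilter_band`.
#' @export
gcc <- function(x_i, x_j, weighting = c("plain", "phat", "scot"),
                prefilter_band = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(x_i, "pressure_signal"), inherits(x_j, "pressure_signal"))
  if (abs(x_i$fs - x_j$fs) > 1e-9 * x_i$fs)
    stop("signals must share the same sample rate")
  a <- x_i$samples; b <- x_j$samples
  if (all(a == 0) || all(b == 0))
    stop("all-zero input signal: correlation peak undefined")
  n <- max(length(a), length(b))
  nfft <- stats::nextn(2L * n, 2)
  A <- stats::fft(c(a, numeric(nfft - length(a))))
  B <- stats::fft(c(b, numeric(nfft - length(b))))

  if (!is.null(prefilter_band)) {
    stopifnot(length(prefilter_band) == 2L, prefilter_band[1] < prefilter_band[2])
    f <- (seq_len(nfft) - 1) / nfft * x_i$fs
    f <- pmin(f, x_i$fs - f)                      # two-sided frequency
    mask <- as.numeric(f >= prefilter_band[1] & f <= prefilter_band[2])
    A <- A * mask; B <- B * mask
    if (all(mask * Mod(A) == 0) || all(mask * Mod(B) == 0))
      stop("prefilter band removes all signal energy")
  }

  G <- B * Conj(A)
  W <- switch(weighting,
    plain = rep(1, nfft),
    phat = {
      m <- Mod(G)
      1 / pmax(m, 1e-12 * max(m))
    },
    scot = {
      m <- Mod(A) * Mod(B)
      1 / pmax(m, 1e-12 * max(m))
    })
  r <- Re(stats::fft(G * W, inverse = TRUE)) / nfft

  lags_n <- seq.int(-(n - 1L), n - 1L)
  idx <- ifelse(lags_n >= 0, lags_n + 1L, nfft + lags_n + 1L)
  structure(list(
    lags = lags_n / x_i$fs,
    values = r[idx],
    weighting = weighting,
    prefilter_band = prefilter_band
  ), class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  imax <- which.max(x$values)
  cat(sprintf("<correlation_function> %s weighting, %d lags, peak at %g us\n",
              x$weighting, length(x$lags), x$lags[imax] * 1e6))
  invisible(x)
}

#' Time-of-arrival estimate from a waveform pair
#'
#' The TOA is the lag that maximizes the (generalized) cross-correlation
#' between the emitted and received signals; with `subsample = TRUE` a
#' three-point parabolic fit around the discrete peak refines the
#' estimate below one sample. Differing record start times (`t0`) are
#' accounted for. The estimate carries a `quality` attribute (ratio of
#' the peak to the largest correlation value more than 5 samples away)
#' and an `unreliable` flag when the peak sits on the lag-range boundary.
#'
#' @param emitted,received [pressure_signal()]s with equal sample rates.
#' @param weighting,prefilter_band Passed to [gcc()].
#' @param subsample Logical: parabolic sub-sample refinement (default
#'   TRUE).
#' @return Delay of `received` relative to `emitted`, s.
#' @export
estimate_toa <- function(emitted, received,
                         weighting = c("plain", "phat", "scot"),
                         subsample = TRUE, prefilter_band = NULL) {
  cf <- gcc(emitted, received, weighting = weighting,
            prefilter_band = prefilter_band)
  imax <- which.max(cf$values)
  nl <- length(cf$lags)
  unreliable <- imax == 1L || imax == nl
  if (unreliable)
    warning("correlation peak at the lag-range boundary: estimate unreliable")
  lag <- cf$lags[imax]
  if (subsample && !unreliable) {
    y1 <- cf$values[imax - 1L]; y2 <- cf$values[imax]; y3 <- cf$values[imax + 1L]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {                         # proper maximum curvature
      delta <- 0.5 * (y1 - y3) / den
      lag <- lag + delta * (cf$lags[2] - cf$lags[1])
    }
  }
  far <- abs(cf$lags - cf$lags[imax]) > 5 / emitted$fs
  quality <- if (any(far)) cf$values[imax] / max(abs(cf$values[far])) else Inf
  structure(lag + (received$t0 - emitted$t0),
            quality = quality, unreliable = unreliable)
}

#' TDOAs relative to a reference sensor
#'
#' Converts per-sensor TOAs to time differences of arrival
#' \eqn{\tau_{i1} = t_i - t_{ref}}; invariant under any common additive
#' offset in the TOAs.
#'
#' @param toas Numeric vector of TOAs, s (length >= 2).
#' @param ref_index Index of the reference ("first") sensor.
#' @param quality Optional per-TOA quality values, stored alongside.
#' @return Object of class `tdoa_set`: `tau` (same length as `toas`,
#'   zero at `ref_index`), `ref_index`, `quality`.
#' @export
#' @examples
#' tdoas_from_toas(c(10, 12, 15) * 1e-6)$tau * 1e6   # 0 2 5
tdoas_from_toas <- function(toas, ref_index = 1L, quality = NULL) {
  stopifnot(is.numeric(toas), length(toas) >= 2L)
  if (ref_index < 1L || ref_index > length(toas))
    stop("ref_index out of range")
  structure(list(
    tau = as.numeric(toas) - toas[ref_index],
    ref_index = as.integer(ref_index),
    quality = quality
  ), class = "tdoa_set")
}

#' @export
print.tdoa_set <- function(x, ...) {
  cat(sprintf("<tdoa_set> %d sensors, ref = %d, tau (us): %s\n",
              length(x$tau), x$ref_index,
              paste(sprintf("%.3f", x$tau * 1e6), collapse = " ")))
  invisible(x)
}
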