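#' Uniformly sampled pressure waveform
#'
#' @param samples Pressure samples, Pa (finite numeric vector).
#' @param fs Sample rate, Hz (> 0; acquisition default 10 MS/s).
#' @param t0 Time of the first sample, s.
#' @return Object of class `pressure_signal`.
#' @export
pressure_signal <- function(samples, fs = DEFAULT_FS, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0,
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!all(is.finite(samples))) stop("pressure samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "pressure_signal")
}

#' Time axis of a pressure signal
#' @param sig A [pressure_signal()].
#' @return Sample times, s.
#' @export
signal_time <- function(sig) {
  stopifnot(inherits(sig, "pressure_signal"))
  sig$t0 + (seq_along(sig$samples) - 1) / sig$fs
}

#' @export
print.pressure_signal <- function(x, ...) {
  cat(sprintf("<pressure_signal> %d samples @ %g MS/s, t0 = %g us, peak |p| = %.4g Pa\n",
              length(x$samples), x$fs / 1e6, x$t0 * 1e6, max(abs(x$samples))))
  invisible(x)
}
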