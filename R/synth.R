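# Synthetic acquisition: the emitted thermoacoustic pulse is embedded in
# a long record, delayed to each sensor by the exact propagation time
# (band-limited fractional-sample delay), scaled 1/r, and corrupted by
# white Gaussian noise at a stated per-channel SNR. This emulates the
# tank acquisition: 10 MS/s, 500 us records, known emitted pulse.

# exact band-limited fractional delay of a real record (frequency-domain
# linear phase); delay in seconds, record assumed long enough that the
# circularly wrapped tail carries no energy
frac_delay <- function(x, fs, delay_s) {
  n <- length(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  ph <- exp(-2i * pi * k * fs / n * delay_s)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1])  # real Nyquist bin
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE)) / n
}

# RMS over the signal's effective support (above 1% of peak magnitude)
support_rms <- function(x) {
  s <- abs(x) > 0.01 * max(abs(x))
  sqrt(mean(x[s]^2))
}

#' Synthesize received signals for a sensor array
#'
#' Builds one record per sensor: the emitted pulse delayed by the exact
#' propagation time `|sensor - source| / c_s` (band-limited
#' fractional-sample delay), scaled by 1/r, plus white Gaussian noise at
#' the stated per-channel SNR (noise sigma set from the clean channel's
#' RMS over its effective support). All randomness is governed by
#' `seed`; the same seed gives bit-identical records.
#'
#' @param pulse A [pressure_signal()] holding the emitted pulse shape;
#'   its sample rate must equal `fs`.
#' @param source_pos Source position, 3-vector, m.
#' @param array A [sensor_array()].
#' @param medium An [acoustic_medium()] (supplies c_s).
#' @param fs Sample rate, Hz (default 10 MS/s).
#' @param duration Record length, s (default 500 us). Must cover the
#'   emission time plus the largest propagation delay plus the pulse.
#' @param snr_db Per-channel SNR in dB; `Inf` (default) for noiseless.
#' @param seed Integer seed for the noise generator (optional).
#' @param emit_time Offset of the pulse within the emitted record, s.
#' @return Object of class `synth_set`: `emitted` (the clean reference
#'   record), `received` (list of [pressure_signal()]), `delays` (true
#'   propagation delays, s), plus the generation parameters.
#' @export
synthesize_received_signals <- function(pulse, source_pos, array,
                                        medium = medium_water(),
                                        fs = DEFAULT_FS,
                                        duration = DEFAULT_DURATION,
                                        snr_db = Inf, seed = NULL,
                                        emit_time = 5e-5) {
  stopifnot(inherits(pulse, "pressure_signal"), inherits(array, "sensor_array"),
            inherits(medium, "acoustic_medium"), length(source_pos) == 3L)
  if (abs(pulse$fs - fs) > 1e-6 * fs)
    stop("pulse sample rate must equal the acquisition rate fs")
  d <- sensor_distances(source_pos, array)
  delays <- d / medium$c_s
  n <- round(duration * fs)
  np <- length(pulse$samples)
  needed <- emit_time + max(delays) + np / fs + 10e-6
  if (duration < needed)
    stop(sprintf("duration %.1f us too short: need at least %.1f us (emission + max delay + pulse)",
                 duration * 1e6, needed * 1e6))

  emitted <- numeric(n)
  k0 <- round(emit_time * fs)
  emitted[k0 + seq_len(np)] <- pulse$samples

  if (!is.null(seed)) set.seed(seed)
  received <- vector("list", nrow(array$positions))
  for (i in seq_along(received)) {
    clean <- frac_delay(emitted, fs, delays[i]) / d[i]
    if (is.finite(snr_db)) {
      sd_noise <- support_rms(clean) * 10^(-snr_db / 20)
      clean <- clean + stats::rnorm(n, sd = sd_noise)
    }
    received[[i]] <- pressure_signal(clean, fs = fs, t0 = 0)
  }
  structure(list(
    emitted = pressure_signal(emitted, fs = fs, t0 = 0),
    received = received,
    delays = delays,
    snr_db = snr_db,
    seed = seed,
    emit_time = emit_time
  ), class = "synth_set")
}

#' @export
print.synth_set <- function(x, ...) {
  cat(sprintf("<synth_set> %d channels, SNR %s dB, delays %.1f-%.1f us\n",
              length(x$received), format(x$snr_db),
              min(x$delays) * 1e6, max(x$delays) * 1e6))
  invisible(x)
}
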