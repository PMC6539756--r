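# Seeded study drivers: solver-convergence study, cube-array simulation
# study (TOA-jitter noise, Table-2-style aggregation) and the full
# signal-level tank surrogate (Table-4-style aggregation).

# exact TOAs with optional Gaussian jitter and sampling quantization
simulate_toas <- function(array, source, c_s = WATER_SOUND_SPEED,
                          jitter_sigma = 0, fs_quant = NULL) {
  toas <- sensor_distances(source, array) / c_s
  if (jitter_sigma > 0) toas <- toas + stats::rnorm(length(toas), sd = jitter_sigma)
  if (!is.null(fs_quant)) toas <- round(toas * fs_quant) / fs_quant
  toas
}

#' Convergence of the solver versus initialization distance
#'
#' For each trial an initial guess is drawn uniformly in a box around
#' the array, the solver is run on noiseless TDOAs, and the initial
#' distance, final error and convergence flag are recorded (the layout
#' of the 10,000-run scatter study).
#'
#' @param array A [sensor_array()].
#' @param source True source position, 3-vector, m.
#' @param bounds 2 x 3 matrix of lower/upper corners for the initial
#'   guess box, m; default the array bounding box.
#' @param n_sim Number of trials (default 10000).
#' @param c_s Sound speed, m/s.
#' @param seed Integer seed.
#' @return Object of class `convergence_table`: data.frame with columns
#'   `d0` (initial distance, m), `err` (final error, m), `converged`,
#'   `iterations`; attributes record the configuration.
#' @export
run_convergence_study <- function(array, source, bounds = NULL,
                                  n_sim = 10000L, c_s = WATER_SOUND_SPEED,
                                  seed = 1L) {
  stopifnot(inherits(array, "sensor_array"), n_sim >= 1L)
  if (is.null(bounds)) bounds <- apply(array$positions, 2, range)
  stopifnot(is.matrix(bounds), nrow(bounds) == 2L, ncol(bounds) == 3L)
  tdoas <- tdoas_from_toas(simulate_toas(array, source, c_s),
                           ref_index = array$ref_index)
  set.seed(seed)
  x0s <- cbind(stats::runif(n_sim, bounds[1, 1], bounds[2, 1]),
               stats::runif(n_sim, bounds[1, 2], bounds[2, 2]),
               stats::runif(n_sim, bounds[1, 3], bounds[2, 3]))
  out <- data.frame(d0 = numeric(n_sim), err = numeric(n_sim),
                    converged = logical(n_sim), iterations = integer(n_sim))
  for (k in seq_len(n_sim)) {
    res <- localize(array, tdoas, c_s = c_s, x0 = x0s[k, ], tol = 1e-9)
    out$d0[k] <- sqrt(sum((x0s[k, ] - source)^2))
    out$err[k] <- sqrt(sum((res$position - source)^2))
    out$converged[k] <- res$converged && out$err[k] < 1e-6
    out$iterations[k] <- res$iterations
  }
  structure(out, class = c("convergence_table", "data.frame"),
            source = source, bounds = bounds, seed = seed, c_s = c_s)
}

#' Cube-array localization study
#'
#' For every cube edge `H` and every source, simulates TOAs at `c_s`,
#' applies the noise model (Gaussian TOA jitter, then quantization to
#' the sampling grid), reconstructs the source with the Gauss-Newton
#' solver from the centroid start, and aggregates mean and standard
#' deviation per coordinate over the converged repeats.
#'
#' The default noise model is Gaussian TOA jitter with sigma of one
#' sample period at 10 MS/s (0.1 us, about 0.15 mm of range), plus
#' quantization to that sampling grid.
#'
#' @param H_list_mm Cube edges, mm (default 300-700, matching cube
#'   volumes of 27 to 343 litres).
#' @param sources Source positions, matrix with one 3-vector row, m
#'   (default [cube_sources()]).
#' @param jitter_sigma TOA jitter sigma, s.
#' @param fs_quant Sampling rate used for TOA quantization, Hz (NULL to
#'   disable).
#' @param n_repeats Repeats per (H, source) case (default 20).
#' @param c_s Sound speed, m/s.
#' @param seed Integer seed.
#' @return Object of class `study_result`: `summary` data.frame (one
#'   row per source x volume: per-coordinate mean +/- SD in mm,
#'   convergence counts, mean and max 3-D error), `trials` data.frame
#'   (per-trial errors), and the configuration.
#' @export
run_cube_study <- function(H_list_mm = c(300, 400, 500, 600, 700),
                           sources = cube_sources(),
                           jitter_sigma = 1e-7, fs_quant = DEFAULT_FS,
                           n_repeats = 20L, c_s = WATER_SOUND_SPEED,
                           seed = 1L) {
  stopifnot(length(H_list_mm) >= 1L, n_repeats >= 1L)
  if (is.null(dim(sources))) sources <- matrix(sources, 1L)
  set.seed(seed)
  summ <- NULL; trials <- NULL
  for (H in H_list_mm) {
    array <- cube_geometry(H)
    lo <- apply(array$positions, 2, min); hi <- apply(array$positions, 2, max)
    for (si in seq_len(nrow(sources))) {
      src <- sources[si, ]
      if (any(src < lo) || any(src > hi))
        warning(sprintf("source %d outside the sensor hull for H = %g mm", si, H))
      est <- matrix(NA_real_, n_repeats, 3L)
      conv <- logical(n_repeats)
      for (r in seq_len(n_repeats)) {
        toas <- simulate_toas(array, src, c_s, jitter_sigma, fs_quant)
        res <- localize(array, tdoas_from_toas(toas, array$ref_index), c_s = c_s)
        conv[r] <- res$converged
        if (res$converged) est[r, ] <- res$position
      }
      ok <- which(conv)
      if (!length(ok)) {
        err_mm <- NA_real_
        m <- s <- rep(NA_real_, 3L)
      } else {
        err_mm <- sqrt(rowSums((est[ok, , drop = FALSE] -
                                  matrix(src, length(ok), 3L, byrow = TRUE))^2)) / MM_TO_M
        m <- colMeans(est[ok, , drop = FALSE]) / MM_TO_M
        s <- apply(est[ok, , drop = FALSE], 2, stats::sd) / MM_TO_M
      }
      summ <- rbind(summ, data.frame(
        source = si, H_mm = H, volume_m3 = (H * MM_TO_M)^3,
        x_true_mm = src[1] / MM_TO_M, y_true_mm = src[2] / MM_TO_M,
        z_true_mm = src[3] / MM_TO_M,
        x_mm = m[1], y_mm = m[2], z_mm = m[3],
        x_sd_mm = s[1], y_sd_mm = s[2], z_sd_mm = s[3],
        n_converged = length(ok), n_repeats = n_repeats,
        mean_err_mm = mean(err_mm), max_err_mm = max(err_mm)))
      if (length(ok))
        trials <- rbind(trials, data.frame(
          source = si, H_mm = H, repeat_i = ok, err_mm = err_mm))
    }
  }
  structure(list(summary = summ, trials = trials,
                 config = list(H_list_mm = H_list_mm,
                               jitter_sigma = jitter_sigma,
                               fs_quant = fs_quant, n_repeats = n_repeats,
                               c_s = c_s, seed = seed, kind = "cube")),
            class = "study_result")
}

#' Water-tank surrogate study (full signal-level chain)
#'
#' Synthetic surrogate of the tank experiment: the thermoacoustic pulse
#' of the reference beam is computed once with the Kirchhoff solver,
#' then for each repeat the 12 channel records are synthesized with
#' exact propagation delays, 1/r scaling and per-channel noise, TOAs
#' are estimated by correlation argmax with parabolic refinement, and
#' each sensor group is localized.
#'
#' @param groups List of sensor index vectors (default [tank_groups()]);
#'   every group needs at least 4 sensors.
#' @param snr_db Per-channel SNR, dB (default 20; `Inf` noiseless).
#' @param n_repeats Seeded repeats (default 20).
#' @param beam,model Beam and stopping model for the pulse (defaults:
#'   the 100 MeV reference spill).
#' @param medium An [acoustic_medium()].
#' @param fs,duration Acquisition rate (Hz) and record length (s).
#' @param voxel_size Kirchhoff voxel size, m (default: resolution bound
#'   of [build_source()]).
#' @param sensor_offset_m Distance from the Bragg peak at which the
#'   emitted-pulse template is computed, m (default 0.04).
#' @param seed Integer seed; repeat r uses `seed + r`.
#' @return Object of class `study_result`: `summary` (one row per
#'   group: per-coordinate mean +/- SD in cm, Table-4 layout, plus
#'   median/max 3-D error in mm), `trials` (per repeat x group), and
#'   the configuration.
#' @export
run_tank_study <- function(groups = tank_groups(), snr_db = 20,
                           n_repeats = 20L, beam = beam_pulse(),
                           model = stopping_model(),
                           medium = medium_water(), fs = DEFAULT_FS,
                           duration = DEFAULT_DURATION, voxel_size = NULL,
                           sensor_offset_m = 0.04, seed = 1L) {
  stopifnot(is.list(groups), n_repeats >= 1L)
  if (any(vapply(groups, length, 0L) < 4L))
    stop("every sensor group needs at least 4 sensors")
  geom <- tank_geometry()
  if (any(unlist(groups) < 1L) || any(unlist(groups) > nrow(geom$array$positions)))
    stop("group indices must lie in 1..12")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))

  pulse <- tank_pulse(beam, model, medium, fs, voxel_size, sensor_offset_m)

  src <- geom$source
  gn <- names(groups)
  est <- array(NA_real_, c(n_repeats, length(groups), 3L),
               dimnames = list(NULL, gn, c("x", "y", "z")))
  conv <- matrix(FALSE, n_repeats, length(groups), dimnames = list(NULL, gn))
  for (r in seq_len(n_repeats)) {
    ss <- synthesize_received_signals(pulse, src, geom$array, medium,
                                      fs = fs, duration = duration,
                                      snr_db = snr_db, seed = seed + r)
    toas <- vapply(ss$received, function(ch)
      as.numeric(estimate_toa(ss$emitted, ch)), 0)
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      sub <- sensor_array(geom$array$positions[idx, , drop = FALSE])
      res <- localize(sub, tdoas_from_toas(toas[idx]), c_s = medium$c_s)
      conv[r, gi] <- res$converged
      if (res$converged) est[r, gi, ] <- res$position
    }
  }
  summ <- NULL; trials <- NULL
  for (gi in seq_along(groups)) {
    ok <- which(conv[, gi])
    e <- est[ok, gi, , drop = FALSE]
    dim(e) <- c(length(ok), 3L)
    err_mm <- if (length(ok))
      sqrt(rowSums((e - matrix(src, length(ok), 3L, byrow = TRUE))^2)) / MM_TO_M
    else NA_real_
    cm <- function(v) if (length(v)) mean(v) / CM_TO_M else NA_real_
    cs <- function(v) if (length(v) > 1) stats::sd(v) / CM_TO_M else NA_real_
    summ <- rbind(summ, data.frame(
      group = gn[gi], n_sensors = length(groups[[gi]]),
      sensors = paste(groups[[gi]], collapse = ","),
      x_cm = cm(e[, 1]), x_sd_cm = cs(e[, 1]),
      y_cm = cm(e[, 2]), y_sd_cm = cs(e[, 2]),
      z_cm = cm(e[, 3]), z_sd_cm = cs(e[, 3]),
      n_converged = length(ok), n_repeats = n_repeats,
      median_err_mm = stats::median(err_mm), max_err_mm = max(err_mm)))
    if (length(ok))
      trials <- rbind(trials, data.frame(group = gn[gi], repeat_i = ok,
                                         err_mm = err_mm))
  }
  structure(list(summary = summ, trials = trials,
                 config = list(snr_db = snr_db, n_repeats = n_repeats,
                               fs = fs, duration = duration,
                               sensor_offset_m = sensor_offset_m,
                               c_s = medium$c_s, seed = seed,
                               energy_mev = beam$energy_mev, kind = "tank")),
            class = "study_result")
}

# emitted-pulse template: Kirchhoff waveform at a sensor on the beam
# axis sensor_offset_m beyond the Bragg peak, trimmed to its support
tank_pulse <- function(beam = beam_pulse(), model = stopping_model(),
                       medium = medium_water(), fs = DEFAULT_FS,
                       voxel_size = NULL, sensor_offset_m = 0.04) {
  prof <- dose_profile(beam, model)
  source <- build_source(prof, beam, medium, voxel_size = voxel_size)
  peak <- bragg_peak_position(prof)
  sensor <- peak + c(0, 0, sensor_offset_m)
  t_arr <- sensor_offset_m / medium$c_s
  span <- 12 * beam$sigma_t + (prof$R0 * CM_TO_M) / medium$c_s
  t_grid <- seq(max(0, t_arr - span), t_arr + span, by = 1 / fs)
  p <- kirchhoff_pressure(source, sensor, t_grid, medium)
  keep <- which(abs(p$samples) > 1e-4 * max(abs(p$samples)))
  pressure_signal(p$samples[min(keep):max(keep)], fs = fs,
                  t0 = p$t0 + (min(keep) - 1) / fs)
}

#' Solver timing study
#'
#' Reports (never asserts: wall-clock is hardware-dependent) the
#' Gauss-Newton runtime for different sensor counts and cube sizes on
#' noiseless TDOAs.
#'
#' @param sensor_counts Sensor counts (4-12).
#' @param H_list_mm Cube edges, mm.
#' @param n_repeats Localizations timed per configuration.
#' @param source Source position, m.
#' @return data.frame with one row per (count, H): mean seconds per
#'   solve and the (deterministic) iteration count.
#' @export
run_timing_study <- function(sensor_counts = c(4L, 6L, 8L, 10L, 12L),
                             H_list_mm = c(300, 400, 500, 600, 700),
                             n_repeats = 20L,
                             source = c(0.1, 0.1, 0.1)) {
  out <- NULL
  for (m in sensor_counts) {
    for (H in H_list_mm) {
      array <- cube_geometry_n(H, m)
      tdoas <- tdoas_from_toas(simulate_toas(array, source),
                               ref_index = array$ref_index)
      tm <- system.time(for (r in seq_len(n_repeats))
        res <- localize(array, tdoas))[["elapsed"]]
      out <- rbind(out, data.frame(n_sensors = m, H_mm = H,
                                   seconds_per_solve = tm / n_repeats,
                                   iterations = res$iterations))
    }
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s study, seed %d\n", x$config$kind, x$config$seed))
  print(x$summary, digits = 4)
  invisible(x)
}
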