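# Study drivers and synthetic acquisition. Scaled-down repeat counts are
# used here to keep the suite fast; the acceptance tests run the sizes
# the studies prescribe.

small_pulse <- function(fs = 1e7) {
  t <- seq(-6e-6, 6e-6, by = 1 / fs)
  pressure_signal(-t / 1e-12 * exp(-t^2 / (2 * 1e-12)), fs = fs)
}

test_that("synthesized channels carry the exact geometric delay", {
  pos <- rbind(c(0.1, 0, 0), c(0, 0.15, 0), c(0, 0, 0.2), c(0.1, 0.1, 0.1))
  array <- sensor_array(pos)
  ss <- synthesize_received_signals(small_pulse(), c(0, 0, 0), array,
                                    duration = 3e-4, snr_db = Inf)
  # channel 1 at 0.1 m: delay 67.02 us, within one sample
  toa <- as.numeric(estimate_toa(ss$emitted, ss$received[[1]]))
  expect_equal(toa, 0.1 / 1492, tolerance = 1e-7 / (0.1 / 1492))
  expect_equal(ss$delays[1], 0.1 / 1492)
  # 1/r amplitude scaling between channels 1 (0.1 m) and 3 (0.2 m)
  expect_equal(max(abs(ss$received[[1]]$samples)) /
                 max(abs(ss$received[[3]]$samples)), 2, tolerance = 0.01)
})

test_that("synthesis is bit-identical under a fixed seed", {
  array <- cube_geometry(300)
  s1 <- synthesize_received_signals(small_pulse(), c(0.1, 0.1, 0.1), array,
                                    snr_db = 10, seed = 5)
  s2 <- synthesize_received_signals(small_pulse(), c(0.1, 0.1, 0.1), array,
                                    snr_db = 10, seed = 5)
  s3 <- synthesize_received_signals(small_pulse(), c(0.1, 0.1, 0.1), array,
                                    snr_db = 10, seed = 6)
  expect_identical(s1$received[[2]]$samples, s2$received[[2]]$samples)
  expect_false(identical(s1$received[[2]]$samples, s3$received[[2]]$samples))
})

test_that("too-short records are refused with the required minimum named", {
  array <- cube_geometry(300)
  expect_error(
    synthesize_received_signals(small_pulse(), c(0.1, 0.1, 0.1), array,
                                duration = 6e-5),
    "need at least")
})

test_that("TOA scatter grows when the SNR drops (paired seeds)", {
  array <- cube_geometry(300)
  src <- c(0.1, 0.1, 0.1)
  rms_at <- function(snr) {
    errs <- vapply(1:40, function(r) {
      ss <- synthesize_received_signals(small_pulse(), src, array,
                                        duration = 3e-4, snr_db = snr,
                                        seed = 100 + r)
      as.numeric(estimate_toa(ss$emitted, ss$received[[1]])) - ss$delays[1]
    }, 0)
    sqrt(mean(errs^2))
  }
  expect_gt(rms_at(0), rms_at(40))
})

test_that("convergence study: exact starts converge immediately, wide starts do not", {
  array <- cube_geometry(400)
  src <- c(0.1, 0.1, 0.1)
  at_truth <- run_convergence_study(array, src,
                                    bounds = rbind(src, src), n_sim = 5,
                                    seed = 3)
  expect_true(all(at_truth$converged))
  expect_true(all(at_truth$iterations <= 2))
  expect_true(all(at_truth$err < 1e-9))

  frac <- vapply(c(1, 3, 10), function(scale) {
    ctr <- colMeans(array$positions)
    half <- scale * 0.2
    b <- rbind(ctr - half, ctr + half)
    mean(run_convergence_study(array, src, bounds = b, n_sim = 150,
                               seed = 17)$converged)
  }, 0)
  expect_true(all(diff(frac) <= 0))
  expect_gt(frac[1], frac[3])
})

test_that("noiseless cube study recovers every source exactly", {
  res <- suppressWarnings(
    run_cube_study(H_list_mm = c(300, 500), jitter_sigma = 0,
                   fs_quant = NULL, n_repeats = 1, seed = 1))
  expect_equal(nrow(res$summary), 6L)
  expect_true(all(res$summary$n_converged == 1L))
  expect_lt(max(abs(res$summary$x_mm - res$summary$x_true_mm)), 1e-6)
  expect_lt(max(abs(res$summary$y_mm - res$summary$y_true_mm)), 1e-6)
  expect_lt(max(abs(res$summary$z_mm - res$summary$z_true_mm)), 1e-6)
})

test_that("cube study is reproducible from its seed and reports its config", {
  r1 <- suppressWarnings(run_cube_study(H_list_mm = 400, n_repeats = 5, seed = 9))
  r2 <- suppressWarnings(run_cube_study(H_list_mm = 400, n_repeats = 5, seed = 9))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$config$seed, 9)
  expect_true(all(c("n_converged", "n_repeats") %in% names(r1$summary)))
})

test_that("tank study runs the full signal chain; degenerate groups are caught", {
  expect_error(run_tank_study(groups = list(bad = c(1L, 2L, 3L))), "at least 4")
  expect_error(run_tank_study(groups = list(bad = c(1L, 2L, 3L, 44L))), "1..12")
  res <- run_tank_study(groups = tank_groups()[c("g3", "g7", "g10")],
                        n_repeats = 4, seed = 2)
  s <- res$summary
  expect_equal(s$n_sensors, c(4L, 6L, 12L))
  expect_true(all(s$n_converged == 4L))
  # well-conditioned groups localize to well under a millimetre
  expect_lt(s$median_err_mm[s$group == "g10"], 1)
  expect_lt(s$median_err_mm[s$group == "g7"], 1)
  # one-sided group 3 (all its sensors at y = 65 cm) shows a larger
  # offset in its unconstrained coordinate than group 7
  off3 <- abs(s$y_cm[s$group == "g3"] - 53.0)
  off7 <- abs(s$y_cm[s$group == "g7"] - 53.0)
  expect_gt(off3, off7)
  expect_gt(s$median_err_mm[s$group == "g3"],
            s$median_err_mm[s$group == "g7"])
})

test_that("timing study reports one positive row per configuration", {
  tt <- run_timing_study(sensor_counts = c(4L, 6L), H_list_mm = c(300, 400),
                         n_repeats = 2)
  expect_equal(nrow(tt), 4L)
  expect_true(all(tt$seconds_per_solve >= 0))
  tt2 <- run_timing_study(sensor_counts = c(4L, 6L), H_list_mm = c(300, 400),
                          n_repeats = 2)
  expect_identical(tt$iterations, tt2$iterations)
})
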