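# Cross-correlation delay estimation: oracle equivalence with the
# brute-force time-domain correlation, constructed shifts, sub-sample
# refinement and noise robustness.

# band-limited test pulse: derivative-of-Gaussian embedded in a record
dog_record <- function(n = 4096L, fs = 1e7, center = 60e-6, sigma = 1e-6) {
  t <- (seq_len(n) - 1) / fs
  pressure_signal(-(t - center) / sigma^2 * exp(-(t - center)^2 / (2 * sigma^2)),
                  fs = fs)
}

test_that("plain GCC equals brute-force time-domain cross-correlation", {
  set.seed(42)
  for (n in c(257L, 1024L)) {
    a <- pressure_signal(rnorm(n), fs = 1e6)
    b <- pressure_signal(rnorm(n), fs = 1e6)
    cf <- gcc(a, b, weighting = "plain")
    ref <- xcorr_brute(a$samples, b$samples)
    expect_equal(cf$values, ref, tolerance = 1e-10)
    expect_equal(cf$lags, seq.int(-(n - 1L), n - 1L) / 1e6)
  }
})

test_that("correlation peaks at the constructed delay", {
  x <- dog_record()
  expect_equal(gcc(x, x)$lags[which.max(gcc(x, x)$values)], 0)
  # integer shift of 100 samples at 10 MS/s -> peak at exactly 10 us
  y <- pressure_signal(c(numeric(100), head(x$samples, -100)), fs = x$fs)
  for (w in c("plain", "phat", "scot")) {
    cf <- gcc(x, y, weighting = w)
    expect_equal(cf$lags[which.max(cf$values)], 1e-5,
                 label = sprintf("weighting %s", w))
  }
  expect_error(gcc(x, pressure_signal(numeric(64) + 0, fs = x$fs)), "zero")
  expect_error(gcc(x, pressure_signal(1:5, fs = 2e6)), "sample rate")
})

test_that("TOA estimation is exact for integer shifts and equivariant", {
  x <- dog_record()
  expect_equal(as.numeric(estimate_toa(x, x)), 0)
  for (k in c(7L, 131L)) {
    y <- pressure_signal(c(numeric(k), head(x$samples, -k)), fs = x$fs)
    expect_equal(as.numeric(estimate_toa(x, y, subsample = FALSE)), k / x$fs)
  }
  # differing record start times are folded into the estimate
  y <- pressure_signal(x$samples, fs = x$fs, t0 = 3e-6)
  expect_equal(as.numeric(estimate_toa(x, y)), 3e-6)
})

test_that("parabolic refinement resolves a 50.05-sample fractional delay", {
  x <- dog_record()
  delay <- 50.05 / x$fs
  y <- pressure_signal(braggloc:::frac_delay(x$samples, x$fs, delay), fs = x$fs)
  est <- as.numeric(estimate_toa(x, y, subsample = TRUE))
  expect_lt(abs(est - delay) * x$fs, 0.2)
  est0 <- as.numeric(estimate_toa(x, y, subsample = FALSE))
  expect_lte(abs(est0 - delay) * x$fs, 0.5 + 1e-9)
})

test_that("bipolar pulse at 20 dB SNR is timed within 0.1 us over 100 draws", {
  x <- dog_record(n = 2048L)
  delay <- 26.8e-6
  clean <- braggloc:::frac_delay(x$samples, x$fs, delay)
  amp <- sqrt(mean(clean[abs(clean) > 0.01 * max(abs(clean))]^2))
  set.seed(7)
  errs <- replicate(100, {
    y <- pressure_signal(clean + rnorm(length(clean), sd = amp * 10^(-20 / 20)),
                         fs = x$fs)
    as.numeric(estimate_toa(x, y)) - delay
  })
  expect_lt(max(abs(errs)), 1e-7)
})

test_that("TOA error is non-increasing from 0 to 40 dB SNR", {
  x <- dog_record(n = 2048L)
  delay <- 31.7e-6
  clean <- braggloc:::frac_delay(x$samples, x$fs, delay)
  amp <- sqrt(mean(clean[abs(clean) > 0.01 * max(abs(clean))]^2))
  rms_at <- function(snr_db, n_rep = 60) {
    set.seed(123)   # paired noise draws across SNR levels
    errs <- replicate(n_rep, {
      y <- pressure_signal(clean + rnorm(length(clean),
                                         sd = amp * 10^(-snr_db / 20)),
                           fs = x$fs)
      as.numeric(estimate_toa(x, y)) - delay
    })
    sqrt(mean(errs^2))
  }
  r <- vapply(c(0, 20, 40), rms_at, 0)
  expect_true(all(diff(r) <= 0))
  expect_gt(r[1], r[3])
})

test_that("boundary peaks are flagged unreliable", {
  a <- pressure_signal(c(1, rep(0, 63)), fs = 1e6)
  b <- pressure_signal(c(rep(0, 63), 1), fs = 1e6)
  expect_warning(est <- estimate_toa(a, b), "boundary")
  expect_true(attr(est, "unreliable"))
})

test_that("TDOA construction subtracts the reference and ignores common offsets", {
  td <- tdoas_from_toas(c(10, 12, 15) * 1e-6)
  expect_equal(td$tau, c(0, 2, 5) * 1e-6)
  td2 <- tdoas_from_toas(c(10, 12, 15) * 1e-6 + 7e-6)
  expect_equal(td2$tau, td$tau)
  # reordering sensors permutes tau consistently
  perm <- c(3, 1, 2)
  td3 <- tdoas_from_toas((c(10, 12, 15) * 1e-6)[perm], ref_index = 2L)
  expect_equal(td3$tau, (c(10, 12, 15) * 1e-6)[perm] - 10e-6)
  expect_error(tdoas_from_toas(c(1, 2) * 1e-6, ref_index = 5L), "out of range")
})
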