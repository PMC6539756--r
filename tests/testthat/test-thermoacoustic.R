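# Thermoacoustic forward model: thermal relation, source assembly,
# Kirchhoff quadrature vs closed-form point source, waveform shape,
# timing and scaling laws.

test_that("dose-to-temperature relation is 1/C_p", {
  expect_equal(temperature_rise(1), 1 / 4186)
  expect_identical(temperature_rise(0), 0)
  expect_identical(temperature_rise(2), 2 * temperature_rise(1))
  expect_error(temperature_rise(-1), "non-negative")
  med <- acoustic_medium(C_p = 2000)
  expect_equal(temperature_rise(1, med), 5e-4)
})

make_ref_source <- function(energy_mev = 100, n_protons = 3.4e6,
                            gamma = 0.6, voxel_size = NULL) {
  model <- stopping_model(gamma = gamma)
  beam <- beam_pulse(energy_mev = energy_mev, n_protons = n_protons)
  prof <- dose_profile(beam, model)
  list(prof = prof,
       src = build_source(prof, beam, voxel_size = voxel_size),
       beam = beam)
}

test_that("source field deposits the beam energy (gamma = 1) and is Gaussian transversely", {
  # with full local absorption of nuclear-interaction energy the volume
  # integral must return n_protons * E0
  s1 <- make_ref_source(gamma = 1)
  e_beam <- 3.4e6 * 100 * 1.602176634e-13
  expect_equal(s1$src$total_energy_j, e_beam, tolerance = 0.01)
  expect_equal(sum(s1$src$energy_j), s1$src$total_energy_j, tolerance = 1e-10)

  # with the default gamma = 0.6 about 2.1% of the beam energy escapes
  # with nuclear secondaries (frozen closed-form ratio 0.97857)
  s2 <- make_ref_source(gamma = 0.6)
  expect_equal(s2$src$total_energy_j / e_beam, 0.978565253794, tolerance = 1e-3)

  # transverse slice through the Bragg peak: Gaussian with sigma = 1 mm
  peak_z <- bragg_peak_position(s2$prof)[3]
  sl <- abs(s2$src$centers[, 3] - peak_z) < s2$src$voxel_size / 2
  axis <- sl & abs(s2$src$centers[, 2]) < s2$src$voxel_size / 2
  x <- s2$src$centers[axis, 1]
  w <- s2$src$energy_j[axis]
  fit <- stats::lm(log(w) ~ I(x^2))
  sigma_fit <- sqrt(-1 / (2 * stats::coef(fit)[2]))
  expect_equal(as.numeric(sigma_fit), 1e-3, tolerance = 0.02)
})

test_that("empty spill gives an identically zero field; coarse voxels are rejected", {
  m <- make_ref_source(n_protons = 0)
  expect_true(all(m$src$energy_j == 0))
  prof <- dose_profile(beam_pulse())
  expect_error(build_source(prof, voxel_size = 1e-3), "too coarse")
})

test_that("Kirchhoff quadrature matches the closed-form point source to < 0.5%", {
  med <- medium_water()
  e_vox <- 1e-6            # J
  sigma_t <- 1e-6
  src <- structure(list(centers = matrix(0, 1, 3), energy_j = e_vox,
                        voxel_size = 1e-4, sigma_t = sigma_t,
                        total_energy_j = e_vox, medium = med),
                   class = "source_field")
  r <- 0.05
  t_grid <- seq(r / med$c_s - 8e-6, r / med$c_s + 8e-6, by = 1e-8)
  p <- kirchhoff_pressure(src, c(0, 0, r), t_grid, med)
  # closed form written out independently in the test
  tr <- t_grid - r / med$c_s
  gdd <- -tr / sigma_t^2 * exp(-tr^2 / (2 * sigma_t^2)) / (sigma_t * sqrt(2 * pi))
  p_ref <- med$alpha_exp * e_vox / (4 * pi * med$C_p * r) * gdd
  expect_lt(max(abs(p$samples - p_ref)) / max(abs(p_ref)), 0.005)
  # sensor inside the voxel: singular kernel refused
  expect_error(kirchhoff_pressure(src, c(0, 0, 5e-5), t_grid, med), "singular")
})

test_that("Gaussian heating gives a bipolar pulse arriving at the geometric delay", {
  m <- make_ref_source()
  peak <- bragg_peak_position(m$prof)
  sensor <- peak + c(0, 0, 0.04)
  t_grid <- seq(0, 6e-5, by = 1e-7)
  p <- kirchhoff_pressure(m$src, sensor, t_grid)
  s <- p$samples
  sig <- which(abs(s) > 0.02 * max(abs(s)))
  lobes <- s[min(sig):max(sig)]
  # exactly one compression and one rarefaction lobe
  expect_equal(sum(diff(sign(lobes[lobes != 0])) != 0), 1)
  expect_gt(max(lobes), 0)
  expect_lt(min(lobes), 0)
  expect_gt(which.max(lobes), 0)
  expect_lt(which.max(lobes), which.min(lobes))  # compression first
  # zero crossing between the lobes at the geometric delay 40 mm / c_s
  t <- signal_time(p)
  i1 <- which.max(s); i2 <- which.min(s)
  cross <- t[i1:i2][which.min(abs(s[i1:i2]))]
  expect_equal(cross, 0.04 / 1492, tolerance = 0.04)   # within ~1 us
})

test_that("pressure obeys superposition, 1/r far-field decay and time-shift equivariance", {
  m1 <- make_ref_source(n_protons = 3.4e6)
  m2 <- make_ref_source(n_protons = 6.8e6)
  peak <- bragg_peak_position(m1$prof)
  t_grid <- seq(1e-5, 5e-5, by = 1e-7)
  sensor <- peak + c(0, 0, 0.04)
  p1 <- kirchhoff_pressure(m1$src, sensor, t_grid)
  p2 <- kirchhoff_pressure(m2$src, sensor, t_grid)
  expect_equal(p2$samples, 2 * p1$samples, tolerance = 1e-12)

  t_far <- seq(2e-5, 1.2e-4, by = 1e-7)
  pa <- kirchhoff_pressure(m1$src, peak + c(0, 0, 0.06), t_far)
  pb <- kirchhoff_pressure(m1$src, peak + c(0, 0, 0.12), t_far)
  expect_equal(max(abs(pa$samples)) / max(abs(pb$samples)), 2, tolerance = 0.05)

  # shifting the evaluation grid by an integer number of samples shifts
  # the waveform by exactly that amount
  k <- 25L
  p_sh <- kirchhoff_pressure(m1$src, sensor, t_grid + k * 1e-7)
  n <- length(t_grid)
  expect_equal(p_sh$samples[seq_len(n - k)], p1$samples[-seq_len(k)],
               tolerance = 1e-10)
})

test_that("halving the voxel size changes the peak pressure by < 1%", {
  m <- make_ref_source()
  m_fine <- make_ref_source(voxel_size = m$src$voxel_size / 2)
  peak <- bragg_peak_position(m$prof)
  sensor <- peak + c(0, 0, 0.04)
  t_grid <- seq(1.5e-5, 4e-5, by = 1e-7)
  pk1 <- max(abs(kirchhoff_pressure(m$src, sensor, t_grid)$samples))
  pk2 <- max(abs(kirchhoff_pressure(m_fine$src, sensor, t_grid)$samples))
  expect_equal(pk1 / pk2, 1, tolerance = 0.01)
})
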