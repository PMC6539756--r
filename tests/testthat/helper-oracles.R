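# Independent oracles used across the suite.

# brute-force time-domain cross-correlation: r(lag) = sum_t b[t] a[t-lag]
xcorr_brute <- function(a, b, max_lag = length(a) - 1L) {
  lags <- seq.int(-max_lag, max_lag)
  vapply(lags, function(L) {
    t_idx <- seq_along(b)
    s_idx <- t_idx - L
    ok <- s_idx >= 1L & s_idx <= length(a)
    sum(b[t_idx[ok]] * a[s_idx[ok]])
  }, 0)
}

# central finite-difference Jacobian of the range residuals
jacobian_fd <- function(x_s, array, tdoas, c_s = 1492, h = 1e-6) {
  J <- matrix(0, length(range_residuals(x_s, array, tdoas, c_s)), 3L)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J[, j] <- (range_residuals(x_s + e, array, tdoas, c_s) -
                 range_residuals(x_s - e, array, tdoas, c_s)) / (2 * h)
  }
  J
}

# unconvolved Bortfeld dose per fluence, independent re-derivation used
# as the convolution-oracle integrand (same closed form, sourced from
# the residual-energy and fluence primitives rather than the dose code)
dhat_oracle <- function(z, R0, model, rho = 1) {
  p <- model$p
  u <- R0 - z
  out <- numeric(length(z))
  i <- u > 0
  out[i] <- (u[i]^(1 / p - 1) / p +
               (model$beta / p + model$gamma * model$beta) * u[i]^(1 / p)) /
    (rho * (1 + model$beta * R0) * model$alpha^(1 / p))
  out
}

# Gaussian-convolution oracle: brute-force quadrature of the straggled
# dose at one depth, using the substitution u = (R0 - z')^(1/p) to
# remove the endpoint singularity of the unconvolved curve. The closed
# form treats the beam as entering from an infinite medium, so the
# power-law curve is continued across the entrance plane (pad, cm);
# within ~4 sigma of the surface the two conventions would otherwise
# differ (entrance edge effect).
convolve_oracle <- function(z, R0, model, sigma, rho = 1, n = 4000L,
                            pad = 0.6) {
  p <- model$p
  u <- seq(0, (R0 + pad)^(1 / p), length.out = n + 1L)
  zp <- R0 - u^p
  # dhat(z') dz' = [u^(1-p)/p + b u] ... * p u^(p-1) du  (smooth in u)
  b <- model$beta / p + model$gamma * model$beta
  f <- (1 / p + b * u^p) * p /
    (rho * (1 + model$beta * R0) * model$alpha^(1 / p))
  kern <- exp(-(z - zp)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  g <- f * kern
  h <- u[2] - u[1]
  (h / 3) * (g[1] + g[n + 1L] + 4 * sum(g[seq(2L, n, 2L)]) +
               2 * sum(g[seq(3L, n - 1L, 2L)]))
}

# random well-separated sensor geometry with an interior source
random_case <- function(m = 6L) {
  repeat {
    pos <- matrix(runif(3L * m), m, 3L)
    if (min(dist(pos)) > 0.15) break
  }
  w <- runif(m); w <- w / sum(w)
  list(array = sensor_array(pos), source = as.numeric(w %*% pos))
}
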