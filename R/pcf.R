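# Parabolic cylinder function D_nu(x) and the Gaussian-scaled variant used
# by the straggled Bragg curve. No pre-installed R package provides D_nu,
# so it is authored here with a three-branch evaluator:
#   * Kummer (confluent hypergeometric 1F1) series where it is stable,
#   * a regularized integral representation on the strongly decaying side
#     (x >> 0), where the Kummer form cancels catastrophically,
#   * the large-argument asymptotic expansion where the series would
#     overflow.

# Kummer's M(a, b, y) by direct series; y >= 0 vectorized, terms positive
# for the (a, b) used here so there is no intra-series cancellation.
kummer_m <- function(a, b, y) {
  s <- rep(1, length(y))
  term <- rep(1, length(y))
  for (k in 0:1000) {
    term <- term * (a + k) / (b + k) * y / (k + 1)
    s <- s + term
    if (all(abs(term) <= 1e-17 * abs(s))) break
  }
  s
}

# f_nu(zeta) = exp(-zeta^2/4) * D_nu(-zeta), stable for all zeta.
# This is the combination that enters the straggled depth-dose: for
# zeta -> +Inf it tends to sqrt(2*pi)/Gamma(-nu) * zeta^(-nu-1) (the
# unconvolved power law), for zeta -> -Inf it vanishes.
pcf_dstar <- function(nu, zeta) {
  stopifnot(is.numeric(nu), length(nu) == 1L, nu < 0, is.numeric(zeta))
  out <- numeric(length(zeta))

  ik <- zeta > -5 & zeta <= 30      # Kummer branch
  ii <- zeta <= -5 & zeta > -40     # integral branch (decaying side)
  ia <- zeta > 30                   # asymptotic branch (growing side)
  # zeta <= -40: exp(-zeta^2/2) underflows; value is 0.

  if (any(ik)) {
    z <- zeta[ik]
    y <- z^2 / 2
    m1 <- kummer_m(-nu / 2, 1 / 2, y)
    m2 <- kummer_m((1 - nu) / 2, 3 / 2, y)
    out[ik] <- 2^(nu / 2) * sqrt(pi) * exp(-y) *
      (m1 / gamma((1 - nu) / 2) + sqrt(2) * z * m2 / gamma(-nu / 2))
  }
  if (any(ii)) out[ii] <- vapply(zeta[ii], pcf_dstar_integral, 0, nu = nu)
  if (any(ia)) out[ia] <- pcf_dstar_asymp(nu, zeta[ia])
  out
}

# Generalized Gauss-Laguerre rule for Int_0^Inf s^alpha e^(-s) phi(s) ds
# (Golub-Welsch on the Laguerre Jacobi matrix), cached per (n, alpha).
gauss_laguerre_cache <- new.env(parent = emptyenv())
gauss_laguerre <- function(n, alpha) {
  key <- sprintf("%d_%.15g", n, alpha)
  if (!is.null(gauss_laguerre_cache[[key]])) return(gauss_laguerre_cache[[key]])
  k <- seq_len(n) - 1
  d <- 2 * k + alpha + 1
  e <- sqrt(seq_len(n - 1) * (seq_len(n - 1) + alpha))
  J <- diag(d)
  J[cbind(1:(n - 1), 2:n)] <- e
  J[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(J, symmetric = TRUE)
  rule <- list(nodes = eg$values,
               weights = gamma(alpha + 1) * eg$vectors[1, ]^2)
  gauss_laguerre_cache[[key]] <- rule
  rule
}

# Decaying side, x = -zeta >= 5:
#   f_nu(zeta) = (1/Gamma(-nu)) Int_0^Inf t^(-nu-1) exp(-(t-zeta)^2/2) dt
#              = e^(-x^2/2) x^nu / Gamma(-nu) *
#                Int_0^Inf s^(-nu-1) e^(-s) exp(-s^2/(2 x^2)) ds   (s = x t).
# The weight s^(-nu-1) e^(-s) is handled exactly by generalized
# Gauss-Laguerre; the remaining factor is analytic, so 64 nodes reach
# near machine precision.
pcf_dstar_integral <- function(nu, zeta) {
  x <- -zeta                        # x >= 5
  r <- gauss_laguerre(64L, -nu - 1)
  s <- sum(r$weights * exp(-r$nodes^2 / (2 * x^2)))
  exp(-x^2 / 2) * x^nu * s / gamma(-nu)
}

# Growing side, zeta > 30: asymptotic expansion; the exp(-zeta^2/2)
# recessive term is below underflow and is dropped.
pcf_dstar_asymp <- function(nu, zeta) {
  s <- rep(1, length(zeta))
  a <- rep(1, length(zeta))
  for (m in 1:30) {
    a_new <- a * (nu + 2 * m - 1) * (nu + 2 * m) / (2 * m * zeta^2)
    if (all(abs(a_new) >= abs(a)) && m > 2) break  # divergence onset
    a <- a_new
    s <- s + a
    if (all(abs(a) <= 1e-16 * abs(s))) break
  }
  sqrt(2 * pi) / gamma(-nu) * zeta^(-nu - 1) * s
}

#' Parabolic cylinder function
#'
#' Whittaker's parabolic cylinder function \eqn{D_\nu(x)} for negative
#' order \eqn{\nu}, as needed by the straggled Bragg curve (orders
#' \eqn{-1/p} and \eqn{-1/p - 1}).
#'
#' @param nu Order, a single negative number.
#' @param x Argument (vectorized); \eqn{|x| \le 52} to avoid overflow of
#'   the \eqn{e^{x^2/4}} factor.
#' @return \eqn{D_\nu(x)}, same length as `x`.
#' @export
#' @examples
#' pcf_d(-1 / 1.77, 0)   # 2^(nu/2) sqrt(pi) / gamma((1 - nu)/2)
pcf_d <- function(nu, x) {
  stopifnot(is.numeric(x))
  if (any(abs(x) > 52)) stop("|x| > 52: e^(x^2/4) overflows; use the scaled form")
  exp(x^2 / 4) * pcf_dstar(nu, -x)
}
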