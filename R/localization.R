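# TDOA multilateration: range-difference residuals, analytic Jacobian,
# and a damped Gauss-Newton solver (least squares via SVD pseudo-inverse
# for overdetermined arrays).

#' Sensor array geometry
#'
#' Ordered 3-D sensor coordinates with a designated reference ("first")
#' sensor. At least four sensors are required for 3-D localization.
#'
#' @param positions M x 3 numeric matrix (or data.frame with columns
#'   x, y, z) of sensor coordinates, m.
#' @param ref_index Reference sensor index (default 1).
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(positions, ref_index = 1L) {
  if (is.data.frame(positions)) positions <- as.matrix(positions[, c("x", "y", "z")])
  positions <- unname(as.matrix(positions))
  stopifnot(is.numeric(positions), ncol(positions) == 3L)
  if (nrow(positions) < 4L)
    stop("at least 4 sensors are required for 3-D localization")
  if (!all(is.finite(positions))) stop("sensor positions must be finite")
  dd <- as.matrix(stats::dist(positions))
  if (any(dd[upper.tri(dd)] < 1e-12)) stop("coincident sensors in array")
  if (ref_index < 1L || ref_index > nrow(positions))
    stop("ref_index out of range")
  structure(list(positions = positions, ref_index = as.integer(ref_index)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors, ref = %d\n",
              nrow(x$positions), x$ref_index))
  print(round(x$positions, 4))
  invisible(x)
}

# distances from a candidate source to every sensor
sensor_distances <- function(x_s, array) {
  sqrt(colSums((t(array$positions) - x_s)^2))
}

#' Range-difference residuals of a candidate source position
#'
#' For each non-reference sensor i,
#' \eqn{f_i(x_s) = (d_i(x_s) - d_{ref}(x_s)) - c\,\tau_{i1}}; the vector
#' is zero exactly when the candidate reproduces the measured TDOAs.
#'
#' @param x_s Candidate source position, 3-vector, m.
#' @param array A [sensor_array()].
#' @param tdoas A [tdoas_from_toas()] result aligned with the array
#'   ordering.
#' @param c_s Sound speed, m/s.
#' @return Residual vector, m (length M - 1).
#' @export
range_residuals <- function(x_s, array, tdoas, c_s = WATER_SOUND_SPEED) {
  stopifnot(inherits(array, "sensor_array"), inherits(tdoas, "tdoa_set"),
            length(x_s) == 3L)
  if (length(tdoas$tau) != nrow(array$positions))
    stop("tdoa set not aligned with the sensor array")
  if (tdoas$ref_index != array$ref_index)
    stop("tdoa reference sensor differs from the array reference")
  d <- sensor_distances(x_s, array)
  if (any(d < 1e-12)) stop("source coincident with a sensor: undefined gradient")
  i <- setdiff(seq_len(nrow(array$positions)), array$ref_index)
  (d[i] - d[array$ref_index]) - c_s * tdoas$tau[i]
}

#' Jacobian of the range-difference residuals
#'
#' Row i is the unit vector from sensor i to the source minus the unit
#' vector from the reference sensor to the source (rows therefore have
#' norm at most 2).
#'
#' @inheritParams range_residuals
#' @return (M - 1) x 3 matrix.
#' @export
tdoa_jacobian <- function(x_s, array) {
  stopifnot(inherits(array, "sensor_array"), length(x_s) == 3L)
  d <- sensor_distances(x_s, array)
  if (any(d < 1e-12)) stop("source coincident with a sensor: undefined gradient")
  U <- (matrix(x_s, nrow(array$positions), 3, byrow = TRUE) - array$positions) / d
  i <- setdiff(seq_len(nrow(array$positions)), array$ref_index)
  U[i, , drop = FALSE] -
    matrix(U[array$ref_index, ], length(i), 3, byrow = TRUE)
}

#' Locate the source by damped Gauss-Newton iteration
#'
#' Solves the range-difference system for the 3-D source position. Each
#' step solves the linearized least-squares problem through an SVD
#' pseudo-inverse (exactly determined for 4 sensors, least squares for
#' more); the printed update rule lacking the Newton minus sign is
#' corrected here, since \eqn{x_{r+1} = x_r - J^+ f} is the only
#' fixed-point-attracting form. Steps that do not reduce the residual
#' norm are halved up to 10 times. Iteration stops when the step norm
#' falls below `tol`; convergence is reported honestly (singular
#' Jacobians and iteration overruns give `converged = FALSE`, never an
#' exception).
#'
#' @param array A [sensor_array()] (M >= 4).
#' @param tdoas A [tdoas_from_toas()] result.
#' @param c_s Sound speed, m/s.
#' @param x0 Initial guess, m. When omitted, the solver starts from the
#'   sensor centroid (inside the hull, where convergence is reliable)
#'   nudged by 5% of the array span per axis — the exact centroid of a
#'   coplanar sub-array sits on the plane of symmetry where the
#'   Jacobian is singular — and, if that run does not converge, retries
#'   from a small deterministic set of axis-offset starts, returning
#'   the converged solution with the smallest residual. A user-supplied
#'   `x0` disables the multi-start fallback.
#' @param tol Step-norm stopping tolerance, m (default 1e-6).
#' @param max_iter Maximum iterations (default 100).
#' @param residual_tol Residual norm above which a step-converged point
#'   is still flagged non-converged, m (default 1e-2).
#' @param keep_history Record per-iteration positions.
#' @return Object of class `localization_result`: `position` (m),
#'   `iterations`, `residual_norm` (m), `converged`, `reason`,
#'   `history` (optional matrix).
#' @export
localize <- function(array, tdoas, c_s = WATER_SOUND_SPEED, x0 = NULL,
                     tol = 1e-6, max_iter = 100L, residual_tol = 1e-2,
                     keep_history = FALSE) {
  stopifnot(inherits(array, "sensor_array"), inherits(tdoas, "tdoa_set"))
  if (is.null(x0)) {
    span <- max(apply(array$positions, 2, function(v) diff(range(v))))
    ctr <- colMeans(array$positions)
    starts <- rbind(ctr + 0.05 * span,
                    ctr + c(0, 0, span / 4), ctr - c(0, 0, span / 4),
                    ctr + c(span / 4, 0, 0), ctr - c(span / 4, 0, 0),
                    ctr + c(0, span / 4, 0), ctr - c(0, span / 4, 0),
                    ctr + span / 4, ctr - span / 4)
    best <- NULL
    for (si in seq_len(nrow(starts))) {
      res <- localize(array, tdoas, c_s = c_s, x0 = starts[si, ], tol = tol,
                      max_iter = max_iter, residual_tol = residual_tol,
                      keep_history = keep_history)
      if (res$converged &&
          (is.null(best) || res$residual_norm < best$residual_norm))
        best <- res
      if (!is.null(best) && si >= 1L && best$residual_norm < 1e-12) break
    }
    if (!is.null(best)) return(best)
    return(localize(array, tdoas, c_s = c_s, x0 = starts[1, ], tol = tol,
                    max_iter = max_iter, residual_tol = residual_tol,
                    keep_history = keep_history))
  }
  stopifnot(length(x0) == 3L, all(is.finite(x0)))

  x <- as.numeric(x0)
  hist <- if (keep_history) matrix(x, 1L, 3L) else NULL
  converged <- FALSE
  reason <- "max_iter"
  f <- tryCatch(range_residuals(x, array, tdoas, c_s), error = function(e) NULL)
  if (is.null(f)) {
    return(structure(list(position = x, iterations = 0L,
                          residual_norm = NA_real_, converged = FALSE,
                          reason = "singular", history = hist),
                     class = "localization_result"))
  }
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    J <- tdoa_jacobian(x, array)
    sv <- svd(J)
    if (sv$d[1] <= 0 || sv$d[3] / sv$d[1] < 1e-12) {
      reason <- "singular"
      break
    }
    delta <- sv$v %*% (crossprod(sv$u, f) / sv$d)
    step <- 1
    f_new <- NULL; x_new <- x
    for (k in 0:10) {
      x_try <- x - step * as.numeric(delta)
      f_try <- tryCatch(range_residuals(x_try, array, tdoas, c_s),
                        error = function(e) NULL)
      if (!is.null(f_try) &&
          (sum(f_try^2) < sum(f^2) || sqrt(sum(delta^2)) < tol)) {
        x_new <- x_try; f_new <- f_try
        break
      }
      step <- step / 2
    }
    if (is.null(f_new)) {       # no decreasing step found
      reason <- "stalled"
      break
    }
    moved <- sqrt(sum((x_new - x)^2))
    x <- x_new; f <- f_new
    if (keep_history) hist <- rbind(hist, x)
    if (moved < tol) {
      converged <- TRUE
      reason <- "step_tol"
      break
    }
  }
  rn <- sqrt(sum(f^2))
  if (converged && rn > residual_tol) {
    converged <- FALSE
    reason <- "residual_too_large"
  }
  structure(list(position = x, iterations = iter, residual_norm = rn,
                 converged = converged, reason = reason, history = hist),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> position (m): %s\n  %d iterations, residual %.3g m, converged: %s (%s)\n",
              paste(sprintf("%.6f", x$position), collapse = " "),
              x$iterations, x$residual_norm, x$converged, x$reason))
  invisible(x)
}
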