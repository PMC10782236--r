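#' Fit an ellipse to rim points by direct least squares
#'
#' Fits the conic \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0} to a set of
#' 2-D points, minimizing the algebraic residual subject to the
#' ellipse-guaranteeing constraint \eqn{4AC - B^2 = 1} (the direct
#' least-squares formulation, solved with the numerically stable partitioned
#' eigensystem). The constraint matters for cup openings: the visible rim is
#' often a short, noisy arc, and an unconstrained conic fit can drift into a
#' hyperbola. Points are internally centered and isotropically scaled before
#' fitting, which makes the recovered geometry invariant to translation and
#' rotation of the input.
#'
#' @param points A data frame with numeric columns `x` and `y`, or a
#'   two-column numeric matrix, in film coordinates (mm, or any single
#'   consistent unit; the fit is unit-agnostic).
#' @return An object of class `cup_ellipse`: a list with
#'   * `conic` — named numeric `A..F`, normalized so `A + C = 1`;
#'   * `params` — one-row tibble with `center_x`, `center_y`, `a` (semi-major),
#'     `b` (semi-minor), `psi_deg` (major-axis orientation in `[0, 180)`,
#'     counter-clockwise from the film +x axis);
#'   * `residuals` — per-point algebraic residuals of the normalized conic;
#'   * `n` — number of points used.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 61)[-61]
#' pts <- data.frame(x = 5 + 30 * cos(th), y = -3 + 12 * sin(th))
#' fit_ellipse(pts)$params
#' @seealso [conic_to_params()], [params_to_conic()]
#' @export
fit_ellipse <- function(points) {
  xy <- points_matrix(points)
  n <- nrow(xy)
  if (n < 5) {
    stop_cupversion(
      sprintf("Ellipse fitting needs at least 5 points; got %d.", n),
      "cupversion_error_insufficient_data"
    )
  }
  ctr <- colMeans(xy)
  cen <- sweep(xy, 2, ctr)
  # collinearity / coincidence check on the centered coordinates
  sv <- svd(cen, nu = 0, nv = 0)$d
  if (sv[1] <= 0 || sv[2] / sv[1] < 1e-10) {
    stop_cupversion(
      "Points are (nearly) collinear or coincident; no ellipse is determined.",
      "cupversion_error_degenerate_fit"
    )
  }
  s <- sqrt(mean(rowSums(cen^2)) / 2)
  u <- cen[, 1] / s
  v <- cen[, 2] / s

  d1 <- cbind(u^2, u * v, v^2)
  d2 <- cbind(u, v, rep(1, n))
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  tmat <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(tmat)) {
    stop_cupversion(
      "Degenerate point configuration; the reduced scatter system is singular.",
      "cupversion_error_degenerate_fit"
    )
  }
  m <- s1 + s2 %*% tmat
  m_red <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  eg <- eigen(m_red)
  vec <- Re(eg$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0 & abs(Im(eg$values)) < 1e-8)
  if (length(ok) == 0) {
    stop_cupversion(
      "No ellipse satisfies the constrained fit for these points.",
      "cupversion_error_degenerate_fit"
    )
  }
  a1 <- vec[, ok[1]]
  a2 <- as.numeric(tmat %*% a1)

  # un-normalize: conic was fitted in u = (x - mx)/s, v = (y - my)/s
  ap <- a1[1]; bp <- a1[2]; cp <- a1[3]
  dp <- a2[1]; ep <- a2[2]; fp <- a2[3]
  mx <- ctr[1]; my <- ctr[2]
  conic <- c(
    A = ap / s^2,
    B = bp / s^2,
    C = cp / s^2,
    D = (-2 * ap * mx - bp * my) / s^2 + dp / s,
    E = (-bp * mx - 2 * cp * my) / s^2 + ep / s,
    F = (ap * mx^2 + bp * mx * my + cp * my^2) / s^2 - (dp * mx + ep * my) / s + fp
  )
  conic <- normalize_conic(conic)
  params <- conic_to_params(conic)
  res <- conic[["A"]] * xy[, 1]^2 + conic[["B"]] * xy[, 1] * xy[, 2] +
    conic[["C"]] * xy[, 2]^2 + conic[["D"]] * xy[, 1] +
    conic[["E"]] * xy[, 2] + conic[["F"]]
  structure(
    list(conic = conic, params = params, residuals = as.numeric(res), n = n),
    class = "cup_ellipse"
  )
}

points_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      stop_cupversion("`points` must have columns `x` and `y`.",
                      "cupversion_error_invalid_point")
    }
    xy <- cbind(points$x, points$y)
  } else {
    xy <- as.matrix(points)
  }
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2 || anyNA(xy) || !all(is.finite(xy))) {
    stop_cupversion("Points must be finite (x, y) pairs.",
                    "cupversion_error_invalid_point")
  }
  xy
}

# scale so A + C = 1 (ellipses have A, C of common sign, so A + C != 0)
normalize_conic <- function(conic) {
  conic <- as.numeric(conic)
  names(conic) <- c("A", "B", "C", "D", "E", "F")
  tr <- conic[["A"]] + conic[["C"]]
  if (abs(tr) < .Machine$double.eps * max(abs(conic))) {
    stop_cupversion("Conic is not an ellipse (A + C vanishes).",
                    "cupversion_error_not_ellipse")
  }
  conic / tr
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' @param conic Named (or positional) numeric vector `(A, B, C, D, E, F)` of
#'   the conic \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0}. Any overall scale is
#'   accepted; the ellipse discriminant \eqn{B^2 - 4AC < 0} must hold.
#' @return A one-row tibble with `center_x`, `center_y`, `a`, `b` (`a >= b`),
#'   and `psi_deg`, the major-axis orientation in `[0, 180)`. For a circle
#'   (`a == b`) the orientation is reported as 0 by convention.
#' @examples
#' conic_to_params(c(A = 1 / 900, B = 0, C = 1 / 144, D = 0, E = 0, F = -1))
#' @export
conic_to_params <- function(conic) {
  conic <- normalize_conic(conic)
  a0 <- conic[["A"]]; b0 <- conic[["B"]]; c0 <- conic[["C"]]
  d0 <- conic[["D"]]; e0 <- conic[["E"]]; f0 <- conic[["F"]]
  disc <- b0^2 - 4 * a0 * c0
  if (disc >= 0) {
    stop_cupversion("Conic is not an ellipse (discriminant >= 0).",
                    "cupversion_error_not_ellipse")
  }
  q <- matrix(c(a0, b0 / 2, b0 / 2, c0), 2, 2)
  center <- as.numeric(-solve(q, c(d0, e0)) / 2)
  k <- f0 + 0.5 * (d0 * center[1] + e0 * center[2])
  if (-k <= 0) {
    stop_cupversion("Conic has no real points (imaginary ellipse).",
                    "cupversion_error_not_ellipse")
  }
  eg <- eigen(q, symmetric = TRUE)  # eigenvalues decreasing, both > 0 here
  lam <- eg$values
  a_semi <- sqrt(-k / lam[2])
  b_semi <- sqrt(-k / lam[1])
  if ((lam[1] - lam[2]) / lam[1] < 1e-10) {
    psi <- 0  # circle: orientation undefined, fixed to 0
  } else {
    mv <- eg$vectors[, 2]  # smaller eigenvalue <-> major axis
    psi <- fold_180(rad2deg(atan2(mv[2], mv[1])))
  }
  tibble::tibble(
    center_x = center[1], center_y = center[2],
    a = a_semi, b = b_semi, psi_deg = psi
  )
}

#' Build conic coefficients from geometric ellipse parameters
#'
#' Inverse of [conic_to_params()]: round-tripping geometric parameters through
#' the conic form is the identity (to numerical precision) on the open set
#' `a > b > 0`, `psi_deg` in `(0, 180)`.
#'
#' @param center_x,center_y Ellipse center.
#' @param a,b Semi-major and semi-minor axis lengths, `a >= b > 0`.
#' @param psi_deg Major-axis orientation in degrees.
#' @return Named numeric `(A, B, C, D, E, F)`, normalized so `A + C = 1`.
#' @export
params_to_conic <- function(center_x, center_y, a, b, psi_deg) {
  if (!(a > 0 && b > 0 && a >= b)) {
    stop_cupversion("Require a >= b > 0.", "cupversion_error_invalid_params")
  }
  t <- deg2rad(psi_deg)
  r <- matrix(c(cos(t), -sin(t), sin(t), cos(t)), 2, 2, byrow = TRUE)
  q <- r %*% diag(c(1 / a^2, 1 / b^2)) %*% t(r)
  cen <- c(center_x, center_y)
  lin <- -2 * as.numeric(q %*% cen)
  f0 <- as.numeric(t(cen) %*% q %*% cen) - 1
  normalize_conic(c(q[1, 1], 2 * q[1, 2], q[2, 2], lin[1], lin[2], f0))
}

#' @export
print.cup_ellipse <- function(x, ...) {
  p <- x$params
  cat("<cup_ellipse>", x$n, "points\n")
  cat(sprintf("  center (%.3f, %.3f)  a = %.3f  b = %.3f  psi = %.3f deg\n",
              p$center_x, p$center_y, p$a, p$b, p$psi_deg))
  cat(sprintf("  max |algebraic residual| = %.3g\n", max(abs(x$residuals))))
  invisible(x)
}
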