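# Shared fixture builders. Everything is generated in code; no stored data.

ellipse_points <- function(center = c(0, 0), a = 1, b = 1, psi_deg = 0,
                           n = 60, noise_sd = 0, seed = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- psi_deg * pi / 180
  x <- center[1] + a * cos(th) * cos(r) - b * sin(th) * sin(r)
  y <- center[2] + a * cos(th) * sin(r) + b * sin(th) * cos(r)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, sd = noise_sd)
    y <- y + rnorm(n, sd = noise_sd)
  }
  data.frame(x = x, y = y)
}

# Independent construction of a rotated conic from the canonical quadratic
# form x'R diag(1/a^2, 1/b^2) R'x = 1, used as an oracle for conic_to_params.
rotated_conic_oracle <- function(center, a, b, psi_deg) {
  t <- psi_deg * pi / 180
  R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  Q <- R %*% diag(c(1 / a^2, 1 / b^2)) %*% t(R)
  lin <- -2 * as.numeric(Q %*% center)
  f0 <- as.numeric(t(center) %*% Q %*% center) - 1
  c(A = Q[1, 1], B = 2 * Q[1, 2], C = Q[2, 2], D = lin[1], E = lin[2], F = f0)
}

# Minimal hand-built single-film landmark tibble (neutral symmetric pelvis,
# cup ellipse drawn directly on the film).
toy_landmarks <- function(film = "film1", side = "left",
                          td = list(l = c(62, 0), r = c(-62, 0)),
                          scj = c(0, 45), ps = c(0, -55),
                          ellipse = list(center = c(48, 18), a = 25, b = 10,
                                         psi_deg = 40),
                          n_rim = 24, scale = 1) {
  rim <- ellipse_points(ellipse$center, ellipse$a, ellipse$b, ellipse$psi_deg,
                        n = n_rim)
  tibble::tibble(
    film = film,
    landmark = c("left_teardrop", "right_teardrop", "scj", "ps",
                 rep("rim", n_rim)),
    x = c(td$l[1], td$r[1], scj[1], ps[1], rim$x),
    y = c(td$l[2], td$r[2], scj[2], ps[2], rim$y),
    side = side,
    scale_mm_per_unit = scale
  )
}

# equality of undirected axis orientations (mod 180 degrees)
expect_angle_equal <- function(object, expected, tol = 1e-6) {
  d <- abs(object - expected) %% 180
  expect_lt(min(d, 180 - d), tol)
}
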