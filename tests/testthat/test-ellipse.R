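test_that("circle points recover the circle conic exactly", {
  pts <- ellipse_points(c(0, 0), a = 10, b = 10, n = 8)
  fit <- fit_ellipse(pts)
  # conic equivalent to x^2 + y^2 = 100, normalized so A + C = 1
  expect_equal(unname(fit$conic),
               c(0.5, 0, 0.5, 0, 0, -50), tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_equal(fit$params$a, 10, tolerance = 1e-9)
  expect_equal(fit$params$b, 10, tolerance = 1e-9)
  expect_equal(fit$params$psi_deg, 0)  # circle orientation convention
})

test_that("noiseless sampled ellipses are recovered to 1e-6 relative", {
  cases <- expand.grid(a = c(10, 30), ratio = c(0.2, 0.5, 0.9),
                       psi = c(0, 40, 115.5), cx = c(-7, 5), cy = c(-3, 40))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    pts <- ellipse_points(c(cs$cx, cs$cy), cs$a, cs$a * cs$ratio, cs$psi,
                          n = 60)
    p <- fit_ellipse(pts)$params
    expect_equal(p$a, cs$a, tolerance = 1e-6)
    expect_equal(p$b, cs$a * cs$ratio, tolerance = 1e-6)
    expect_equal(p$center_x, cs$cx, tolerance = 1e-6)
    expect_equal(p$center_y, cs$cy, tolerance = 1e-6)
    expect_angle_equal(p$psi_deg %% 180, cs$psi %% 180, tol = 1e-5)
  }
})

test_that("noisy rim points recover axes within the Monte-Carlo tolerance", {
  pts <- ellipse_points(c(5, -3), a = 30, b = 12, psi_deg = 40, n = 60,
                        noise_sd = 0.2, seed = 11)
  p <- fit_ellipse(pts)$params
  expect_lt(abs(p$a - 30), 0.5)
  expect_lt(abs(p$b - 12), 0.5)
})

test_that("conic_to_params handles canonical, circular, and rotated conics", {
  p <- conic_to_params(c(A = 1 / 900, B = 0, C = 1 / 144, D = 0, E = 0, F = -1))
  expect_equal(c(p$center_x, p$center_y, p$a, p$b, p$psi_deg),
               c(0, 0, 30, 12, 0), tolerance = 1e-9)

  circ <- conic_to_params(c(1, 0, 1, 0, 0, -100))
  expect_equal(c(circ$a, circ$b, circ$psi_deg), c(10, 10, 0), tolerance = 1e-9)

  # oracle: conic built by explicit rotation of the quadratic form
  con <- rotated_conic_oracle(c(5, -3), a = 30, b = 12, psi_deg = 40)
  p2 <- conic_to_params(con)
  expect_equal(c(p2$center_x, p2$center_y, p2$a, p2$b),
               c(5, -3, 30, 12), tolerance = 1e-9)
  expect_angle_equal(p2$psi_deg, 40, tol = 1e-9)
})

test_that("params -> conic -> params round trip is the identity", {
  for (psi in c(10, 40, 89.9, 170)) {
    con <- params_to_conic(2.5, -8, a = 21, b = 6.5, psi_deg = psi)
    p <- conic_to_params(con)
    expect_equal(c(p$center_x, p$center_y, p$a, p$b, p$psi_deg),
                 c(2.5, -8, 21, 6.5, psi), tolerance = 1e-9)
  }
})

test_that("fit geometry is invariant to translation and rotation of points", {
  base <- ellipse_points(c(5, -3), a = 30, b = 12, psi_deg = 40, n = 17)
  p0 <- fit_ellipse(base)$params
  set.seed(4)
  for (k in 1:5) {
    ang <- runif(1, 0, 2 * pi)
    shift <- runif(2, -200, 200)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    xy <- as.matrix(base) %*% t(R)
    moved <- data.frame(x = xy[, 1] + shift[1], y = xy[, 2] + shift[2])
    p1 <- fit_ellipse(moved)$params
    expect_equal(p1$a, p0$a, tolerance = 1e-9)
    expect_equal(p1$b, p0$b, tolerance = 1e-9)
    expect_angle_equal((p1$psi_deg - p0$psi_deg) %% 180,
                       (ang * 180 / pi) %% 180, tol = 1e-6)
    ctr1 <- c(p1$center_x, p1$center_y)
    expect_equal(ctr1, as.numeric(R %*% c(p0$center_x, p0$center_y) + shift),
                 tolerance = 1e-8)
  }
})

test_that("exact ellipse points leave near-zero algebraic residuals", {
  pts <- ellipse_points(c(-4, 9), a = 18, b = 7, psi_deg = 123, n = 40)
  expect_lt(max(abs(fit_ellipse(pts)$residuals)), 1e-9)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(fit_ellipse(data.frame(x = 1:4, y = (1:4)^2)),
               class = "cupversion_error_insufficient_data")
  expect_error(fit_ellipse(data.frame(x = 1:10, y = 2 * (1:10) + 1)),
               class = "cupversion_error_degenerate_fit")
  expect_error(fit_ellipse(data.frame(x = rep(1, 8), y = rep(2, 8))),
               class = "cupversion_error_degenerate_fit")
  # hyperbola conic rejected by the parameter conversion
  expect_error(conic_to_params(c(1, 0, -0.5, 0, 0, -1)),
               class = "cupversion_error_not_ellipse")
})
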