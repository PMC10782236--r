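test_that("default pelvis model is bilaterally symmetric and consistent", {
  m <- default_pelvis_model()
  expect_equal(m$scj[1], 0)
  expect_equal(m$ps[1], 0)
  expect_equal(m$left_teardrop, m$right_teardrop * c(-1, 1, 1))
  expect_equal(m$cup_center_left, m$cup_center_right * c(-1, 1, 1))
  # neutral ratio is definitional: projected axis length over teardrop span
  expect_equal(m$neutral_axis_ratio,
               sqrt(sum((m$ps - m$scj)[1:2]^2)) / m$itl_mm)
  # mid-sagittal axis projects perpendicular to the inter-teardrop line
  film <- project_film(m, simulation_truth())
  expect_equal(pelvic_axis(film)$direction[1], 0, tolerance = 1e-12)
  expect_equal(inter_teardrop_direction(film)$angle_deg, 0, tolerance = 1e-12)
})

test_that("orthographic projection obeys b/a = sin(version) at neutral pose", {
  film <- project_film(default_pelvis_model(),
                       simulation_truth(version_deg = 30))
  g <- glance(fit_ellipse(film[film$landmark == "rim", c("x", "y")]))
  expect_equal(g$axis_ratio, sin(30 * pi / 180), tolerance = 1e-9)
})

test_that("a face-on cup projects to a degenerate rim with a warning", {
  expect_warning(
    project_film(default_pelvis_model(), simulation_truth(version_deg = 0)),
    class = "cupversion_warning_degenerate_projection"
  )
})

test_that("flexion foreshortens the pelvic axis by the model cosine law", {
  m <- default_pelvis_model()
  film <- project_film(m, simulation_truth(flexion_deg = 10))
  ratio <- estimate_pose(film, m)$axis_ratio
  alpha <- m$neutral_axis_angle_deg * pi / 180
  expect_equal(ratio,
               (m$axis_length_mm / m$itl_mm) * cos(10 * pi / 180 - alpha),
               tolerance = 1e-9)
})

test_that("mirroring the film equals simulating the other hip", {
  m <- default_pelvis_model()
  left <- project_film(m, simulation_truth(version_deg = 17, side = "left"))
  right <- project_film(m, simulation_truth(version_deg = 17, side = "right"))
  named_l <- left[left$landmark != "rim", ]
  named_r <- right[right$landmark != "rim", ]
  # reflection swaps the teardrop labels; scj and ps are mid-sagittal
  mirror_of <- c(left_teardrop = "right_teardrop",
                 right_teardrop = "left_teardrop", scj = "scj", ps = "ps")
  idx <- match(mirror_of[named_l$landmark], named_r$landmark)
  expect_equal(named_l$x, -named_r$x[idx], tolerance = 1e-12)
  expect_equal(named_l$y, named_r$y[idx], tolerance = 1e-12)
  ml <- measure_cup(left, m)
  mr <- measure_cup(right, m)
  expect_equal(ml$inclination_deg, mr$inclination_deg, tolerance = 1e-9)
  expect_equal(ml$liaw_v1_deg, mr$liaw_v1_deg, tolerance = 1e-9)
  expect_equal(ml$liaw_v2_deg, mr$liaw_v2_deg, tolerance = 1e-9)
})

test_that("seeded projections are bit-reproducible", {
  truth <- simulation_truth(version_deg = 9, noise_sd_mm = 1, seed = 123)
  f1 <- project_film(default_pelvis_model(), truth)
  f2 <- project_film(default_pelvis_model(), truth)
  expect_identical(f1, f2)
  f3 <- project_film(default_pelvis_model(), truth, film_index = 2)
  expect_false(identical(f1$x, f3$x))
  s1 <- simulate_study(truth = truth)
  s2 <- simulate_study(truth = truth)
  expect_identical(s1$films, s2$films)
})

test_that("two identically posed films make the pipeline indeterminate", {
  truth <- simulation_truth(version_deg = 15, flexion_deg = 4, seed = 2)
  study <- simulate_study(truth = truth,
                          pose2 = list(flexion_deg = 4))
  m <- measure_cup(study$films)
  d <- suppressWarnings(decide_version(m))
  expect_identical(d$label, "indeterminate")
  expect_equal(d$delta_ante_deg, d$delta_retro_deg, tolerance = 1e-9)
})

test_that("noiseless two-film pipelines recover sign and angle on a sub-grid", {
  g <- recovery_grid(versions = c(-15, -5, 5, 15), flexions = c(-10, 10),
                     rotations = 0)
  s <- summarize_recovery(g)
  expect_equal(s$sign_accuracy_pct, 100)
  expect_lt(s$max_abs_error_deg, 0.5)
  expect_equal(s$n_degenerate, 0)
})

test_that("perspective projection is a mild, controlled model violation", {
  m <- default_pelvis_model()
  truth <- simulation_truth(version_deg = 15, flexion_deg = 5)
  ortho <- measure_cup(project_film(m, truth), m)
  persp <- measure_cup(project_film(m, truth, perspective_sfd = 1000), m)
  expect_gt(abs(persp$liaw_v1_deg - ortho$liaw_v1_deg), 0)
  expect_lt(abs(persp$liaw_v1_deg - ortho$liaw_v1_deg), 2)
})
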