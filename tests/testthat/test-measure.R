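test_that("inter-teardrop direction matches analytic angles", {
  lm <- toy_landmarks(td = list(l = c(80, 0), r = c(-80, 0)))
  itd <- inter_teardrop_direction(lm)
  expect_equal(itd$angle_deg, 0)
  expect_equal(itd$length_mm, 160)

  lm2 <- toy_landmarks(td = list(l = c(80, 5), r = c(-80, 0)))
  expect_equal(inter_teardrop_direction(lm2)$angle_deg,
               atan2(5, 160) * 180 / pi, tolerance = 1e-12)

  # the simulator's in-plane roll reappears as the inter-teardrop tilt
  film <- project_film(default_pelvis_model(),
                       simulation_truth(rotation_deg = 3))
  expect_equal(inter_teardrop_direction(film)$angle_deg, 3, tolerance = 1e-6)

  lm_bad <- toy_landmarks(td = list(l = c(1, 1), r = c(1, 1)))
  expect_error(inter_teardrop_direction(lm_bad),
               class = "cupversion_error_degenerate_landmark")
})

test_that("pelvic axis direction matches analytic values", {
  lm <- toy_landmarks(scj = c(0, 40), ps = c(0, -60))
  ax <- pelvic_axis(lm)
  expect_equal(ax$direction, c(0, -1), tolerance = 1e-12)
  expect_equal(ax$length_mm, 100)

  lm2 <- toy_landmarks(scj = c(2, 40), ps = c(-2, -60))
  expect_equal(pelvic_axis(lm2)$angle_deg, atan2(-100, -4) * 180 / pi,
               tolerance = 1e-12)

  lm_bad <- toy_landmarks(scj = c(1, 2), ps = c(1, 2))
  expect_error(pelvic_axis(lm_bad),
               class = "cupversion_error_degenerate_landmark")
})

test_that("radiographic inclination folds into [0, 90]", {
  ell <- tibble::tibble(a = 30, b = 12, psi_deg = 45)
  expect_equal(radiographic_inclination(ell, 0), 45)
  ell$psi_deg <- 135
  expect_equal(radiographic_inclination(ell, 0), 45)
  ell$psi_deg <- 10
  expect_equal(radiographic_inclination(ell, -10), 20)
  # simulated neutral film reproduces the true inclination
  film <- project_film(default_pelvis_model(),
                       simulation_truth(inclination_deg = 40, version_deg = 20))
  expect_equal(measure_cup(film)$inclination_deg, 40, tolerance = 1e-6)
})

test_that("planar version is asin(b/a), with the circular limit flagged", {
  expect_equal(planar_version(tibble::tibble(a = 30, b = 15, psi_deg = 0)), 30)
  expect_warning(
    v <- planar_version(tibble::tibble(a = 10, b = 10, psi_deg = 0)),
    class = "cupversion_warning_circular_cup"
  )
  expect_equal(v, 90)
  # strictly increasing in b/a
  ratios <- seq(0.05, 1, by = 0.05)
  vs <- vapply(ratios, function(r) {
    suppressWarnings(planar_version(tibble::tibble(a = 1, b = r, psi_deg = 0)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
  # forward-projector identity: b/a = sin(version) at neutral pose
  film <- project_film(default_pelvis_model(),
                       simulation_truth(version_deg = 20))
  expect_equal(measure_cup(film)$planar_version_deg, 20, tolerance = 1e-6)
})

test_that("pose estimation recovers the projector's flexion and rotation", {
  model <- default_pelvis_model()
  neutral <- project_film(model, simulation_truth())
  p0 <- estimate_pose(neutral, model)
  expect_equal(p0$rotation_deg, 0, tolerance = 1e-9)
  expect_equal(p0$flexion_deg, 0, tolerance = 1e-9)
  expect_equal(p0$axis_ratio, model$neutral_axis_ratio, tolerance = 1e-12)

  flexed <- project_film(model, simulation_truth(flexion_deg = 10))
  expect_equal(estimate_pose(flexed, model)$flexion_deg, 10, tolerance = 1e-6)

  rolled <- project_film(model, simulation_truth(rotation_deg = 5))
  p <- estimate_pose(rolled, model)
  expect_equal(p$rotation_deg, 5, tolerance = 1e-6)
  expect_equal(p$flexion_deg, 0, tolerance = 1e-6)

  # an axis longer than the model can project raises the unsolvable error
  stretched <- toy_landmarks(scj = c(0, 70), ps = c(0, -70))
  expect_error(estimate_pose(stretched, model),
               class = "cupversion_error_unsolvable_flexion")
})

test_that("standardized versions are symmetric at neutral pose", {
  pose <- tibble::tibble(rotation_deg = 0, flexion_deg = 0)
  for (ratio in c(0.2, 0.5, 0.8)) {
    ell <- tibble::tibble(a = 25, b = 25 * ratio, psi_deg = 40)
    sv <- standardized_versions(ell, pose, 0, "left")
    expect_equal(sv$liaw_v1_deg, asin(ratio) * 180 / pi, tolerance = 1e-9)
    expect_equal(sv$liaw_v2_deg, -sv$liaw_v1_deg, tolerance = 1e-9)
  }
})

test_that("the candidate matching the true sign recovers the true version", {
  model <- default_pelvis_model()
  ante <- measure_cup(project_film(model, simulation_truth(
    version_deg = 15, flexion_deg = 10
  )), model)
  expect_equal(ante$liaw_v1_deg, 15, tolerance = 0.1)
  expect_gt(abs(abs(ante$liaw_v2_deg) - 15), 0.5)  # mirror is asymmetric

  retro <- measure_cup(project_film(model, simulation_truth(
    version_deg = -12, flexion_deg = -5
  )), model)
  expect_equal(retro$liaw_v2_deg, -12, tolerance = 0.1)
})

test_that("measurements are invariant to film translation and uniform scale", {
  model <- default_pelvis_model()
  film <- project_film(model, simulation_truth(
    version_deg = -18, inclination_deg = 45, flexion_deg = 6, rotation_deg = 2
  ))
  m0 <- measure_cup(film, model)
  moved <- dplyr::mutate(film, x = (x + 137.5) * 4, y = (y - 52.25) * 4,
                         scale_mm_per_unit = scale_mm_per_unit / 4)
  m1 <- measure_cup(moved, model)
  for (col in c("inclination_deg", "planar_version_deg", "liaw_v1_deg",
                "liaw_v2_deg", "rotation_deg", "flexion_deg", "axis_ratio")) {
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("landmark validation names the offending film and field", {
  lm <- toy_landmarks()
  expect_error(measure_cup(lm[lm$landmark != "ps", ]), regexp = "'ps'",
               class = "cupversion_error_schema")
  few_rim <- lm[c(1:4, which(lm$landmark == "rim")[1:4]), ]
  expect_error(measure_cup(few_rim), regexp = "rim",
               class = "cupversion_error_schema")
  bad_scale <- dplyr::mutate(lm, scale_mm_per_unit = 0)
  expect_error(measure_cup(bad_scale), regexp = "scale_mm_per_unit",
               class = "cupversion_error_schema")
})
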