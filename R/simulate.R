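# Forward projector: parameterized 3-D pelvis + cup-opening circle to
# synthetic AP-film landmark sets with known ground truth.

#' Ground truth for a simulated radiographic study
#'
#' Bundles the cup orientation and the (film 1) pelvic pose that drive the
#' forward projector.
#'
#' @param inclination_deg True radiographic inclination of the cup (default 40).
#' @param version_deg True signed version (positive anteverted, negative
#'   retroverted; default 15).
#' @param side Operated hip, `"left"` (default) or `"right"`.
#' @param flexion_deg Pelvic sagittal flexion/tilt about the transverse axis
#'   (positive tips the superior pelvis anteriorly; default 0).
#' @param rotation_deg In-plane pelvic rotation about the beam axis (default 0).
#' @param obliquity_deg Axial rotation about the vertical axis (default 0).
#'   Not corrected by the measurement model; available to probe robustness.
#' @param noise_sd_mm Isotropic Gaussian annotation noise added to every
#'   projected landmark coordinate, in film mm (default 0).
#' @param n_rim_points Number of rim points sampled on the cup opening
#'   (default 24, minimum 5).
#' @param seed Integer seed making every projection reproducible.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(inclination_deg = 40, version_deg = 15,
                             side = "left", flexion_deg = 0, rotation_deg = 0,
                             obliquity_deg = 0, noise_sd_mm = 0,
                             n_rim_points = 24, seed = 1L) {
  side <- match.arg(side, c("left", "right"))
  if (n_rim_points < 5) {
    stop_cupversion("n_rim_points must be >= 5.", "cupversion_error_invalid_params")
  }
  if (noise_sd_mm < 0) {
    stop_cupversion("noise_sd_mm must be >= 0.", "cupversion_error_invalid_params")
  }
  structure(
    list(inclination_deg = inclination_deg, version_deg = version_deg,
         side = side, flexion_deg = flexion_deg, rotation_deg = rotation_deg,
         obliquity_deg = obliquity_deg, noise_sd_mm = noise_sd_mm,
         n_rim_points = as.integer(n_rim_points), seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

# Cup-opening plane unit normal in the pelvic frame for (inclination, version,
# side). The in-coronal component points laterally and inferiorly so the
# projected major axis makes the inclination angle with the inter-teardrop
# line; the anterior component is sin(version).
cup_normal <- function(inclination_deg, version_deg, side) {
  s <- if (identical(side, "left")) 1 else -1
  ci <- cos(deg2rad(inclination_deg)); si <- sin(deg2rad(inclination_deg))
  cv <- cos(deg2rad(version_deg)); sv <- sin(deg2rad(version_deg))
  c(s * si * cv, -ci * cv, sv)
}

#' Forward-project one synthetic AP film
#'
#' Places a circular cup opening at the true orientation in the pelvic frame,
#' applies the film's pelvic pose (`Rz(rotation) Ry(obliquity) Rx(flexion)`),
#' orthographically projects the rim points and the four pelvic landmarks onto
#' the film plane (dropping the beam coordinate), and adds isotropic Gaussian
#' annotation noise. Deterministic given `(truth, film_index)`.
#'
#' @param model A [pelvis_model()].
#' @param truth A [simulation_truth()].
#' @param film_index Integer distinguishing films of one study (seeds the
#'   film's noise sub-stream; default 1).
#' @param pose Optional list overriding the truth's per-film pose; any of
#'   `flexion_deg`, `rotation_deg`, `obliquity_deg`.
#' @param perspective_sfd Optional source-to-film distance (mm) switching on a
#'   point-source perspective projection (source on the beam axis anterior to
#'   the film). `NULL` (default) keeps the orthographic model.
#' @return A landmark tibble (see [validate_landmarks()]) for one film named
#'   `film<film_index>`. A cup plane (near-)parallel to the beam raises a
#'   `cupversion_warning_degenerate_projection` warning: the projected rim
#'   collapses to a segment.
#' @export
project_film <- function(model, truth, film_index = 1, pose = NULL,
                         perspective_sfd = NULL) {
  pose_full <- list(flexion_deg = truth$flexion_deg,
                    rotation_deg = truth$rotation_deg,
                    obliquity_deg = truth$obliquity_deg)
  if (!is.null(pose)) pose_full[names(pose)] <- pose
  rot <- rot_z(pose_full$rotation_deg) %*% rot_y(pose_full$obliquity_deg) %*%
    rot_x(pose_full$flexion_deg)

  n <- cup_normal(truth$inclination_deg, truth$version_deg, truth$side)
  if (abs((rot %*% n)[3]) < 1e-3) {
    warn_cupversion(
      "Cup plane is (near-)parallel to the beam: projected rim collapses to a segment.",
      "cupversion_warning_degenerate_projection"
    )
  }
  # orthonormal basis of the cup plane, deterministic in n
  ref <- if (abs(n[3]) > 1 - 1e-9) c(0, 1, 0) else c(0, 0, 1)
  e1 <- unitize(pracma_cross(n, ref))
  e2 <- pracma_cross(n, e1)
  th <- seq(0, 2 * pi, length.out = truth$n_rim_points + 1)[-(truth$n_rim_points + 1)]
  ctr <- cup_center_for(model, truth$side)
  rim3 <- t(vapply(th, function(t) {
    ctr + model$cup_radius_mm * (cos(t) * e1 + sin(t) * e2)
  }, numeric(3)))

  lms3 <- rbind(
    left_teardrop = model$left_teardrop,
    right_teardrop = model$right_teardrop,
    scj = model$scj,
    ps = model$ps
  )
  all3 <- rbind(lms3, rim3) %*% t(rot)
  film_xy <- project_to_film(all3, perspective_sfd)

  sub_seed <- (abs(truth$seed) %% 1000003L) * 1009L + film_index * 101L
  film_xy <- withr::with_seed(as.integer(sub_seed), {
    film_xy + matrix(stats::rnorm(length(film_xy), sd = truth$noise_sd_mm),
                     ncol = 2)
  })

  tibble::tibble(
    film = paste0("film", film_index),
    landmark = c("left_teardrop", "right_teardrop", "scj", "ps",
                 rep("rim", nrow(rim3))),
    x = unname(film_xy[, 1]),
    y = unname(film_xy[, 2]),
    side = truth$side,
    scale_mm_per_unit = 1
  )
}

project_to_film <- function(pts3, perspective_sfd = NULL) {
  if (is.null(perspective_sfd)) {
    pts3[, 1:2, drop = FALSE]
  } else {
    mag <- perspective_sfd / (perspective_sfd - pts3[, 3])
    cbind(pts3[, 1] * mag, pts3[, 2] * mag)
  }
}

# cross product (kept local; no need to import a linear algebra package)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate a two-film radiographic study
#'
#' Projects two AP films of the same cup under different pelvic poses — the
#' setting the two-film comparison rule requires ("different orientations and
#' pelvic radiographic axes").
#'
#' @inheritParams project_film
#' @param pose2 Pose overrides for the second film (list with any of
#'   `flexion_deg`, `rotation_deg`, `obliquity_deg`). The default flexes the
#'   pelvis 8 degrees beyond film 1. Identical poses are allowed (the
#'   downstream decision is then indeterminate) but only when passed
#'   explicitly.
#' @return A list of class `cup_study` with `films` (landmark tibble, two
#'   films) and `truth`.
#' @export
simulate_study <- function(model = default_pelvis_model(),
                           truth = simulation_truth(),
                           pose2 = list(flexion_deg = truth$flexion_deg + 8),
                           perspective_sfd = NULL) {
  f1 <- project_film(model, truth, film_index = 1,
                     perspective_sfd = perspective_sfd)
  f2 <- project_film(model, truth, film_index = 2, pose = pose2,
                     perspective_sfd = perspective_sfd)
  structure(list(films = dplyr::bind_rows(f1, f2), truth = truth,
                 model = model),
            class = "cup_study")
}

#' Noiseless forward-inverse recovery grid
#'
#' Runs the full two-film pipeline (project, measure, decide) over a grid of
#' true cup orientations and film-1 poses, with film 2 flexed
#' `flexion2_offset_deg` further. This is the package's principal
#' self-consistency surface: on noiseless input the winning candidate should
#' recover the true signed version and the label its sign, wherever the true
#' version is away from zero.
#'
#' @param model A [pelvis_model()].
#' @param inclinations,versions,flexions,rotations Grid values (degrees) for
#'   true inclination, true signed version, film-1 flexion, film-1 rotation.
#' @param flexion2_offset_deg Additional flexion of film 2 (default 8).
#' @param noise_sd_mm Landmark noise (default 0: noiseless).
#' @param seed Base seed.
#' @return A tibble with one row per grid cell: the true parameters, the
#'   decision label, `final_version_deg`, `sign_correct` (NA where the true
#'   version is 0), `abs_error_deg`, and `degenerate` (TRUE where the
#'   projection collapsed and no measurement was possible).
#' @export
recovery_grid <- function(model = default_pelvis_model(),
                          inclinations = c(30, 40, 50),
                          versions = seq(-25, 25, by = 5),
                          flexions = c(-10, 0, 10),
                          rotations = c(-5, 0, 5),
                          flexion2_offset_deg = 8,
                          noise_sd_mm = 0,
                          seed = 1L) {
  grid <- tidyr::expand_grid(
    inclination_deg = inclinations,
    version_deg = versions,
    flexion_deg = flexions,
    rotation_deg = rotations
  )
  res <- purrr::pmap(grid, function(inclination_deg, version_deg,
                                    flexion_deg, rotation_deg) {
    truth <- simulation_truth(
      inclination_deg = inclination_deg, version_deg = version_deg,
      flexion_deg = flexion_deg, rotation_deg = rotation_deg,
      noise_sd_mm = noise_sd_mm, seed = seed
    )
    out <- tryCatch({
      dec <- suppressWarnings({
        study <- simulate_study(
          model, truth,
          pose2 = list(flexion_deg = flexion_deg + flexion2_offset_deg)
        )
        decide_version(measure_cup(study$films, model))
      })
      tibble::tibble(label = dec$label,
                     final_version_deg = dec$final_version_deg %||% NA_real_,
                     degenerate = FALSE)
    }, cupversion_error = function(e) {
      tibble::tibble(label = NA_character_, final_version_deg = NA_real_,
                     degenerate = TRUE)
    })
    out
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$sign_correct <- dplyr::case_when(
    out$version_deg == 0 ~ NA,
    is.na(out$label) ~ FALSE,
    out$version_deg > 0 ~ out$label == "anteverted",
    TRUE ~ out$label == "retroverted"
  )
  out$abs_error_deg <- abs(out$final_version_deg - out$version_deg)
  out
}

#' Summarize a recovery grid
#'
#' @param grid Output of [recovery_grid()].
#' @param min_abs_version_deg Cells with `|true version|` below this are
#'   excluded from the sign-accuracy and error summaries (default 3: the sign
#'   of a near-zero version is not a meaningful target).
#' @return A one-row tibble: `n_cells`, `n_scored`, `sign_accuracy_pct`,
#'   `max_abs_error_deg`, `n_degenerate`.
#' @export
summarize_recovery <- function(grid, min_abs_version_deg = 3) {
  scored <- grid[abs(grid$version_deg) >= min_abs_version_deg, ]
  tibble::tibble(
    n_cells = nrow(grid),
    n_scored = nrow(scored),
    sign_accuracy_pct = 100 * mean(scored$sign_correct),
    max_abs_error_deg = max(scored$abs_error_deg, na.rm = FALSE),
    n_degenerate = sum(grid$degenerate)
  )
}

#' Monte-Carlo noise sensitivity of the sign decision
#'
#' Repeats the two-film pipeline under increasing landmark annotation noise
#' and records how often the ante/retro decision misses the true sign
#' (indeterminate outcomes count as misses).
#'
#' @param model A [pelvis_model()].
#' @param inclination_deg,version_deg True cup orientation (defaults 40, +15).
#' @param flexions Length-2 vector of the two films' flexion angles
#'   (default `c(-5, 8)`).
#' @param noise_sds Noise standard deviations in mm (default 0, 0.5, 1, 2).
#' @param n_rep Replicates per noise level (default 200).
#' @param seed Base seed; replicate r at any noise level uses seed
#'   `seed + r`, so levels share landmark geometry streams.
#' @return A tibble with one row per noise level: `noise_sd_mm`, `n_rep`,
#'   `n_misclassified`, `misclass_rate_pct`.
#' @export
noise_study <- function(model = default_pelvis_model(),
                        inclination_deg = 40, version_deg = 15,
                        flexions = c(-5, 8),
                        noise_sds = c(0, 0.5, 1, 2),
                        n_rep = 200, seed = 1L) {
  true_label <- if (version_deg > 0) "anteverted" else "retroverted"
  rows <- lapply(noise_sds, function(sd) {
    miss <- 0L
    for (r in seq_len(n_rep)) {
      truth <- simulation_truth(
        inclination_deg = inclination_deg, version_deg = version_deg,
        flexion_deg = flexions[1], noise_sd_mm = sd,
        seed = as.integer((seed + r) %% .Machine$integer.max)
      )
      dec <- tryCatch(
        suppressWarnings({
          study <- simulate_study(model, truth,
                                  pose2 = list(flexion_deg = flexions[2]))
          decide_version(measure_cup(study$films, model))
        }),
        cupversion_error = function(e) NULL
      )
      if (is.null(dec) || dec$label != true_label) miss <- miss + 1L
    }
    tibble::tibble(noise_sd_mm = sd, n_rep = n_rep, n_misclassified = miss,
                   misclass_rate_pct = 100 * miss / n_rep)
  })
  dplyr::bind_rows(rows)
}
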