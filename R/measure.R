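# Per-film measurement: from one radiograph's landmark set to radiographic
# inclination, the unsigned planar version, the pelvic pose estimate, and the
# paired standardized version candidates.

#' Validate a landmark tibble
#'
#' Landmark sets are long tibbles with one row per annotated point and columns
#' `film` (identifier), `landmark` (one of `"left_teardrop"`,
#' `"right_teardrop"`, `"scj"`, `"ps"`, or `"rim"`), `x`, `y` (film
#' coordinates), `side` (`"left"`/`"right"`, the operated hip), and
#' `scale_mm_per_unit` (positive; 1 when coordinates are already mm).
#'
#' @param landmarks A landmark tibble (one or more films).
#' @return The input, invisibly, after validation; errors name the offending
#'   film and field.
#' @export
validate_landmarks <- function(landmarks) {
  required <- c("film", "landmark", "x", "y", "side", "scale_mm_per_unit")
  missing_cols <- setdiff(required, names(landmarks))
  if (length(missing_cols) > 0) {
    stop_cupversion(
      paste0("Landmark data is missing column(s): ",
             paste(missing_cols, collapse = ", "), "."),
      "cupversion_error_schema"
    )
  }
  for (f in unique(landmarks$film)) {
    lf <- landmarks[landmarks$film == f, ]
    for (nm in c("left_teardrop", "right_teardrop", "scj", "ps")) {
      if (sum(lf$landmark == nm) != 1) {
        stop_cupversion(
          sprintf("Film '%s': landmark '%s' must appear exactly once.", f, nm),
          "cupversion_error_schema"
        )
      }
    }
    if (sum(lf$landmark == "rim") < 5) {
      stop_cupversion(
        sprintf("Film '%s': need at least 5 'rim' points, got %d.",
                f, sum(lf$landmark == "rim")),
        "cupversion_error_schema"
      )
    }
    if (!all(lf$side %in% c("left", "right"))) {
      stop_cupversion(
        sprintf("Film '%s': 'side' must be \"left\" or \"right\".", f),
        "cupversion_error_schema"
      )
    }
    if (!all(is.finite(lf$scale_mm_per_unit)) || any(lf$scale_mm_per_unit <= 0)) {
      stop_cupversion(
        sprintf("Film '%s': 'scale_mm_per_unit' must be positive.", f),
        "cupversion_error_schema"
      )
    }
    if (!all(is.finite(lf$x)) || !all(is.finite(lf$y))) {
      stop_cupversion(
        sprintf("Film '%s': coordinates must be finite.", f),
        "cupversion_error_schema"
      )
    }
  }
  invisible(landmarks)
}

# extract a named landmark of one film, in mm
landmark_mm <- function(lf, name) {
  row <- lf[lf$landmark == name, ][1, ]
  c(row$x, row$y) * row$scale_mm_per_unit
}

rim_mm <- function(lf) {
  rim <- lf[lf$landmark == "rim", ]
  cbind(rim$x, rim$y) * rim$scale_mm_per_unit[1]
}

#' Inter-teardrop line direction
#'
#' Direction of the horizontal pelvic reference: the line joining the
#' radiographic teardrops, oriented from the right to the left teardrop.
#'
#' @param landmarks A single-film landmark tibble (see [validate_landmarks()]).
#' @return A list with `direction` (unit 2-vector), `angle_deg` (orientation
#'   vs the film +x axis, in `(-90, 90]`), and `length_mm`.
#' @export
inter_teardrop_direction <- function(landmarks) {
  lf <- one_film(landmarks)
  d <- landmark_mm(lf, "left_teardrop") - landmark_mm(lf, "right_teardrop")
  len <- vnorm(d)
  if (len < .Machine$double.eps * 100) {
    stop_cupversion("Teardrop landmarks coincide.",
                    "cupversion_error_degenerate_landmark")
  }
  if (d[1] < 0) d <- -d  # orient toward patient's left (+x) up to 90 deg roll
  list(direction = d / len,
       angle_deg = wrap_90(rad2deg(atan2(d[2], d[1]))),
       length_mm = len)
}

#' Pelvic radiographic axis on the film
#'
#' The projected line from the mid-point of the sacrococcygeal junction to the
#' center of the upper pole of the pubic symphysis.
#'
#' @inheritParams inter_teardrop_direction
#' @return A list with `direction` (unit 2-vector, scj toward ps, i.e.
#'   pointing inferiorly on a neutral film), `angle_deg` (direction angle vs
#'   the film +x axis in `(-180, 180]`), and `length_mm`.
#' @export
pelvic_axis <- function(landmarks) {
  lf <- one_film(landmarks)
  d <- landmark_mm(lf, "ps") - landmark_mm(lf, "scj")
  len <- vnorm(d)
  if (len < .Machine$double.eps * 100) {
    stop_cupversion("scj and ps landmarks coincide.",
                    "cupversion_error_degenerate_landmark")
  }
  list(direction = d / len,
       angle_deg = rad2deg(atan2(d[2], d[1])),
       length_mm = len)
}

one_film <- function(landmarks) {
  films <- unique(landmarks$film)
  if (length(films) != 1) {
    stop_cupversion("Expected landmarks from exactly one film.",
                    "cupversion_error_schema")
  }
  landmarks
}

#' Radiographic cup inclination
#'
#' Acute angle between the fitted cup-opening ellipse's major axis and the
#' inter-teardrop line, folded into `[0, 90]` degrees.
#'
#' @param ellipse A `cup_ellipse` object from [fit_ellipse()], or a one-row
#'   data frame with columns `a`, `b`, `psi_deg`.
#' @param itl_angle_deg Inter-teardrop line orientation on the film (degrees).
#' @return Inclination in degrees.
#' @export
radiographic_inclination <- function(ellipse, itl_angle_deg) {
  p <- ellipse_row(ellipse)
  acute_between(p$psi_deg, itl_angle_deg)
}

#' Planar (unsigned) cup version
#'
#' The axis-ratio version of the projected cup opening:
#' `asin(b / a)` in degrees. Under orthographic projection of a circular cup
#' opening this equals the unsigned angle between the cup plane and the beam
#' axis; the sign (anteversion vs retroversion) is not recoverable from one
#' film, which is the ambiguity the paired standardized versions and the
#' two-film rule resolve.
#'
#' @inheritParams radiographic_inclination
#' @return Version in degrees, in `[0, 90]`. A circular projection
#'   (`a == b`, face-on cup) returns 90 with a warning of class
#'   `cupversion_warning_circular_cup`.
#' @export
planar_version <- function(ellipse) {
  p <- ellipse_row(ellipse)
  if (!(p$a >= p$b && p$b > 0)) {
    stop_cupversion("Require a >= b > 0.", "cupversion_error_invalid_params")
  }
  v <- rad2deg(asin(min(1, p$b / p$a)))
  if (1 - p$b / p$a < 1e-12) {
    warn_cupversion(
      "Projected rim is circular (a == b): version 90 deg is anatomically implausible.",
      "cupversion_warning_circular_cup"
    )
  }
  v
}

ellipse_row <- function(ellipse) {
  if (inherits(ellipse, "cup_ellipse")) return(ellipse$params)
  if (is.data.frame(ellipse)) return(ellipse[1, ])
  stop_cupversion("`ellipse` must be a cup_ellipse or a parameter data frame.",
                  "cupversion_error_invalid_params")
}

#' Estimate the pelvic pose from one film's landmarks
#'
#' Two pose components are observable on a single AP film of a (modeled)
#' symmetric pelvis:
#' * `rotation_deg` — in-film pelvic rotation about the beam axis, measured as
#'   the signed angle of the projected pelvic radiographic axis from the film
#'   vertical (equivalently, the tilt of the inter-teardrop line from the film
#'   horizontal for a symmetric pelvis). Positive is counter-clockwise on the
#'   film.
#' * `flexion_deg` — sagittal flexion/tilt, recovered from foreshortening of
#'   the pelvic axis. With `r = |scj - ps| / |inter-teardrop|` measured on the
#'   film, `L` and `alpha` the model's 3-D axis length and neutral sagittal
#'   axis angle, and `ITL` the model inter-teardrop distance, the projection
#'   identity is `r = (L / ITL) * cos(flexion - alpha)`, solved on the branch
#'   `flexion < alpha` (unique for the clinically plausible range; `alpha` is
#'   about 29 degrees for the default model).
#'
#' @inheritParams inter_teardrop_direction
#' @param model A [pelvis_model()] supplying the anatomical prior.
#' @param clamp_tol Relative tolerance by which the measured ratio may exceed
#'   the geometrically attainable maximum before an error (default 0.02);
#'   within tolerance the ratio is clamped (noise robustness).
#' @return A one-row tibble: `rotation_deg`, `flexion_deg`, `axis_ratio`.
#' @export
estimate_pose <- function(landmarks, model = default_pelvis_model(),
                          clamp_tol = 0.02) {
  lf <- one_film(landmarks)
  itd <- inter_teardrop_direction(lf)
  axis <- pelvic_axis(lf)
  # signed angle from film "down" (0, -1) to the projected axis direction
  rotation <- rad2deg(atan2(axis$direction[1], -axis$direction[2]))
  rotation <- wrap_90(rotation)
  ratio <- axis$length_mm / itd$length_mm
  rmax <- model$axis_length_mm / model$itl_mm
  cosval <- ratio / rmax
  if (cosval > 1 + clamp_tol) {
    stop_cupversion(
      sprintf(paste0("Measured axis ratio %.4f exceeds the model's attainable ",
                     "maximum %.4f beyond tolerance; flexion is unsolvable."),
              ratio, rmax),
      "cupversion_error_unsolvable_flexion",
      axis_ratio = ratio,
      flexion_clamped_deg = model$neutral_axis_angle_deg
    )
  }
  cosval <- min(1, max(-1, cosval))
  flexion <- model$neutral_axis_angle_deg - rad2deg(acos(cosval))
  tibble::tibble(rotation_deg = rotation, flexion_deg = flexion,
                 axis_ratio = ratio)
}

#' Paired standardized version candidates
#'
#' Reconstructs the two candidate 3-D cup-plane normals compatible with the
#' projected ellipse — the in-film component is perpendicular to the major
#' axis with magnitude `cos(planar_version)`, the out-of-film component is
#' `+sin(planar_version)` (anterior candidate) or `-sin(planar_version)`
#' (posterior candidate) — then removes the film's estimated in-plane rotation
#' and flexion to express both normals in the standardized pelvic frame. Each
#' candidate's standardized version is the signed angle between the cup plane
#' and the standardized coronal plane, i.e. `asin` of the anterior component
#' of the de-rotated normal. At zero flexion and rotation the pair is exactly
#' `(+planar_version, -planar_version)`.
#'
#' @inheritParams radiographic_inclination
#' @param pose A pose tibble from [estimate_pose()] (columns `rotation_deg`,
#'   `flexion_deg`).
#' @param itl_angle_deg Inter-teardrop line orientation (degrees); used to fix
#'   the medial-lateral sign of the in-film normal for the declared side.
#' @param side `"left"` or `"right"` (the operated hip).
#' @return A one-row tibble with `liaw_v1_deg` (anterior candidate, the
#'   anteversion interpretation) and `liaw_v2_deg` (posterior candidate, the
#'   retroversion interpretation), `liaw_v1_deg >= liaw_v2_deg`.
#' @export
standardized_versions <- function(ellipse, pose, itl_angle_deg, side) {
  p <- ellipse_row(ellipse)
  side <- match.arg(side, c("left", "right"))
  v <- asin(min(1, p$b / p$a))  # planar version, radians
  psi <- deg2rad(p$psi_deg)
  u0 <- c(-sin(psi), cos(psi))  # in-film unit normal to the major axis
  u_itl <- c(cos(deg2rad(itl_angle_deg)), sin(deg2rad(itl_angle_deg)))
  lateral <- if (side == "left") u_itl else -u_itl
  d <- sum(u0 * lateral)
  if (abs(d) < 1e-9) {
    inferior <- c(u_itl[2], -u_itl[1])
    d <- sum(u0 * inferior)
  }
  if (d < 0) u0 <- -u0
  derot <- rot_x(-pose$flexion_deg[1]) %*% rot_z(-pose$rotation_deg[1])
  n_plus <- derot %*% c(cos(v) * u0, sin(v))
  n_minus <- derot %*% c(cos(v) * u0, -sin(v))
  th <- sort(c(rad2deg(asin(n_plus[3])), rad2deg(asin(n_minus[3]))),
             decreasing = TRUE)
  tibble::tibble(liaw_v1_deg = th[1], liaw_v2_deg = th[2])
}

#' Measure cup orientation on one or more films
#'
#' Runs the full single-film pipeline for every film in a landmark tibble:
#' ellipse fit of the rim points, inter-teardrop reference, pelvic axis, pose
#' estimate, radiographic inclination, planar version, and the paired
#' standardized version candidates.
#'
#' @param landmarks A landmark tibble (see [validate_landmarks()]); may
#'   contain several films.
#' @param model A [pelvis_model()] used as the anatomical prior for pose
#'   estimation.
#' @return A tibble with one row per film: `film`, `side`,
#'   `inclination_deg`, `planar_version_deg`, `liaw_v1_deg`, `liaw_v2_deg`,
#'   `rotation_deg`, `flexion_deg`, `axis_ratio`, `itl_angle_deg`, fitted
#'   ellipse geometry (`a_mm`, `b_mm`, `psi_deg`, `center_x_mm`,
#'   `center_y_mm`), and `circular_rim` (TRUE when the projected rim was a
#'   circle). Carries class `cup_measurement`.
#' @examples
#' study <- simulate_study(truth = simulation_truth(version_deg = -12),
#'                         pose2 = list(flexion_deg = 8))
#' measure_cup(study$films)
#' @export
measure_cup <- function(landmarks, model = default_pelvis_model()) {
  validate_landmarks(landmarks)
  rows <- lapply(unique(landmarks$film), function(f) {
    lf <- landmarks[landmarks$film == f, ]
    side <- lf$side[1]
    itd <- inter_teardrop_direction(lf)
    pose <- estimate_pose(lf, model)
    circ <- FALSE
    fit <- fit_ellipse(rim_mm(lf))
    pv <- withCallingHandlers(
      planar_version(fit),
      cupversion_warning_circular_cup = function(w) {
        circ <<- TRUE
        rlang::cnd_muffle(w)
      }
    )
    sv <- standardized_versions(fit, pose, itd$angle_deg, side)
    tibble::tibble(
      film = f,
      side = side,
      inclination_deg = radiographic_inclination(fit, itd$angle_deg),
      planar_version_deg = pv,
      liaw_v1_deg = sv$liaw_v1_deg,
      liaw_v2_deg = sv$liaw_v2_deg,
      rotation_deg = pose$rotation_deg,
      flexion_deg = pose$flexion_deg,
      axis_ratio = pose$axis_ratio,
      itl_angle_deg = itd$angle_deg,
      a_mm = fit$params$a,
      b_mm = fit$params$b,
      psi_deg = fit$params$psi_deg,
      center_x_mm = fit$params$center_x,
      center_y_mm = fit$params$center_y,
      circular_rim = circ
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "neutral_axis_angle_deg") <- model$neutral_axis_angle_deg
  class(out) <- c("cup_measurement", class(out))
  out
}
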