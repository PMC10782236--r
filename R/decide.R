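#' Resolve anteversion vs retroversion from two radiographs
#'
#' One AP film cannot distinguish an anteverted from a retroverted cup: both
#' candidate interpretations project to the same ellipse. Across two films
#' with different pelvic poses, however, the physically correct candidate is
#' pose-invariant (it re-measures the same cup), while the mirror candidate
#' shifts with pose. The rule: the candidate pair with the smaller inter-film
#' difference is the true one.
#'
#' `decide_version()` computes the inter-film differences of the anteversion
#' candidates (`delta_ante_deg = |v1_film1 - v1_film2|`) and of the
#' retroversion candidates (`delta_retro_deg = |v2_film1 - v2_film2|`). It
#' additionally evaluates the two crossed pairings (`v1` of one film against
#' `v2` of the other): when the cup passes near face-on between the two films
#' (small true version combined with differing flexion), the true measurement
#' can swap between the anterior and posterior candidate slots, and the
#' crossed pairing is then the self-consistent one. The winning pairing is the
#' one with the smallest difference; the final angle is the signed mean of the
#' winning pair and the ante/retro label follows its sign. Whenever all
#' candidates keep their nominal signs this reduces exactly to comparing
#' `delta_ante_deg` with `delta_retro_deg`.
#'
#' @param measurements A measurement tibble from [measure_cup()] (or any data
#'   frame with columns `liaw_v1_deg` and `liaw_v2_deg`), with at least two
#'   rows; the first two films are compared.
#' @param tie_tol_deg Differences within this tolerance of the best pairing
#'   are considered tied (default 0.1 deg). If tied pairings disagree on the
#'   sign, the outcome is `"indeterminate"` — the two films were too similar
#'   to separate the candidates.
#' @param min_separation_deg Minimum angular separation of the two films'
#'   estimated 3-D pelvic-axis directions below which a
#'   `cupversion_warning_similar_poses` warning is raised (default 1 deg).
#'   Requires pose columns (`rotation_deg`, `flexion_deg`); otherwise the
#'   separation is reported as `NA` without warning.
#' @return An object of class `version_decision`: a list with
#'   `delta_ante_deg`, `delta_retro_deg`, `label` (`"anteverted"`,
#'   `"retroverted"` or `"indeterminate"`), `final_version_deg` (signed mean
#'   of the winning pair; `NA` when indeterminate), `pose_separation_deg`,
#'   `pairings` (a tibble of all four candidate pairings), and the two input
#'   measurement rows. Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @examples
#' films <- tibble::tibble(
#'   film = c("day0", "week2"),
#'   liaw_v1_deg = c(23.81, 18.86),
#'   liaw_v2_deg = c(-9.52, -8.56)
#' )
#' decide_version(films)
#' @export
decide_version <- function(measurements, tie_tol_deg = 0.1,
                           min_separation_deg = 1) {
  if (!is.data.frame(measurements) ||
      !all(c("liaw_v1_deg", "liaw_v2_deg") %in% names(measurements))) {
    stop_cupversion(
      "`measurements` must have columns `liaw_v1_deg` and `liaw_v2_deg`.",
      "cupversion_error_invalid_measurement"
    )
  }
  if (nrow(measurements) < 2) {
    stop_cupversion("Need measurements from at least two films.",
                    "cupversion_error_invalid_measurement")
  }
  if (nrow(measurements) > 2) {
    rlang::inform("More than two films supplied; comparing the first two.")
  }
  m1 <- measurements[1, ]
  m2 <- measurements[2, ]
  if (anyNA(c(m1$liaw_v1_deg, m1$liaw_v2_deg, m2$liaw_v1_deg, m2$liaw_v2_deg))) {
    stop_cupversion("Measurements carry missing version candidates.",
                    "cupversion_error_invalid_measurement")
  }

  pairings <- tibble::tibble(
    pairing = c("ante", "retro", "crossed_12", "crossed_21"),
    film1_deg = c(m1$liaw_v1_deg, m1$liaw_v2_deg, m1$liaw_v1_deg, m1$liaw_v2_deg),
    film2_deg = c(m2$liaw_v1_deg, m2$liaw_v2_deg, m2$liaw_v2_deg, m2$liaw_v1_deg)
  )
  pairings$delta_deg <- abs(pairings$film1_deg - pairings$film2_deg)
  pairings$mean_deg <- (pairings$film1_deg + pairings$film2_deg) / 2

  best <- which.min(pairings$delta_deg)
  contenders <- which(pairings$delta_deg <= pairings$delta_deg[best] + tie_tol_deg)
  signs <- sign(pairings$mean_deg[contenders])
  if (length(unique(signs)) == 1 && signs[1] != 0) {
    label <- if (signs[1] > 0) "anteverted" else "retroverted"
    final <- pairings$mean_deg[best]
  } else {
    label <- "indeterminate"
    final <- NA_real_
  }

  alpha <- attr(measurements, "neutral_axis_angle_deg") %||%
    default_pelvis_model()$neutral_axis_angle_deg
  sep <- pose_separation(m1, m2, alpha)
  if (is.finite(sep) && sep < min_separation_deg) {
    warn_cupversion(
      sprintf(paste0("Pelvic-axis separation between films is only %.2f deg ",
                     "(< %.2f): the films may be too similarly oriented to ",
                     "separate anteversion from retroversion."),
              sep, min_separation_deg),
      "cupversion_warning_similar_poses"
    )
  }

  structure(
    list(
      delta_ante_deg = pairings$delta_deg[pairings$pairing == "ante"],
      delta_retro_deg = pairings$delta_deg[pairings$pairing == "retro"],
      label = label,
      final_version_deg = final,
      pose_separation_deg = sep,
      winning_pairing = pairings$pairing[best],
      pairings = pairings,
      tie_tol_deg = tie_tol_deg,
      measurements = dplyr::bind_rows(m1, m2)
    ),
    class = "version_decision"
  )
}

# 3-D angle between the films' pelvic-axis directions implied by their pose
# estimates (rotation about the beam axis, flexion about the transverse axis).
pose_separation <- function(m1, m2, alpha) {
  if (!all(c("rotation_deg", "flexion_deg") %in% names(m1)) ||
      anyNA(c(m1$rotation_deg, m1$flexion_deg, m2$rotation_deg, m2$flexion_deg))) {
    return(NA_real_)
  }
  d0 <- c(0, -cos(deg2rad(alpha)), sin(deg2rad(alpha)))
  d1 <- rot_z(m1$rotation_deg) %*% rot_x(m1$flexion_deg) %*% d0
  d2 <- rot_z(m2$rotation_deg) %*% rot_x(m2$flexion_deg) %*% d0
  rad2deg(acos(min(1, max(-1, sum(d1 * d2)))))
}

#' @export
print.version_decision <- function(x, ...) {
  cat("<version_decision>\n")
  cat(sprintf("  delta (anteversion candidates): %.2f deg\n", x$delta_ante_deg))
  cat(sprintf("  delta (retroversion candidates): %.2f deg\n", x$delta_retro_deg))
  cat(sprintf("  label: %s\n", x$label))
  if (is.finite(x$final_version_deg %||% NA_real_)) {
    cat(sprintf("  final version: %.2f deg\n", x$final_version_deg))
  }
  if (is.finite(x$pose_separation_deg)) {
    cat(sprintf("  pelvic-axis separation: %.2f deg\n", x$pose_separation_deg))
  }
  invisible(x)
}
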