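#' Parameterized 3-D pelvis anatomy model
#'
#' A bilaterally symmetric set of 3-D landmark coordinates in the standardized
#' pelvic frame (x toward the patient's left, y superior, z anterior; units
#' mm; origin at the mid-point of the inter-teardrop line). The model supplies
#' the anatomical prior a single AP film cannot provide: the expected length
#' and sagittal inclination of the pelvic radiographic axis (mid-point of the
#' sacrococcygeal junction to the center of the upper pole of the pubic
#' symphysis) relative to the inter-teardrop distance, from which pelvic
#' flexion is recovered from axis foreshortening.
#'
#' @param teardrop_halfwidth_mm Half the inter-teardrop distance (default 62,
#'   i.e. a 124 mm inter-teardrop line — mid-range adult anatomy).
#' @param scj Numeric `(x, y, z)` of the sacrococcygeal-junction mid-point
#'   (default `c(0, 45, -35)`: on the mid-sagittal plane, superior and
#'   posterior to the teardrop line).
#' @param ps Numeric `(x, y, z)` of the center of the upper pole of the pubic
#'   symphysis (default `c(0, -55, 20)`: mid-sagittal, inferior and anterior).
#' @param cup_center Numeric `(x, y, z)` of the acetabular cup-opening center
#'   for a LEFT hip (default `c(48, 18, 8)`, slightly superolateral and
#'   anterior to the teardrop); the right-hip center is its mirror image.
#' @param cup_radius_mm Cup-opening radius (default 25 mm, a 50 mm shell).
#' @return An object of class `pelvis_model` (a list) with the landmark
#'   coordinates plus derived constants: `itl_mm` (inter-teardrop distance),
#'   `axis_length_mm` (3-D pelvic-axis length), `neutral_axis_angle_deg`
#'   (sagittal angle of the axis out of the coronal plane), and
#'   `neutral_axis_ratio` (projected axis length / inter-teardrop distance at
#'   zero pose).
#' @examples
#' default_pelvis_model()
#' @export
pelvis_model <- function(teardrop_halfwidth_mm = 62,
                         scj = c(0, 45, -35),
                         ps = c(0, -55, 20),
                         cup_center = c(48, 18, 8),
                         cup_radius_mm = 25) {
  scj <- as.numeric(scj); ps <- as.numeric(ps); cup_center <- as.numeric(cup_center)
  stopifnot(length(scj) == 3, length(ps) == 3, length(cup_center) == 3)
  if (teardrop_halfwidth_mm <= 0) {
    stop_cupversion("teardrop_halfwidth_mm must be positive.",
                    "cupversion_error_invalid_params")
  }
  if (cup_radius_mm <= 0) {
    stop_cupversion("cup_radius_mm must be positive.",
                    "cupversion_error_invalid_params")
  }
  axis_vec <- ps - scj
  axis_len <- vnorm(axis_vec)
  if (axis_len <= 0) {
    stop_cupversion("scj and ps must be distinct.",
                    "cupversion_error_degenerate_landmark")
  }
  itl <- 2 * teardrop_halfwidth_mm
  proj_len <- vnorm(axis_vec[1:2])
  m <- list(
    left_teardrop = c(teardrop_halfwidth_mm, 0, 0),
    right_teardrop = c(-teardrop_halfwidth_mm, 0, 0),
    scj = scj,
    ps = ps,
    cup_center_left = cup_center,
    cup_center_right = cup_center * c(-1, 1, 1),
    cup_radius_mm = cup_radius_mm,
    itl_mm = itl,
    axis_length_mm = axis_len,
    neutral_axis_angle_deg = rad2deg(asin(axis_vec[3] / axis_len)),
    neutral_axis_ratio = proj_len / itl
  )
  structure(m, class = "pelvis_model")
}

#' @rdname pelvis_model
#' @export
default_pelvis_model <- function() pelvis_model()

#' @export
print.pelvis_model <- function(x, ...) {
  cat("<pelvis_model>\n")
  cat(sprintf("  inter-teardrop distance: %.1f mm\n", x$itl_mm))
  cat(sprintf("  pelvic axis (scj -> ps): %.1f mm, sagittal angle %.2f deg\n",
              x$axis_length_mm, x$neutral_axis_angle_deg))
  cat(sprintf("  neutral axis ratio: %.4f\n", x$neutral_axis_ratio))
  cat(sprintf("  cup radius: %.1f mm\n", x$cup_radius_mm))
  invisible(x)
}

cup_center_for <- function(model, side) {
  if (identical(side, "left")) model$cup_center_left else model$cup_center_right
}
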