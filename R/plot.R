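#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one film's landmarks and fitted geometry
#'
#' Draws the annotated landmarks, the inter-teardrop reference line, the
#' pelvic radiographic axis, and (when a measurement row is supplied) the
#' fitted cup-opening ellipse with its axes.
#'
#' @param landmarks A single-film landmark tibble.
#' @param measurement Optional one-row measurement tibble for the same film
#'   (from [measure_cup()]); adds the fitted ellipse.
#' @return A ggplot object.
#' @export
plot_film <- function(landmarks, measurement = NULL) {
  lf <- one_film(validate_landmarks(landmarks))
  named <- lf[lf$landmark != "rim", ]
  rim <- lf[lf$landmark == "rim", ]
  td <- named[named$landmark %in% c("left_teardrop", "right_teardrop"), ]
  ax <- named[named$landmark %in% c("scj", "ps"), ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = td, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "steelblue") +
    ggplot2::geom_line(data = ax, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "purple") +
    ggplot2::geom_point(data = rim, ggplot2::aes(x = .data$x, y = .data$y),
                        color = "darkgreen", size = 1) +
    ggplot2::geom_point(data = named,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$landmark), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (film, toward patient's left)",
                  y = "y (film, superior)",
                  title = unique(lf$film))
  if (!is.null(measurement)) {
    m <- measurement[1, ]
    th <- seq(0, 2 * pi, length.out = 181)
    rot <- deg2rad(m$psi_deg)
    ex <- m$center_x_mm + m$a_mm * cos(th) * cos(rot) - m$b_mm * sin(th) * sin(rot)
    ey <- m$center_y_mm + m$a_mm * cos(th) * sin(rot) + m$b_mm * sin(th) * cos(rot)
    p <- p + ggplot2::geom_path(
      data = data.frame(x = ex / lf$scale_mm_per_unit[1],
                        y = ey / lf$scale_mm_per_unit[1]),
      ggplot2::aes(x = .data$x, y = .data$y), color = "darkgreen"
    )
  }
  p
}

#' Plot a version decision
#'
#' Shows the anteversion and retroversion candidate angles of both films; the
#' candidate pair with the smaller inter-film spread identifies the true
#' version.
#'
#' @param object A `version_decision` from [decide_version()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.version_decision <- function(object, ...) {
  m <- object$measurements
  df <- tibble::tibble(
    film = rep(c("film 1", "film 2"), 2),
    candidate = rep(c("anteversion (v1)", "retroversion (v2)"), each = 2),
    angle_deg = c(m$liaw_v1_deg, m$liaw_v2_deg)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate, y = .data$angle_deg,
                                   color = .data$film)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$candidate),
                       color = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      y = "standardized version (deg)", x = NULL,
      title = sprintf("label: %s", object$label),
      subtitle = sprintf("delta ante = %.2f deg, delta retro = %.2f deg",
                         object$delta_ante_deg, object$delta_retro_deg)
    )
}
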