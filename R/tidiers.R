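#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted cup ellipse
#'
#' @param x A `cup_ellipse` from [fit_ellipse()].
#' @param ... Unused.
#' @return A tibble with one row per geometric parameter (`term`, `estimate`).
#' @export
tidy.cup_ellipse <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("center_x", "center_y", "a", "b", "psi_deg"),
    estimate = c(p$center_x, p$center_y, p$a, p$b, p$psi_deg)
  )
}

#' Glance at a fitted cup ellipse
#'
#' @inheritParams tidy.cup_ellipse
#' @return A one-row tibble: `n` points, `rss` (sum of squared algebraic
#'   residuals), `max_abs_residual`, `axis_ratio` (`b / a`).
#' @export
glance.cup_ellipse <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    rss = sum(x$residuals^2),
    max_abs_residual = max(abs(x$residuals)),
    axis_ratio = x$params$b / x$params$a
  )
}

#' Tidy a version decision
#'
#' @param x A `version_decision` from [decide_version()].
#' @param ... Unused.
#' @return The candidate-pairing tibble: one row per cross-film pairing with
#'   both film angles, the inter-film difference, and the pair mean.
#' @export
tidy.version_decision <- function(x, ...) x$pairings

#' Glance at a version decision
#'
#' @inheritParams tidy.version_decision
#' @return A one-row tibble: `delta_ante_deg`, `delta_retro_deg`, `label`,
#'   `final_version_deg`, `pose_separation_deg`, `winning_pairing`.
#' @export
glance.version_decision <- function(x, ...) {
  tibble::tibble(
    delta_ante_deg = x$delta_ante_deg,
    delta_retro_deg = x$delta_retro_deg,
    label = x$label,
    final_version_deg = x$final_version_deg,
    pose_separation_deg = x$pose_separation_deg,
    winning_pairing = x$winning_pairing
  )
}
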