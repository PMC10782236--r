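# Small geometric helpers shared across modules. Angles are degrees in all
# user-facing code; radians appear only transiently inside these helpers.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Right-handed rotation matrices about the pelvic/film axes:
# x toward patient's left, y superior, z anterior (out of the film).
rot_x <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t),  cos(t)), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  t <- deg2rad(deg)
  matrix(c( cos(t), 0, sin(t),
            0,      1, 0,
           -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# Fold an orientation to [0, 180).
fold_180 <- function(deg) deg %% 180

# Acute angle between two undirected lines given their orientations (deg).
acute_between <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Wrap a signed angle into (-90, 90].
wrap_90 <- function(deg) {
  w <- (deg + 90) %% 180 - 90
  ifelse(w == -90, 90, w)
}

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) v / vnorm(v)

stop_cupversion <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "cupversion_error"), ...)
}

warn_cupversion <- function(message, class, ...) {
  rlang::warn(message, class = c(class, "cupversion_warning"), ...)
}

# Coerce an (x, y) point input (length-2 numeric, list, or 1-row df) to numeric.
as_point2 <- function(p, what = "point") {
  if (is.data.frame(p)) p <- c(p$x[1], p$y[1])
  p <- as.numeric(unlist(p))
  if (length(p) != 2 || !all(is.finite(p))) {
    stop_cupversion(
      sprintf("`%s` must be two finite coordinates.", what),
      "cupversion_error_invalid_point"
    )
  }
  p
}
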