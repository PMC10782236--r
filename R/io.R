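# Annotation and report serialization. Annotations are JSON with an explicit
# schema version: landmark clicks have no entrenched imaging-adjacent text
# standard, and JSON keeps fixtures hand-editable. Reports mirror clinical
# spreadsheet use (CSV) with a JSON twin encoding identical numbers.

ANNOTATION_SCHEMA_VERSION <- 1L

#' Read a landmark annotation file
#'
#' Parses and validates a JSON annotation file (see Details) into the long
#' landmark tibble used by [measure_cup()].
#'
#' @details The schema is
#' ```json
#' {
#'   "schema_version": 1,
#'   "films": [
#'     {
#'       "film_id": "film1",
#'       "side": "left",
#'       "scale_mm_per_unit": 1.0,
#'       "landmarks": {
#'         "left_teardrop": [x, y], "right_teardrop": [x, y],
#'         "scj": [x, y], "ps": [x, y]
#'       },
#'       "rim_points": [[x, y], ...],
#'       "provenance": "free text (optional)"
#'     }
#'   ]
#' }
#' ```
#' Coordinates are film units (mm when `scale_mm_per_unit` is 1); `x` runs
#' toward the patient's left, `y` superior.
#'
#' @param path Path to the annotation file.
#' @return A landmark tibble (one row per point; columns `film`, `landmark`,
#'   `x`, `y`, `side`, `scale_mm_per_unit`). Film provenance strings, if any,
#'   are kept in the `"provenance"` attribute.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_cupversion(sprintf("Annotation file '%s' does not exist.", path),
                    "cupversion_error_io")
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_cupversion(
                      sprintf("Annotation file '%s' is not valid JSON: %s",
                              path, conditionMessage(e)),
                      "cupversion_error_schema"
                    )
                  })
  if (is.null(doc$schema_version)) {
    stop_cupversion("Annotation file is missing 'schema_version'.",
                    "cupversion_error_schema")
  }
  if (!identical(as.integer(doc$schema_version), ANNOTATION_SCHEMA_VERSION)) {
    stop_cupversion(
      sprintf("Unsupported schema_version %s (supported: %d).",
              doc$schema_version, ANNOTATION_SCHEMA_VERSION),
      "cupversion_error_schema"
    )
  }
  if (is.null(doc$films) || length(doc$films) == 0) {
    stop_cupversion("Annotation file has no 'films'.", "cupversion_error_schema")
  }
  prov <- character(0)
  rows <- lapply(seq_along(doc$films), function(i) {
    f <- doc$films[[i]]
    where <- sprintf("films[%d]", i)
    film_id <- f$film_id %||% paste0("film", i)
    for (key in c("side", "scale_mm_per_unit", "landmarks", "rim_points")) {
      if (is.null(f[[key]])) {
        stop_cupversion(sprintf("%s: missing required field '%s'.", where, key),
                        "cupversion_error_schema")
      }
    }
    if (!f$side %in% c("left", "right")) {
      stop_cupversion(sprintf("%s: field 'side' must be \"left\" or \"right\".", where),
                      "cupversion_error_schema")
    }
    scale <- as.numeric(f$scale_mm_per_unit)
    if (!is.finite(scale) || scale <= 0) {
      stop_cupversion(sprintf("%s: field 'scale_mm_per_unit' must be positive.", where),
                      "cupversion_error_schema")
    }
    lm <- lapply(c("left_teardrop", "right_teardrop", "scj", "ps"), function(nm) {
      if (is.null(f$landmarks[[nm]])) {
        stop_cupversion(sprintf("%s: missing landmark '%s'.", where, nm),
                        "cupversion_error_schema")
      }
      as_point2(f$landmarks[[nm]], sprintf("%s landmark '%s'", where, nm))
    })
    if (length(f$rim_points) < 5) {
      stop_cupversion(
        sprintf("%s: field 'rim_points' must hold at least 5 points, got %d.",
                where, length(f$rim_points)),
        "cupversion_error_schema"
      )
    }
    rim <- t(vapply(seq_along(f$rim_points), function(k) {
      as_point2(f$rim_points[[k]], sprintf("%s rim_points[%d]", where, k))
    }, numeric(2)))
    if (!is.null(f$provenance)) {
      prov <<- c(prov, stats::setNames(as.character(f$provenance), film_id))
    }
    tibble::tibble(
      film = film_id,
      landmark = c("left_teardrop", "right_teardrop", "scj", "ps",
                   rep("rim", nrow(rim))),
      x = c(vapply(lm, `[`, numeric(1), 1), rim[, 1]),
      y = c(vapply(lm, `[`, numeric(1), 2), rim[, 2]),
      side = f$side,
      scale_mm_per_unit = scale
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_landmarks(out)
  attr(out, "provenance") <- prov
  out
}

#' Write a landmark annotation file
#'
#' Inverse of [read_annotations()]; the round trip is lossless (full double
#' precision is written).
#'
#' @param landmarks A landmark tibble (see [validate_landmarks()]).
#' @param path Output path.
#' @param provenance Optional character vector (recycled or named by film)
#'   stored as free text per film.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(landmarks, path, provenance = NULL) {
  validate_landmarks(landmarks)
  films <- lapply(unique(landmarks$film), function(f) {
    lf <- landmarks[landmarks$film == f, ]
    rim <- lf[lf$landmark == "rim", ]
    pt <- function(nm) {
      row <- lf[lf$landmark == nm, ][1, ]
      c(row$x, row$y)
    }
    entry <- list(
      film_id = f,
      side = lf$side[1],
      scale_mm_per_unit = lf$scale_mm_per_unit[1],
      landmarks = list(
        left_teardrop = pt("left_teardrop"),
        right_teardrop = pt("right_teardrop"),
        scj = pt("scj"),
        ps = pt("ps")
      ),
      rim_points = lapply(seq_len(nrow(rim)), function(k) c(rim$x[k], rim$y[k]))
    )
    pv <- if (!is.null(provenance)) {
      if (!is.null(names(provenance))) provenance[[f]] else provenance[[1]]
    } else {
      attr(landmarks, "provenance")[f]
    }
    if (!is.null(pv) && !is.na(pv)) entry$provenance <- unname(pv)
    entry
  })
  doc <- list(schema_version = ANNOTATION_SCHEMA_VERSION, films = films)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Write a measurement report
#'
#' Serializes per-film cup measurements, and optionally the two-film
#' ante/retro decision, to CSV or JSON. All angles are reported in degrees to
#' two decimals; the two formats encode identical numbers and the output
#' carries no timestamps, so reports are deterministic given their inputs.
#'
#' @param measurements A measurement tibble from [measure_cup()] (or any data
#'   frame with at least `liaw_v1_deg` and `liaw_v2_deg`).
#' @param path Output path.
#' @param decision Optional `version_decision` from [decide_version()].
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(measurements, path, decision = NULL,
                         format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(measurements) || nrow(measurements) == 0) {
    stop_cupversion("`measurements` must be a non-empty data frame.",
                    "cupversion_error_invalid_measurement")
  }
  cols <- c("film", "side", "inclination_deg", "planar_version_deg",
            "liaw_v1_deg", "liaw_v2_deg", "rotation_deg", "flexion_deg",
            "axis_ratio")
  films <- measurements[, intersect(cols, names(measurements)), drop = FALSE]
  films <- dplyr::mutate(films, dplyr::across(dplyr::where(is.numeric),
                                              ~ round(.x, 2)))
  dec_row <- NULL
  if (!is.null(decision)) {
    if (!inherits(decision, "version_decision")) {
      stop_cupversion("`decision` must be a version_decision object.",
                      "cupversion_error_invalid_measurement")
    }
    dec_row <- tibble::tibble(
      delta_ante_deg = round(decision$delta_ante_deg, 2),
      delta_retro_deg = round(decision$delta_retro_deg, 2),
      label = decision$label,
      final_version_deg = round(decision$final_version_deg, 2),
      pose_separation_deg = round(decision$pose_separation_deg, 2)
    )
  }
  if (format == "csv") {
    out <- films
    if (!is.null(dec_row)) {
      out <- dplyr::bind_cols(out, dec_row[rep(1, nrow(out)), ])
    }
    readr::write_csv(out, path)
  } else {
    doc <- list(films = films)
    if (!is.null(dec_row)) doc$decision <- as.list(dec_row)
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), path)
  }
  invisible(path)
}
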