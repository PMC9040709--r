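#' Define a playing field with surveyed control points
#'
#' A `field_spec` describes a rectangular playing area in a field-fixed
#' coordinate frame whose origin sits at one corner, with X running along the
#' length (`0..length`) and Y along the width (`0..width`), both in metres.
#' Control points are surveyed markers (cones) with known world coordinates
#' used for per-frame camera calibration and for static validation.
#'
#' The convention of placing the origin at a corner follows standard practice
#' for court/field surveys; an axis flip relative to a given broadcast view is
#' a fixed linear map and can be applied with [flip_axes()].
#'
#' @param name Label for the field (e.g. `"tennis"`).
#' @param length Field length in metres along X. Must be positive.
#' @param width Field width in metres along Y. Must be positive.
#' @param control_points `data.frame` with columns `id`, `x`, `y` (metres) and
#'   at least four rows. Optionally a logical column `calibration` marking the
#'   subset used for homography estimation (defaults to all points).
#' @param marker_diameter Physical marker (cone) diameter in metres.
#' @param margin Tolerance in metres by which control points may lie outside
#'   the nominal play area (markers are sometimes placed on the outer lines).
#'
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(name, length, width, control_points,
                       marker_diameter = 0.15, margin = 1) {
  stopifnot(is.character(name), base::length(name) == 1L)
  if (!is.numeric(length) || length <= 0) stop("field `length` must be > 0")
  if (!is.numeric(width) || width <= 0) stop("field `width` must be > 0")
  cp <- as.data.frame(control_points)
  req <- c("id", "x", "y")
  if (!all(req %in% names(cp))) {
    stop("control_points must have columns id, x, y")
  }
  if (nrow(cp) < 4L) stop("at least 4 control points are required")
  if (anyDuplicated(cp$id)) stop("control point ids must be unique")
  if (is.null(cp$calibration)) cp$calibration <- TRUE
  out_x <- cp$x < -margin | cp$x > length + margin
  out_y <- cp$y < -margin | cp$y > width + margin
  if (any(out_x | out_y)) {
    bad <- cp$id[out_x | out_y]
    stop("control points outside field (margin ", margin, " m): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(name = name, length = length, width = width,
         control_points = cp[, c("id", "x", "y", "calibration")],
         marker_diameter = marker_diameter, margin = margin),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %s: %.2f m x %.2f m, %d control points (%d for calibration)\n",
              x$name, x$length, x$width, nrow(x$control_points),
              sum(x$control_points$calibration)))
  invisible(x)
}

#' Built-in field presets
#'
#' Three ready-made setups covering the typical validation scenarios: a tennis
#' court (23.77 m x 8.23 m, camera at 27 m, 2 players), an Ultimate Frisbee
#' field (97.11 m x 36.25 m, camera at 85 m, 14 players) and a small-sided
#' soccer pitch (39 m x 29 m, camera at 50 m, 8 players).
#'
#' Each preset carries eight control points: the four field corners
#' (`c1`..`c4`, used for calibration) and four interior line intersections
#' (`v1`..`v4`, reserved for static validation). The interior points are
#' placed at the service-line/singles-sideline intersections (tennis), the
#' end-zone-line/side-line intersections (Ultimate, 18 m end zones) and the
#' halfway-line and mid-side marks (soccer); exact interior coordinates are
#' this package's own layout derived from the rules of each sport.
#'
#' @param name One of `"tennis"`, `"ultimate"`, `"soccer"`.
#' @return A [field_spec()] with extra attributes `camera_height` (metres) and
#'   `n_players`.
#' @export
field_preset <- function(name = c("tennis", "ultimate", "soccer")) {
  name <- match.arg(name)
  def <- switch(name,
    tennis = list(
      length = 23.77, width = 8.23, height = 27, players = 2L,
      interior = data.frame(
        id = c("v1", "v2", "v3", "v4"),
        x = c(5.485, 5.485, 18.285, 18.285),
        y = c(0, 8.23, 0, 8.23))),
    ultimate = list(
      length = 97.11, width = 36.25, height = 85, players = 14L,
      interior = data.frame(
        id = c("v1", "v2", "v3", "v4"),
        x = c(18, 18, 79.11, 79.11),
        y = c(0, 36.25, 0, 36.25))),
    soccer = list(
      length = 39, width = 29, height = 50, players = 8L,
      interior = data.frame(
        id = c("v1", "v2", "v3", "v4"),
        x = c(19.5, 19.5, 0, 39),
        y = c(0, 29, 14.5, 14.5)))
  )
  corners <- data.frame(
    id = c("c1", "c2", "c3", "c4"),
    x = c(0, def$length, def$length, 0),
    y = c(0, 0, def$width, def$width))
  cp <- rbind(cbind(corners, calibration = TRUE),
              cbind(def$interior, calibration = FALSE))
  fs <- field_spec(name, def$length, def$width, cp)
  attr(fs, "camera_height") <- def$height
  attr(fs, "n_players") <- def$players
  fs
}

#' Flip field axes
#'
#' Returns a copy of the points with X and/or Y mirrored about the field
#' centre, for matching an alternative corner-origin convention.
#'
#' @param xy Two-column matrix or data.frame of field coordinates (metres).
#' @param field A [field_spec()].
#' @param flip_x,flip_y Mirror the respective axis.
#' @return Object of the same shape as `xy`.
#' @export
flip_axes <- function(xy, field, flip_x = TRUE, flip_y = FALSE) {
  out <- xy
  if (flip_x) out[, 1] <- field$length - xy[, 1]
  if (flip_y) out[, 2] <- field$width - xy[, 2]
  out
}
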