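#' Circular or limited-view detector scan geometry
#'
#' Places `n_views` point detectors uniformly over an arc of a circle centred
#' on the image origin. The coordinate frame has the image centre at the
#' origin, x rightward, y upward, and angles measured counter-clockwise from
#' the +x axis. A full-circle scan (`arc_deg = 360`) has angular spacing
#' `360 / n_views` degrees; a limited-view scan over `arc_deg` degrees has
#' spacing `arc_deg / n_views` (so 30 views over 120 degrees are 4 degrees
#' apart, the layout used for limited-view studies).
#'
#' @param n_views Number of detector positions (M >= 1).
#' @param radius_mm Scan radius in mm (> 0).
#' @param start_angle_deg Angle of the first detector, degrees.
#' @param arc_deg Arc covered by the scan, degrees, in (0, 360].
#' @return A `scan_geometry` object: list with `positions` (M x 2 matrix, mm),
#'   `mode` ("circular" or "limited_view"), `radius_mm`, `n_views`.
#' @examples
#' g <- circular_scan(30, 36)          # 12 degree spacing, full circle
#' g <- circular_scan(30, 36, 0, 120)  # 4 degree spacing, limited view
#' @export
circular_scan <- function(n_views, radius_mm, start_angle_deg = 0, arc_deg = 360) {
  if (length(n_views) != 1L || !is.finite(n_views) || n_views < 1 ||
      n_views != round(n_views)) {
    stop("`n_views` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(radius_mm) || radius_mm <= 0) {
    stop("`radius_mm` must be positive", call. = FALSE)
  }
  if (!is.finite(arc_deg) || arc_deg <= 0 || arc_deg > 360) {
    stop("`arc_deg` must lie in (0, 360]", call. = FALSE)
  }
  ang <- (start_angle_deg + (seq_len(n_views) - 1) * arc_deg / n_views) * pi / 180
  positions <- cbind(x = radius_mm * cos(ang), y = radius_mm * sin(ang))
  structure(
    list(
      positions = positions,
      mode = if (arc_deg < 360) "limited_view" else "circular",
      radius_mm = radius_mm,
      n_views = as.integer(n_views),
      start_angle_deg = start_angle_deg,
      arc_deg = arc_deg
    ),
    class = "scan_geometry"
  )
}

#' Linear detector scan geometry
#'
#' Places `n_points` collinear detectors spanning `length_mm` inclusive of
#' both endpoints, so the spacing is `length_mm / (n_points - 1)` (41 points
#' over 40 mm give the 1 mm pitch of a typical linear scan). The line is
#' centred on `offset` and runs along `direction`.
#'
#' @param n_points Number of detectors (>= 2).
#' @param length_mm Length of the scan line in mm (> 0).
#' @param offset 2-vector, centre of the scan line in mm. The standoff of the
#'   line from the imaging region is the caller's choice; the default places
#'   the line 50 mm below the image centre.
#' @param direction 2-vector giving the line direction (normalized internally).
#' @return A `scan_geometry` object with `mode = "linear"`.
#' @export
linear_scan <- function(n_points, length_mm, offset = c(0, -50), direction = c(1, 0)) {
  if (length(n_points) != 1L || !is.finite(n_points) || n_points < 2 ||
      n_points != round(n_points)) {
    stop("`n_points` must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(length_mm) || length_mm <= 0) {
    stop("`length_mm` must be positive", call. = FALSE)
  }
  if (length(offset) != 2L || length(direction) != 2L) {
    stop("`offset` and `direction` must be 2-vectors", call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be nonzero", call. = FALSE)
  dir <- direction / nrm
  s <- seq(-length_mm / 2, length_mm / 2, length.out = n_points)
  positions <- cbind(x = offset[1] + s * dir[1], y = offset[2] + s * dir[2])
  structure(
    list(
      positions = positions,
      mode = "linear",
      radius_mm = NA_real_,
      n_views = as.integer(n_points),
      length_mm = length_mm,
      offset = offset,
      direction = dir
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> mode=%s, %d detectors", x$mode, x$n_views))
  if (x$mode != "linear") {
    cat(sprintf(", radius %.2f mm, arc %.1f deg", x$radius_mm, x$arc_deg))
  } else {
    cat(sprintf(", length %.2f mm", x$length_mm))
  }
  cat("\n")
  invisible(x)
}
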