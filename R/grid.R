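#' Imaging grid
#'
#' Discretizes the square (or rectangular) imaging region into pixel centres
#' symmetric about the origin. The pixel pitch is `extent_mm / n_x`; a
#' 128 x 128 grid over 76.8 mm has 0.6 mm pixels. Images on this grid are
#' plain numeric matrices `A[i, j]` where `i` indexes x (position `x[i]`) and
#' `j` indexes y (position `y[j]`). Whenever an image is flattened to the
#' pixel vector `A'` used by the system matrix, R's native column-major order
#' `m = i + (j - 1) * n_x` is used; the same enumeration is used everywhere
#' the matrix is built or applied.
#'
#' @param n_x,n_y Grid size in pixels (>= 1).
#' @param extent_mm Physical width of the grid along x, in mm.
#' @return A `pat_grid` object: list with `n_x`, `n_y`, `pixel_mm`, and pixel
#'   centre coordinates `x`, `y` (mm).
#' @examples
#' g <- make_grid(128, 128, 76.8)  # pixel_mm = 0.6
#' @export
make_grid <- function(n_x, n_y, extent_mm) {
  if (!is.finite(n_x) || !is.finite(n_y) || n_x < 1 || n_y < 1 ||
      n_x != round(n_x) || n_y != round(n_y)) {
    stop("grid sizes must be positive integers", call. = FALSE)
  }
  if (!is.finite(extent_mm) || extent_mm <= 0) {
    stop("`extent_mm` must be positive", call. = FALSE)
  }
  pixel_mm <- extent_mm / n_x
  structure(
    list(
      n_x = as.integer(n_x),
      n_y = as.integer(n_y),
      pixel_mm = pixel_mm,
      x = (seq_len(n_x) - (n_x + 1) / 2) * pixel_mm,
      y = (seq_len(n_y) - (n_y + 1) / 2) * pixel_mm
    ),
    class = "pat_grid"
  )
}

#' Acoustic time sampling
#'
#' Time discretization of the detected signals: sound speed `c` (m/s), time
#' step `dt` (s) and `n_samples` samples at `t_h = h * dt`, `h = 1..S`.
#' The proportionality constant `4 * pi * C_p / beta` linking pressure and
#' the integrated signal is folded to 1 (normalized units): reconstructed
#' images are normalized before any comparison, so absolute amplitudes carry
#' no information here.
#'
#' @param c Speed of sound in m/s (default 1500, soft tissue).
#' @param dt Time step in seconds.
#' @param n_samples Number of time samples S.
#' @return A `pat_sampling` object with fields `c`, `dt`, `n_samples`, `t`.
#' @export
make_sampling <- function(c = 1500, dt, n_samples) {
  if (!is.finite(c) || c <= 0) stop("`c` must be positive", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!is.finite(n_samples) || n_samples < 1 || n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      c = c,
      dt = dt,
      n_samples = as.integer(n_samples),
      t = seq_len(n_samples) * dt
    ),
    class = "pat_sampling"
  )
}

#' Default time sampling for a geometry/grid pair
#'
#' Chooses `dt` so that one time bin corresponds to one pixel
#' (`c * dt = pixel_mm`): the triangular arc-interpolation band of the
#' system matrix is then one pixel thick on either side, every arc touches
#' a contiguous band of pixels, and the weight sum along a matrix row
#' approximates the arc length in pixel units. `n_samples` is set large
#' enough that `c * S * dt` covers the largest detector-to-pixel distance
#' plus a small margin.
#'
#' @param geom A `scan_geometry`.
#' @param grid A `pat_grid`.
#' @param c Speed of sound in m/s.
#' @param dt Optional override of the time step (s).
#' @param n_samples Optional override of the sample count.
#' @return A `pat_sampling` object.
#' @export
sampling_for <- function(geom, grid, c = 1500, dt = NULL, n_samples = NULL) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(grid, "pat_grid"))
  c_mm <- c * 1000  # mm/s
  if (is.null(dt)) dt <- grid$pixel_mm / c_mm
  if (is.null(n_samples)) {
    corners <- as.matrix(expand.grid(x = range(grid$x), y = range(grid$y)))
    dmax <- 0
    for (k in seq_len(nrow(corners))) {
      d <- sqrt((geom$positions[, 1] - corners[k, 1])^2 +
                  (geom$positions[, 2] - corners[k, 2])^2)
      dmax <- max(dmax, d)
    }
    n_samples <- ceiling(dmax / (c_mm * dt)) + 2L
  }
  make_sampling(c = c, dt = dt, n_samples = n_samples)
}

#' Sinogram container
#'
#' Per-detector time series, tagged with the signal domain: raw acoustic
#' pressure (`"pressure_p"`) or the time-integrated arc-integral signal
#' (`"integrated_g"`) consumed by the model-based solvers.
#'
#' @param values M x S numeric matrix (detectors by time samples).
#' @param domain One of "pressure_p", "integrated_g".
#' @param geom The `scan_geometry` the rows refer to.
#' @param sampling The `pat_sampling` the columns refer to.
#' @return A `pat_sinogram` object.
#' @export
sinogram <- function(values, domain = c("integrated_g", "pressure_p"),
                     geom, sampling) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (nrow(values) != geom$n_views) {
    stop("sinogram must have one row per detector", call. = FALSE)
  }
  if (ncol(values) != sampling$n_samples) {
    stop("sinogram must have one column per time sample", call. = FALSE)
  }
  structure(
    list(values = values, domain = domain, geom = geom, sampling = sampling),
    class = "pat_sinogram"
  )
}

#' @export
print.pat_sinogram <- function(x, ...) {
  cat(sprintf("<pat_sinogram> %d detectors x %d samples, domain=%s\n",
              nrow(x$values), ncol(x$values), x$domain))
  invisible(x)
}
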