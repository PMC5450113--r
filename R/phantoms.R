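# Ellipse table of the Shepp-Logan head phantom: intensity, semi-axes,
# centre, rotation (degrees, counter-clockwise). "modified" uses the
# high-contrast intensities common in reconstruction benchmarks.
.shepp_logan_table <- function(variant = c("modified", "original")) {
  variant <- match.arg(variant)
  I_orig <- c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  I_mod <- c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  data.frame(
    I = if (variant == "modified") I_mod else I_orig,
    a = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0 = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0 = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

# Sum of ellipse intensities at points (x, y) in [-1, 1]^2 coordinates.
.shepp_logan_eval <- function(x, y, tab) {
  v <- numeric(length(x))
  for (e in seq_len(nrow(tab))) {
    phi <- tab$phi[e] * pi / 180
    xr <- (x - tab$x0[e]) * cos(phi) + (y - tab$y0[e]) * sin(phi)
    yr <- -(x - tab$x0[e]) * sin(phi) + (y - tab$y0[e]) * cos(phi)
    inside <- (xr / tab$a[e])^2 + (yr / tab$b[e])^2 <= 1
    v[inside] <- v[inside] + tab$I[e]
  }
  v
}

#' Shepp-Logan head phantom
#'
#' Renders the standard ten-ellipse Shepp-Logan intensity map on an `n x n`
#' grid over `[-1, 1]^2` (pixel centres), normalized to `[0, 1]` with an
#' exactly zero background. The default "modified" variant uses the
#' high-contrast intensities standard in reconstruction benchmarks.
#'
#' @param n Grid side in pixels (>= 16).
#' @param variant "modified" (default) or "original" intensities.
#' @param antialias Sub-pixel supersampling factor (1 = point sampling at
#'   pixel centres, the conventional rendering; larger values average the
#'   ellipse membership over each pixel, which is the appropriate rendering
#'   when comparing the phantom across resolutions).
#' @return `n x n` image matrix in `[0, 1]`.
#' @export
shepp_logan <- function(n, variant = c("modified", "original"),
                        antialias = 1L) {
  if (n < 16) stop("`n` must be >= 16", call. = FALSE)
  tab <- .shepp_logan_table(variant)
  k <- max(1L, as.integer(antialias))
  A <- matrix(0, n, n)
  for (s in seq_len(k)) for (t in seq_len(k)) {
    cc_x <- ((seq_len(n) - 1 + (s - 0.5) / k) / n) * 2 - 1
    cc_y <- ((seq_len(n) - 1 + (t - 0.5) / k) / n) * 2 - 1
    A <- A + matrix(.shepp_logan_eval(rep(cc_x, times = n),
                                      rep(cc_y, each = n), tab), n, n)
  }
  normalize_image(pmax(A / k^2, 0))
}

#' Transverse (striped) texture phantom
#'
#' Binary stripe pattern of the given period, with stripes running along
#' `angle_deg` (0 = stripes along x, so each column of constant y is
#' constant). A surrogate for scanned directional-texture images.
#'
#' @param n Grid side in pixels.
#' @param period_px Stripe period in pixels (>= 2).
#' @param angle_deg Stripe direction in degrees counter-clockwise from +x.
#' @return `n x n` binary image matrix.
#' @export
texture_transverse <- function(n, period_px = 8, angle_deg = 0) {
  if (period_px < 2) stop("`period_px` must be >= 2", call. = FALSE)
  a <- angle_deg * pi / 180
  i <- seq_len(n) - (n + 1) / 2
  X <- matrix(rep(i, times = n), n, n)
  Y <- matrix(rep(i, each = n), n, n)
  u <- -sin(a) * X + cos(a) * Y  # coordinate across the stripes
  (((u %% period_px) < period_px / 2) * 1)
}

#' Concentric-ring texture phantom
#'
#' Binary concentric rings centred on the grid, with radial period
#' `period_px` pixels. Exactly invariant under 90-degree rotation by
#' construction. A surrogate for circular-texture images.
#'
#' @param n Grid side in pixels.
#' @param period_px Radial period in pixels (>= 2).
#' @return `n x n` binary image matrix.
#' @export
texture_circular <- function(n, period_px = 8) {
  if (period_px < 2) stop("`period_px` must be >= 2", call. = FALSE)
  i <- seq_len(n) - (n + 1) / 2
  X <- matrix(rep(i, times = n), n, n)
  Y <- matrix(rep(i, each = n), n, n)
  r <- sqrt(X^2 + Y^2)
  (((r %% period_px) < period_px / 2) * 1)
}

#' Sinusoidal grating
#'
#' Smooth grating `0.5 + 0.5 * cos(2 pi u / period)` with stripes along
#' `angle_deg`; the standard construction for orientation-recovery checks,
#' free of the staircase edges of binary stripes.
#'
#' @inheritParams texture_transverse
#' @return `n x n` image matrix in `[0, 1]`.
#' @export
grating <- function(n, period_px = 8, angle_deg = 0) {
  a <- angle_deg * pi / 180
  i <- seq_len(n) - (n + 1) / 2
  X <- matrix(rep(i, times = n), n, n)
  Y <- matrix(rep(i, each = n), n, n)
  u <- -sin(a) * X + cos(a) * Y
  0.5 + 0.5 * cos(2 * pi * u / period_px)
}

#' Centred uniform disk phantom
#'
#' Disk of the given radius (in mm on the supplied grid) and unit value;
#' the standard fixture with a closed-form arc-integral signal.
#'
#' @param grid A `pat_grid`.
#' @param radius_mm Disk radius in mm.
#' @param center Disk centre, mm.
#' @param antialias Sub-pixel supersampling factor for edge pixels (1 =
#'   hard binary edge). Coverage-weighted edges represent the continuum
#'   disk more faithfully, which matters when comparing simulated signals
#'   against the closed-form arc integral.
#' @return Image matrix on `grid`.
#' @export
disk_phantom <- function(grid, radius_mm, center = c(0, 0), antialias = 1L) {
  X <- matrix(rep(grid$x, times = grid$n_y), grid$n_x, grid$n_y)
  Y <- matrix(rep(grid$y, each = grid$n_x), grid$n_x, grid$n_y)
  if (antialias <= 1) {
    return(((X - center[1])^2 + (Y - center[2])^2 <= radius_mm^2) * 1)
  }
  k <- as.integer(antialias)
  off <- ((seq_len(k) - 0.5) / k - 0.5) * grid$pixel_mm
  A <- matrix(0, grid$n_x, grid$n_y)
  for (ox in off) for (oy in off) {
    A <- A + ((X + ox - center[1])^2 + (Y + oy - center[2])^2 <= radius_mm^2)
  }
  A / k^2
}

#' Normalize an image by its maximum absolute value
#'
#' Divides all pixels by `max(abs(A))`, so the maximum becomes 1;
#' idempotent, and an all-zero image is returned unchanged. This is the
#' normalization applied before any PSNR or distance comparison, putting
#' reconstructions with different overall gray scales on a common level.
#'
#' @param A Image matrix.
#' @return Normalized image matrix.
#' @export
normalize_image <- function(A) {
  m <- max(abs(A))
  if (m == 0) return(A)
  A / m
}
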