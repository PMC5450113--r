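#' Simulate detector signals by dense arc quadrature
#'
#' Computes the integrated signals `g(r_l, t_h)` as circular-mean (arc)
#' integrals of the absorption image. Each time sample is the finite
#' bandwidth measurement over the arc band of radius `c * t_h` with the
#' triangular radial response of one time bin (any sampled system averages
#' over its sample interval); the band is evaluated by dense quadrature --
#' tent-weighted sub-radii, arc-length steps of `pixel_mm / upsample`,
#' bilinear interpolation of the image at sub-pixel positions. This
#' generator is numerically independent of the sparse system matrix of
#' [build_weight_matrix()] (continuous sub-pixel quadrature versus pixel
#' sums), so reconstructions from these signals do not commit an inverse
#' crime. With `radial = 1` the band collapses to the ideal zero-width arc
#' integral.
#'
#' @param A Image matrix on `grid`.
#' @param geom A `scan_geometry`.
#' @param sampling A `pat_sampling`.
#' @param grid A `pat_grid` describing `A`.
#' @param upsample Sub-pixel quadrature factor (>= 2; default 8).
#' @param radial Number of tent-weighted radial sub-samples across the
#'   one-bin measurement band (default `upsample`; 1 = ideal arc).
#' @return A `pat_sinogram` tagged `integrated_g`.
#' @export
simulate_spherical_means <- function(A, geom, sampling, grid, upsample = 8,
                                     radial = upsample) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(grid, "pat_grid"),
            inherits(sampling, "pat_sampling"))
  if (!is.matrix(A) || nrow(A) != grid$n_x || ncol(A) != grid$n_y) {
    stop("image shape does not match the grid", call. = FALSE)
  }
  if (grid$n_x < 2 || grid$n_y < 2) {
    stop("arc quadrature needs a grid of at least 2 x 2 pixels", call. = FALSE)
  }
  if (upsample < 2) stop("`upsample` must be >= 2", call. = FALSE)
  g <- sim_arc_integrals_cpp(
    A, geom$positions,
    grid$x[1], grid$y[1], grid$pixel_mm,
    sampling$c * 1000, sampling$dt, sampling$n_samples,
    as.integer(upsample), as.integer(radial)
  )
  sinogram(g, "integrated_g", geom, sampling)
}

#' Convert an integrated-g sinogram to acoustic pressure
#'
#' Inverts `g(t) = t * integral_0^t p dt` on the discrete grid: the running
#' integral is `q_h = g_h / t_h` and `p_h = (q_h - q_{h-1}) / dt` with
#' `q_0 = 0`. Exact discrete inverse of [pressure_to_g()]. Used to feed the
#' filtered back-projection baseline, which consumes pressure.
#'
#' @param g A `pat_sinogram` tagged `integrated_g`.
#' @param sampling Optional `pat_sampling` override.
#' @return A `pat_sinogram` tagged `pressure_p`.
#' @export
differentiate_to_pressure <- function(g, sampling = NULL) {
  stopifnot(inherits(g, "pat_sinogram"))
  if (g$domain != "integrated_g") {
    stop("`g` must be an integrated-g sinogram", call. = FALSE)
  }
  if (is.null(sampling)) sampling <- g$sampling
  q <- sweep(g$values, 2, sampling$t, `/`)
  p <- cbind(q[, 1, drop = FALSE],
             q[, -1, drop = FALSE] - q[, -ncol(q), drop = FALSE]) / sampling$dt
  sinogram(p, "pressure_p", g$geom, sampling)
}

#' Add calibrated white Gaussian noise to a sinogram
#'
#' Additive zero-mean Gaussian noise with variance set from the mean signal
#' power over all detectors jointly:
#' `var = mean(s^2) / 10^(snr_db / 10)` (one global noise level, the common
#' convention when a single SNR figure is quoted for a whole acquisition).
#' The realization is fixed by `seed`; the caller's RNG state is left
#' untouched. `snr_db = Inf` returns the signal unchanged.
#'
#' @param s A `pat_sinogram`.
#' @param snr_db Signal-to-noise ratio in dB (may be `Inf`).
#' @param seed Integer seed fixing the noise realization.
#' @return A `pat_sinogram` in the same domain.
#' @export
add_noise <- function(s, snr_db, seed) {
  stopifnot(inherits(s, "pat_sinogram"))
  if (is.infinite(snr_db)) return(s)
  pw <- mean(s$values^2)
  if (pw == 0) {
    stop("SNR is undefined for an all-zero sinogram", call. = FALSE)
  }
  sd_n <- sqrt(pw / 10^(snr_db / 10))
  noise <- .with_local_seed(seed, {
    matrix(stats::rnorm(length(s$values), sd = sd_n),
           nrow = nrow(s$values), ncol = ncol(s$values))
  })
  out <- s
  out$values <- s$values + noise
  out
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
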