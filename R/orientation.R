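#' Backward-difference image gradients
#'
#' First-order backward differences along each image axis:
#' `g1[i, j] = A[i, j] - A[i-1, j]`, `g2[i, j] = A[i, j] - A[i, j-1]`, with
#' the first row of `g1` and first column of `g2` set to 0 (no fictitious
#' edge at the boundary). This is the discrete gradient used both by the
#' orientation estimator and by the TV/DDTV functionals, and its exact
#' adjoint is used as the divergence in the dual solver.
#'
#' @param A Image matrix (at least 2 x 2).
#' @return List with matrices `g1`, `g2` of the same shape as `A`.
#' @export
image_gradients <- function(A) {
  if (!is.matrix(A) || nrow(A) < 2 || ncol(A) < 2) {
    stop("`A` must be a matrix of at least 2 x 2", call. = FALSE)
  }
  g1 <- A - rbind(A[1, , drop = FALSE], A[-nrow(A), , drop = FALSE])
  g1[1, ] <- 0
  g2 <- A - cbind(A[, 1, drop = FALSE], A[, -ncol(A), drop = FALSE])
  g2[, 1] <- 0
  list(g1 = g1, g2 = g2)
}

# Exact adjoint of image_gradients: <grad(A), (v1,v2)> == <A, grad_adjoint(v1,v2)>.
# Equal to the negative divergence with the matching boundary convention.
.grad_adjoint <- function(v1, v2) {
  v1[1, ] <- 0
  v2[, 1] <- 0
  d1 <- v1 - rbind(v1[-1, , drop = FALSE], matrix(0, 1, ncol(v1)))
  d2 <- v2 - cbind(v2[, -1, drop = FALSE], matrix(0, nrow(v2), 1))
  d1 + d2
}

# Block index matrices for an n_x x n_y image cut into block_size blocks;
# trailing partial blocks keep their (fewer) pixels.
.block_ids <- function(n_x, n_y, block_size) {
  bi <- ceiling(seq_len(n_x) / block_size)
  bj <- ceiling(seq_len(n_y) / block_size)
  list(bi = bi, bj = bj, nbx = max(bi), nby = max(bj))
}

# Per-block sums of a pixel matrix -> nbx x nby matrix.
.block_sum <- function(M, ids) {
  t(rowsum(t(rowsum(M, ids$bi)), ids$bj))
}

#' Coarse per-block orientation from gradient moments
#'
#' For each block the dominant orientation is
#' `O_k = 0.5 * atan2(sum(2 g1 g2), sum(g1^2 - g2^2)) + pi/2`,
#' i.e. half the doubled-angle of the mean gradient direction, rotated a
#' quarter turn so the angle follows the texture (iso-intensity) direction
#' rather than the gradient. The two-argument arctangent resolves the
#' quadrant ambiguity of the printed single-argument form. Blocks whose
#' gradient moments all vanish are degenerate: they return `pi/2` and are
#' flagged.
#'
#' @param grad A gradient field from [image_gradients()].
#' @param block_size Block side length in pixels (>= 2).
#' @return List with matrices `O` (block angles, radians, defined modulo pi)
#'   and `degenerate` (logical).
#' @export
block_orientation <- function(grad, block_size = 5) {
  if (block_size < 2) stop("`block_size` must be >= 2", call. = FALSE)
  ids <- .block_ids(nrow(grad$g1), ncol(grad$g1), block_size)
  num <- .block_sum(2 * grad$g1 * grad$g2, ids)
  den <- .block_sum(grad$g1^2 - grad$g2^2, ids)
  degenerate <- num == 0 & den == 0
  O <- 0.5 * atan2(num, den) + pi / 2
  O[degenerate] <- pi / 2
  list(O = O, degenerate = degenerate)
}

#' Per-block orientation coherence
#'
#' `C_k = ((sum(g1^2 - g2^2))^2 + 4 (sum(g1 g2))^2) / (sum(g1^2 + g2^2))^2`,
#' the squared resultant length of the doubled-angle gradient distribution:
#' 1 for unidirectional gradients, 0 for isotropic blocks. All-zero blocks
#' (0/0) return 0. Invariant under global rescaling of the image.
#'
#' @inheritParams block_orientation
#' @return Matrix of per-block coherence values in `[0, 1]`.
#' @export
block_coherence <- function(grad, block_size = 5) {
  if (block_size < 2) stop("`block_size` must be >= 2", call. = FALSE)
  ids <- .block_ids(nrow(grad$g1), ncol(grad$g1), block_size)
  d <- .block_sum(grad$g1^2 - grad$g2^2, ids)
  x <- .block_sum(grad$g1 * grad$g2, ids)
  s <- .block_sum(grad$g1^2 + grad$g2^2, ids)
  C <- matrix(0, nrow(d), ncol(d))
  ok <- s > 0
  C[ok] <- (d[ok]^2 + 4 * x[ok]^2) / s[ok]^2
  pmin(pmax(C, 0), 1)
}

# Gaussian smoothing on a small lattice with replicate padding.
.gauss_smooth <- function(M, sigma, truncate = 5) {
  if (sigma <= 0) return(M)
  r <- max(1L, ceiling(truncate * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n1 <- nrow(M); n2 <- ncol(M)
  clamp <- function(idx, n) pmin(pmax(idx, 1L), n)
  # separable convolution
  tmp <- matrix(0, n1, n2)
  for (o in -r:r) {
    tmp <- tmp + k[o + r + 1] * M[clamp(seq_len(n1) + o, n1), , drop = FALSE]
  }
  out <- matrix(0, n1, n2)
  for (o in -r:r) {
    out <- out + k[o + r + 1] * tmp[, clamp(seq_len(n2) + o, n2), drop = FALSE]
  }
  out
}

#' Smooth a block orientation field on the doubled circle
#'
#' Orientations are defined modulo pi, so the field is smoothed through its
#' doubled-angle embedding: Gaussian convolution (replicate boundary) of
#' `sin(2 O)` and `cos(2 O)` on the block lattice, then
#' `theta = 0.5 * atan2(smoothed sin, smoothed cos)`. Neighbouring blocks at
#' +85 and -85 degrees therefore average toward 90 degrees, not 0.
#' `sigma = 0` returns the input unchanged.
#'
#' @param O Matrix of block angles (radians).
#' @param sigma Gaussian standard deviation in block units (>= 0).
#' @return Matrix of smoothed angles `theta`, same shape as `O`.
#' @export
smooth_orientation <- function(O, sigma = 1) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(O)
  s <- .gauss_smooth(sin(2 * O), sigma)
  c_ <- .gauss_smooth(cos(2 * O), sigma)
  0.5 * atan2(s, c_)
}

#' Map coherence to the ellipse major-axis length
#'
#' Affine map `alpha = (alpha_max - 1) * C + 1`: an incoherent pixel
#' (`C = 0`) gets a circle (`alpha = 1`, DDTV reduces to TV there) and a
#' fully coherent pixel gets the maximum axis `alpha_max`.
#'
#' @param C Coherence value(s) in `[0, 1]`.
#' @param alpha_max Maximum major-axis length (>= 1).
#' @return Axis length(s) in `[1, alpha_max]`.
#' @export
axis_length <- function(C, alpha_max) {
  if (any(!is.finite(C)) || any(C < 0) || any(C > 1)) {
    stop("`C` must lie in [0, 1]", call. = FALSE)
  }
  if (alpha_max < 1) stop("`alpha_max` must be >= 1", call. = FALSE)
  (alpha_max - 1) * C + 1
}

#' Estimate the full orientation field of an image
#'
#' Pipeline: backward-difference gradients, per-block orientation and
#' coherence from the gradient moments, doubled-angle Gaussian smoothing of
#' the block orientations, then broadcast of each block's `(theta, C)` to
#' all of its pixels and the affine coherence-to-axis map. The defaults
#' (5 x 5 blocks, smoothing sigma of 1 block) follow common practice for
#' gradient-based orientation fields; trailing partial blocks are treated as
#' full blocks over their available pixels so every pixel is assigned.
#'
#' @param A Image matrix.
#' @param block_size Block side length in pixels (default 5).
#' @param sigma Orientation-smoothing standard deviation in block units.
#' @param alpha_max Maximum ellipse major-axis length.
#' @return An `orientation_field` object: per-pixel matrices `theta`
#'   (radians, modulo pi), `coherence` in `[0, 1]`, `alpha` in
#'   `[1, alpha_max]`, plus the block-level fields in `$block`.
#' @export
estimate_orientation_field <- function(A, block_size = 5, sigma = 1,
                                       alpha_max = 2.5) {
  grad <- image_gradients(A)
  bo <- block_orientation(grad, block_size)
  theta_b <- smooth_orientation(bo$O, sigma)
  C_b <- block_coherence(grad, block_size)
  ids <- .block_ids(nrow(A), ncol(A), block_size)
  theta <- theta_b[ids$bi, ids$bj, drop = FALSE]
  C <- C_b[ids$bi, ids$bj, drop = FALSE]
  structure(
    list(
      theta = theta,
      coherence = C,
      alpha = axis_length(C, alpha_max),
      block = list(O = bo$O, theta = theta_b, coherence = C_b,
                   degenerate = bo$degenerate),
      block_size = as.integer(block_size),
      sigma = sigma,
      alpha_max = alpha_max
    ),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf(
    "<orientation_field> %d x %d pixels, block_size=%d, alpha in [%.2f, %.2f]\n",
    nrow(x$theta), ncol(x$theta), x$block_size, min(x$alpha), max(x$alpha)))
  invisible(x)
}
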