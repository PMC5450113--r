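#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10( Nx Ny MAXI^2 / sum (A - ref)^2 )` with the peak value
#' `MAXI` fixed at 1: both images are expected to be normalized to `[0, 1]`
#' (see [normalize_image()]) before comparison, so reconstructions with
#' different overall gray levels are compared fairly. Identical images give
#' `Inf` (flagged, not an error).
#'
#' @param A Image matrix.
#' @param ref Reference image matrix of the same shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(A, ref) {
  if (!all(dim(A) == dim(ref))) {
    stop("images must have the same shape", call. = FALSE)
  }
  sse <- sum((A - ref)^2)
  if (sse == 0) return(Inf)
  10 * log10(length(A) / sse)
}

#' Normalized L2 distance to a reference image
#'
#' `d = sqrt( sum (A - ref)^2 / sum ref^2 )`: 0 for a perfect
#' reconstruction, 1 for the zero image. Used as the per-iteration
#' convergence measure of the iterative solvers.
#'
#' @inheritParams psnr
#' @return Nonnegative scalar.
#' @export
distance_d <- function(A, ref) {
  if (!all(dim(A) == dim(ref))) {
    stop("images must have the same shape", call. = FALSE)
  }
  den <- sum(ref^2)
  if (den == 0) stop("`ref` must not be all zero", call. = FALSE)
  sqrt(sum((A - ref)^2) / den)
}

#' Extract a line profile from an image
#'
#' Returns a single row or column of pixel values, for profile plots
#' comparing reconstructions with the ground truth along one line.
#'
#' @param A Image matrix.
#' @param row Row index (x index), or `NULL`.
#' @param col Column index (y index), or `NULL`; exactly one of `row`/`col`
#'   must be given.
#' @return Numeric vector of pixel values.
#' @export
line_profile <- function(A, row = NULL, col = NULL) {
  if (is.null(row) == is.null(col)) {
    stop("give exactly one of `row` or `col`", call. = FALSE)
  }
  if (!is.null(row)) {
    if (row < 1 || row > nrow(A)) stop("row index out of range", call. = FALSE)
    return(A[row, ])
  }
  if (col < 1 || col > ncol(A)) stop("column index out of range", call. = FALSE)
  A[, col]
}

#' Metric report for a reconstruction
#'
#' Normalizes the reconstruction (negative values clipped to zero, maximum
#' scaled to 1) and the reference, then computes PSNR and the normalized
#' distance `d`.
#'
#' @param A Reconstructed image.
#' @param ref Ground-truth image.
#' @return A one-row `data.frame` with `psnr_db` and `distance_d`.
#' @export
metric_report <- function(A, ref) {
  An <- normalize_image(pmax(unclass(A), 0))
  rn <- normalize_image(ref)
  data.frame(psnr_db = psnr(An, rn), distance_d = distance_d(An, rn))
}
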