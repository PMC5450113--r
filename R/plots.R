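#' Display an image matrix
#'
#' Grayscale display in the package's coordinate convention (x rightward,
#' y upward).
#'
#' @param A Image matrix.
#' @param grid Optional `pat_grid` supplying physical axes (mm).
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot_image <- function(A, grid = NULL, main = "", ...) {
  A <- unclass(A)
  x <- if (is.null(grid)) seq_len(nrow(A)) else grid$x
  y <- if (is.null(grid)) seq_len(ncol(A)) else grid$y
  graphics::image(x, y, A, col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, main = main, xlab = "x", ylab = "y",
                  useRaster = TRUE, ...)
}

#' Quiver plot of an orientation field
#'
#' Draws one arrow per block, oriented along the estimated texture
#' direction and scaled by the coherence, over the image it was estimated
#' from; the standard diagnostic for orientation-field estimates.
#'
#' @param field An `orientation_field`.
#' @param A Optional background image.
#' @param scale Arrow length of a fully coherent block, in pixels.
#' @export
plot_orientation_field <- function(field, A = NULL, scale = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  b <- field$block_size
  th <- field$block$theta
  C <- field$block$coherence
  if (is.null(scale)) scale <- b
  if (!is.null(A)) plot_image(A) else {
    graphics::plot(NA, xlim = c(1, nrow(field$theta)),
                   ylim = c(1, ncol(field$theta)), asp = 1,
                   xlab = "x", ylab = "y")
  }
  cx <- (seq_len(nrow(th)) - 0.5) * b
  cy <- (seq_len(ncol(th)) - 0.5) * b
  for (i in seq_len(nrow(th))) {
    for (j in seq_len(ncol(th))) {
      len <- scale * C[i, j] / 2
      if (len <= 0) next
      dx <- len * cos(th[i, j])
      dy <- len * sin(th[i, j])
      graphics::segments(cx[i] - dx, cy[j] - dy, cx[i] + dx, cy[j] + dy,
                         col = "red")
    }
  }
  invisible(NULL)
}

#' Compare line profiles of reconstructions with the ground truth
#'
#' @param ref Ground-truth image.
#' @param images Named list of reconstructed images.
#' @param row,col Line selector, passed to [line_profile()].
#' @export
plot_profiles <- function(ref, images, row = NULL, col = NULL) {
  pr <- line_profile(normalize_image(ref), row, col)
  graphics::plot(pr, type = "l", lwd = 2, xlab = "pixel", ylab = "value",
                 ylim = range(0, 1.05))
  cols <- seq_along(images) + 1
  for (k in seq_along(images)) {
    pk <- line_profile(normalize_image(pmax(unclass(images[[k]]), 0)), row, col)
    graphics::lines(pk, col = cols[k])
  }
  graphics::legend("topright", legend = c("reference", names(images)),
                   col = c(1, cols), lty = 1, cex = 0.8)
}

#' Plot per-iteration convergence traces
#'
#' Plots the normalized distance `d` per outer iteration for one or more
#' reconstruction traces.
#'
#' @param traces Named list of trace data frames (see [recon_trace()]).
#' @export
plot_convergence <- function(traces) {
  rng <- range(unlist(lapply(traces, function(t) t$d)), na.rm = TRUE)
  graphics::plot(NA, xlim = c(1, max(sapply(traces, nrow))), ylim = rng,
                 xlab = "iteration", ylab = "distance d")
  for (k in seq_along(traces)) {
    graphics::lines(traces[[k]]$iter, traces[[k]]$d, col = k + 1, type = "b")
  }
  graphics::legend("topright", legend = names(traces),
                   col = seq_along(traces) + 1, lty = 1, cex = 0.8)
}
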