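#' Triangular arc-interpolation weight
#'
#' Weight given to a pixel at distance `dist` from a detector for the time
#' sample `t_h`: `1 - |t_h/dt - dist/(c*dt)|` when that offset is below one
#' time bin, 0 otherwise. This linear interpolation spreads each arc over the
#' two adjacent time bins so the discrete arc does not have to coincide with
#' pixel centres.
#'
#' @param t_h Sample time (s); may be a vector.
#' @param dist Detector-to-pixel distance (mm); may be a vector.
#' @param c Speed of sound (m/s).
#' @param dt Time step (s).
#' @return Weight(s) in `[0, 1]`.
#' @export
arc_weight <- function(t_h, dist, c, dt) {
  off <- abs(t_h / dt - dist / (c * 1000 * dt))
  ifelse(off < 1, 1 - off, 0)
}

#' Build the sparse spherical-mean system matrix
#'
#' Discretizes the arc-integral forward model: the g-sample of detector `l`
#' at time bin `h` is a weighted sum of image pixels lying within one time
#' bin of the arc of radius `c * t_h` centred at the detector, with the
#' triangular weight of [arc_weight()]. The operator is stored as a single
#' sparse matrix with `M * S` rows (g samples, detector-major: row
#' `(l-1) * S + h`) and `n_x * n_y` columns (pixels in column-major order),
#' so the adjoint used by the iterative solvers is its exact transpose.
#'
#' @param geom A `scan_geometry`.
#' @param grid A `pat_grid`.
#' @param sampling A `pat_sampling`; must cover all detector-pixel distances
#'   (a warning is emitted for pixels never reached within `n_samples`).
#' @return A `pat_weights` object wrapping the `Matrix::sparseMatrix` in
#'   field `W`, plus the geometry/grid/sampling it was built from.
#' @export
build_weight_matrix <- function(geom, grid, sampling) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(grid, "pat_grid"),
            inherits(sampling, "pat_sampling"))
  nx <- grid$n_x
  ny <- grid$n_y
  S <- sampling$n_samples
  M <- geom$n_views
  c_mm <- sampling$c * 1000
  px <- rep(grid$x, times = ny)   # pixel m = i + (j-1) nx
  py <- rep(grid$y, each = nx)
  ii <- vector("list", M)
  jj <- vector("list", M)
  ww <- vector("list", M)
  uncovered <- FALSE
  for (l in seq_len(M)) {
    d <- sqrt((px - geom$positions[l, 1])^2 + (py - geom$positions[l, 2])^2)
    u <- d / (c_mm * sampling$dt)   # arrival position on the time-bin axis
    if (any(u >= S + 1)) uncovered <- TRUE
    h0 <- floor(u)
    rows <- integer(0); cols <- integer(0); wts <- numeric(0)
    for (dh in 0:1) {
      h <- h0 + dh
      w <- 1 - abs(h - u)
      keep <- w > 0 & h >= 1 & h <= S
      if (any(keep)) {
        rows <- c(rows, (l - 1L) * S + as.integer(h[keep]))
        cols <- c(cols, which(keep))
        wts <- c(wts, w[keep])
      }
    }
    ii[[l]] <- rows
    jj[[l]] <- cols
    ww[[l]] <- wts
  }
  if (uncovered) {
    warning("`n_samples` does not cover every detector-pixel distance; ",
            "some pixels are invisible to parts of the scan", call. = FALSE)
  }
  W <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(ww),
    dims = c(M * S, nx * ny)
  )
  structure(
    list(W = W, geom = geom, grid = grid, sampling = sampling),
    class = "pat_weights"
  )
}

#' @export
print.pat_weights <- function(x, ...) {
  cat(sprintf("<pat_weights> %d x %d sparse system matrix (%d nonzeros)\n",
              nrow(x$W), ncol(x$W), length(x$W@x)))
  invisible(x)
}

.as_pixel_vector <- function(A, grid) {
  if (!is.matrix(A) || nrow(A) != grid$n_x || ncol(A) != grid$n_y) {
    stop("image shape does not match the grid", call. = FALSE)
  }
  as.vector(A)
}

.g_to_vector <- function(values, S) as.vector(t(values))  # detector-major

.vector_to_g <- function(v, M, S) t(matrix(v, nrow = S, ncol = M))

#' Apply the forward model
#'
#' Computes the integrated-signal sinogram `g = W A'` for an image on the
#' grid the matrix was built for.
#'
#' @param W A `pat_weights` object.
#' @param A Numeric image matrix matching the grid of `W`.
#' @return A `pat_sinogram` tagged `integrated_g`.
#' @export
forward_project <- function(W, A) {
  stopifnot(inherits(W, "pat_weights"))
  v <- .as_pixel_vector(A, W$grid)
  gv <- as.numeric(W$W %*% v)
  sinogram(.vector_to_g(gv, W$geom$n_views, W$sampling$n_samples),
           "integrated_g", W$geom, W$sampling)
}

#' Apply the adjoint (back-projection) of the forward model
#'
#' Exact transpose application, so that
#' `sum(forward_project(W, A) * s) == sum(A * adjoint_project(W, s))`.
#'
#' @param W A `pat_weights` object.
#' @param s A `pat_sinogram` (or plain M x S matrix) matching `W`.
#' @return Image matrix on the grid of `W`.
#' @export
adjoint_project <- function(W, s) {
  stopifnot(inherits(W, "pat_weights"))
  values <- if (inherits(s, "pat_sinogram")) s$values else as.matrix(s)
  if (nrow(values) != W$geom$n_views ||
      ncol(values) != W$sampling$n_samples) {
    stop("sinogram shape does not match the system matrix", call. = FALSE)
  }
  v <- as.numeric(Matrix::crossprod(W$W, .g_to_vector(values, W$sampling$n_samples)))
  matrix(v, nrow = W$grid$n_x, ncol = W$grid$n_y)
}

#' Convert a pressure sinogram to the integrated g-domain
#'
#' Applies `g(t) = t * integral_0^t p dt` (the constant `4 pi C_p / beta`
#' is folded to 1, see [make_sampling()]), by cumulative-sum quadrature.
#' Exact inverse of [differentiate_to_pressure()] on the discrete grid.
#'
#' @param p A `pat_sinogram` tagged `pressure_p`.
#' @param sampling Optional `pat_sampling` override (defaults to the one in `p`).
#' @return A `pat_sinogram` tagged `integrated_g`.
#' @export
pressure_to_g <- function(p, sampling = NULL) {
  stopifnot(inherits(p, "pat_sinogram"))
  if (p$domain != "pressure_p") {
    stop("`p` must be a pressure-domain sinogram", call. = FALSE)
  }
  if (is.null(sampling)) sampling <- p$sampling
  cs <- t(apply(p$values, 1, cumsum)) * sampling$dt
  g <- sweep(cs, 2, sampling$t, `*`)
  sinogram(g, "integrated_g", p$geom, sampling)
}

#' Largest singular value (squared) of the system matrix
#'
#' Deterministic power iteration on `W^T W`; the start vector is fixed, so
#' repeated calls agree exactly. Since all weights are nonnegative the
#' leading singular vector is nonnegative and the all-ones start vector has
#' a nonzero component along it.
#'
#' @param W A `pat_weights` object.
#' @param iters Number of power-iteration steps.
#' @return List with `sigma` (largest singular value), `sigma2` (its square,
#'   the Lipschitz scale of the normal operator) and `frobenius`.
#' @export
w_norms <- function(W, iters = 20) {
  stopifnot(inherits(W, "pat_weights"))
  n <- ncol(W$W)
  v <- rep(1, n) / sqrt(n)
  lam <- 0
  for (k in seq_len(iters)) {
    u <- as.numeric(W$W %*% v)
    v2 <- as.numeric(Matrix::crossprod(W$W, u))
    lam <- sqrt(sum(v2^2))
    v <- v2 / lam
  }
  list(sigma = sqrt(lam), sigma2 = lam,
       frobenius = sqrt(sum(W$W@x^2)))
}
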