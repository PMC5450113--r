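#' Reconstruction configuration
#'
#' Collects the tunable parameters of the iterative solvers. Defaults follow
#' the package's reference simulation settings: 10 outer iterations (each
#' re-estimating the orientation field), 50 inner solver steps per outer
#' iteration, 5 x 5 orientation blocks, orientation smoothing of 1 block,
#' and warm-started dual fields.
#'
#' @param lambda_reg DDTV regularization weight (default 0.01, suited to
#'   piecewise-smooth images like Shepp-Logan; larger values such as 1.2
#'   for strongly textured images).
#' @param alpha_max Maximum ellipse axis (2.5 for weakly directional images,
#'   up to 10 for strong textures; 1 reduces DDTV to TV).
#' @param outer_iters Outer iterations (orientation refresh + solve).
#' @param inner_iters Solver steps per outer iteration: interleaved
#'   primal-dual steps for `scheme = "interleaved"`, dual projected-gradient
#'   steps of the proximal subproblem for `scheme = "sequential"`.
#' @param block_size Orientation-field block side in pixels.
#' @param sigma Orientation-smoothing standard deviation in block units.
#' @param tv_lambda_schedule Length-2 numeric `(initial, floor)` for the TV
#'   baseline: lambda decays geometrically from `initial` at the first
#'   iteration toward `floor`, reaching it after 10 iterations.
#' @param warm_start Logical; carry the dual fields across outer iterations.
#' @param scheme `"interleaved"` (default) alternates one data step and one
#'   dual regularizer step inside the inner loop, so each outer iteration
#'   advances a convergent primal-dual solve of the full regularized
#'   problem under the current orientation field. `"sequential"` is the
#'   literal two-stage composition: one normalized data gradient step, then
#'   the full proximal subproblem; it needs far more outer iterations to
#'   make the same progress.
#' @param step_rule Normalization of the `"sequential"` data gradient step:
#'   `"sigma2"` (largest eigenvalue of `W W^T`; a non-expansive descent
#'   step), `"sigma"` (largest singular value), or `"frobenius"`.
#' @param power_iters Power-iteration steps for the spectral norm.
#' @return A `recon_config` list.
#' @export
recon_config <- function(lambda_reg = 0.01, alpha_max = 2.5,
                         outer_iters = 10, inner_iters = 50,
                         block_size = 5, sigma = 1,
                         tv_lambda_schedule = c(2, 0.2),
                         warm_start = TRUE,
                         scheme = c("interleaved", "sequential"),
                         step_rule = c("sigma2", "sigma", "frobenius"),
                         power_iters = 20) {
  if (lambda_reg <= 0) stop("`lambda_reg` must be positive", call. = FALSE)
  if (alpha_max < 1) stop("`alpha_max` must be >= 1", call. = FALSE)
  if (outer_iters < 1) stop("`outer_iters` must be >= 1", call. = FALSE)
  structure(
    list(lambda_reg = lambda_reg, alpha_max = alpha_max,
         outer_iters = as.integer(outer_iters),
         inner_iters = as.integer(inner_iters),
         block_size = as.integer(block_size), sigma = sigma,
         tv_lambda_schedule = tv_lambda_schedule,
         warm_start = isTRUE(warm_start),
         scheme = match.arg(scheme),
         step_rule = match.arg(step_rule),
         power_iters = as.integer(power_iters)),
    class = "recon_config"
  )
}

# lambda schedule of the TV baseline: geometric decay from `initial`,
# reaching `floor` after 10 iterations and staying there.
.tv_lambda <- function(s, schedule) {
  initial <- schedule[1]
  floor_ <- schedule[2]
  max(floor_, initial * (floor_ / initial)^(min(s - 1, 10) / 10))
}

.step_scale <- function(W, cfg) {
  nrms <- w_norms(W, iters = cfg$power_iters)
  switch(cfg$step_rule,
         sigma2 = nrms$sigma2,
         sigma = nrms$sigma,
         frobenius = nrms$frobenius)
}

#' Data-fidelity gradient step
#'
#' One normalized gradient step on `||W A' - g||^2`: the residual
#' `r = W A' - g` is back-projected and subtracted,
#' `Grad(A) = A - adjoint(r) / ||W||`. With the default `"sigma2"`
#' normalization (largest eigenvalue of the normal operator) the step never
#' increases the fidelity term.
#'
#' @param W A `pat_weights` object.
#' @param A Current image matrix.
#' @param g A `pat_sinogram` tagged `integrated_g` (or plain matrix).
#' @param norm_w Precomputed normalization constant (see [w_norms()]); if
#'   `NULL`, the `"sigma2"` norm is computed.
#' @return List with `grad` (updated image) and `residual_norm2` (the
#'   fidelity value at `A`).
#' @export
grad_step <- function(W, A, g, norm_w = NULL) {
  values <- if (inherits(g, "pat_sinogram")) g$values else as.matrix(g)
  if (is.null(norm_w)) norm_w <- w_norms(W)$sigma2
  gv <- .g_to_vector(values, W$sampling$n_samples)
  r <- as.numeric(W$W %*% .as_pixel_vector(A, W$grid)) - gv
  dA <- -matrix(as.numeric(Matrix::crossprod(W$W, r)),
                nrow = W$grid$n_x, ncol = W$grid$n_y) / norm_w
  list(grad = A + dA, residual_norm2 = sum(r^2))
}

# Shared outer loop of the model-based solvers. `lambda_fun(s)` gives the
# regularization weight at outer iteration s; `alpha_max = 1` turns the
# prior into classical TV.
.reconstruct_iterative <- function(g, W, cfg, lambda_fun, alpha_max,
                                   reference = NULL) {
  stopifnot(inherits(g, "pat_sinogram"), inherits(W, "pat_weights"))
  if (g$domain != "integrated_g") {
    stop("model-based reconstruction consumes integrated-g sinograms",
         call. = FALSE)
  }
  nx <- W$grid$n_x
  ny <- W$grid$n_y
  gv <- .g_to_vector(g$values, W$sampling$n_samples)
  nrms <- w_norms(W, iters = cfg$power_iters)
  seq_norm <- switch(cfg$step_rule, sigma2 = nrms$sigma2,
                     sigma = nrms$sigma, frobenius = nrms$frobenius)
  A <- matrix(0, nx, ny)
  Ab <- A
  y <- numeric(length(gv))   # data dual (interleaved scheme)
  dual <- NULL               # regularizer dual
  first_fid <- NA_real_
  ref_n <- if (is.null(reference)) NULL else normalize_image(reference)
  trace <- vector("list", cfg$outer_iters)

  for (s in seq_len(cfg$outer_iters)) {
    lam <- lambda_fun(s)
    field <- estimate_orientation_field(A, cfg$block_size, cfg$sigma,
                                        alpha_max)
    fid <- sum((as.numeric(W$W %*% as.vector(A)) - gv)^2)
    if (s == 1) first_fid <- max(fid, 1e-12)
    if (fid > 10 * first_fid) {
      stop(sprintf(
        "iteration diverged: fidelity grew from %.3e to %.3e at step %d",
        first_fid, fid, s), call. = FALSE)
    }
    dmax <- 0
    if (cfg$scheme == "sequential") {
      gs <- grad_step(W, A, g, seq_norm)
      A <- ddtv_prox(gs$grad, field, lam, cfg$inner_iters,
                     warm_start = if (cfg$warm_start) dual else NULL)
      dual <- attr(A, "dual")
      dmax <- max(attr(A, "dual_max"))
      attributes(A) <- attributes(A)["dim"]
      Ab <- A
    } else {
      ct <- cos(field$theta); st <- sin(field$theta); a <- field$alpha
      if (is.null(dual) || !cfg$warm_start) {
        dual <- list(G1 = matrix(0, nx, ny), G2 = matrix(0, nx, ny))
      }
      G1 <- dual$G1; G2 <- dual$G2
      # primal-dual step sizes: tau * sigma_d * ||[W; lam K]||^2 <= 1
      L <- sqrt(nrms$sigma2 + 8 * max(a)^2 * lam^2)
      tau <- 1 / L
      sg <- 1 / L
      for (n in seq_len(cfg$inner_iters)) {
        v <- y + sg * as.numeric(W$W %*% as.vector(Ab))
        y <- (v - sg * gv) / (1 + sg / 2)
        q <- .K_apply(Ab, ct, st, a)
        G1p <- G1 + sg * lam * q$q1
        G2p <- G2 + sg * lam * q$q2
        nrm <- pmax(sqrt(G1p^2 + G2p^2), 1)
        G1 <- G1p / nrm
        G2 <- G2p / nrm
        dmax <- max(dmax, max(sqrt(G1^2 + G2^2)))
        Aold <- A
        A <- A - tau * (matrix(as.numeric(Matrix::crossprod(W$W, y)), nx, ny) +
                          lam * .Kt_apply(G1, G2, ct, st, a))
        Ab <- 2 * A - Aold
      }
      dual <- list(G1 = G1, G2 = G2)
    }
    fid_post <- sum((as.numeric(W$W %*% as.vector(A)) - gv)^2)
    reg <- ddtv_value(A, field)
    trace[[s]] <- data.frame(
      iter = s, lambda = lam,
      fidelity = fid_post,
      regularizer = reg,
      objective = fid_post + lam * reg,
      dual_max = dmax,
      d = if (is.null(ref_n)) NA_real_ else {
        distance_d(normalize_image(pmax(A, 0)), ref_n)
      }
    )
  }
  structure(A,
            class = c("pat_recon", "matrix"),
            trace = do.call(rbind, trace),
            config = cfg)
}

#' DDTV model-based reconstruction
#'
#' Minimizes `||W A' - g||^2 + lambda * DDTV(A)` with the orientation field
#' (theta, coherence, alpha) re-estimated from the current iterate at each
#' of the `outer_iters` (default 10) outer iterations, starting from the
#' zero image. Within an outer iteration the regularized problem under the
#' frozen field is advanced by `inner_iters` warm-started solver steps: by
#' default interleaved primal-dual steps (a data-dual update, a projected
#' dual step on the per-pixel ellipse field with
#' `||Gamma_ij|| <= 1`, and a primal gradient update), or, with
#' `scheme = "sequential"`, the literal two-stage normalized gradient step
#' plus proximal subproblem. Because the initial image is zero, the first
#' orientation field is degenerate (coherence 0, alpha 1) and the first
#' outer iteration is a plain TV iteration; directionality enters from the
#' second iteration on.
#'
#' @param g A `pat_sinogram` tagged `integrated_g`.
#' @param W A `pat_weights` built for the same geometry/sampling.
#' @param cfg A [recon_config()].
#' @param reference Optional ground-truth image; when supplied, the
#'   per-iteration normalized distance `d` is recorded in the trace.
#' @return The reconstructed image (class `pat_recon`), with a per-iteration
#'   `data.frame` in `attr(, "trace")` recording lambda, fidelity, the
#'   regularizer value, objective, maximum dual norm and (optionally) `d`.
#' @export
reconstruct_ddtv <- function(g, W, cfg = recon_config(), reference = NULL) {
  .reconstruct_iterative(g, W, cfg, function(s) cfg$lambda_reg,
                         cfg$alpha_max, reference)
}

#' Classical TV model-based reconstruction (baseline)
#'
#' Identical outer loop to [reconstruct_ddtv()] with the ellipse axis fixed
#' at 1 (the TV limit of the directional prior) and the adaptive lambda
#' schedule of `cfg$tv_lambda_schedule`: lambda starts at its initial value
#' and decays geometrically to the floor over 10 iterations.
#'
#' @inheritParams reconstruct_ddtv
#' @return The reconstructed image (class `pat_recon`) with the same trace
#'   attribute as [reconstruct_ddtv()].
#' @export
reconstruct_tv <- function(g, W, cfg = recon_config(), reference = NULL) {
  .reconstruct_iterative(g, W, cfg,
                         function(s) .tv_lambda(s, cfg$tv_lambda_schedule),
                         alpha_max = 1, reference = reference)
}

#' Accessor for the per-iteration trace of a reconstruction
#'
#' @param x A `pat_recon` object.
#' @return The trace `data.frame`.
#' @export
recon_trace <- function(x) attr(x, "trace")

#' Filtered back-projection baseline
#'
#' Classical delay-and-sum back-projection for circular (full or limited
#' arc) geometries: each pressure trace is filtered to
#' `q(t) = 2 p(t) - 2 t dp/dt` (the back-projection term of the universal
#' circular-geometry formula) and summed over detectors at the pixel's
#' acoustic delay with linear interpolation in time. The output is clipped
#' at zero and normalized to `[0, 1]`. Linear geometries are not supported
#' (linear-scan comparisons use the model-based solvers only).
#'
#' @param p A `pat_sinogram` tagged `pressure_p`.
#' @param geom A circular or limited-view `scan_geometry`.
#' @param grid A `pat_grid`.
#' @param sampling A `pat_sampling`.
#' @return Reconstructed image matrix, normalized to `[0, 1]`.
#' @export
reconstruct_fbp <- function(p, geom, grid, sampling) {
  stopifnot(inherits(p, "pat_sinogram"))
  if (p$domain != "pressure_p") {
    stop("FBP consumes pressure-domain sinograms", call. = FALSE)
  }
  if (geom$mode == "linear") {
    stop("FBP is not supported for linear scan geometries", call. = FALSE)
  }
  S <- sampling$n_samples
  tt <- sampling$t
  c_mm <- sampling$c * 1000
  px <- rep(grid$x, times = grid$n_y)
  py <- rep(grid$y, each = grid$n_x)
  b <- numeric(grid$n_x * grid$n_y)
  for (l in seq_len(geom$n_views)) {
    pr <- p$values[l, ]
    dp <- c(diff(pr), 0) / sampling$dt
    q <- 2 * pr - 2 * tt * dp
    d <- sqrt((px - geom$positions[l, 1])^2 + (py - geom$positions[l, 2])^2)
    u <- d / (c_mm * sampling$dt)
    h0 <- pmin(pmax(floor(u), 1), S - 1)
    fr <- pmin(pmax(u - h0, 0), 1)
    b <- b + (1 - fr) * q[h0] + fr * q[h0 + 1]
  }
  A <- matrix(b, grid$n_x, grid$n_y)
  normalize_image(pmax(A, 0))
}
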