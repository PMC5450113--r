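# Small shared problem for the solver tests
rc_grid <- make_grid(32, 32, 32)
rc_geom <- circular_scan(12, 24)
rc_samp <- sampling_for(rc_geom, rc_grid)
rc_W <- build_weight_matrix(rc_geom, rc_grid, rc_samp)

test_that("the normalized gradient step never increases the data fidelity", {
  nw <- w_norms(rc_W)$sigma2
  g <- forward_project(rc_W, disk_phantom(rc_grid, 8))
  for (seed in 1:4) {
    set.seed(seed)
    A <- matrix(rnorm(32 * 32), 32, 32)
    gs <- grad_step(rc_W, A, g, nw)
    fid_before <- gs$residual_norm2
    fid_after <- sum((forward_project(rc_W, gs$grad)$values - g$values)^2)
    expect_lte(fid_after, fid_before * (1 + 1e-12))
  }
  # zero residual leaves the image unchanged
  A0 <- disk_phantom(rc_grid, 8)
  gs <- grad_step(rc_W, A0, forward_project(rc_W, A0), nw)
  expect_equal(gs$grad, A0, tolerance = 1e-10)
  # from zero, the step is a scaled back-projection
  gs0 <- grad_step(rc_W, matrix(0, 32, 32), g, nw)
  expect_equal(gs0$grad, adjoint_project(rc_W, g) / nw, tolerance = 1e-12)
})

test_that("zero data reconstructs to the zero image for every method", {
  zero <- sinogram(matrix(0, rc_geom$n_views, rc_samp$n_samples),
                   "integrated_g", rc_geom, rc_samp)
  cfg <- recon_config(outer_iters = 3, inner_iters = 5)
  expect_true(all(reconstruct_ddtv(zero, rc_W, cfg) == 0))
  expect_true(all(reconstruct_tv(zero, rc_W, cfg) == 0))
  zp <- sinogram(matrix(0, rc_geom$n_views, rc_samp$n_samples),
                 "pressure_p", rc_geom, rc_samp)
  expect_true(all(reconstruct_fbp(zp, rc_geom, rc_grid, rc_samp) == 0))
})

test_that("the TV baseline is bit-identical to DDTV with unit maximum axis", {
  ph <- disk_phantom(rc_grid, 7)
  g <- simulate_spherical_means(ph, rc_geom, rc_samp, rc_grid, upsample = 4)
  lam <- 0.05
  cfg_tv <- recon_config(lambda_reg = 0.5, alpha_max = 2.5,
                         outer_iters = 4, inner_iters = 10,
                         tv_lambda_schedule = c(lam, lam))
  cfg_dd <- recon_config(lambda_reg = lam, alpha_max = 1,
                         outer_iters = 4, inner_iters = 10)
  a <- reconstruct_tv(g, rc_W, cfg_tv)
  b <- reconstruct_ddtv(g, rc_W, cfg_dd)
  expect_identical(matrix(as.numeric(a), 32, 32), matrix(as.numeric(b), 32, 32))
  expect_identical(recon_trace(a)$fidelity, recon_trace(b)$fidelity)
})

test_that("both schemes reconstruct a disk and record a sane trace", {
  ph <- disk_phantom(rc_grid, 7, antialias = 2)
  g <- simulate_spherical_means(ph, rc_geom, rc_samp, rc_grid, upsample = 8)
  cfg <- recon_config(lambda_reg = 0.02, outer_iters = 6, inner_iters = 40)
  rec <- reconstruct_ddtv(g, rc_W, cfg, reference = ph)
  tr <- recon_trace(rec)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$dual_max <= 1 + 1e-12))
  expect_true(all(diff(tr$d) < 0.05))        # no divergence of the error
  expect_lt(tr$d[6], 0.35)
  expect_gt(metric_report(rec, ph)$psnr_db, 18)

  seq_cfg <- recon_config(lambda_reg = 0.02, outer_iters = 6,
                          inner_iters = 10, scheme = "sequential")
  rec_seq <- reconstruct_ddtv(g, rc_W, seq_cfg, reference = ph)
  expect_true(all(diff(recon_trace(rec_seq)$fidelity) <= 1e-9))
})

test_that("the TV lambda schedule decays geometrically to its floor", {
  sched <- sapply(1:12, ddtvpat:::.tv_lambda, schedule = c(2, 0.2))
  expect_equal(sched[1], 2)
  expect_equal(sched[11], 0.2)
  expect_equal(sched[12], 0.2)
  expect_true(all(diff(sched[1:11]) < 0))
  ratio <- sched[2:10] / sched[1:9]
  expect_equal(ratio, rep(ratio[1], 9), tolerance = 1e-12)
})

test_that("FBP localizes point and disk absorbers in a full-view scan", {
  grid <- make_grid(64, 64, 64)
  geom <- circular_scan(180, 45)
  samp <- sampling_for(geom, grid)

  imp <- matrix(0, 64, 64); imp[40, 25] <- 1
  g <- simulate_spherical_means(imp, geom, samp, grid, upsample = 4)
  fb <- reconstruct_fbp(differentiate_to_pressure(g), geom, grid, samp)
  peak <- which(fb == max(fb), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(40, 25))), 1)

  disk <- disk_phantom(grid, 12)
  gd <- simulate_spherical_means(disk, geom, samp, grid, upsample = 4)
  fbd <- reconstruct_fbp(differentiate_to_pressure(gd), geom, grid, samp)
  prof <- line_profile(fbd, row = 33)
  half <- which(prof >= 0.5 * max(prof))
  edges_mm <- range(grid$y[half])
  expect_lt(abs(edges_mm[1] + 12), 2 * grid$pixel_mm)
  expect_lt(abs(edges_mm[2] - 12), 2 * grid$pixel_mm)

  lin <- linear_scan(10, 40)
  expect_error(reconstruct_fbp(differentiate_to_pressure(g), lin, grid, samp),
               "linear")
})

test_that("domain tags are enforced by the reconstruction entry points", {
  g <- forward_project(rc_W, disk_phantom(rc_grid, 6))
  p <- differentiate_to_pressure(g)
  expect_error(reconstruct_ddtv(p, rc_W), "integrated-g")
  expect_error(reconstruct_fbp(g, rc_geom, rc_grid, rc_samp), "pressure")
})
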