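test_that("grids have the stated pixel pitch and origin-symmetric centres", {
  g <- make_grid(128, 128, 76.8)
  expect_equal(g$pixel_mm, 0.6)
  expect_equal(g$x, -rev(g$x))
  g4 <- make_grid(4, 4, 4.0)
  expect_equal(g4$x, c(-1.5, -0.5, 0.5, 1.5))
  g1 <- make_grid(1, 1, 1.0)
  expect_equal(g1$x, 0)
  expect_error(make_grid(0, 4, 1), "grid sizes")
  expect_error(make_grid(4, 4, -1), "extent")
})

test_that("arc weights follow the triangular interpolation rule", {
  c <- 1500; dt <- 4e-7
  # distance exactly c*t_h -> weight 1
  expect_equal(arc_weight(10 * dt, c * 1000 * 10 * dt, c, dt), 1)
  # offset of 0.4 bins -> weight 0.6
  expect_equal(arc_weight(10 * dt, c * 1000 * dt * 10.4, c, dt), 0.6)
  # offsets of one bin or more -> 0
  expect_equal(arc_weight(10 * dt, c * 1000 * dt * 11, c, dt), 0)
  expect_equal(arc_weight(10 * dt, c * 1000 * dt * 14.2, c, dt), 0)
})

test_that("sparse system matrix equals the dense double-loop evaluation", {
  grid <- make_grid(8, 8, 8)
  geom <- circular_scan(3, 6, 10)
  samp <- sampling_for(geom, grid)
  W <- build_weight_matrix(geom, grid, samp)
  dense <- dense_weight_oracle(geom, grid, samp)
  expect_equal(as.matrix(W$W), dense, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(W$W@x > 0 & W$W@x <= 1))
})

test_that("forward projection is linear and localizes impulses correctly", {
  grid <- make_grid(16, 16, 16)
  geom <- circular_scan(4, 12)
  samp <- sampling_for(geom, grid)
  W <- build_weight_matrix(geom, grid, samp)

  zero <- forward_project(W, matrix(0, 16, 16))
  expect_true(all(zero$values == 0))
  expect_equal(zero$domain, "integrated_g")

  A <- smooth_random_image(16, 71)
  expect_equal(forward_project(W, 2 * A)$values,
               2 * forward_project(W, A)$values, tolerance = 1e-12)

  # unit impulse: nonzero bins only within one bin of the arrival time
  imp <- matrix(0, 16, 16); imp[5, 9] <- 1
  gs <- forward_project(W, imp)
  c_mm <- samp$c * 1000
  for (l in 1:4) {
    d <- sqrt(sum((c(grid$x[5], grid$y[9]) - geom$positions[l, ])^2))
    hit <- which(gs$values[l, ] != 0)
    expect_true(all(abs(hit - d / (c_mm * samp$dt)) < 1))
  }
  expect_error(forward_project(W, matrix(0, 4, 4)), "shape")
})

test_that("adjoint projection is the exact transpose of the forward model", {
  grid <- make_grid(16, 16, 16)
  geom <- circular_scan(5, 12)
  samp <- sampling_for(geom, grid)
  W <- build_weight_matrix(geom, grid, samp)

  expect_true(all(adjoint_project(W, matrix(0, 5, samp$n_samples)) == 0))
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(256), 16, 16)
    s <- matrix(rnorm(5 * samp$n_samples), 5, samp$n_samples)
    lhs <- sum(forward_project(W, A)$values * s)
    rhs <- sum(A * adjoint_project(W, s))
    expect_lt(abs(lhs - rhs) / max(abs(rhs), 1e-12), 1e-10)
  }
  # one-hot sinogram sample back-projects to the row's arc band
  onehot <- matrix(0, 5, samp$n_samples); onehot[2, 20] <- 1
  band <- adjoint_project(W, onehot)
  row <- as.numeric(W$W[(2 - 1) * samp$n_samples + 20, ])
  expect_equal(as.vector(band), row, tolerance = 1e-14)
})

test_that("row weight sums approximate the arc length in pixel units", {
  grid <- make_grid(64, 64, 64)
  geom <- circular_scan(1, 100)  # far detector: arcs nearly straight chords
  samp <- sampling_for(geom, grid)
  W <- build_weight_matrix(geom, grid, samp)
  rs <- Matrix::rowSums(W$W)
  c_mm <- samp$c * 1000
  # a bin whose arc crosses the middle of the grid
  h <- round(100 / (c_mm * samp$dt))
  # chord of circle radius R=c t_h through the grid: compute by fine sampling
  R <- c_mm * samp$dt * h
  th <- seq(0, 2 * pi, length.out = 200000)
  x <- geom$positions[1, 1] + R * cos(th)
  y <- geom$positions[1, 2] + R * sin(th)
  inside <- x >= min(grid$x) & x <= max(grid$x) & y >= min(grid$y) & y <= max(grid$y)
  arc_px <- sum(inside) / length(th) * 2 * pi * R / grid$pixel_mm
  expect_lt(abs(rs[h] - arc_px), 1 + 0.02 * arc_px)
})

test_that("forward model shifts arrival bins consistently under translation", {
  grid <- make_grid(32, 32, 32)
  geom <- circular_scan(1, 30)  # detector on +x axis
  samp <- sampling_for(geom, grid)
  W <- build_weight_matrix(geom, grid, samp)
  imp1 <- matrix(0, 32, 32); imp1[10, 16] <- 1
  imp2 <- matrix(0, 32, 32); imp2[11, 16] <- 1  # one pixel closer in x
  h1 <- which.max(forward_project(W, imp1)$values[1, ])
  h2 <- which.max(forward_project(W, imp2)$values[1, ])
  shift_bins <- grid$pixel_mm / (samp$c * 1000 * samp$dt)
  expect_equal(h1 - h2, round(shift_bins), tolerance = 1)
})

test_that("pressure integration matches the closed form and round-trips", {
  geom <- circular_scan(2, 10)
  samp <- make_sampling(1500, 4e-7, 40)
  p1 <- sinogram(matrix(1, 2, 40), "pressure_p", geom, samp)
  g <- pressure_to_g(p1)
  expect_equal(g$values[1, ], samp$t^2, tolerance = 1e-12)  # g_h = t_h^2
  expect_equal(g$domain, "integrated_g")

  set.seed(4)
  p <- sinogram(matrix(rnorm(80), 2, 40), "pressure_p", geom, samp)
  expect_equal(differentiate_to_pressure(pressure_to_g(p))$values, p$values,
               tolerance = 1e-10)
  gq <- pressure_to_g(p)
  expect_equal(pressure_to_g(differentiate_to_pressure(gq))$values, gq$values,
               tolerance = 1e-10)
  expect_error(pressure_to_g(g), "pressure")
  expect_error(differentiate_to_pressure(p), "integrated")
})
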