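test_that("image gradients are backward differences with zero boundaries", {
  A <- matrix(5, 4, 4)
  g <- image_gradients(A)
  expect_true(all(g$g1 == 0) && all(g$g2 == 0))

  ramp <- matrix(rep(1:6, 6), 6, 6)  # A[i, j] = i
  g <- image_gradients(ramp)
  expect_true(all(g$g1[-1, ] == 1))
  expect_true(all(g$g1[1, ] == 0))
  expect_true(all(g$g2 == 0))

  set.seed(2)
  R <- matrix(rnorm(25), 5, 5)
  o <- gradient_oracle(R)
  g <- image_gradients(R)
  expect_equal(g$g1, o$g1, tolerance = 1e-15)
  expect_equal(g$g2, o$g2, tolerance = 1e-15)
  expect_error(image_gradients(matrix(1, 1, 3)), "2 x 2")
})

test_that("block orientation resolves the doubled-angle quadrants", {
  # g2 = 0: orientation perpendicular to the gradient -> pi/2
  grad <- list(g1 = matrix(1, 4, 4), g2 = matrix(0, 4, 4))
  bo <- block_orientation(grad, 4)
  expect_equal(as.numeric(bo$O), pi / 2)
  expect_false(any(bo$degenerate))

  # g1 = g2 != 0: numerator positive, denominator zero -> 3*pi/4
  grad <- list(g1 = matrix(2, 4, 4), g2 = matrix(2, 4, 4))
  expect_equal(as.numeric(block_orientation(grad, 4)$O), 3 * pi / 4)

  # all-zero gradients: flagged degenerate, angle pi/2
  grad <- list(g1 = matrix(0, 4, 4), g2 = matrix(0, 4, 4))
  bo <- block_orientation(grad, 4)
  expect_true(all(bo$degenerate))
  expect_equal(as.numeric(bo$O), pi / 2)
})

test_that("coherence is bounded, extremal on canonical blocks, scale invariant", {
  uni <- list(g1 = matrix(3, 4, 4), g2 = matrix(0, 4, 4))
  expect_equal(as.numeric(block_coherence(uni, 4)), 1)

  flat <- list(g1 = matrix(0, 4, 4), g2 = matrix(0, 4, 4))
  expect_equal(as.numeric(block_coherence(flat, 4)), 0)

  # gradients spread uniformly over directions -> near zero
  th <- seq(0, pi, length.out = 17)[-17]
  iso <- list(g1 = matrix(cos(th), 4, 4), g2 = matrix(sin(th), 4, 4))
  expect_lt(as.numeric(block_coherence(iso, 4)), 1e-10)

  set.seed(8)
  A <- smooth_random_image(20, 8)
  C1 <- block_coherence(image_gradients(A), 5)
  C2 <- block_coherence(image_gradients(3.7 * A), 5)
  expect_equal(C1, C2, tolerance = 1e-12)
  expect_true(all(C1 >= 0 & C1 <= 1))
})

test_that("orientation smoothing respects the doubled-angle wrap", {
  O <- matrix(1.1, 6, 6)
  expect_equal(smooth_orientation(O, 1), O, tolerance = 1e-12)
  expect_identical(smooth_orientation(O, 0), O)

  # +85 and -85 degrees must average toward 90, not 0
  O <- matrix(85 * pi / 180, 2, 2)
  O[, 2] <- -85 * pi / 180
  th <- smooth_orientation(O, 5)
  expect_lt(max(angle_err_deg(th, pi / 2)), 1)
})

test_that("axis length maps coherence affinely onto [1, alpha_max]", {
  expect_equal(axis_length(0, 10), 1)
  expect_equal(axis_length(1, 10), 10)
  expect_equal(axis_length(0.5, 2.5), 1.75)
  expect_error(axis_length(1.2, 10), "\\[0, 1\\]")
  expect_error(axis_length(0.5, 0.5), "alpha_max")
})

test_that("gratings and rings are recovered with the expected orientation", {
  # sinusoidal gratings at several angles: theta within 2 degrees
  for (ang in c(0, 30, 60, 90, 120)) {
    f <- estimate_orientation_field(grating(128, 12, ang), 5, 1, 10)
    interior <- f$block$theta[6:20, 6:20]
    expect_lt(max(angle_err_deg(interior, ang * pi / 180)), 2)
  }
  # axis-aligned gratings have exactly unidirectional gradients
  f0 <- estimate_orientation_field(grating(128, 12, 0), 5, 1, 10)
  expect_gt(min(f0$block$coherence[6:20, 6:20]), 0.999)
  # oblique sampling spreads the two difference stencils slightly
  f30 <- estimate_orientation_field(grating(128, 12, 30), 5, 1, 10)
  expect_gt(min(f30$block$coherence[6:20, 6:20]), 0.7)

  # concentric rings: tangential orientation away from the centre
  tc <- texture_circular(128, 12)
  fc <- estimate_orientation_field(tc, 5, 1, 10)
  nb <- nrow(fc$block$theta)
  cent <- sapply(seq_len(nb), function(k) {
    mean(which(ceiling(seq_len(128) / 5) == k))
  })
  Xc <- matrix(rep(cent - 64.5, times = nb), nb, nb)
  Yc <- matrix(rep(cent - 64.5, each = nb), nb, nb)
  tang <- atan2(Xc, -Yc)
  rad <- sqrt(Xc^2 + Yc^2)
  sel <- rad > 15 & rad < 55 & fc$block$coherence > 0.5
  err <- angle_err_deg(fc$block$theta, tang)
  expect_lt(median(err[sel]), 5)
})

test_that("the estimated field broadcasts block values and handles flat images", {
  flat <- estimate_orientation_field(matrix(1, 20, 20), 5, 1, 2.5)
  expect_true(all(flat$coherence == 0))
  expect_true(all(flat$alpha == 1))
  expect_true(all(flat$block$degenerate))

  A <- smooth_random_image(23, 10)  # 23 = 4 full blocks + partial block of 3
  f <- estimate_orientation_field(A, 5, 1, 2.5)
  expect_equal(dim(f$theta), c(23L, 23L))
  for (bi in 1:5) for (bj in 1:5) {
    rows <- which(ceiling(seq_len(23) / 5) == bi)
    cols <- which(ceiling(seq_len(23) / 5) == bj)
    patch <- f$theta[rows, cols]
    expect_equal(max(patch) - min(patch), 0)
  }
  expect_true(all(f$alpha >= 1 & f$alpha <= 2.5))
})

test_that("orientation estimates are equivariant under 90-degree rotation", {
  A <- grating(64, 10, 25)
  Ar <- t(A)[, rev(seq_len(64))]  # rotate 90 degrees counter-clockwise? (transpose+flip)
  f <- estimate_orientation_field(A, 5, 1, 10)
  fr <- estimate_orientation_field(Ar, 5, 1, 10)
  med <- function(x) median(as.numeric(x))
  # dominant angles differ by 90 degrees modulo pi
  diff_deg <- angle_err_deg(med(fr$block$theta), med(f$block$theta) + pi / 2)
  expect_lt(diff_deg, 3)
})
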