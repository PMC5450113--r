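# Independent oracles used across test files. Everything here is written as
# plain loops / closed forms, deliberately separate from the package's
# vectorized implementations.

# Dense double-loop construction of the triangular arc-interpolation matrix:
# entry ((l-1)*S + h, m) = max(0, 1 - |t_h/dt - d_lm/(c dt)|).
dense_weight_oracle <- function(geom, grid, sampling) {
  nx <- grid$n_x; ny <- grid$n_y
  S <- sampling$n_samples
  M <- geom$n_views
  c_mm <- sampling$c * 1000
  W <- matrix(0, M * S, nx * ny)
  for (l in seq_len(M)) {
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      m <- i + (j - 1) * nx
      d <- sqrt((grid$x[i] - geom$positions[l, 1])^2 +
                  (grid$y[j] - geom$positions[l, 2])^2)
      for (h in seq_len(S)) {
        off <- abs(h - d / (c_mm * sampling$dt))
        if (off < 1) W[(l - 1) * S + h, m] <- 1 - off
      }
    }
  }
  W
}

# Closed-form circle-circle intersection arc length: length of the circle of
# radius rho centred at distance R0 from a disk of radius a, inside the disk.
disk_arc_length <- function(rho, R0, a) {
  x <- (rho^2 + R0^2 - a^2) / (2 * rho * R0)
  ifelse(x >= 1, 0, ifelse(x <= -1, 2 * pi * rho, 2 * rho * acos(pmin(pmax(x, -1), 1))))
}

# Loop evaluation of the backward-difference gradient.
gradient_oracle <- function(A) {
  n1 <- nrow(A); n2 <- ncol(A)
  g1 <- matrix(0, n1, n2); g2 <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (i > 1) g1[i, j] <- A[i, j] - A[i - 1, j]
    if (j > 1) g2[i, j] <- A[i, j] - A[i, j - 1]
  }
  list(g1 = g1, g2 = g2)
}

# Independent classical TV denoiser (projected gradient on the dual with a
# fixed 1/8 step), written with its own explicit difference/divergence code.
# Solves argmin 0.5 ||A - f||^2 + w * sum ||grad A||_2 with the same backward
# difference convention as the package.
tv_denoise_oracle <- function(f, w, iters = 2000) {
  n1 <- nrow(f); n2 <- ncol(f)
  p1 <- matrix(0, n1, n2); p2 <- matrix(0, n1, n2)
  bdiff <- function(A) {
    g1 <- A * 0; g2 <- A * 0
    g1[2:n1, ] <- A[2:n1, ] - A[1:(n1 - 1), ]
    g2[, 2:n2] <- A[, 2:n2] - A[, 1:(n2 - 1)]
    list(g1, g2)
  }
  bdiv <- function(v1, v2) {
    v1[1, ] <- 0; v2[, 1] <- 0
    d1 <- v1; d1[1:(n1 - 1), ] <- d1[1:(n1 - 1), ] - v1[2:n1, ]
    d2 <- v2; d2[, 1:(n2 - 1)] <- d2[, 1:(n2 - 1)] - v2[, 2:n2]
    d1 + d2
  }
  for (k in seq_len(iters)) {
    A <- f - w * bdiv(p1, p2)
    g <- bdiff(A)
    p1n <- p1 + (1 / 8) * g[[1]]
    p2n <- p2 + (1 / 8) * g[[2]]
    nr <- pmax(sqrt(p1n^2 + p2n^2), 1)
    p1 <- p1n / nr; p2 <- p2n / nr
  }
  f - w * bdiv(p1, p2)
}

# Pixel angular error between two orientations defined modulo pi, in degrees.
angle_err_deg <- function(a, b) {
  abs(((a - b + pi / 2) %% pi) - pi / 2) * 180 / pi
}

# Smooth random test image: seeded white noise blurred by repeated 3x3 means.
smooth_random_image <- function(n, seed, passes = 4) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  for (k in seq_len(passes)) {
    Ap <- A
    A <- (Ap +
            rbind(Ap[1, ], Ap[-n, ]) + rbind(Ap[-1, ], Ap[n, ]) +
            cbind(Ap[, 1], Ap[, -n]) + cbind(Ap[, -1], Ap[, n])) / 5
  }
  A
}
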