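test_that("Hankel lifting reproduces the classic 1D structure and round-trips", {
  v <- c(1, 2, 3, 4) + 0i
  M <- hankel_lift(v, 2, spatial_d = 1)
  expect_equal(unname(M), matrix(c(1, 2, 3, 2, 3, 4) + 0i, 3, 2))

  set.seed(2)
  V <- array(complex(real = rnorm(125), imaginary = rnorm(125)), c(5, 5, 5))
  M3 <- hankel_lift(V, 3, spatial_d = 3)
  expect_equal(dim(M3), c(27L, 27L))
  back <- hankel_unlift(M3, dim(V), 3, spatial_d = 3)
  expect_lt(max(Mod(back - V)), 1e-12)

  # adjointness of the unnormalized unlift
  M2 <- matrix(complex(real = rnorm(27 * 27), imaginary = rnorm(27 * 27)), 27)
  lhs <- sum(Conj(hankel_lift(V, 3, spatial_d = 3)) * M2)
  rhs <- sum(Conj(V) * hankel_unlift(M2, dim(V), 3, normalize = FALSE,
                                     spatial_d = 3))
  expect_lt(Mod(lhs - rhs), 1e-10 * Mod(lhs))

  expect_error(hankel_lift(v, 7, spatial_d = 1), "width")
})

test_that("finite support induces annihilation: null space and filter identity", {
  # 2D rectangle-support image on an exact Cartesian grid: a separable
  # 5-tap filter vanishing on the support exists, so the lifted C-matrix
  # has an exact numerical null space
  n <- 16
  img <- matrix(0, n, n)
  img[8:10, 8:10] <- matrix(runif(9), 3)
  K <- ztegap:::grid_fft(img + 0i)
  M <- hankel_lift(K, 5, spatial_d = 2)
  sv <- svd(M)$d
  expect_lt(sv[length(sv)] / sv[1], 1e-6)

  # explicit annihilating-filter prediction of a held-out sample (1D):
  # with filter (w1, w2, w3), k3 = -(w1 k1 + w2 k2) / w3
  x <- rep(0 + 0i, 16)
  x[c(8, 9)] <- c(1, 0.6 + 0.4i)
  k <- as.vector(ztegap:::grid_fft(x))
  Mfull <- hankel_lift(k, 3, spatial_d = 1)
  hold <- 7
  h <- svd(Mfull[-hold, ])$v[, 3]       # null vector from the other rows
  k1 <- Mfull[hold, 1]; k2 <- Mfull[hold, 2]; k3 <- Mfull[hold, 3]
  pred <- -(h[1] * k1 + h[2] * k2) / h[3]
  expect_lt(Mod(pred - k3) / Mod(k3), 1e-6)
})

test_that("relative numerical rank of the lifting falls with support ratio", {
  n <- 32
  ax <- (0:(n - 1)) - n %/% 2
  rel_rank <- vapply(c(0.8, 0.5, 0.3), function(rho) {
    half <- round(rho * n / 2)
    blob <- exp(-outer(ax^2, ax^2, `+`) / (2 * (0.4 * half)^2))
    win <- (abs(outer(ax, rep(1, n))) < half) &
           (abs(outer(rep(1, n), ax)) < half)
    M <- hankel_lift(ztegap:::grid_fft(blob * win + 0i), 5, spatial_d = 2)
    sv <- svd(M)$d
    sum(sv > 1e-4 * sv[1]) / min(dim(M))
  }, numeric(1))
  expect_true(all(diff(rel_rank) < 0))
})

test_that("singular value thresholding follows the hard/soft arithmetic", {
  D <- diag(c(1, 0.02, 0.01)) + 0i
  hard <- svt(D, "hard", 0.015)
  expect_equal(sort(Re(diag(hard)), decreasing = TRUE), c(1, 0.02, 0),
               tolerance = 1e-12)
  soft <- svt(D, "soft", 0.015)
  expect_equal(sort(Re(diag(soft)), decreasing = TRUE),
               c(0.985, 0.005, 0), tolerance = 1e-12)

  # a matrix already at rank <= r with a clear margin is a hard fixed point
  set.seed(8)
  U <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2]
  V <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2]
  A <- U %*% diag(c(3, 2)) %*% t(V)
  expect_lt(max(Mod(svt(A + 0i, "hard", 0.015) - A)), 1e-10)

  nuc <- function(M) sum(svd(M)$d)
  R <- matrix(complex(real = rnorm(30), imaginary = rnorm(30)), 6)
  expect_lte(nuc(svt(R, "hard", 0.3)), nuc(R) + 1e-12)
  expect_lte(nuc(svt(R, "soft", 0.3)), nuc(R) + 1e-12)
})

test_that("low-rank infilling recovers the gap and honors data consistency", {
  sc <- scene_2d()
  clean <- sc$clean_kspace

  f0 <- lowrank_infill(clean, sc$traj, 0)
  expect_identical(f0$data, clean$data)
  expect_identical(attr(f0, "iterations"), 1L)
  expect_true(attr(f0, "converged"))

  gapped <- apply_gap(clean, sc$traj, 2)
  gidx <- seq_len(missing_sample_count(2, 2))
  cfg <- lowrank_config(kernel_width = 3, center_grid = 21,
                        spoke_fraction = 0.45, lambda = 5, tol = 1e-3,
                        max_iter = 60, cg_iter = 20)
  filled <- lowrank_infill(gapped, sc$traj, 2, cfg)
  expect_identical(filled$data[, -gidx, ], gapped$data[, -gidx, ])
  expect_lt(gap_error(filled, clean, gidx), 0.10)
  tr <- attr(filled, "trace")
  expect_true(all(c("iteration", "rel_change", "gap_energy", "sigma_max",
                    "rank") %in% names(tr)))
  # non-convergence within a tiny cap is flagged, not an error
  tight <- lowrank_config(kernel_width = 3, center_grid = 21,
                          spoke_fraction = 0.45, lambda = 5, tol = 1e-12,
                          max_iter = 2, cg_iter = 5)
  capped <- lowrank_infill(gapped, sc$traj, 2, tight)
  expect_false(attr(capped, "converged"))
  expect_identical(attr(capped, "iterations"), 2L)
})
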