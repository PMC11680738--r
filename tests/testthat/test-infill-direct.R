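# Algebraic and Stoch-Olejniczak solvers against independently built dense
# oracles, plus their spec'd structural properties.

# independent oracle: minimize out-of-band energy of the inverse DFT of a
# pair line, built by explicit loops and solved with base qr.solve
oracle_pair_fill <- function(line, n_readout, r, n_miss, lambda = 0) {
  L <- 2L * n_readout - 1L
  jc <- n_readout
  gap <- jc + (-(n_miss - 1L)):(n_miss - 1L)
  off <- (0:(L - 1)) - (jc - 1)
  W <- matrix(0i, L, L)
  for (i in 1:L) for (j in 1:L)
    W[i, j] <- exp(2i * pi * off[i] * off[j] / L) / L
  out <- which(abs(off) > L / (2 * r))
  A <- W[out, gap, drop = FALSE]
  y0 <- line
  y0[gap] <- 0
  b <- -W[out, , drop = FALSE] %*% y0
  if (lambda == 0) qr.solve(A, b)
  else solve(Conj(t(A)) %*% A + lambda * diag(length(gap)), Conj(t(A)) %*% b)
}

test_that("algebraic pair-line solver matches the dense oracle and ground truth", {
  n <- 32; r <- 2; L <- 2 * n - 1
  # two-level boxcar supported inside the nominal band of the oversampled line
  pos <- (0:(L - 1)) - (n - 1)
  x <- ifelse(abs(pos) <= 10, 1, 0) + ifelse(abs(pos) <= 4, 0.5, 0)
  Wm <- oracle_dft_1d(L)
  line_true <- as.vector(Wm %*% x)         # k samples, origin at index n
  n_miss <- missing_sample_count(2, r)     # gap g = 2
  sys <- pair_line_system(n, r, 2)
  expect_identical(sys$L, L)
  expect_identical(length(sys$gap_idx), 2L * n_miss - 1L)

  solver <- ztegap:::gap_line_solver(sys, lambda = 0)
  got <- solver(matrix(line_true, ncol = 1))
  expect_lt(max(Mod(got - line_true[sys$gap_idx])) /
              max(Mod(line_true[sys$gap_idx])), 1e-6)

  ora <- oracle_pair_fill(line_true, n, r, n_miss)
  expect_lt(max(Mod(got - ora)), 1e-8 * max(Mod(ora)))
})

test_that("gap-system conditioning degrades monotonically with gap size", {
  conds <- vapply(1:4, function(g) {
    sv <- svd(pair_line_system(32, 2, g)$A)$d
    sv[1] / sv[length(sv)]
  }, numeric(1))
  expect_true(all(diff(conds) > 0))
  expect_gt(conds[4] / conds[1], 1e3)
})

test_that("algebraic infilling recovers the gap on the 2D scene and leaves data untouched", {
  sc <- scene_2d()
  clean <- sc$clean_kspace
  g0 <- algebraic_infill(clean, sc$traj, 0)
  expect_identical(g0$data, clean$data)

  gapped <- apply_gap(clean, sc$traj, 2)
  gidx <- seq_len(missing_sample_count(2, 2))
  filled <- algebraic_infill(gapped, sc$traj, 2, lambda = 1e-12)
  expect_identical(filled$data[, -gidx, ], gapped$data[, -gidx, ])
  expect_lt(gap_error(filled, clean, gidx), 0.05)

  # truncated-SVD regularization is also accepted
  filled2 <- algebraic_infill(gapped, sc$traj, 2, reg = "tsvd")
  expect_lt(gap_error(filled2, clean, gidx), 0.05)
})

test_that("Stoch-Olejniczak recovers a real symmetric phantom and shrugs off global phase", {
  sc <- scene_2d_1coil()
  clean <- sc$clean_kspace
  gapped <- apply_gap(clean, sc$traj, 2)
  gidx <- seq_len(missing_sample_count(2, 2))

  expect_identical(stoch_olejniczak_infill(clean, sc$traj, 0)$data, clean$data)

  filled <- stoch_olejniczak_infill(gapped, sc$traj, 2)
  expect_identical(filled$data[, -gidx, ], gapped$data[, -gidx, ])
  err0 <- gap_error(filled, clean, gidx)
  expect_lt(err0, 0.05)

  # constant global phase: recovery error essentially unchanged
  rot <- clean
  rot$data <- rot$data * exp(1i * 0.8)
  filled_rot <- stoch_olejniczak_infill(apply_gap(rot, sc$traj, 2), sc$traj, 2)
  err1 <- gap_error(filled_rot, rot, gidx)
  expect_lt(abs(err1 - err0) / err0, 0.10)
})

test_that("single-spoke solver matches a dense real-part oracle", {
  n <- 24; r <- 2
  set.seed(12)
  line <- complex(real = rnorm(n), imaginary = rnorm(n))
  sys <- pair_line_system(n, r, 1.5, single_spoke = TRUE)
  solver <- ztegap:::gap_line_solver(sys, lambda = 1e-10,
                                     real_part_only = TRUE)
  got <- solver(matrix(line, ncol = 1))
  # dense oracle built from scratch: one-sided IDFT over t_i = i/n, out-of-
  # band rows, real-stacked ridge least squares
  gap <- seq_len(missing_sample_count(1.5, r))
  ng <- length(gap)
  freqs <- (0:(n - 1))[pmin(0:(n - 1), n - (0:(n - 1))) > n / (2 * r)]
  Wfull <- matrix(0i, length(freqs), n)
  for (a in seq_along(freqs)) for (j in 1:n)
    Wfull[a, j] <- exp(2i * pi * freqs[a] * (j - 1) / n) / n
  Wfull[, 1] <- Wfull[, 1] / 2      # self-conjugate origin term
  A <- Wfull[, gap, drop = FALSE]
  Ar <- cbind(Re(A), -Im(A))
  y0 <- line; y0[gap] <- 0
  br <- -Re(Wfull %*% y0)
  sol <- solve(t(Ar) %*% Ar + 1e-10 * diag(2 * ng), t(Ar) %*% br)
  ora <- sol[1:ng] + 1i * sol[ng + 1:ng]
  expect_identical(sys$gap_idx, gap)
  expect_lt(max(Mod(got - ora)), 1e-6 * max(1, max(Mod(ora))))
})
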