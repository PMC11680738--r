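test_that("calibration recovers generating weights and has the right size", {
  # data obeying an exact 1-tap linear recurrence per coil:
  # sample m = z * sample (m+1), same z for every spoke
  tr <- make_uniform_spokes_2d(8, 24, oversampling = 2)
  z <- c(1.2 - 0.3i, 0.8 + 0.5i)
  dat <- array(0i, c(8, 24, 2))
  set.seed(3)
  for (s in 1:8) for (c in 1:2)
    dat[s, , c] <- z[c]^(23:0) * (rnorm(1) + 1i * rnorm(1))
  ks <- multicoil_kspace(dat)
  cal <- calibrate_kernel(ks, tr, s = 1, fill_pos = 2, kernel_length = 1,
                          calib_readout = 10, calib_spokes = 5, lambda = 0)
  # weights: (n_coils*1) x n_coils; coil c predicted only from its own source
  expect_equal(dim(cal$weights), c(2L, 2L))
  expect_lt(Mod(cal$weights[1, 1] - z[1]), 1e-6)
  expect_lt(Mod(cal$weights[2, 2] - z[2]), 1e-6)
  expect_lt(Mod(cal$weights[1, 2]) + Mod(cal$weights[2, 1]), 1e-6)

  cal5 <- calibrate_kernel(ks, tr, 1, 2, kernel_length = 5,
                           calib_readout = 16, calib_spokes = 5)
  expect_equal(length(cal5$weights), 2^2 * 5)   # n_coils^2 * kernel_length
})

test_that("duplicate calibration spokes do not change the weights", {
  tr1 <- make_uniform_spokes_2d(4, 24, oversampling = 2)
  set.seed(9)
  base <- array(complex(real = rnorm(4 * 24 * 2),
                        imaginary = rnorm(4 * 24 * 2)), c(4, 24, 2))
  ks1 <- multicoil_kspace(base)
  # a trajectory where spoke 1 appears twice (tiny angular perturbation zero)
  dirs2 <- rbind(tr1$spoke_dirs[1, ], tr1$spoke_dirs)
  tr2 <- radial_trajectory(dirs2, 24, 2)
  ks2 <- multicoil_kspace(array(base[c(1, 1:4), , ], c(5, 24, 2)))
  w1 <- calibrate_kernel(ks1, tr1, 1, 2, kernel_length = 3,
                         calib_readout = 12, calib_spokes = 1)$weights
  w2 <- calibrate_kernel(ks2, tr2, 1, 2, kernel_length = 3,
                         calib_readout = 12, calib_spokes = 2)$weights
  expect_lt(max(Mod(w1 - w2)), 1e-8 * max(Mod(w1)))
})

test_that("ZINFANDEL fills from the outside inward, degrading with depth", {
  sc <- scene_2d()
  clean <- sc$clean_kspace
  expect_identical(zinfandel_infill(clean, sc$traj, 0)$data, clean$data)

  gapped <- apply_gap(clean, sc$traj, 2)
  gidx <- seq_len(missing_sample_count(2, 2))
  filled <- zinfandel_infill(gapped, sc$traj, 2)
  expect_identical(filled$data[, -gidx, ], gapped$data[, -gidx, ])
  # desk-scale 2D bound: angular neighbors are ~2 degrees apart here, so the
  # extrapolation is coarser than on a dense 3D acquisition (below)
  expect_lt(gap_error(filled, clean, gidx), 0.20)

  # extrapolation degrades with depth: innermost worse than outermost
  per_pos <- vapply(gidx, function(m)
    sqrt(sum(Mod(filled$data[, m, ] - clean$data[, m, ])^2) /
           sum(Mod(clean$data[, m, ])^2)), numeric(1))
  expect_gt(per_pos[1], per_pos[length(gidx)])

  expect_error(zinfandel_infill(gapped, sc$traj, 20), "too large")
})

test_that("ZINFANDEL is accurate on a densely sampled 3D acquisition", {
  N <- 32
  tr <- make_phyllotaxis_spokes_3d(1509, N, oversampling = 2,
                                   bidirectional = TRUE)
  img <- make_brain_like_phantom_3d(N, seed = 7)
  sc <- make_scene(img, tr, n_coils = 4, seed = 1, nufft_width = 4)
  gapped <- apply_gap(sc$clean_kspace, tr, 2)
  gidx <- seq_len(missing_sample_count(2, 2))
  filled <- zinfandel_infill(gapped, tr, 2)
  expect_lt(gap_error(filled, sc$clean_kspace, gidx), 0.05)

  # angular locality of the calibration: weights from the 5 nearest spokes
  # and from all spokes predict nearly the same outermost gap sample
  nb_all <- seq_len(tr$n_spokes)
  cal_all <- ztegap:::calibrate_shifted(gapped, tr, nb_all,
                                        fill_pos = max(gidx), offset = 1L,
                                        kernel_length = 5, calib_readout = 16,
                                        lambda = 1e-6)
  spokes <- round(seq(1, tr$n_spokes, length.out = 25))
  v5 <- vall <- matrix(0i, length(spokes), 4)
  for (i in seq_along(spokes)) {
    s <- spokes[i]
    nb5 <- ztegap:::nearest_spokes(tr, s, 5)
    cal5 <- ztegap:::calibrate_shifted(gapped, tr, nb5,
                                       fill_pos = max(gidx), offset = 1L,
                                       kernel_length = 5, calib_readout = 16,
                                       lambda = 1e-6)
    src <- as.vector(gapped$data[s, max(gidx) + seq_len(5), ])
    v5[i, ] <- ztegap:::crossprod_fill(cal5, src)
    vall[i, ] <- ztegap:::crossprod_fill(cal_all, src)
  }
  expect_lt(sqrt(sum(Mod(vall - v5)^2) / sum(Mod(v5)^2)), 0.10)
})
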