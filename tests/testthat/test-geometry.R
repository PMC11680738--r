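test_that("uniform 2D spokes are paired, unit-norm and evenly spaced", {
  t2 <- make_uniform_spokes_2d(2, 8, paired = TRUE)
  expect_equal(t2$spoke_dirs, cbind(c(1, -1), c(0, 0)), tolerance = 1e-12)
  expect_identical(t2$pair_index, c(2L, 1L))

  t4 <- make_uniform_spokes_2d(4, 8, paired = TRUE)
  expect_equal(sort(atan2(t4$spoke_dirs[, 2], t4$spoke_dirs[, 1]) %% (2 * pi)),
               c(0, pi / 2, pi, 3 * pi / 2), tolerance = 1e-12)
  expect_true(all(abs(sqrt(rowSums(t4$spoke_dirs^2)) - 1) < 1e-12))

  tr <- make_uniform_spokes_2d(402, 256, oversampling = 2)
  ang <- sort(atan2(tr$spoke_dirs[, 2], tr$spoke_dirs[, 1]) %% (2 * pi))
  expect_equal(unique(round(diff(ang), 12)), pi / 201, tolerance = 1e-9)
  expect_equal(traj_max_radius(tr), 127.5)

  expect_error(make_uniform_spokes_2d(3, 8, paired = TRUE), "even")
})

test_that("diametric pairing is an involution with antipodal directions", {
  for (tr in list(make_uniform_spokes_2d(10, 8),
                  make_phyllotaxis_spokes_3d(25, 8, bidirectional = TRUE))) {
    p <- tr$pair_index
    expect_identical(p[p], seq_len(tr$n_spokes))
    expect_lt(max(abs(tr$spoke_dirs[p, ] + tr$spoke_dirs)), 1e-9)
  }
})

test_that("phyllotaxis spokes cover the sphere nearly uniformly", {
  t1 <- make_phyllotaxis_spokes_3d(1, 8, bidirectional = TRUE)
  expect_identical(t1$n_spokes, 2L)
  expect_identical(t1$pair_index, c(2L, 1L))
  expect_equal(t1$spoke_dirs[1, ], -t1$spoke_dirs[2, ], tolerance = 1e-12)

  tr <- make_phyllotaxis_spokes_3d(1000, 8, bidirectional = FALSE)
  D <- tr$spoke_dirs
  expect_true(all(abs(sqrt(rowSums(D^2)) - 1) < 1e-12))
  nn <- vapply(seq_len(nrow(D)), function(i) {
    d <- acos(pmin(1, pmax(-1, D %*% D[i, ])))
    min(d[-i])
  }, numeric(1))
  # uniform-hemisphere spacing: ~sqrt(area per tip) = sqrt(2*pi/n)
  expect_lt(abs(mean(nn) - sqrt(2 * pi / 1000)) / sqrt(2 * pi / 1000), 0.25)
  expect_gt(min(nn), 0.1 * mean(nn))

  t4 <- make_phyllotaxis_spokes_3d(4000, 8, bidirectional = FALSE)
  ks <- suppressWarnings(stats::ks.test(t4$spoke_dirs[, 3], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("missing-sample counting reproduces both printed nominal/oversampled pairs", {
  expect_identical(missing_sample_count(2.5, 1), 3L)
  expect_identical(missing_sample_count(2.5, 2), 5L)
  expect_identical(missing_sample_count(4.5, 1), 5L)
  expect_identical(missing_sample_count(4.5, 2), 9L)
  expect_identical(missing_sample_count(0, 2), 0L)
  # a sample landing exactly on the gap boundary is acquired
  expect_identical(missing_sample_count(2, 1), 2L)
  expect_identical(missing_sample_count(3, 2), 6L)
  expect_error(missing_sample_count(-1), "nonnegative")
})

test_that("apply_gap zeroes exactly the dead-time samples and is idempotent", {
  tr <- make_uniform_spokes_2d(8, 16, oversampling = 2)
  dm <- c(8, 16, 2)
  ks <- multicoil_kspace(array(complex(real = rnorm(prod(dm)),
                                       imaginary = rnorm(prod(dm))), dm))
  g0 <- apply_gap(ks, tr, 0)
  expect_identical(g0$data, ks$data)
  expect_true(all(g0$mask))

  g <- apply_gap(ks, tr, 2.5)
  expect_true(all(g$data[, 1:5, ] == 0))
  expect_identical(g$data[, 6:16, ], ks$data[, 6:16, ])
  expect_identical(unname(colSums(!g$mask)[1:5]), rep(8, 5))
  expect_identical(apply_gap(g, tr, 2.5), g)

  tr1 <- make_uniform_spokes_2d(8, 16, oversampling = 1)
  g1 <- apply_gap(ks, tr1, 1)
  expect_true(all(g1$data[, 1, ] == 0))
  expect_identical(g1$data[, 2:16, ], ks$data[, 2:16, ])

  bad <- multicoil_kspace(array(0i, c(4, 16, 2)))
  expect_error(apply_gap(bad, tr, 1), "conform")
})
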