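test_that("disc phantom matches brute-force lattice counting", {
  p <- make_disc_phantom(8, 3, 1, outer_value = 1, inner_value = 0.5)
  # brute-force count over the 8x8 lattice
  nc <- 4L
  cnt <- 0L
  for (i in 0:7) for (j in 0:7)
    if (sqrt((i - nc)^2 + (j - nc)^2) <= 3) cnt <- cnt + 1L
  expect_identical(sum(Mod(p$values) > 0), cnt)

  same <- make_disc_phantom(32, 10, 5, outer_value = 0.7, inner_value = 0.7)
  single <- make_disc_phantom(32, 10, 6, outer_value = 0.7, inner_value = 0.7)
  expect_identical(same$values, single$values)

  expect_error(make_disc_phantom(64, 40, 10), "n/2")
  expect_error(make_disc_phantom(64, 10, 20), "inner")
})

test_that("3D brain-like phantom is deterministic, supported in half the FOV, multi-level", {
  a <- make_brain_like_phantom_3d(32, seed = 7)
  b <- make_brain_like_phantom_3d(32, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         make_brain_like_phantom_3d(32, seed = 8)$values))

  v <- Re(make_brain_like_phantom_3d(64, seed = 7)$values)
  nz <- which(v != 0, arr.ind = TRUE)
  ctr <- 32L
  expect_true(all(abs(nz - 1L - ctr) < 16))
  expect_gte(length(unique(round(v[v != 0], 6))), 3L)
})

test_that("coil maps are unit-RSS, smooth, deterministic", {
  m1 <- make_coil_maps(c(24, 24), 1, seed = 3)
  expect_lt(max(abs(Mod(m1$maps) - 1)), 1e-6)

  for (shape in list(c(48, 48), c(24, 24, 24))) {
    mp <- make_coil_maps(shape, 4, seed = 5)
    d <- length(shape)
    rss <- sqrt(apply(Mod(mp$maps)^2, seq_len(d), sum))
    expect_lt(max(abs(rss - 1)), 1e-6)
    # >= 99% of each coil's spectral energy in the lowest-frequency eighth
    N <- shape[1]
    nc <- N %/% 2
    band <- (nc + 1 - N %/% 4):(nc + 1 + N %/% 4)
    for (c in seq_len(4)) {
      idx <- c(rep(list(quote(expr = )), d), list(c))
      m <- array(do.call(`[`, c(list(mp$maps), idx)), dim = shape)
      K <- ztegap:::grid_fft(m)
      sel <- as.matrix(expand.grid(rep(list(band), d)))
      expect_gt(sum(Mod(K[sel])^2) / sum(Mod(K)^2), 0.99)
    }
  }
  expect_identical(make_coil_maps(c(24, 24), 4, seed = 5)$maps,
                   make_coil_maps(c(24, 24), 4, seed = 5)$maps)
})

test_that("forward simulation matches DC, Gaussian closed form, and is linear", {
  tr <- make_uniform_spokes_2d(52, 32, oversampling = 2)
  maps1 <- sensitivity_maps(array(1 + 0i, c(32, 32, 1)))  # uniform single coil
  zero <- image_volume(matrix(0, 32, 32))
  expect_true(all(simulate_kspace(zero, maps1, tr)$data == 0))

  ones <- image_volume(matrix(1, 32, 32))
  ks <- simulate_kspace(ones, maps1, tr)
  dc <- ks$data[1, 1, 1]   # sample 0 sits at the k-space origin
  expect_lt(Mod(dc - 32^2) / 32^2, 1e-3)

  # centered Gaussian against its analytic Fourier transform
  s <- 3
  ax <- (0:31) - 16
  g <- image_volume(exp(-outer(ax^2, ax^2, `+`) / (2 * s^2)))
  ksg <- simulate_kspace(g, maps1, tr)
  co <- traj_coords(tr)
  keep <- sqrt(rowSums(co^2)) < 8          # low band where the sum ~ integral
  analytic <- 2 * pi * s^2 * exp(-2 * pi^2 * s^2 * rowSums(co^2) / 32^2)
  got <- as.vector(ksg$data[, , 1])
  expect_lt(max(Mod(got[keep] - analytic[keep])) / max(analytic), 1e-3)

  # linearity
  maps <- make_coil_maps(c(32, 32), 3)
  x1 <- image_volume(matrix(rnorm(32^2), 32))
  x2 <- image_volume(matrix(rnorm(32^2), 32))
  lhs <- simulate_kspace(image_volume(2 * x1$values - 3 * x2$values), maps, tr)
  rhs <- 2 * simulate_kspace(x1, maps, tr)$data -
         3 * simulate_kspace(x2, maps, tr)$data
  expect_lt(max(Mod(lhs$data - rhs)) / max(Mod(rhs)), 1e-10)
})

test_that("noise injection hits the requested SNR and is seed-stable", {
  sc <- scene_2d()
  noisy <- add_noise_at_snr(sc$clean_kspace, noise_spec(10, 99), sc$image,
                            sc$traj)
  expect_lt(abs(attr(noisy, "achieved_snr_db") - 10), 0.2)
  again <- add_noise_at_snr(sc$clean_kspace, noise_spec(10, 99), sc$image,
                            sc$traj)
  expect_identical(noisy$data, again$data)

  other <- add_noise_at_snr(sc$clean_kspace, noise_spec(10, 100), sc$image,
                            sc$traj)
  expect_false(identical(noisy$data, other$data))
  # same sigma target: realized noise powers agree to a few percent
  p1 <- sum(Mod(noisy$data - sc$clean_kspace$data)^2)
  p2 <- sum(Mod(other$data - sc$clean_kspace$data)^2)
  expect_lt(abs(p1 - p2) / p1, 0.05)

  zero <- image_volume(matrix(0, 48, 48))
  expect_error(add_noise_at_snr(sc$clean_kspace, noise_spec(10, 1), zero,
                                sc$traj), "zero-energy")
})
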