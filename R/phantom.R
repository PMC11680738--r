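# Synthetic phantoms, coil sensitivities, forward simulation and
# SNR-calibrated noise.

#' Image volume container
#'
#' @param values complex (or real) voxel array, 1D/2D/3D.
#' @param fov field-of-view extent per axis in mm (metadata).
#' @return object of class `image_volume`.
#' @export
image_volume <- function(values, fov = NULL) {
  values <- as.array(values)
  if (any(!is.finite(Re(values))) || (is.complex(values) && any(!is.finite(Im(values)))))
    stop("non-finite voxel values")
  structure(list(values = array(as.complex(values), dim = dim(values)),
                 fov = fov, shape = dim(values)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image volume [%s], energy %.4g\n",
              paste(x$shape, collapse = " x "), sum(Mod(x$values)^2)))
  invisible(x)
}

#' Two-disc 2D phantom
#'
#' A bright outer disc with a darker concentric inner disc on an n x n grid,
#' centered on the FFT-center voxel (0-based index floor(n/2)). A voxel gets
#' `inner_value` when its distance from the center is <= `inner_radius`, else
#' `outer_value` when <= `outer_radius`, else 0.
#'
#' @param n grid size (pixels per axis).
#' @param outer_radius,inner_radius disc radii in pixels,
#'   `inner_radius < outer_radius < n/2`.
#' @param outer_value,inner_value intensities of the two regions.
#' @return an `image_volume` (real-valued).
#' @export
make_disc_phantom <- function(n, outer_radius = 80, inner_radius = 40,
                              outer_value = 1.0, inner_value = 0.5) {
  stopifnot(n >= 2)
  if (!(inner_radius < outer_radius && outer_radius < n / 2))
    stop("radii must satisfy inner < outer < n/2")
  nc <- n %/% 2L
  ax <- (seq_len(n) - 1L) - nc
  r <- sqrt(outer(ax^2, ax^2, `+`))
  img <- matrix(0, n, n)
  img[r <= outer_radius] <- outer_value
  img[r <= inner_radius] <- inner_value
  image_volume(img)
}

#' Procedural 3D brain-like phantom
#'
#' A deterministic (per seed) stack of nested smooth-boundary ellipsoids with
#' distinct intensities: an outer shell, a main interior, and `n_ellipsoids`
#' randomly placed internal structures. The whole object is confined to the
#' central `n/2` cube so that twice-oversampled readouts see a signal-free
#' outer band (the premise of the finite-support prior).
#'
#' @param n grid size (>= 16).
#' @param n_ellipsoids number of internal structures (default 6).
#' @param seed RNG seed.
#' @return an `image_volume` (real-valued).
#' @export
make_brain_like_phantom_3d <- function(n, n_ellipsoids = 6, seed = 1) {
  stopifnot(n >= 16)
  nc <- n %/% 2L
  ax <- (seq_len(n) - 1L) - nc
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))
  soft <- function(q, edge = 0.15) pmin(1, pmax(0, (1 - q) / edge))
  paint <- function(vol, cen, semi, value) {
    q <- ((X - cen[1]) / semi[1])^2 + ((Y - cen[2]) / semi[2])^2 +
         ((Z - cen[3]) / semi[3])^2
    w <- soft(q)
    vol * (1 - w) + value * w
  }
  rmax <- n / 4 - 1            # strict half-FOV support (with soft edge)
  with_seed(seed, {
    vol <- array(0, dim = c(n, n, n))
    # outer shell and interior
    vol <- paint(vol, c(0, 0, 0), rep(rmax, 3) * c(1, 0.92, 0.85), 1.0)
    vol <- paint(vol, c(0, 0, 0), rep(rmax, 3) * c(0.88, 0.80, 0.73), 0.55)
    values <- runif(n_ellipsoids, 0.2, 1.2)
    for (j in seq_len(n_ellipsoids)) {
      cen <- runif(3, -0.4, 0.4) * rmax
      semi <- runif(3, 0.12, 0.30) * rmax
      vol <- paint(vol, cen, semi, values[j])
    }
    # hard clip to the guaranteed support
    R2 <- (X / (n / 4))^2 + (Y / (n / 4))^2 + (Z / (n / 4))^2
    vol[R2 >= 1] <- 0
    image_volume(vol)
  })
}

#' Sensitivity maps container
#' @param maps complex array: spatial grid dims followed by a coil dimension.
#' @export
sensitivity_maps <- function(maps) {
  maps <- as.array(maps)
  nd <- length(dim(maps))
  structure(list(maps = array(as.complex(maps), dim = dim(maps)),
                 n_coils = dim(maps)[nd], grid = dim(maps)[-nd]),
            class = "sensitivity_maps")
}

coil_map <- function(maps, c) {
  nd <- length(dim(maps$maps))
  idx <- c(rep(list(quote(expr = )), nd - 1), list(c))
  array(do.call(`[`, c(list(maps$maps), idx)), dim = maps$grid)
}

#' Smooth simulated coil sensitivity maps
#'
#' Each coil is a surface-coil-like Lorentzian amplitude profile
#' `1 / (1 + |x - c|^2 / R0^2)` whose center sits on the FOV boundary (a
#' ring in 2D, a sphere in 3D), with a random low-order (linear) phase —
#' smooth but spatially distinct profiles, the kind of receive-array
#' modulation parallel-imaging methods rely on. Maps are jointly normalized
#' to unit root-sum-of-squares everywhere, so coil combination of a
#' magnitude image is transparent; with a single coil the map is constant
#' modulus 1.
#'
#' @param grid_shape integer vector of spatial grid sizes (2D or 3D).
#' @param n_coils number of coils (>= 1).
#' @param seed RNG seed (deterministic per seed).
#' @param falloff_frac Lorentzian half-width R0 as a fraction of the grid
#'   size (default 0.35).
#' @return a `sensitivity_maps` object.
#' @export
make_coil_maps <- function(grid_shape, n_coils = 4, seed = 1,
                           falloff_frac = 0.35) {
  stopifnot(n_coils >= 1)
  N <- as.integer(grid_shape)
  d <- length(N)
  stopifnot(d %in% c(2L, 3L))
  nc <- N %/% 2L
  pos <- lapply(seq_len(d), function(a) (seq_len(N[a]) - 1L) - nc[a])
  grids <- list()
  for (a in seq_len(d)) {
    perm <- rep(1, d); perm[a] <- N[a]
    grids[[a]] <- array(rep(pos[[a]], each = prod(N[seq_len(a - 1)])),
                        dim = N)
  }
  with_seed(seed, {
    centers <- coil_centers(d, n_coils) * max(N) / 2
    R0 <- falloff_frac * max(N)
    maps <- array(0 + 0i, dim = c(N, n_coils))
    idx_all <- rep(list(quote(expr = )), d)
    for (c in seq_len(n_coils)) {
      r2 <- array(0, dim = N)
      phase <- array(0, dim = N)
      slope <- runif(d, -0.5, 0.5) / max(N)
      for (a in seq_len(d)) {
        r2 <- r2 + (grids[[a]] - centers[c, a])^2
        phase <- phase + slope[a] * grids[[a]]
      }
      amp <- 1 / (1 + r2 / R0^2)
      m <- amp * exp(2i * pi * phase + 1i * runif(1, 0, 2 * pi))
      m <- bandlimit_halfband(m)
      maps <- do.call(`[<-`, c(list(maps), idx_all, list(c), list(as.vector(m))))
    }
    # alternate band-limiting and RSS normalization: the pair converges to
    # maps that are both unit-RSS and essentially band-limited
    for (pass in 1:3) {
      rss <- sqrt(apply(Mod(maps)^2, seq_len(d), sum))
      maps <- maps / array(rep(as.vector(rss), n_coils), dim = c(N, n_coils))
      if (pass < 3)
        for (c in seq_len(n_coils)) {
          m <- bandlimit_halfband(array(do.call(`[`, c(list(maps), idx_all,
                                                       list(c))), dim = N))
          maps <- do.call(`[<-`, c(list(maps), idx_all, list(c),
                                   list(as.vector(m))))
        }
    }
    sensitivity_maps(maps)
  })
}

# clip the spectrum to the central half-band (|k| <= N/4 per axis) so each
# profile is band-limited by construction
bandlimit_halfband <- function(m) {
  N <- dim(m)
  K <- grid_fft(m)
  keep <- lapply(N, function(n) {
    nc <- n %/% 2L
    idx <- rep(FALSE, n)
    idx[(nc + 1L - n %/% 4L):(nc + 1L + n %/% 4L)] <- TRUE
    idx
  })
  mask <- Reduce(function(acc, v) outer(acc, v, `&`), keep)
  K[!mask] <- 0 + 0i
  grid_ifft(K)
}

# evenly spread unit vectors for coil centers
coil_centers <- function(d, n_coils) {
  if (n_coils == 1) return(matrix(0, 1, d))
  if (d == 2) {
    ang <- (0:(n_coils - 1)) * 2 * pi / n_coils
    cbind(cos(ang), sin(ang))
  } else {
    i <- seq_len(n_coils)
    z <- (2 * i - 1) / n_coils - 1
    az <- i * pi * (3 - sqrt(5))
    rho <- sqrt(pmax(0, 1 - z^2))
    cbind(rho * cos(az), rho * sin(az), z)
  }
}

#' Forward-simulate multi-coil radial k-space
#'
#' Per coil c: `samples_c = NUFFT_forward(maps_c * image)` at the trajectory
#' coordinates. The returned mask is all-acquired; apply [apply_gap()]
#' downstream to impose the dead time.
#'
#' @param image an `image_volume` (ground truth).
#' @param maps a `sensitivity_maps` with matching grid.
#' @param traj a `radial_trajectory`.
#' @param plan optional precomputed [nufft_plan()] for the full trajectory.
#' @return a `multicoil_kspace`.
#' @export
simulate_kspace <- function(image, maps, traj, plan = NULL) {
  stopifnot(inherits(image, "image_volume"), inherits(maps, "sensitivity_maps"))
  if (!identical(as.integer(maps$grid), as.integer(image$shape)))
    stop("sensitivity maps do not conform to the image grid")
  if (is.null(plan)) plan <- nufft_plan(traj_coords(traj), image$shape)
  ncoil <- maps$n_coils
  data <- array(0 + 0i, dim = c(traj$n_spokes, traj$n_readout, ncoil))
  for (c in seq_len(ncoil)) {
    y <- nufft_forward(coil_map(maps, c) * image$values, plan)
    data[, , c] <- y   # flattening order matches traj_coords()
  }
  multicoil_kspace(data)
}

#' Noise specification
#'
#' @param snr_db target SNR in dB under the image-domain SNR definition used
#'   by [measure_snr_db()].
#' @param seed RNG seed for the realization.
#' @export
noise_spec <- function(snr_db, seed = 1) {
  stopifnot(is.finite(snr_db))
  structure(list(snr_db = snr_db, seed = as.integer(seed)), class = "noise_spec")
}

#' Add complex Gaussian noise at a target image-domain SNR
#'
#' Draws an i.i.d. circular complex Gaussian realization over every radial
#' sample and coil (acquired or not; gap samples are re-zeroed by
#' [apply_gap()] downstream), transforms the pure-noise channel to the
#' nominal image grid with the (grid-normalized) adjoint NUFFT, and scales
#' the realization so that
#' `10*log10( sum|x|^2 / sum|noise_image|^2 )` equals `snr_db` exactly for
#' this realization. Deterministic per seed; the same realization can be
#' reused across methods.
#'
#' @param kspace noise-free `multicoil_kspace`.
#' @param noise a [noise_spec()].
#' @param reference_image the noise-free ground-truth `image_volume`.
#' @param traj the `radial_trajectory` (needed to transform the noise
#'   channel).
#' @param plan optional precomputed full-trajectory [nufft_plan()].
#' @return noisy `multicoil_kspace`; attributes `"sigma"` (per-sample complex
#'   SD) and `"achieved_snr_db"`.
#' @export
add_noise_at_snr <- function(kspace, noise, reference_image, traj, plan = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  sig_energy <- sum(Mod(reference_image$values)^2)
  if (sig_energy == 0) stop("zero-energy reference image: SNR undefined")
  dm <- dim(kspace$data)
  unit <- with_seed(noise$seed, {
    array(complex(real = rnorm(prod(dm), sd = sqrt(0.5)),
                  imaginary = rnorm(prod(dm), sd = sqrt(0.5))), dim = dm)
  })
  if (is.null(plan)) plan <- nufft_plan(traj_coords(traj), reference_image$shape)
  noise_energy <- 0
  scale <- prod(reference_image$shape)   # grid-normalized adjoint
  for (c in seq_len(dm[3]))
    noise_energy <- noise_energy +
      sum(Mod(nufft_adjoint(as.vector(unit[, , c]), plan) / scale)^2)
  sigma <- sqrt(sig_energy / (10^(noise$snr_db / 10) * noise_energy))
  out <- kspace
  out$data <- out$data + sigma * unit
  attr(out, "sigma") <- sigma
  attr(out, "achieved_snr_db") <-
    10 * log10(sig_energy / (sigma^2 * noise_energy))
  out
}
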