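# Center-of-k-space regridding: move the innermost part of every spoke onto
# a small Cartesian k-space volume (via CG-NUFFT inversion of the truncated
# data followed by an FFT of the low-resolution image) and back.
#
# The center grid has nominal dwell spacing (Delta-k = 1 cycle/FOV), so a
# grid of side c covers radius c/2. The low-resolution image therefore spans
# the full FOV at c-pixel resolution and the object does not alias.

#' Regrid the k-space center onto a small Cartesian volume
#'
#' Uses only the innermost `spoke_fraction` of every readout, inverts the
#' truncated data onto a low-resolution image grid of side `grid_size`, and
#' FFTs that image to the centered Cartesian k-space cube, so the cube holds
#' consistent Cartesian Fourier coefficients rather than raw kernel
#' accumulation. Two inversion modes: `"cg"` (default) solves the truncated
#' system with [cg_nufft_inverse()]; `"adjoint"` is classic gridding, the
#' apodization-corrected adjoint NUFFT of quadrature-weighted samples
#' (k-space cell volumes). The adjoint mode spreads each sample with the
#' finite-width gridding kernel, which partially fills unmeasured center
#' coefficients - the fill-in engine of the low-rank POCS iteration.
#'
#' @param kspace a `multicoil_kspace`.
#' @param traj the matching `radial_trajectory`.
#' @param spoke_fraction fraction of readout samples to use, in (0, 1].
#' @param grid_size side c of the Cartesian cube; must not exceed twice the
#'   covered radius by more than one dwell (over-resolved otherwise).
#' @param cg_iter CG iterations for the inversion (default 10).
#' @param plan optional precomputed plan for the truncated coordinates on the
#'   low-resolution grid (as built internally).
#' @param nufft_width gridding kernel width passed to [nufft_plan()].
#' @param weights optional per-sample weights over the truncated samples
#'   (flattened spoke-fastest, like [traj_coords()]). In "cg" mode these are
#'   least-squares weights (default density compensation; zero-weighted
#'   samples are treated as unobserved and interpolated). In "adjoint" mode
#'   they are absolute quadrature volumes (default Pipe-Menon calibrated to
#'   the covered volume).
#' @param mode `"cg"` or `"adjoint"` (see Details).
#' @return object of class `center_volume`: complex array
#'   (c^d x n_coils), the covered k-radius, the kept sample indices.
#' @export
regrid_center <- function(kspace, traj, spoke_fraction = 0.20, grid_size = 26,
                          cg_iter = 10, plan = NULL, nufft_width = 6,
                          weights = NULL, mode = c("cg", "adjoint")) {
  mode <- match.arg(mode)
  stopifnot(spoke_fraction > 0, spoke_fraction <= 1)
  check_conformal(kspace, traj)
  n_keep <- max(2L, as.integer(round(spoke_fraction * traj$n_readout)))
  kept <- 0:(n_keep - 1L)
  covered <- (n_keep - 1L) / traj$oversampling * traj$dwell_spacing
  if (grid_size > 2 * covered + 1 + 1e-9)
    stop(sprintf(
      "grid_size %d over-resolves the covered radius %.2f (max %d)",
      grid_size, covered, floor(2 * covered + 1)))
  d <- traj$d
  if (is.null(plan))
    plan <- nufft_plan(traj_coords(traj, kept), rep(grid_size, d),
                       width = nufft_width)
  ncoil <- n_coils(kspace)
  cube <- array(0 + 0i, dim = c(rep(grid_size, d), ncoil))
  idx_all <- rep(list(quote(expr = )), d)
  if (mode == "cg") {
    wq <- if (is.null(weights)) radial_dcf(traj, kept) else weights
  } else {
    wq <- if (is.null(weights)) regrid_quadrature(traj, kept, plan) else weights
  }
  for (c in seq_len(ncoil)) {
    y <- as.vector(kspace$data[, kept + 1L, c])
    img <- if (mode == "cg")
      cg_nufft_inverse(y, plan, n_iter = cg_iter, weights = wq)
    else
      nufft_adjoint(y * wq, plan) / grid_size^d
    kc <- grid_fft(img)       # Cartesian Fourier coefficients, centered
    cube <- do.call(`[<-`, c(list(cube), idx_all, list(c), list(as.vector(kc))))
  }
  structure(list(cube = cube, grid_size = as.integer(grid_size), d = d,
                 covered_radius = covered, kept_idx = kept,
                 spoke_fraction = spoke_fraction, plan = plan),
            class = "center_volume")
}

#' Evaluate a center volume back onto the covered radial samples
#'
#' The Cartesian cube is inverse-FFTed to its low-resolution image, and that
#' image's Fourier series is evaluated at the covered radial coordinates with
#' the forward NUFFT. Only the samples inside the covered radius (the ones
#' [regrid_center()] consumed) are produced.
#'
#' @param volume a `center_volume`.
#' @param traj the `radial_trajectory` it came from.
#' @return complex array (n_spokes x n_kept x n_coils).
#' @export
degrid_center <- function(volume, traj) {
  stopifnot(inherits(volume, "center_volume"))
  plan <- volume$plan
  d <- volume$d
  ncoil <- dim(volume$cube)[d + 1]
  n_kept <- length(volume$kept_idx)
  out <- array(0 + 0i, dim = c(traj$n_spokes, n_kept, ncoil))
  idx_all <- rep(list(quote(expr = )), d)
  for (c in seq_len(ncoil)) {
    kc <- array(do.call(`[`, c(list(volume$cube), idx_all, list(c))),
                dim = rep(volume$grid_size, d))
    img <- grid_ifft(kc)
    out[, , c] <- nufft_forward(img, plan)
  }
  out
}

# Pipe-Menon quadrature for the truncated readout. The absolute scale is
# calibrated on a reference: a centered Gaussian on the plan's grid is
# forward-sampled and inverted with the candidate weights, and the weights
# are divided by the fitted gain so that grid -> degrid is unit-gain for
# smooth content.
regrid_quadrature <- function(traj, kept, plan) {
  w <- pipe_menon_dcf(plan)
  d <- plan$d
  cs <- plan$N[1]
  nc <- cs %/% 2L
  ax <- (seq_len(cs) - 1L) - nc
  r2 <- Reduce(`+`, lapply(seq_len(d), function(a) {
    perm <- rep(1L, d); perm[a] <- cs
    array(rep(ax^2, each = prod(rep(cs, a - 1L))), dim = rep(cs, d))
  }))
  x_ref <- exp(-r2 / (2 * (cs / 6)^2)) + 0i
  y_ref <- nufft_forward(x_ref, plan)
  x_hat <- nufft_adjoint(y_ref * w, plan) / cs^d
  gain <- Re(sum(Conj(x_ref) * x_hat)) / sum(Mod(x_ref)^2)
  w / gain
}

# centered DFT of an image on its own grid: coefficient at integer frequency
# (j - nc) equals sum_n x_n exp(-2i pi (j - nc)(n - nc)/N), matching the
# package's k-space convention with the origin at index floor(N/2).
grid_fft <- function(img) {
  N <- dim(img)
  if (is.null(N)) N <- length(img)
  shift_all(fft(shift_all(img, -(N %/% 2L))), N %/% 2L)
}

grid_ifft <- function(kc) {
  N <- dim(kc)
  if (is.null(N)) N <- length(kc)
  shift_all(fft(shift_all(kc, -(N %/% 2L)), inverse = TRUE), N %/% 2L) / prod(N)
}

# circular shift of an array by `by` along every axis
shift_all <- function(x, by) {
  dm <- dim(x)
  if (is.null(dm)) dm <- length(x)
  by <- rep_len(by, length(dm))
  idx <- lapply(seq_along(dm), function(a)
    ((seq_len(dm[a]) - 1L - by[a]) %% dm[a]) + 1L)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @export
print.center_volume <- function(x, ...) {
  cat(sprintf("center k-space volume: %s^%d grid, covered radius %.2f dk (%.0f%% of readout)\n",
              x$grid_size, x$d, x$covered_radius, 100 * x$spoke_fraction))
  invisible(x)
}
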