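# Non-uniform Fourier transform (NUFFT) between a Cartesian image grid and
# arbitrary k-space sample locations.
#
# Conventions shared by the whole package:
#   * image grid of size N per axis, center voxel at 0-based index floor(N/2)
#     (the FFT-shift center); voxel n sits at spatial offset (n - floor(N/2))
#     in pixel units, the field of view spans N pixels;
#   * k-space coordinates are in cycles/FOV, so the nominal Nyquist step is
#     Delta-k = 1 and the grid supports |k| <= N/2;
#   * forward model  y(k) = sum_n x_n exp(-2i pi k . (n - nc) / N).
#
# The "kb" method is Kaiser-Bessel gridding: deapodize, zero-pad onto a
# 2x-oversampled grid, FFT, and interpolate with a separable Kaiser-Bessel
# kernel (and the exact adjoint of that chain for the adjoint transform).
# The "exact" method materializes the dense DFT matrix and is intended for
# small problems and oracle-grade accuracy.

#' Plan a non-uniform Fourier transform
#'
#' @param coords numeric matrix (n_samples x d) of k-space coordinates in
#'   cycles/FOV, d in 1..3.
#' @param grid_shape integer vector of image grid sizes (length d).
#' @param oversampling gridding oversampling factor for the internal Cartesian
#'   grid (not the readout oversampling of the trajectory). Default 2.
#' @param width Kaiser-Bessel kernel width in oversampled grid units. Wider
#'   kernels are more accurate and slower; 6 gives ~1e-5 relative accuracy,
#'   4 about 1e-3.
#' @param method "kb" for gridding (default) or "exact" for the dense DFT
#'   matrix (only sensible for small grids).
#' @return an object of class `nufft_plan`.
#' @export
nufft_plan <- function(coords, grid_shape, oversampling = 2, width = 6,
                       method = c("kb", "exact")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  d <- ncol(coords)
  stopifnot(d >= 1, d <= 3, length(grid_shape) == d)
  N <- as.integer(grid_shape)
  for (a in seq_len(d)) {
    if (any(abs(coords[, a]) > N[a] / 2 + 1e-9))
      stop("k-space coordinate outside the Nyquist band of the oversampled grid")
  }
  nc <- N %/% 2L
  if (method == "exact") {
    if (prod(N) > 16384)
      stop("exact NUFFT requested for a grid too large to densify")
    # dense matrix E[(i), (n)] = exp(-2i pi sum_a k_ia (n_a - nc_a) / N_a)
    pos <- lapply(seq_len(d), function(a) (seq_len(N[a]) - 1L) - nc[a])
    gridpos <- as.matrix(expand.grid(pos))
    phase <- matrix(0, nrow(coords), nrow(gridpos))
    for (a in seq_len(d))
      phase <- phase + outer(coords[, a] / N[a], gridpos[, a])
    E <- exp(-2i * pi * phase)
    plan <- list(method = "exact", coords = coords, N = N, d = d, E = E,
                 n_samples = nrow(coords))
    class(plan) <- "nufft_plan"
    return(plan)
  }
  osf <- oversampling
  M <- as.integer(round(osf * N))
  W <- as.integer(width)
  # Beatty et al. choice of the KB shape parameter for this width/osf
  beta <- pi * sqrt((W / osf)^2 * (osf - 0.5)^2 - 0.8)
  Mc <- M %/% 2L
  # apodization = Fourier transform of the KB kernel, per axis, on the N grid
  apod_ax <- lapply(seq_len(d), function(a) {
    x <- ((seq_len(N[a]) - 1L) - nc[a]) / M[a]
    ft_kaiser_bessel(x, W, beta)
  })
  apod <- Reduce(function(acc, v) outer(acc, v), apod_ax)
  apod <- array(apod, dim = N)
  # placement maps: image index n -> wrapped oversampled index (n - nc) mod M
  imap <- lapply(seq_len(d), function(a)
    (((seq_len(N[a]) - 1L) - nc[a]) %% M[a]) + 1L)
  coords_os <- sweep(coords, 2, osf, `*`)
  tab <- kb_table_cpp(coords_os, M, W, beta)
  plan <- list(method = "kb", coords = coords, coords_os = coords_os,
               N = N, M = M, d = d, W = W, beta = beta, apod = apod,
               imap = imap, n_samples = nrow(coords),
               tab_w = tab$wts, tab_o = tab$offs)
  class(plan) <- "nufft_plan"
  plan
}

# closed-form Fourier transform of the (unnormalized) Kaiser-Bessel kernel
ft_kaiser_bessel <- function(x, W, beta) {
  g2 <- beta^2 - (pi * W * x)^2
  g <- sqrt(abs(g2))
  out <- numeric(length(x))
  pos <- g2 >= 0
  out[pos] <- ifelse(g[pos] == 0, W, W * sinh(g[pos]) / g[pos])
  out[!pos] <- W * sin(g[!pos]) / g[!pos]
  out
}

place_grid <- function(xa, plan) {
  w <- array(0 + 0i, dim = plan$M)
  im <- plan$imap
  if (plan$d == 1) w[im[[1]]] <- xa
  else if (plan$d == 2) w[im[[1]], im[[2]]] <- xa
  else w[im[[1]], im[[2]], im[[3]]] <- xa
  w
}

crop_grid <- function(w, plan) {
  im <- plan$imap
  if (plan$d == 1) out <- w[im[[1]]]
  else if (plan$d == 2) out <- w[im[[1]], im[[2]]]
  else out <- w[im[[1]], im[[2]], im[[3]]]
  array(out, dim = plan$N)
}

#' Forward NUFFT: image to non-uniform k-space samples
#'
#' @param image complex array with dim equal to the plan's grid shape.
#' @param plan a [nufft_plan()].
#' @return complex vector of samples, one per coordinate row.
#' @export
nufft_forward <- function(image, plan) {
  stopifnot(inherits(plan, "nufft_plan"))
  image <- as.array(image)
  if (!identical(as.integer(dim(image)), plan$N) &&
      !(plan$d == 1 && length(image) == plan$N[1]))
    stop("image shape does not match the NUFFT plan")
  if (any(!is.finite(Re(image))) || any(!is.finite(Im(image))))
    stop("non-finite image values")
  if (plan$method == "exact")
    return(as.vector(plan$E %*% as.vector(image)))
  xa <- image / plan$apod
  w <- place_grid(xa, plan)
  v <- fft(w)
  kb_interp_tab_cpp(as.vector(v), plan$tab_w, plan$tab_o, plan$M, plan$W,
                    plan$d)
}

#' Adjoint NUFFT: non-uniform samples to image grid
#'
#' The exact adjoint of [nufft_forward()] (conjugate-transpose operator, not
#' the inverse). For an approximate inverse use [cg_nufft_inverse()].
#'
#' @param samples complex vector of k-space samples.
#' @param plan a [nufft_plan()].
#' @return complex array on the image grid.
#' @export
nufft_adjoint <- function(samples, plan) {
  stopifnot(inherits(plan, "nufft_plan"), length(samples) == plan$n_samples)
  samples <- as.complex(samples)
  if (plan$method == "exact") {
    out <- as.vector(Conj(t(plan$E)) %*% samples)
    return(array(out, dim = plan$N))
  }
  v <- array(kb_spread_tab_cpp(samples, plan$tab_w, plan$tab_o, plan$M,
                               plan$W, plan$d),
             dim = plan$M)
  w <- fft(v, inverse = TRUE)  # unnormalized: exact adjoint of fft()
  crop_grid(w, plan) / plan$apod
}

#' Conjugate-gradient NUFFT inverse
#'
#' Approximately solves the normal equations `(A^H A + lambda I) x = A^H y`
#' for the forward plan `A` by conjugate gradient, starting from the zero
#' image. With `x0 = 0` the CG iterates minimize the data residual
#' `||A x - y||` over growing Krylov subspaces, so that residual is
#' non-increasing.
#'
#' @param samples complex vector of measured samples.
#' @param plan a [nufft_plan()].
#' @param n_iter number of CG iterations (default 10).
#' @param lambda Tikhonov weight on the image (default 0).
#' @param weights optional nonnegative per-sample least-squares weights `W`
#'   (the iteration solves `A^H W A x = A^H W y`). A 0/1 acquisition mask or
#'   density-compensation weights such as [radial_dcf()] both fit here; the
#'   latter act as a preconditioner that greatly accelerates convergence on
#'   center-out radial data. Defaults to all ones.
#' @param track_residual if TRUE, record the weighted data residual
#'   `||W^(1/2)(A x - y)||` after every iteration in attribute
#'   `"residuals"` (costs one extra forward transform each).
#' @return complex image array; attribute `"residuals"` when tracked.
#' @export
cg_nufft_inverse <- function(samples, plan, n_iter = 10, lambda = 0,
                             weights = NULL, track_residual = FALSE) {
  stopifnot(n_iter >= 0, lambda >= 0)
  if (is.null(weights)) weights <- rep(1, plan$n_samples)
  wts <- as.numeric(weights)
  if (any(wts < 0)) stop("weights must be nonnegative")
  A <- function(x) nufft_forward(x, plan)
  AHW <- function(s) nufft_adjoint(s * wts, plan)
  x <- array(0 + 0i, dim = if (plan$d == 1) plan$N[1] else plan$N)
  resids <- numeric(0)
  if (n_iter == 0) {
    if (track_residual) attr(x, "residuals") <- resids
    return(x)
  }
  b <- AHW(samples)
  r <- b
  p <- r
  rs <- re_inner(r, r)
  for (it in seq_len(n_iter)) {
    if (rs == 0) break
    q <- AHW(A(p)) + lambda * p
    alpha <- rs / re_inner(p, q)
    if (!is.finite(alpha)) stop("CG-NUFFT diverged (non-finite step)")
    x <- x + alpha * p
    r <- r - alpha * q
    rs_new <- re_inner(r, r)
    if (!is.finite(rs_new)) stop("CG-NUFFT diverged (non-finite residual)")
    if (track_residual) {
      dr <- A(x) - samples
      resids <- c(resids, sqrt(sum(wts * Mod(dr)^2)))
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (track_residual) attr(x, "residuals") <- resids
  x
}

#' Density-compensation weights for a center-out radial trajectory
#'
#' Per-sample weights proportional to the k-space shell volume each readout
#' sample represents: `((m + 1/2)^d - (m - 1/2)^d) / (r^d n_spokes)` at
#' readout index m (the origin sample gets the central sphere's volume split
#' across spokes). Used as least-squares weights in [cg_nufft_inverse()]
#' they act like the classic ramp/Ram-Lak compensation and make the CG
#' iteration well conditioned.
#'
#' @param traj a `radial_trajectory`.
#' @param sample_idx optional 0-based readout indices (default all), matching
#'   [traj_coords()].
#' @return numeric weight vector aligned with the flattened sample order.
#' @export
radial_dcf <- function(traj, sample_idx = NULL) {
  w <- radial_sample_volume(traj, sample_idx)
  w / max(w)
}

#' Pipe-Menon iterative density compensation
#'
#' Computes per-sample quadrature weights for adjoint-gridding inversion by
#' the fixed point w <- w / (C * w) (kernel convolution evaluated with the
#' plan's spread/interpolate pair), then scales them so the weights sum to
#' the covered k-space volume (exact quadrature of the constant). More
#' accurate than the analytic shell volumes near the origin and at the
#' readout boundary.
#'
#' @param plan a gridding [nufft_plan()] ("kb" method).
#' @param n_iter fixed-point iterations (default 15).
#' @param total_volume covered k-space volume the weights should sum to (in
#'   dwell^d units); when NULL the weights are left in relative scale.
#' @return numeric weight vector, one per plan coordinate row.
#' @export
pipe_menon_dcf <- function(plan, n_iter = 15, total_volume = NULL) {
  stopifnot(plan$method == "kb")
  w <- rep(1, plan$n_samples)
  for (it in seq_len(n_iter)) {
    den <- Re(kb_interp_tab_cpp(
      kb_spread_tab_cpp(as.complex(w), plan$tab_w, plan$tab_o, plan$M,
                        plan$W, plan$d),
      plan$tab_w, plan$tab_o, plan$M, plan$W, plan$d))
    den[den <= 0] <- 1
    w <- w / den
  }
  if (!is.null(total_volume)) w <- w * total_volume / sum(w)
  w
}

# absolute k-space quadrature cell volume per sample (dwell^d units):
# the spherical shell between radii (m - 1/2)/r and (m + 1/2)/r shared by all
# spokes. Used for adjoint-gridding inversion.
radial_sample_volume <- function(traj, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- 0:(traj$n_readout - 1L)
  d <- traj$d
  vd <- c(2, pi, 4 * pi / 3)[d]     # unit-ball volume
  m <- sample_idx
  shell <- vd * (((m + 0.5) / traj$oversampling)^d -
                 (pmax(m - 0.5, 0) / traj$oversampling)^d)
  rep(shell / traj$n_spokes, each = traj$n_spokes)
}

#' @export
print.nufft_plan <- function(x, ...) {
  cat(sprintf("NUFFT plan (%s): %d samples -> grid [%s]\n",
              x$method, x$n_samples, paste(x$N, collapse = " x ")))
  if (x$method == "kb")
    cat(sprintf("  oversampled grid [%s], kernel width %d, beta %.3f\n",
                paste(x$M, collapse = " x "), x$W, x$beta))
  invisible(x)
}
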