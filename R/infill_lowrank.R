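# Structured low-rank iterative infilling.
#
# A finite-support image admits band-limited annihilating filters in
# k-space, so the block-Hankel (LORAKS C-matrix style) lifting of a Cartesian
# neighborhood of the k-space center is low rank; coils are concatenated
# along the kernel axis so inter-coil correlations contribute to the rank
# deficiency. The dead-time gap is recovered by alternating projections
# (POCS): lift the regridded center volume, shrink its singular values,
# unlift, evaluate back onto the radial samples, and re-impose the acquired
# data, iterating until the k-space estimate stops changing.

#' Configuration for low-rank iterative infilling
#'
#' @param kernel_width isotropic Hankel kernel size w (default 5).
#' @param threshold_mode "hard" (zero singular values below the threshold,
#'   default) or "soft" (shrink them, the nuclear-norm proximal map).
#' @param threshold_frac threshold as a fraction of the current iterate's
#'   largest singular value (default 0.015, i.e. 1.5%).
#' @param spoke_fraction innermost fraction of each readout fed to the center
#'   volume (default 0.20).
#' @param center_grid side of the Cartesian center volume (default 26; must
#'   not over-resolve `spoke_fraction` times the trajectory's max radius).
#' @param lambda relative weight of the annihilation (low-rank) penalty
#'   against the data term, after probe normalization of the two operators
#'   (default 20; larger enforces the subspace model harder).
#' @param tol relative Euclidean k-space change at which to stop
#'   (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @param cg_iter CG iterations inside each regridding (default 10).
#' @param nufft_width gridding kernel width for the center-volume transforms
#'   (default 4; the center volume is tiny and this keeps iterations cheap).
#' @param seed optional seed recorded for provenance (the iteration itself is
#'   deterministic).
#' @return a `lowrank_config` list.
#' @export
lowrank_config <- function(kernel_width = 5, threshold_mode = c("hard", "soft"),
                           threshold_frac = 0.015, spoke_fraction = 0.20,
                           center_grid = 26, lambda = 20, tol = 1e-6,
                           max_iter = 200, cg_iter = 10, nufft_width = 4,
                           seed = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(threshold_frac > 0, threshold_frac < 1, tol > 0, max_iter >= 1,
            spoke_fraction > 0, spoke_fraction <= 1, kernel_width >= 2,
            lambda > 0)
  structure(list(kernel_width = as.integer(kernel_width),
                 threshold_mode = threshold_mode,
                 threshold_frac = threshold_frac,
                 spoke_fraction = spoke_fraction,
                 center_grid = as.integer(center_grid), lambda = lambda,
                 tol = tol,
                 max_iter = as.integer(max_iter), cg_iter = as.integer(cg_iter),
                 nufft_width = as.integer(nufft_width), seed = seed),
            class = "lowrank_config")
}

# linear index table for the lifting: rows = kernel positions, cols = offsets
lift_index <- function(c_side, w, d) {
  npos_ax <- c_side - w + 1L
  stride <- cumprod(c(1L, rep(c_side, d - 1L)))
  ax_pos <- lapply(seq_len(d), function(a) (0:(npos_ax - 1L)) * stride[a])
  ax_off <- lapply(seq_len(d), function(a) (0:(w - 1L)) * stride[a])
  pos_lin <- Reduce(function(acc, v) as.vector(outer(acc, v, `+`)), ax_pos)
  off_lin <- Reduce(function(acc, v) as.vector(outer(acc, v, `+`)), ax_off)
  outer(pos_lin, off_lin, `+`) + 1L
}

#' Block-Hankel (C-matrix) lifting of a Cartesian k-space volume
#'
#' Every w^d kernel neighborhood of the volume is flattened into one matrix
#' row; with multiple coils the per-coil blocks are concatenated along the
#' columns, giving a ((c-w+1)^d) x (w^d * n_coils) matrix. Linear in the
#' volume. Column order: offset (first axis fastest) within coil, coils in
#' order.
#'
#' @param volume complex array, either c^d (single coil) or c^d x n_coils, or
#'   a `center_volume`.
#' @param w isotropic kernel width (w <= c).
#' @param spatial_d number of spatial dims, needed only when the coil count
#'   equals the grid side and the layout is ambiguous.
#' @return complex matrix.
#' @export
hankel_lift <- function(volume, w, spatial_d = NULL) {
  if (inherits(volume, "center_volume")) {
    spatial_d <- volume$d
    v <- volume$cube
  } else v <- volume
  info <- lift_dims(v, w, spatial_d)
  I <- lift_index(info$c_side, w, info$d)
  blocks <- lapply(seq_len(info$ncoil), function(c) {
    vc <- info$coil(v, c)
    matrix(vc[as.vector(I)], nrow = nrow(I))
  })
  do.call(cbind, blocks)
}

#' Adjoint/inverse of the lifting: average overlapping contributions
#'
#' `hankel_unlift(hankel_lift(V), dim(V), w)` returns V exactly: each
#' Cartesian entry is the count-normalized sum of every matrix entry it fed
#' (the count-normalized adjoint). With `normalize = FALSE` the raw
#' (unnormalized) adjoint is returned, the true conjugate-transpose of
#' [hankel_lift()].
#'
#' @param M lifted matrix.
#' @param vol_dim dims of the target volume (spatial dims, then coil dim when
#'   multi-coil).
#' @param w kernel width used in the lifting.
#' @param normalize divide by the contribution counts (default TRUE).
#' @param spatial_d number of spatial dims when ambiguous (see
#'   [hankel_lift()]).
#' @return complex array of dim `vol_dim`.
#' @export
hankel_unlift <- function(M, vol_dim, w, normalize = TRUE, spatial_d = NULL) {
  v0 <- array(0 + 0i, dim = vol_dim)
  info <- lift_dims(v0, w, spatial_d)
  I <- lift_index(info$c_side, w, info$d)
  n_off <- ncol(I)
  npx <- info$c_side^info$d
  idx <- as.vector(I)
  counts <- tabulate(idx, nbins = npx)
  out <- array(0 + 0i, dim = vol_dim)
  coil_len <- npx
  for (c in seq_len(info$ncoil)) {
    block <- M[, (c - 1L) * n_off + seq_len(n_off), drop = FALSE]
    sr <- rowsum(Re(as.vector(block)), idx, reorder = FALSE)
    si <- rowsum(Im(as.vector(block)), idx, reorder = FALSE)
    grp <- as.integer(rownames(sr))
    acc <- complex(real = rep(0, npx), imaginary = rep(0, npx))
    acc[grp] <- complex(real = sr[, 1], imaginary = si[, 1])
    if (normalize) acc <- acc / pmax(counts, 1L)
    out[(c - 1L) * coil_len + seq_len(coil_len)] <- acc
  }
  out
}

lift_dims <- function(v, w, spatial_d = NULL) {
  dm <- dim(v)
  if (is.null(dm)) dm <- length(v)
  c_side <- dm[1]
  if (w > c_side) stop("kernel width exceeds the volume side")
  # volume is c^d or c^d x ncoil with isotropic spatial dims
  if (!is.null(spatial_d)) {
    d <- as.integer(spatial_d)
    stopifnot(length(dm) %in% c(d, d + 1L), all(dm[seq_len(d)] == c_side))
    ncoil <- if (length(dm) == d) 1L else dm[d + 1L]
    coil <- if (ncoil == 1L && length(dm) == d) function(v, c) v else
      function(v, c) {
        idx <- c(rep(list(quote(expr = )), d), list(c))
        array(do.call(`[`, c(list(v), idx)), dim = dm[seq_len(d)])
      }
    return(list(c_side = c_side, d = d, ncoil = ncoil, coil = coil))
  }
  if (length(dm) >= 2 && all(dm == c_side)) {
    d <- length(dm); ncoil <- 1L
    coil <- function(v, c) v
  } else {
    d <- length(dm) - 1L
    if (!all(dm[seq_len(d)] == c_side)) stop("volume must be isotropic c^d (x coils)")
    ncoil <- dm[d + 1L]
    coil <- function(v, c) {
      idx <- c(rep(list(quote(expr = )), d), list(c))
      array(do.call(`[`, c(list(v), idx)), dim = dm[seq_len(d)])
    }
  }
  if (length(dm) == 1) { d <- 1L; ncoil <- 1L; coil <- function(v, c) v }
  list(c_side = c_side, d = d, ncoil = ncoil, coil = coil)
}

#' Singular value thresholding
#'
#' Hard mode zeroes every singular value below `threshold_frac` times the
#' largest; soft mode shrinks all singular values by that amount (clamped at
#' zero), the proximal operator of the nuclear norm. Either way the output's
#' nuclear norm never exceeds the input's.
#'
#' @param M complex matrix.
#' @param mode "hard" or "soft".
#' @param threshold_frac fraction of the largest singular value.
#' @return the thresholded matrix; attribute `"singular_values"` holds the
#'   original spectrum.
#' @export
svt <- function(M, mode = c("hard", "soft"), threshold_frac = 0.015) {
  mode <- match.arg(mode)
  sv <- svd(M)
  d1 <- sv$d[1]
  if (d1 == 0) return(M)
  thr <- threshold_frac * d1
  dd <- if (mode == "hard") ifelse(sv$d < thr, 0, sv$d) else pmax(sv$d - thr, 0)
  out <- sv$u %*% (dd * Conj(t(sv$v)))
  attr(out, "singular_values") <- sv$d
  out
}

#' Low-rank iterative infilling of the dead-time gap
#'
#' Solves the structured low-rank infilling problem on the k-space center
#' volume: find the Cartesian center cube that (a) reproduces the acquired
#' radial samples inside the covered radius and (b) makes its block-Hankel
#' lifting low rank. Each sweep (1) lifts the current cube and splits
#' signal/null subspaces by singular value thresholding at
#' `threshold_frac` of the current largest singular value, then (2) solves
#' the resulting regularized least squares
#' `min_u ||W(degrid(u) - y_acq)||^2 + lambda ||lift(u) P_null||_F^2`
#' by warm-started conjugate gradient over the cube (`P_null` projects onto
#' the thresholded subspace). The synthesized gap samples are read off the
#' cube by [degrid_center()]-style evaluation; acquired samples are never
#' touched. Sweeps repeat until the relative Euclidean k-space change drops
#' below `tol` or `max_iter` is reached (flagged, not an error).
#'
#' @param kspace gapped `multicoil_kspace`.
#' @param traj `radial_trajectory`.
#' @param gap gap in Nyquist dwells or `dead_time_gap`.
#' @param config a [lowrank_config()].
#' @return the filled `multicoil_kspace` with attributes `trace`
#'   (data.frame: iteration, rel_change, gap_energy, sigma_max, rank),
#'   `iterations`, and `converged`.
#' @export
lowrank_infill <- function(kspace, traj, gap, config = lowrank_config()) {
  stopifnot(inherits(config, "lowrank_config"))
  check_conformal(kspace, traj)
  gidx <- gap_sample_idx(traj, gap)
  cur <- kspace
  if (!length(gidx)) {
    attr(cur, "trace") <- data.frame(iteration = 1L, rel_change = 0,
                                     gap_energy = 0, sigma_max = NA_real_,
                                     rank = NA_integer_)
    attr(cur, "iterations") <- 1L
    attr(cur, "converged") <- TRUE
    return(cur)
  }
  n_keep <- max(2L, as.integer(round(config$spoke_fraction * traj$n_readout)))
  if (max(gidx) >= n_keep)
    stop("gap extends beyond the center volume; increase spoke_fraction")
  d <- traj$d
  cs <- config$center_grid
  w <- config$kernel_width
  ncoil <- n_coils(kspace)
  kept <- 0:(n_keep - 1L)
  plan <- nufft_plan(traj_coords(traj, kept), rep(cs, d),
                     width = config$nufft_width)
  w_data <- radial_dcf(traj, kept) * as.numeric(cur$mask[, seq_len(n_keep)])
  cube_dim <- c(rep(cs, d), ncoil)
  idx_all <- rep(list(quote(expr = )), d)
  get_coil <- function(u, c) array(do.call(`[`, c(list(u), idx_all, list(c))),
                                   dim = rep(cs, d))
  degrid_op <- function(u) {
    out <- matrix(0 + 0i, traj$n_spokes * n_keep, ncoil)
    for (c in seq_len(ncoil))
      out[, c] <- nufft_forward(grid_ifft(get_coil(u, c)), plan)
    out
  }
  degrid_adj <- function(s) {
    out <- array(0 + 0i, dim = cube_dim)
    for (c in seq_len(ncoil)) {
      g <- grid_fft(nufft_adjoint(s[, c], plan)) / cs^d
      out <- do.call(`[<-`, c(list(out), idx_all, list(c), list(as.vector(g))))
    }
    out
  }
  lift_u <- function(u) hankel_lift(u, w, spatial_d = d)
  unlift_u <- function(M) hankel_unlift(M, cube_dim, w, normalize = FALSE,
                                        spatial_d = d)
  # probe-based normalization so lambda balances the two quadratic terms
  probe <- with_seed(1L, array(complex(real = rnorm(prod(cube_dim)),
                                       imaginary = rnorm(prod(cube_dim))),
                               dim = cube_dim))
  s_data <- l2(degrid_adj(degrid_op(probe) * w_data)) / l2(probe)
  s_ann <- l2(unlift_u(lift_u(probe))) / l2(probe)
  lam <- config$lambda * s_data / max(s_ann, 1e-300)
  # cube corners beyond the covered radius carry no data: hold them near
  # zero with a data-scaled ridge so the annihilation term cannot drift them
  nc_cube <- cs %/% 2L
  axp <- (seq_len(cs) - 1L) - nc_cube
  r2g <- Reduce(`+`, lapply(seq_len(d), function(a)
    array(rep(axp^2, each = cs^(a - 1L)), dim = rep(cs, d))))
  covered <- (n_keep - 1L) / traj$oversampling
  corner <- array(rep(as.vector(sqrt(r2g) > covered + 0.5), ncoil),
                  dim = cube_dim)
  ridge <- s_data * corner
  # initialization: consistent inversion of the acquired samples only
  y_acq <- matrix(0 + 0i, traj$n_spokes * n_keep, ncoil)
  for (c in seq_len(ncoil)) y_acq[, c] <- as.vector(cur$data[, seq_len(n_keep), c])
  cv0 <- regrid_center(cur, traj, config$spoke_fraction, cs,
                       cg_iter = config$cg_iter, plan = plan, weights = w_data)
  cube <- cv0$cube
  b <- degrid_adj(y_acq * w_data)
  total_norm <- l2(cur$data)
  trace <- vector("list", config$max_iter)
  converged <- FALSE
  iters <- 0L
  gap_prev <- cur$data[, gidx, , drop = FALSE]
  for (it in seq_len(config$max_iter)) {
    sv <- svd(lift_u(cube))
    d1 <- sv$d[1]
    thr <- config$threshold_frac * d1
    if (config$threshold_mode == "hard") {
      r <- max(1L, sum(sv$d >= thr))
      keep_w <- rep(1, r)                 # P_null = I - Vs Vs^H
    } else {
      r <- max(1L, sum(sv$d > thr))
      keep_w <- 1 - pmin(1, thr / sv$d[seq_len(r)])  # soft: partial shrink
    }
    Vs <- sv$v[, seq_len(r), drop = FALSE]
    ann_op <- function(u) {
      Mu <- lift_u(u)
      unlift_u(Mu - (Mu %*% Vs) %*% (keep_w * Conj(t(Vs))))
    }
    Aop <- function(u) degrid_adj(degrid_op(u) * w_data) + lam * ann_op(u) +
      ridge * u
    # warm-started CG on the normal equations
    rr <- b - Aop(cube)
    p <- rr
    rs <- re_inner(rr, rr)
    for (k in seq_len(config$cg_iter)) {
      if (rs == 0) break
      q <- Aop(p)
      alpha <- rs / re_inner(p, q)
      if (!is.finite(alpha)) break
      cube <- cube + alpha * p
      rr <- rr - alpha * q
      rs2 <- re_inner(rr, rr)
      p <- rr + (rs2 / rs) * p
      rs <- rs2
    }
    synth <- degrid_op(cube)
    gap_new <- array(synth, dim = c(traj$n_spokes, n_keep, ncoil))[, gidx, ,
                                                                   drop = FALSE]
    delta <- l2(gap_new - gap_prev)
    rel <- delta / max(total_norm, l2(gap_new))
    gap_prev <- gap_new
    iters <- it
    trace[[it]] <- data.frame(iteration = it, rel_change = rel,
                              gap_energy = sum(Mod(gap_new)^2),
                              sigma_max = d1, rank = r)
    if (rel < config$tol) { converged <- TRUE; break }
  }
  cur$data[, gidx, ] <- gap_prev
  attr(cur, "trace") <- do.call(rbind, trace[seq_len(iters)])
  attr(cur, "iterations") <- iters
  attr(cur, "converged") <- converged
  cur
}
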