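# ZINFANDEL: GRAPPA-like kernel calibration and inward extrapolation along
# radial spokes. A 1D multi-coil interpolation kernel is trained on acquired
# samples just outside the dead-time gap, using the angularly nearest spokes
# as calibration data, and applied one missing dwell at a time from the
# outside inward, recalibrating at every depth.

#' Calibrate a ZINFANDEL prediction kernel
#'
#' For the target spoke's `calib_spokes` angularly nearest neighbors
#' (great-circle angle between spoke directions, ties broken by spoke index,
#' the spoke itself included), regression rows are built by sliding the 1D
#' kernel over the `calib_readout` samples that start just outside the
#' position being predicted: the sample at readout index q is regressed onto
#' the `kernel_length` samples at q+1, ..., q+kernel_length across all coils.
#' Solved by Tikhonov-regularized least squares (ridge relative to the Gram
#' trace).
#'
#' @param kspace `multicoil_kspace` (current state: earlier-filled samples
#'   take part in calibration for deeper positions).
#' @param traj `radial_trajectory`.
#' @param s target spoke index.
#' @param fill_pos 1-based readout index being predicted.
#' @param kernel_length readout taps (default 5).
#' @param calib_readout samples per spoke used for calibration (default 16).
#' @param calib_spokes number of angular neighbors (default 5).
#' @param lambda relative Tikhonov weight (default 1e-6).
#' @return list with `weights` (complex, (n_coils*kernel_length) x n_coils),
#'   `neighbors`, and the calibration row count `n_rows`.
#' @export
calibrate_kernel <- function(kspace, traj, s, fill_pos, kernel_length = 5,
                             calib_readout = 16, calib_spokes = 5,
                             lambda = 1e-6) {
  stopifnot(calib_readout >= kernel_length + 1)
  n <- traj$n_readout
  ncoil <- n_coils(kspace)
  if (fill_pos + calib_readout > n)
    stop("calibration window exceeds the readout")
  nb <- nearest_spokes(traj, s, calib_spokes)
  qs <- (fill_pos + 1L):(fill_pos + calib_readout - kernel_length)
  n_rows <- length(nb) * length(qs)
  X <- matrix(0 + 0i, n_rows, ncoil * kernel_length)
  Tm <- matrix(0 + 0i, n_rows, ncoil)
  row <- 1L
  for (b in nb) {
    for (q in qs) {
      X[row, ] <- as.vector(kspace$data[b, q + seq_len(kernel_length), ])
      Tm[row, ] <- kspace$data[b, q, ]
      row <- row + 1L
    }
  }
  G <- Conj(t(X)) %*% X
  tr <- Re(sum(diag(G)))
  if (tr == 0) {
    weights <- matrix(0 + 0i, ncoil * kernel_length, ncoil)
  } else {
    ridge <- lambda * tr / ncol(G)
    sv_min <- tryCatch(min(abs(diag(qr.R(qr(G))))), error = function(e) 0)
    if (sv_min < 1e-12 * tr && lambda == 0)
      warning("underdetermined ZINFANDEL calibration; using Tikhonov fallback")
    weights <- solve(G + ridge * diag(ncol(G)), Conj(t(X)) %*% Tm)
  }
  list(weights = weights, neighbors = nb, n_rows = n_rows)
}

# indices of the k angularly nearest spokes to s (including s itself)
nearest_spokes <- function(traj, s, k) {
  dots <- pmin(1, pmax(-1, traj$spoke_dirs %*% traj$spoke_dirs[s, ]))
  ang <- acos(dots)
  order(ang, seq_len(traj$n_spokes))[seq_len(min(k, traj$n_spokes))]
}

#' ZINFANDEL dead-time gap infilling
#'
#' Fills the gap one dwell at a time from the outside inward. All spokes are
#' advanced position by position, so previously synthesized samples are
#' available (as sources and calibration data) when predicting deeper
#' positions; `recursive = FALSE` instead calibrates a shifted kernel that
#' reaches across the remaining gap and only ever reads acquired samples.
#' Acquired samples are untouched.
#'
#' @inheritParams calibrate_kernel
#' @param gap gap in Nyquist dwells or `dead_time_gap`.
#' @param recursive use previously synthesized samples when descending
#'   (default TRUE).
#' @return the filled `multicoil_kspace`.
#' @export
zinfandel_infill <- function(kspace, traj, gap, kernel_length = 5,
                             calib_readout = 16, calib_spokes = 5,
                             lambda = 1e-6, recursive = TRUE) {
  check_conformal(kspace, traj)
  n_miss <- missing_sample_count(as_gap(gap), traj$oversampling)
  if (n_miss == 0) return(kspace)
  n <- traj$n_readout
  if (n_miss + calib_readout + 1L > n)
    stop("gap too large for the calibration region")
  out <- kspace
  ncoil <- n_coils(kspace)
  nb_cache <- lapply(seq_len(traj$n_spokes), function(s)
    nearest_spokes(traj, s, calib_spokes))
  for (p in n_miss:1) {
    offset <- if (recursive) 1L else (n_miss + 1L) - p
    filled <- matrix(0 + 0i, traj$n_spokes, ncoil)
    for (s in seq_len(traj$n_spokes)) {
      cal <- calibrate_shifted(out, traj, nb_cache[[s]], p, offset,
                               kernel_length, calib_readout, lambda)
      src <- as.vector(out$data[s, p + offset - 1L + seq_len(kernel_length), ])
      filled[s, ] <- crossprod_fill(cal, src)
    }
    if (any(!is.finite(Re(filled)))) stop("ZINFANDEL produced non-finite values")
    out$data[, p, ] <- filled
  }
  out
}

# calibration with a source window displaced `offset` dwells beyond the target
calibrate_shifted <- function(kspace, traj, nb, fill_pos, offset,
                              kernel_length, calib_readout, lambda) {
  n <- traj$n_readout
  ncoil <- dim(kspace$data)[3]
  q_hi <- min(n - offset - kernel_length + 1L,
              fill_pos + calib_readout - kernel_length)
  qs <- (fill_pos + 1L):q_hi
  qs <- qs[qs + offset + kernel_length - 1L <= n]
  X <- matrix(0 + 0i, length(nb) * length(qs), ncoil * kernel_length)
  Tm <- matrix(0 + 0i, length(nb) * length(qs), ncoil)
  row <- 1L
  for (b in nb) {
    for (q in qs) {
      X[row, ] <- as.vector(kspace$data[b, q + offset - 1L + seq_len(kernel_length), ])
      Tm[row, ] <- kspace$data[b, q, ]
      row <- row + 1L
    }
  }
  G <- Conj(t(X)) %*% X
  tr <- Re(sum(diag(G)))
  if (tr == 0) return(matrix(0 + 0i, ncoil * kernel_length, ncoil))
  ridge <- lambda * tr / ncol(G)
  solve(G + ridge * diag(ncol(G)), Conj(t(X)) %*% Tm)
}

# predicted targets: weights^T . sources  (weights: nsrc x ncoil)
crossprod_fill <- function(weights, src) {
  as.vector(t(weights) %*% src)
}
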