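# Explicit per-spoke gap solvers.
#
# Both methods exploit readout oversampling: on an r-times oversampled
# readout the reconstructed 1D projection spans r times the nominal FOV, so
# everything outside the central nominal band must be (close to) zero. The
# missing central Fourier coefficients are chosen to minimize the energy
# (algebraic method: full complex signal; Stoch-Olejniczak: real part only)
# that leaks outside that band.

#' Concatenate a diametric spoke pair into one k-space line
#'
#' The partner spoke supplies the negative frequencies (reversed), spoke `s`
#' the nonnegative ones; the shared origin sample is used once, so the line
#' has length `L = 2 * n_readout - 1` with the k-space origin at (1-based)
#' index `n_readout`.
#'
#' @param kspace a `multicoil_kspace`.
#' @param traj the `radial_trajectory` (spoke `s` must be paired).
#' @param s spoke index (1-based).
#' @return complex matrix (L x n_coils); attribute `"center"` holds the
#'   origin index.
#' @export
build_pair_line <- function(kspace, traj, s) {
  t <- traj$pair_index[s]
  if (is.na(t)) stop("spoke has no diametric partner")
  n <- traj$n_readout
  neg <- kspace$data[t, n:2, , drop = FALSE]    # reversed partner, no origin
  pos <- kspace$data[s, , , drop = FALSE]
  line <- rbind(array(neg, dim = c(n - 1L, dim(kspace$data)[3])),
                array(pos, dim = c(n, dim(kspace$data)[3])))
  attr(line, "center") <- n
  line
}

#' The pair-line linear system of the algebraic method
#'
#' Builds the inverse-DFT rows of the out-of-band region for a full pair line
#' of length `L = 2 * n_readout - 1` (or for a single spoke half-line of
#' length `n_readout` when `single_spoke = TRUE`), split into the columns
#' acting on the gap unknowns and on the acquired samples. Exposed so the
#' conditioning of the gap-restricted system can be inspected directly.
#'
#' @param n_readout samples per spoke.
#' @param oversampling readout oversampling factor r.
#' @param gap gap in Nyquist dwells or `dead_time_gap`.
#' @param single_spoke build the single-spoke (one-sided) system instead of
#'   the pair-line system.
#' @return list with `A` (out-of-band rows x gap columns), `W_out` (full
#'   out-of-band IDFT block), `gap_idx` (1-based line indices of the gap),
#'   `out_idx`, `L`, and `center`.
#' @export
pair_line_system <- function(n_readout, oversampling, gap,
                             single_spoke = FALSE) {
  r <- oversampling
  n_miss <- missing_sample_count(as_gap(gap), r)
  if (single_spoke) {
    L <- n_readout
    center <- 1L                               # origin = first sample
    gap_idx <- if (n_miss > 0) seq_len(min(n_miss, L)) else integer(0)
    # IDFT over t_i = (i-1)/L of the one-sided spectrum; out-of-band when the
    # position is farther than FOV/2 from 0 (mod the oversampled extent)
    i <- 0:(L - 1L)
    frac <- i / L
    out_idx <- which(pmin(frac, 1 - frac) > 1 / (2 * r))
    W <- exp(2i * pi * outer(i, i) / L) / L
    # the origin is the only self-conjugate term of the one-sided spectrum:
    # half weight makes Re of the one-sided sum equal half the projection
    W[, 1] <- W[, 1] / 2
  } else {
    L <- 2L * n_readout - 1L
    center <- n_readout
    gap_idx <- if (n_miss > 0) center + (-(n_miss - 1L)):(n_miss - 1L)
               else integer(0)
    i <- 0:(L - 1L)
    off <- i - (center - 1L)
    out_idx <- which(abs(off) > L / (2 * r))
    W <- exp(2i * pi * outer(off, off) / L) / L
  }
  W_out <- W[out_idx, , drop = FALSE]
  list(A = W_out[, gap_idx, drop = FALSE], W_out = W_out,
       gap_idx = gap_idx, out_idx = out_idx, L = L, center = center)
}

# Factorized least-squares solver for many lines sharing one gap geometry.
# Returns a function mapping a matrix of lines (L x n_lines, gap rows
# arbitrary) to solved gap entries (n_gap x n_lines).
gap_line_solver <- function(sys, lambda = 1e-12,
                            reg = c("tikhonov", "tsvd"), tsvd_tol = 1e-6,
                            real_part_only = FALSE) {
  reg <- match.arg(reg)
  A <- sys$A
  ng <- ncol(A)
  if (ng == 0) return(function(lines) matrix(0 + 0i, 0, ncol(lines)))
  if (!real_part_only) {
    sv <- svd(A)
    if (reg == "tikhonov") {
      if (lambda == 0 && sv$d[ng] < 1e-12 * sv$d[1])
        warning("gap system is numerically singular; add regularization")
      filt <- sv$d / (sv$d^2 + lambda)
    } else {
      filt <- ifelse(sv$d >= tsvd_tol * sv$d[1], 1 / sv$d, 0)
    }
    P <- sv$v %*% (filt * Conj(t(sv$u)))    # regularized pseudo-inverse
    function(lines) {
      y0 <- lines
      y0[sys$gap_idx, ] <- 0 + 0i
      b <- -(sys$W_out %*% y0)
      P %*% b
    }
  } else {
    Ar <- cbind(Re(A), -Im(A))
    sv <- svd(Ar)
    if (reg == "tikhonov") {
      filt <- sv$d / (sv$d^2 + lambda)
    } else {
      filt <- ifelse(sv$d >= tsvd_tol * sv$d[1], 1 / sv$d, 0)
    }
    P <- sv$v %*% (filt * t(sv$u))
    function(lines) {
      y0 <- lines
      y0[sys$gap_idx, ] <- 0 + 0i
      b <- -Re(sys$W_out %*% y0)
      m_ri <- P %*% b
      m_ri[seq_len(ng), , drop = FALSE] +
        1i * m_ri[ng + seq_len(ng), , drop = FALSE]
    }
  }
}

#' Algebraic dead-time gap infilling
#'
#' For every diametric spoke pair and coil independently, solves the small
#' least-squares system for the missing central line samples that minimizes
#' the signal energy outside the nominal FOV band of the oversampled
#' pair-line projection, with Tikhonov or truncated-SVD regularization.
#' Acquired samples are untouched.
#'
#' @param kspace gapped `multicoil_kspace`.
#' @param traj `radial_trajectory`; all spokes must be paired and the readout
#'   oversampling must be >= 2 (the outer band is the prior).
#' @param gap gap in Nyquist dwells or `dead_time_gap`.
#' @param lambda Tikhonov weight (default 1e-12).
#' @param reg "tikhonov" or "tsvd".
#' @param tsvd_tol relative singular-value cutoff for "tsvd".
#' @return the filled `multicoil_kspace` (mask unchanged: synthesized samples
#'   keep `mask = FALSE`).
#' @export
algebraic_infill <- function(kspace, traj, gap, lambda = 1e-12,
                             reg = c("tikhonov", "tsvd"), tsvd_tol = 1e-6) {
  reg <- match.arg(reg)
  check_conformal(kspace, traj)
  if (traj$oversampling < 2)
    stop("algebraic infilling requires readout oversampling >= 2")
  if (any(is.na(traj$pair_index)))
    stop("algebraic infilling requires all spokes to be diametrically paired")
  n_miss <- missing_sample_count(as_gap(gap), traj$oversampling)
  if (n_miss == 0) return(kspace)
  n <- traj$n_readout
  ncoil <- n_coils(kspace)
  sys <- pair_line_system(n, traj$oversampling, gap)
  solver <- gap_line_solver(sys, lambda, reg, tsvd_tol)
  pairs_s <- which(seq_len(traj$n_spokes) < traj$pair_index)
  lines <- matrix(0 + 0i, sys$L, length(pairs_s) * ncoil)
  col <- 1L
  for (s in pairs_s) {
    pl <- build_pair_line(kspace, traj, s)
    lines[, col:(col + ncoil - 1L)] <- pl
    col <- col + ncoil
  }
  M <- solver(lines)
  out <- kspace
  jc <- sys$center
  for (pi in seq_along(pairs_s)) {
    s <- pairs_s[pi]
    t <- traj$pair_index[s]
    cols <- (pi - 1L) * ncoil + seq_len(ncoil)
    for (gi in seq_along(sys$gap_idx)) {
      j <- sys$gap_idx[gi]
      v <- M[gi, cols]
      if (j >= jc) out$data[s, j - jc + 1L, ] <- v
      if (j <= jc) out$data[t, jc - j + 1L, ] <- v
    }
  }
  out
}

#' Stoch-Olejniczak dead-time gap infilling
#'
#' Single-spoke variant of the algebraic method: per spoke and coil, the
#' missing samples minimize only the *real part* of the one-sided projection
#' outside the nominal FOV band, which presumes an essentially real
#' projection and removes the need for diametric pairing. Each line is
#' normalized by its global phase (estimated from the acquired samples just
#' outside the gap) before the solve and rotated back afterwards, so a
#' constant phase error on the data leaves the recovery unchanged - the
#' phase-immunity rationale of the method.
#'
#' @inheritParams algebraic_infill
#' @return the filled `multicoil_kspace`.
#' @export
stoch_olejniczak_infill <- function(kspace, traj, gap, lambda = 1e-12,
                                    reg = c("tikhonov", "tsvd"),
                                    tsvd_tol = 1e-6) {
  reg <- match.arg(reg)
  check_conformal(kspace, traj)
  if (traj$oversampling < 2)
    stop("Stoch-Olejniczak infilling requires readout oversampling >= 2")
  n_miss <- missing_sample_count(as_gap(gap), traj$oversampling)
  if (n_miss == 0) return(kspace)
  n <- traj$n_readout
  ncoil <- n_coils(kspace)
  sys <- pair_line_system(n, traj$oversampling, gap, single_spoke = TRUE)
  solver <- gap_line_solver(sys, lambda, reg, tsvd_tol, real_part_only = TRUE)
  lines <- matrix(0 + 0i, n, traj$n_spokes * ncoil)
  for (c in seq_len(ncoil))
    lines[, (c - 1L) * traj$n_spokes + seq_len(traj$n_spokes)] <-
      t(kspace$data[, , c])
  # per-line global-phase normalization from the near-gap acquired samples
  ref_idx <- (n_miss + 1L):min(n, n_miss + 8L)
  phase <- Arg(colSums(lines[ref_idx, , drop = FALSE]))
  lines <- sweep(lines, 2, exp(-1i * phase), `*`)
  M <- solver(lines)
  M <- sweep(M, 2, exp(1i * phase), `*`)
  out <- kspace
  for (c in seq_len(ncoil)) {
    cols <- (c - 1L) * traj$n_spokes + seq_len(traj$n_spokes)
    out$data[, sys$gap_idx, c] <- t(M[, cols, drop = FALSE])
  }
  out
}
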