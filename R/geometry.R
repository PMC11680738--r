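# Center-out radial trajectories and the ZTE dead-time gap.
#
# A spoke samples k-space at radii (m / r) * Delta-k for m = 0 .. n_readout-1
# along its direction, with sample 0 exactly at the k-space origin; r is the
# readout oversampling factor and Delta-k = 1/FOV = 1 in the cycles/FOV units
# used throughout. The dead time after excitation removes every readout-grid
# time strictly inside [0, g * dt), g being the gap in nominal Nyquist dwells.

#' Construct a radial trajectory object
#'
#' Usually called through [make_uniform_spokes_2d()] or
#' [make_phyllotaxis_spokes_3d()].
#'
#' @param spoke_dirs numeric matrix (n_spokes x d) of unit direction vectors.
#' @param n_readout samples per spoke on the oversampled readout grid.
#' @param oversampling readout oversampling factor r >= 1.
#' @param pair_index integer vector: for each spoke the index of its diametric
#'   counterpart, or NA when unpaired.
#' @param fov_mm optional field of view in mm (metadata only; coordinates are
#'   kept in cycles/FOV).
#' @return object of class `radial_trajectory`.
#' @export
radial_trajectory <- function(spoke_dirs, n_readout, oversampling = 2,
                              pair_index = NULL, fov_mm = NULL) {
  spoke_dirs <- as.matrix(spoke_dirs)
  n_spokes <- nrow(spoke_dirs)
  nrm <- sqrt(rowSums(spoke_dirs^2))
  if (any(abs(nrm - 1) > 1e-12))
    spoke_dirs <- spoke_dirs / nrm
  stopifnot(n_readout >= 1, oversampling >= 1)
  if (!is.null(pair_index)) {
    pair_index <- as.integer(pair_index)
    stopifnot(length(pair_index) == n_spokes)
    ok <- !is.na(pair_index)
    if (any(ok)) {
      t <- pair_index[ok]
      if (any(pair_index[t] != which(ok)))
        stop("pair_index is not an involution")
      if (max(abs(spoke_dirs[t, , drop = FALSE] +
                  spoke_dirs[ok, , drop = FALSE])) > 1e-9)
        stop("paired spokes are not antipodal")
    }
  } else {
    pair_index <- rep(NA_integer_, n_spokes)
  }
  structure(list(spoke_dirs = spoke_dirs, n_spokes = n_spokes,
                 n_readout = as.integer(n_readout),
                 oversampling = oversampling, dwell_spacing = 1,
                 pair_index = pair_index, d = ncol(spoke_dirs),
                 fov_mm = fov_mm),
            class = "radial_trajectory")
}

#' Per-sample k-space coordinates of a trajectory
#'
#' Row order matches the flattening of the k-space data array
#' (spoke index fastest, then readout sample), i.e. row
#' `(m * n_spokes + s)` holds sample m of spoke s (0-based).
#'
#' @param traj a `radial_trajectory`.
#' @param sample_idx optional 0-based readout sample indices to keep
#'   (default: all).
#' @return numeric matrix ((n_spokes * n_kept) x d) in cycles/FOV.
#' @export
traj_coords <- function(traj, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- 0:(traj$n_readout - 1L)
  radii <- sample_idx / traj$oversampling * traj$dwell_spacing
  do.call(cbind, lapply(seq_len(traj$d), function(a)
    as.vector(outer(traj$spoke_dirs[, a], radii))))
}

#' Maximum sampled k-space radius of a trajectory (cycles/FOV)
#' @param traj a `radial_trajectory`.
#' @export
traj_max_radius <- function(traj) {
  (traj$n_readout - 1L) / traj$oversampling * traj$dwell_spacing
}

#' @export
print.radial_trajectory <- function(x, ...) {
  npair <- sum(!is.na(x$pair_index))
  cat(sprintf(
    "%dD center-out radial trajectory: %d spokes (%d paired), %d samples/spoke, %gx readout oversampling, max radius %.1f dk\n",
    x$d, x$n_spokes, npair, x$n_readout, x$oversampling, traj_max_radius(x)))
  invisible(x)
}

#' Uniform 2D radial spokes
#'
#' When `paired = TRUE` (even `n_spokes`) the directions are `n_spokes`
#' equispaced angles over the full circle, so every spoke has its diametric
#' counterpart and each spoke pair forms a full line through the k-space
#' origin. Unpaired spokes are spread over the half circle `[0, pi)`.
#'
#' @param n_spokes number of spokes (even when paired).
#' @param n_readout samples per spoke.
#' @param oversampling readout oversampling factor.
#' @param paired request diametric pairing (default TRUE).
#' @inheritParams radial_trajectory
#' @return a `radial_trajectory`.
#' @export
make_uniform_spokes_2d <- function(n_spokes, n_readout, oversampling = 2,
                                   paired = TRUE, fov_mm = NULL) {
  stopifnot(n_spokes >= 1, n_readout >= 1)
  if (paired) {
    if (n_spokes %% 2L != 0L)
      stop("paired 2D spokes require an even number of spokes")
    ang <- (0:(n_spokes - 1L)) * (2 * pi / n_spokes)
    half <- n_spokes %/% 2L
    pair_index <- ((0:(n_spokes - 1L) + half) %% n_spokes) + 1L
  } else {
    ang <- (0:(n_spokes - 1L)) * (pi / n_spokes)
    pair_index <- NULL
  }
  dirs <- cbind(cos(ang), sin(ang))
  radial_trajectory(dirs, n_readout, oversampling, pair_index, fov_mm)
}

#' 3D phyllotaxis (golden-angle) radial spokes
#'
#' Spoke tips follow a spherical Fibonacci/phyllotaxis layout: the azimuth
#' advances by the golden angle while the polar coordinate sweeps the upper
#' hemisphere with uniform area per tip. With `bidirectional = TRUE` every
#' spoke's antipode is appended and `pair_index` links the two, giving full
#' diametric coverage of the sphere.
#'
#' @param n_spokes number of base (hemisphere) spokes, >= 1.
#' @param n_readout samples per spoke.
#' @param oversampling readout oversampling factor.
#' @param bidirectional append antipodal partners (default TRUE).
#' @inheritParams radial_trajectory
#' @return a `radial_trajectory` with `2 * n_spokes` spokes when
#'   bidirectional.
#' @export
make_phyllotaxis_spokes_3d <- function(n_spokes, n_readout, oversampling = 2,
                                       bidirectional = TRUE, fov_mm = NULL) {
  stopifnot(n_spokes >= 1, n_readout >= 1)
  i <- seq_len(n_spokes)
  z <- 1 - (i - 0.5) / n_spokes           # area-uniform on the hemisphere
  golden <- pi * (3 - sqrt(5))
  az <- i * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rho * cos(az), rho * sin(az), z)
  if (bidirectional) {
    dirs <- rbind(dirs, -dirs)
    pair_index <- c(n_spokes + i, i)
  } else {
    pair_index <- NULL
  }
  radial_trajectory(dirs, n_readout, oversampling, pair_index, fov_mm)
}

#' Dead-time gap descriptor
#'
#' @param gap_dwells dead time expressed in nominal Nyquist dwells
#'   `g = dead_time / dwell_time`; may be half-integer (e.g. 2.5), must be
#'   nonnegative.
#' @return object of class `dead_time_gap`.
#' @export
dead_time_gap <- function(gap_dwells) {
  if (!is.numeric(gap_dwells) || length(gap_dwells) != 1 || gap_dwells < 0)
    stop("gap_dwells must be a single nonnegative number")
  structure(list(gap_dwells = as.numeric(gap_dwells)), class = "dead_time_gap")
}

as_gap <- function(gap) {
  if (inherits(gap, "dead_time_gap")) gap else dead_time_gap(gap)
}

#' Number of missing readout samples for a dead-time gap
#'
#' Counts the readout-grid times `m * dt / r` (m >= 0, sample 0 at the
#' k-space origin) that fall strictly inside the dead time `[0, g * dt)`;
#' a sample landing exactly on the gap boundary is acquired. This is
#' `ceil(r * g)`: a gap of 2.5 dwells loses 3 samples on the nominal grid
#' and 5 on a twice-oversampled grid, a gap of 4.5 loses 5 and 9.
#'
#' @param gap_dwells gap size g in nominal Nyquist dwells (or a
#'   `dead_time_gap`).
#' @param oversampling readout oversampling factor r >= 1.
#' @return nonnegative integer count of missing samples per spoke.
#' @export
missing_sample_count <- function(gap_dwells, oversampling = 1) {
  if (inherits(gap_dwells, "dead_time_gap")) gap_dwells <- gap_dwells$gap_dwells
  if (gap_dwells < 0) stop("gap must be nonnegative")
  stopifnot(oversampling >= 1)
  as.integer(ceiling(oversampling * gap_dwells - 1e-12))
}

#' Apply the dead-time gap to multi-coil k-space
#'
#' Zeroes every readout sample with `m / r < g` on all spokes and coils and
#' flags it unacquired in the mask; all other samples are untouched.
#' Idempotent.
#'
#' @param kspace a [multicoil_kspace()].
#' @param traj the matching `radial_trajectory`.
#' @param gap gap in Nyquist dwells or a `dead_time_gap`.
#' @return the masked `multicoil_kspace`.
#' @export
apply_gap <- function(kspace, traj, gap) {
  gap <- as_gap(gap)
  check_conformal(kspace, traj)
  n_miss <- missing_sample_count(gap, traj$oversampling)
  if (n_miss > traj$n_readout) n_miss <- traj$n_readout
  if (n_miss > 0) {
    kspace$data[, seq_len(n_miss), ] <- 0 + 0i
    kspace$mask[, seq_len(n_miss)] <- FALSE
  }
  kspace
}

#' Readout indices (1-based) inside the gap
#' @noRd
gap_sample_idx <- function(traj, gap) {
  n_miss <- missing_sample_count(as_gap(gap), traj$oversampling)
  if (n_miss == 0) integer(0) else seq_len(min(n_miss, traj$n_readout))
}

#' Multi-coil radial k-space container
#'
#' @param data complex array of dim (n_spokes, n_readout, n_coils).
#' @param mask logical matrix (n_spokes, n_readout); TRUE = acquired. After
#'   infilling, entries that were synthesized keep `mask = FALSE`, so the mask
#'   always records what was measured.
#' @return object of class `multicoil_kspace`.
#' @export
multicoil_kspace <- function(data, mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  data <- array(as.complex(data), dim = dim(data))
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(identical(dim(mask), dim(data)[1:2]))
  structure(list(data = data, mask = mask), class = "multicoil_kspace")
}

#' @export
print.multicoil_kspace <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("multi-coil k-space: %d spokes x %d samples x %d coils; %d unacquired samples/spoke\n",
              dm[1], dm[2], dm[3], sum(!x$mask[1, ])))
  invisible(x)
}

check_conformal <- function(kspace, traj) {
  dm <- dim(kspace$data)
  if (dm[1] != traj$n_spokes || dm[2] != traj$n_readout)
    stop("k-space array does not conform to the trajectory")
  invisible(TRUE)
}

n_coils <- function(kspace) dim(kspace$data)[3]
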