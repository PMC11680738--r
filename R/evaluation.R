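# Metrics and Monte Carlo sweeps over gap size, SNR and noise realization.

#' Squared error between two magnitude images
#'
#' Sum of squared voxel differences `sum_i (a_i - b_i)^2`.
#'
#' @param a,b nonnegative magnitude arrays of identical shape (or
#'   `image_volume`s, whose moduli are taken).
#' @return nonnegative number.
#' @export
squared_error <- function(a, b) {
  a <- as_magnitude(a)
  b <- as_magnitude(b)
  if (!identical(dim(a), dim(b)) && length(a) != length(b))
    stop("shape mismatch")
  sum((a - b)^2)
}

as_magnitude <- function(x) {
  if (inherits(x, "image_volume")) x <- x$values
  if (is.complex(x)) Mod(x) else as.array(x)
}

#' Image-domain SNR in dB
#'
#' `10 * log10( sum|x|^2 / sum|n_img|^2 )`, with `n_img` the pure-noise
#' channel transported to the image domain (the grid-normalized adjoint NUFFT
#' used by [add_noise_at_snr()]). Returns `Inf` for a zero noise image.
#'
#' @param clean_image noise-free image (array or `image_volume`).
#' @param noise_only_image image-domain transform of the pure noise.
#' @return SNR in dB.
#' @export
measure_snr_db <- function(clean_image, noise_only_image) {
  sx <- sum(as_magnitude(clean_image)^2)
  sn <- sum(as_magnitude(noise_only_image)^2)
  if (sn == 0) return(Inf)
  10 * log10(sx / sn)
}

#' Per-coil CG-NUFFT magnitude reconstruction
#'
#' The method-agnostic readout used to compare infilling methods: every coil
#' is reconstructed from its (filled) radial samples by [cg_nufft_inverse()]
#' and the coil images are combined by root sum of squares. All samples,
#' including zero or synthesized gap samples, enter as data, so
#' reconstructions differ only through the gap coefficients.
#'
#' @param kspace `multicoil_kspace` (filled or zero-filled).
#' @param traj `radial_trajectory`.
#' @param grid_shape reconstruction grid (defaults to the nominal grid
#'   implied by the trajectory radius).
#' @param cg_iter CG iterations (default 10).
#' @param plan optional precomputed plan.
#' @return an `image_volume` with real nonnegative values.
#' @export
recon_rss <- function(kspace, traj, grid_shape = NULL, cg_iter = 10,
                      plan = NULL) {
  if (is.null(grid_shape)) {
    n <- 2L * as.integer(floor(traj_max_radius(traj) + 0.5))
    grid_shape <- rep(n, traj$d)
  }
  if (is.null(plan)) plan <- nufft_plan(traj_coords(traj), grid_shape)
  acc <- array(0, dim = grid_shape)
  dcf <- radial_dcf(traj)
  for (c in seq_len(n_coils(kspace))) {
    img <- cg_nufft_inverse(as.vector(kspace$data[, , c]), plan,
                            n_iter = cg_iter, weights = dcf)
    acc <- acc + Mod(img)^2
  }
  image_volume(sqrt(acc))
}

#' Monte Carlo sweep over gap size, SNR and noise realization
#'
#' For every (gap, SNR, realization) cell one noise realization is drawn
#' (seeded by [derive_seed()] from `base_seed` and the cell counter, so the
#' sweep is bit-reproducible and every method sees the identical noisy
#' data), the dead-time gap is applied, each method fills it, and the squared
#' error of the RSS reconstruction against the ground-truth magnitude is
#' recorded. Method failures yield NaN rows and the sweep continues.
#'
#' @param scene a list describing the simulation: `image` (`image_volume`
#'   ground truth), `maps`, `traj`, and optionally `clean_kspace` (computed
#'   if absent), as built by [make_scene()].
#' @param methods character vector among "zerofill", "algebraic", "stoch",
#'   "zinfandel", "cgsense", "lowrank".
#' @param gaps gap sizes in Nyquist dwells (default `seq(1, 4.5, by = 0.5)`).
#' @param snrs_db SNR levels in dB (default `c(5, 10, 15, 20)`).
#' @param n_realizations noise realizations per cell (default 20).
#' @param base_seed master seed.
#' @param control named list of per-method argument lists, e.g.
#'   `list(lowrank = list(config = lowrank_config(...)), cgsense =
#'   list(n_iter = 20))`.
#' @param recon_cg_iter CG iterations of the readout reconstruction.
#' @param verbose print one line per cell.
#' @return long-format data.frame: method, gap, snr_db, realization,
#'   squared_error, normalized_error, iterations, converged.
#' @export
monte_carlo_sweep <- function(scene, methods = c("zerofill", "algebraic",
                                                 "stoch", "zinfandel",
                                                 "cgsense", "lowrank"),
                              gaps = seq(1, 4.5, by = 0.5),
                              snrs_db = c(5, 10, 15, 20),
                              n_realizations = 20, base_seed = 1,
                              control = list(), recon_cg_iter = 10,
                              verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  image <- scene$image
  traj <- scene$traj
  maps <- scene$maps
  full_plan <- nufft_plan(traj_coords(traj), image$shape,
                          width = scene$nufft_width %||% 6)
  clean <- scene$clean_kspace
  if (is.null(clean)) clean <- simulate_kspace(image, maps, traj, plan = full_plan)
  truth_mag <- Mod(image$values)
  ref_energy <- sum(truth_mag^2)
  rows <- list()
  counter <- 0L
  for (gap in gaps) {
    for (snr in snrs_db) {
      for (rep_i in seq_len(n_realizations)) {
        counter <- counter + 1L
        seed <- derive_seed(base_seed, counter)
        noisy <- add_noise_at_snr(clean, noise_spec(snr, seed), image, traj,
                                  plan = full_plan)
        gapped <- apply_gap(noisy, traj, gap)
        for (m in methods) {
          t0 <- proc.time()[["elapsed"]]
          res <- tryCatch(
            run_method(m, gapped, traj, gap, maps, control, seed),
            error = function(e) e)
          if (inherits(res, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
              method = m, gap = gap, snr_db = snr, realization = rep_i,
              squared_error = NaN, normalized_error = NaN,
              iterations = NA_integer_, converged = NA, seconds = NA_real_)
            next
          }
          rec <- recon_rss(res$kspace, traj, image$shape,
                           cg_iter = recon_cg_iter, plan = full_plan)
          se <- squared_error(truth_mag, rec)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, gap = gap, snr_db = snr, realization = rep_i,
            squared_error = se, normalized_error = se / ref_energy,
            iterations = res$iterations %||% NA_integer_,
            converged = res$converged %||% NA,
            seconds = proc.time()[["elapsed"]] - t0)
          if (verbose)
            message(sprintf("gap %.1f snr %g rep %d %-10s err %.4g",
                            gap, snr, rep_i, m, se))
        }
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_method <- function(m, gapped, traj, gap, maps, control, seed) {
  args <- control[[m]] %||% list()
  fit <- do.call(gap_infill, c(list(kspace = gapped, traj = traj, gap = gap,
                                    method = m, maps = maps), args))
  list(kspace = fit$kspace, iterations = fit$iterations,
       converged = fit$converged)
}

#' Bundle a simulated acquisition scene
#'
#' Convenience constructor used by sweeps and examples: a phantom, smooth
#' coil maps, a matching fully sampled trajectory and the noise-free k-space.
#'
#' @param image `image_volume` ground truth.
#' @param traj `radial_trajectory`.
#' @param n_coils number of coils.
#' @param seed seed for the coil-map draw.
#' @param nufft_width gridding kernel width used for simulation and
#'   reconstruction transforms.
#' @return list(image, maps, traj, clean_kspace, nufft_width).
#' @export
make_scene <- function(image, traj, n_coils = 4, seed = 1, nufft_width = 6) {
  maps <- make_coil_maps(image$shape, n_coils, seed = derive_seed(seed, 1L))
  plan <- nufft_plan(traj_coords(traj), image$shape, width = nufft_width)
  clean <- simulate_kspace(image, maps, traj, plan = plan)
  list(image = image, maps = maps, traj = traj, clean_kspace = clean,
       nufft_width = nufft_width)
}

#' Summaries of a low-rank convergence trace
#'
#' @param trace data.frame trace as attached by [lowrank_infill()] (or a
#'   `zte_infill` object holding one).
#' @param tol convergence tolerance the run used.
#' @return list: `iterations`, `converged`, `monotone_gap_energy` (TRUE when
#'   the synthesized gap energy grew monotonically, the expected fill-in
#'   behavior), and the trace itself.
#' @export
convergence_diagnostics <- function(trace, tol = 1e-6) {
  if (inherits(trace, "zte_infill")) trace <- trace$trace
  if (!is.data.frame(trace) && !is.null(attr(trace, "trace")))
    trace <- attr(trace, "trace")
  if (is.null(trace) || !is.data.frame(trace) || !nrow(trace))
    stop("empty convergence trace")
  n <- nrow(trace)
  converged <- trace$rel_change[n] < tol
  ge <- trace$gap_energy
  list(iterations = n, converged = converged,
       monotone_gap_energy = n < 2 ||
         all(diff(ge) >= -1e-9 * max(ge, 1e-300)),
       trace = trace)
}
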