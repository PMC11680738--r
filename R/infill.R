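# Single dispatching entry point over the five infilling methods plus the
# zero-filled baseline, returning a classed result with print/summary/plot
# methods.

#' Fill the ZTE dead-time gap
#'
#' Dispatches to one of the gap-infilling methods and wraps the result. All
#' methods leave acquired samples bit-identical to the input and only
#' synthesize the Fourier coefficients inside the dead-time gap; the k-space
#' mask keeps recording which samples were actually measured.
#'
#' @param kspace gapped `multicoil_kspace` (see [apply_gap()]).
#' @param traj `radial_trajectory`.
#' @param gap gap in Nyquist dwells or a `dead_time_gap`.
#' @param method one of "zerofill" (baseline: leave the gap at zero),
#'   "algebraic", "stoch" (Stoch-Olejniczak), "zinfandel", "cgsense",
#'   "lowrank".
#' @param maps `sensitivity_maps`, required by "cgsense" (and used by no
#'   other method).
#' @param ... further arguments passed to the method function
#'   ([algebraic_infill()], [stoch_olejniczak_infill()],
#'   [zinfandel_infill()], [cg_sense_infill()], [lowrank_infill()]).
#' @return object of class `zte_infill` with elements `kspace`, `method`,
#'   `gap`, `params`, and for iterative methods `trace`, `iterations`,
#'   `converged`.
#' @export
gap_infill <- function(kspace, traj, gap,
                       method = c("zerofill", "algebraic", "stoch",
                                  "zinfandel", "cgsense", "lowrank"),
                       maps = NULL, ...) {
  method <- match.arg(method)
  gap <- as_gap(gap)
  params <- list(...)
  filled <- switch(method,
    zerofill = apply_gap(kspace, traj, gap),
    algebraic = algebraic_infill(kspace, traj, gap, ...),
    stoch = stoch_olejniczak_infill(kspace, traj, gap, ...),
    zinfandel = zinfandel_infill(kspace, traj, gap, ...),
    cgsense = {
      if (is.null(maps)) stop("cgsense requires sensitivity maps")
      cg_sense_infill(kspace, traj, gap, maps, ...)
    },
    lowrank = lowrank_infill(kspace, traj, gap, ...))
  out <- structure(
    list(kspace = filled, method = method, gap = gap$gap_dwells,
         n_missing = missing_sample_count(gap, traj$oversampling),
         params = params,
         trace = attr(filled, "trace"),
         iterations = attr(filled, "iterations"),
         converged = attr(filled, "converged")),
    class = "zte_infill")
  out
}

#' @export
print.zte_infill <- function(x, ...) {
  cat(sprintf("ZTE gap infill: method '%s', gap %.2f Nyquist dwells (%d oversampled samples/spoke)\n",
              x$method, x$gap, x$n_missing))
  if (!is.null(x$iterations))
    cat(sprintf("  %d iterations, %s\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.zte_infill <- function(object, ...) {
  ks <- object$kspace
  gidx <- seq_len(min(object$n_missing, dim(ks$data)[2]))
  gap_energy <- if (object$n_missing > 0)
    sum(Mod(ks$data[, gidx, , drop = FALSE])^2) else 0
  out <- list(method = object$method, gap = object$gap,
              n_missing = object$n_missing,
              gap_energy = gap_energy,
              total_energy = sum(Mod(ks$data)^2),
              iterations = object$iterations, converged = object$converged)
  class(out) <- "summary.zte_infill"
  out
}

#' @export
print.summary.zte_infill <- function(x, ...) {
  cat(sprintf("method '%s': gap %.2f dwells (%d samples/spoke)\n",
              x$method, x$gap, x$n_missing))
  cat(sprintf("  synthesized gap energy %.4g (%.3f%% of total k-space energy)\n",
              x$gap_energy, 100 * x$gap_energy / max(x$total_energy, 1e-300)))
  if (!is.null(x$iterations))
    cat(sprintf("  iterations: %d (%s)\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "hit the cap"))
  invisible(x)
}

#' Plot the convergence trace of an iterative infill
#'
#' @param x a `zte_infill` from the low-rank method.
#' @param ... passed to `plot`.
#' @export
plot.zte_infill <- function(x, ...) {
  if (is.null(x$trace)) {
    warning("no convergence trace to plot for method '", x$method, "'")
    return(invisible(x))
  }
  tr <- x$trace
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(tr$iteration, tr$rel_change, type = "l", log = "y",
       xlab = "iteration", ylab = "relative k-space change",
       main = sprintf("gap %.1f dwells", x$gap), ...)
  plot(tr$iteration, tr$gap_energy, type = "l",
       xlab = "iteration", ylab = "synthesized gap energy", ...)
  invisible(x)
}
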