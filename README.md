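# ztegap

Dead-time gap infilling for zero echo time (ZTE) radial MRI.

ZTE sequences excite the spins while the encoding gradient is already on and
sample the free induction decay immediately afterwards, tracing center-out
radial spokes through k-space. The RF pulse duration and transmit/receive
switching impose a dead time Δt<sub>d</sub> during which nothing can be
acquired, so every spoke misses its innermost samples — on an r-times
oversampled readout, the ⌈r·Δt<sub>d</sub>/dt⌉ lowest spatial frequencies,
including the k-space origin. Left at zero, these missing Fourier
coefficients convolve the image with a sinc and destroy its contrast.

`ztegap` is for people studying or prototyping reconstruction-side remedies
to this problem. It simulates multi-coil center-out radial acquisitions (2D
uniform and 3D phyllotaxis trajectories, synthetic phantoms, smooth coil
sensitivity profiles, SNR-calibrated complex Gaussian noise) and recovers the
gap with five methods:

| method | idea |
|---|---|
| `algebraic` | per spoke-pair line, solve for the gap samples minimizing the signal outside the nominal FOV band of the oversampled projection |
| `stoch` (Stoch–Olejniczak) | single-spoke variant minimizing only the **real part** outside the band |
| `zinfandel` | GRAPPA-style 1D multi-coil kernel, calibrated near the gap on the angularly nearest spokes, extrapolating inward one dwell at a time |
| `cgsense` | conjugate-gradient SENSE with the gap excluded from the data term; the implicit fill is resampled back onto the gap coordinates |
| `lowrank` | structured low-rank infilling on the k-space center volume: block-Hankel (C-matrix) lifting of all coils jointly, singular value thresholding at 1.5 % of σ₁, and data-consistent solves iterated until the k-space estimate stops changing |

The low-rank model is the annihilating-filter property of finite-support
images: a band-limited filter h with (F·x) ∗ h = 0 exists whenever x does not
fill the field of view, so the lifted matrix H(Fx) has a nontrivial null
space and the missing center is the completion that keeps it low rank. Only
the center volume is processed, which keeps iterations cheap.

All methods share one contract: acquired samples are bit-identical before and
after infilling; only the coefficients inside the gap are synthesized, and
the sampling mask keeps recording what was actually measured.

## Worked example

```r
library(ztegap)

# a 64^2 two-disc phantom, 202 paired spokes, twice-oversampled readout,
# four receive coils
traj  <- make_uniform_spokes_2d(202, 64, oversampling = 2)
image <- make_disc_phantom(64, 20, 10)
scene <- make_scene(image, traj, n_coils = 4, seed = 1)

# a 2.5-dwell dead time removes the innermost five oversampled samples
gapped <- apply_gap(scene$clean_kspace, traj, gap = 2.5)
print(gapped)
#> multi-coil k-space: 202 spokes x 64 samples x 4 coils; 5 unacquired samples/spoke

fit <- gap_infill(gapped, traj, gap = 2.5, method = "lowrank",
                  config = lowrank_config(kernel_width = 3, center_grid = 29,
                                          spoke_fraction = 0.45, lambda = 5,
                                          tol = 1e-3, max_iter = 150,
                                          cg_iter = 30))
print(summary(fit))
#> method 'lowrank': gap 2.50 dwells (5 samples/spoke)
#>   synthesized gap energy 3.531e+08 (95.156% of total k-space energy)
#>   iterations: 73 (converged)

truth <- Mod(image$values)
se_zero <- squared_error(truth, recon_rss(gapped, traj, c(64, 64)))
se_fill <- squared_error(truth, recon_rss(fit$kspace, traj, c(64, 64)))
cat(sprintf("squared error: zero-filled %.1f -> low-rank %.2f (%.0fx lower)\n",
            se_zero, se_fill, se_zero / se_fill))
#> squared error: zero-filled 504.7 -> low-rank 5.98 (84x lower)
```

The synthesized gap carries ~95 % of the total k-space energy — the whole
central lobe was missing — and restoring it reduces the image-domain squared
error 84-fold. `plot(fit)` shows the convergence trace (relative k-space
change and synthesized gap energy per sweep).

`monte_carlo_sweep()` runs the full gap × SNR × realization comparison of all
methods with identical noise per cell and bit-reproducible seeding, and
`inst/cli/ztegap.R` exposes simulate / infill / sweep subcommands for shell
use (`Rscript inst/cli/ztegap.R simulate --out ks.rds --n 64 --gap 2`).

The methods vignette (`vignettes/dead-time-gap-infilling.Rmd`) documents the
models, every tunable parameter with its default and rationale, the
numerical design choices, and what the synthetic studies do and do not show.

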