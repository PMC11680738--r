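---
title: "Filling the ZTE dead-time gap: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filling the ZTE dead-time gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Zero echo time (ZTE) imaging ramps the encoding gradient before excitation
and acquires the free induction decay immediately afterwards, tracing
center-out radial spokes through k-space. The RF pulse and
transmit/receive switching impose a dead time during which no samples can
be recorded, so the innermost samples of *every* spoke — the lowest spatial
frequencies, including the k-space origin — are missing. Expressed in
nominal Nyquist dwells, a gap of `g` dwells removes `ceiling(r * g)`
samples from an `r`-times oversampled readout: sample `m` of a spoke sits
at radius `(m / r) * dk` with sample 0 exactly at the origin, and every
sample inside the half-open interval `[0, g * dt)` is lost (a sample
landing exactly on the boundary is acquired). This counting rule is the
only one that reproduces both standard bandwidth settings at once: a
2.5-dwell gap loses 3 nominal / 5 oversampled samples, a 4.5-dwell gap 5 /
9. Zeroing the missing coefficients is equivalent to convolving the object
with a sinc, producing strong shading and contrast loss.

`ztegap` simulates such acquisitions end to end and fills the gap with five
methods, all sharing one contract: acquired samples are bit-identical
before and after infilling, only the Fourier coefficients inside the
dead-time gap are synthesized, and the acquisition mask keeps recording
what was actually measured.

## Shared physical priors

Two priors power every method here:

* **Readout oversampling (finite support).** With `r = 2`, the
  reconstructed 1D projection of a spoke (or spoke pair) spans twice the
  nominal FOV; the object occupies at most the central half, so the outer
  band of the projection must vanish. The missing samples are the
  low-frequency coefficients most responsible for violating that
  constraint.
* **Coil sensitivity diversity.** Multi-coil acquisitions sample the same
  object through smooth, spatially distinct receive profiles; local
  k-space neighborhoods across coils are therefore linearly dependent,
  which both kernel interpolation and low-rank models exploit.

## The five methods

* **Algebraic**: each diametric spoke pair forms one full line through the
  origin (`L = 2 * n_readout - 1` samples; the shared origin sample is
  used once). The gap unknowns minimize the out-of-band energy of the
  line's inverse DFT, solved per pair and coil by a small regularized
  least-squares system (Tikhonov, default `lambda = 1e-12`, or truncated
  SVD). The system's conditioning degrades rapidly with gap size — its
  condition number grows monotonically over `g = 1..4` — which is why this
  method fails beyond about three dwells.
* **Stoch–Olejniczak**: the single-spoke variant minimizes only the *real
  part* of the one-sided projection outside the band, assuming an
  essentially real projection. Two numerical details matter: the origin
  sample is the only self-conjugate term of a one-sided spectrum and must
  enter the inverse transform at half weight (otherwise the solver halves
  the DC), and each line is normalized by a global phase estimated from
  the acquired samples just outside the gap and rotated back afterwards,
  which makes the recovery exactly invariant under constant phase errors —
  the phase-immunity rationale of the method. Its blind spot is the
  imaginary component of the origin sample, which the objective never
  sees; regularization sends it to zero, correct only for near-real lines.
* **ZINFANDEL**: a GRAPPA-style 1D kernel (default length 5) is calibrated
  on the first 16 acquired readout samples of the 5 angularly nearest
  spokes and predicts each missing sample from the samples just outside
  it, one dwell at a time from the outside inward, recalibrating at every
  depth; previously synthesized samples serve as sources and calibration
  data for deeper positions (a flag disables this recursion in favor of
  shifted kernels that only read acquired data). Accuracy depends directly
  on the angular density of the trajectory: on a dense 3D acquisition the
  gap recovery is a few percent, on sparse desk-scale 2D trajectories it
  is several times coarser.
* **CG SENSE**: conjugate gradient on the Tikhonov normal equations of the
  multi-coil forward model with the gap excluded from the data term; the
  implicit fill is read out by resampling the reconstructed image at the
  gap coordinates so that the method can be compared sample-by-sample with
  the explicit ones. Plain CG converges very slowly on the gap modes (they
  are the smallest-singular-value directions); the iteration count and the
  Tikhonov weight jointly act as the effective regularizer, and the
  `lambda_rel` option expresses the weight relative to a probe-based
  estimate of the normal operator's scale so settings transfer across
  problem sizes. Density-compensation weighting (`dcf = TRUE`) helps
  well-conditioned reconstructions but down-weights exactly the
  center-adjacent samples that drive gap extrapolation, so the infill path
  defaults are chosen per use below.
* **Low-rank iterative infilling**: the package's core. The innermost
  `spoke_fraction` of every readout is regridded onto a small Cartesian
  center volume at nominal dwell spacing (side `center_grid`; `26` covers
  the default 20% fraction at a 128-class readout). All coils jointly feed
  one block-Hankel (C-matrix) lifting with an isotropic kernel (default
  `5`). Finite support makes this matrix low rank: band-limited
  annihilating filters vanish on the object, so every kernel-size
  neighborhood of k-space satisfies linear annihilation relations.
  Each sweep splits the lifted matrix's singular spectrum at 1.5% of the
  current largest singular value (hard thresholding; soft mode implements
  the nuclear-norm shrinkage weights instead) and then solves, by
  warm-started conjugate gradient over the cube, the quadratic
  `||W(degrid(u) - y_acq)||^2 + lambda * ||lift(u) P_null||^2`,
  where `P_null` projects onto the sub-threshold subspace; the synthesized
  gap values are read off the cube and the acquired samples re-imposed.
  Sweeps repeat until the relative Euclidean k-space change drops below
  `tol` (default `1e-6`) or `max_iter` is reached (flagged, not an
  error). Iterations-to-tolerance grow steeply with gap size, as the
  annihilation relations must be chained ever deeper into the hole.

### Why the low-rank solver is the least-squares form

The textbook projection-onto-convex-sets sweep — lift, threshold the
singular values, unlift, re-impose data — was implemented first and found
to stall on every desk-scale configuration we tried, including exact
Cartesian toy problems with machine-precision null spaces: hard
thresholding only moves the iterate when the corruption introduced by the
missing center falls *below* the threshold, and a fully missing k-space
center corrupts singular values comparable to the largest one. Solving the
thresholded subspace model as a regularized least-squares problem over the
whole center volume (the majorize–minimize treatment of the nuclear-norm
relaxation, with the SVT cut defining the null space each sweep) converges
decisively and keeps every ingredient of the method — lifting, SVT,
degridding, data consistency — in place. Three stabilizers matter:

* the quadratic is solved jointly over the cube, so the acquired
  coefficients anchor the annihilation extrapolation (hard substitution of
  the gap alone diverges at larger problem sizes);
* cube corners beyond the covered readout radius carry no data and are
  held near zero by a data-scaled ridge, otherwise the annihilation term
  drifts them freely;
* `lambda` (default 20 in the configuration object; the desk-scale
  studies below use 2–5) is normalized by probing both operators on a
  random volume, making it a dimensionless balance between data fit and
  subspace consistency.

## Simulation machinery

* **NUFFT.** No non-uniform FFT was available in this stack, so the
  package implements Kaiser–Bessel gridding (2x oversampled FFT grid,
  tabulated kernels in C++, Beatty beta, closed-form apodization). Width 6
  gives ~1e-5 relative accuracy, width 4 ~1e-3, width 2 ~1e-2; forward and
  adjoint are exact adjoints by construction, and a dense "exact" mode
  serves as the oracle on small problems. The CG inverse accepts
  per-sample least-squares weights; shell-volume density compensation
  (`radial_dcf`) or Pipe–Menon fixed-point weights (`pipe_menon_dcf`,
  gain-calibrated on a Gaussian reference) make center-out radial normal
  equations well conditioned.
* **Phantoms.** The 2D two-disc phantom (256^2, radii 80/40) reproduces
  the classic demonstration geometry. The 3D "brain-like" phantom is a
  seeded stack of nested smooth ellipsoids confined to the central half of
  the FOV, standing in for an external digital brain volume; it shares the
  support-in-half-FOV property the finite-support prior relies on but none
  of a real brain's texture, so passing tests demonstrate method behavior,
  not clinical image quality.
* **Coil maps.** Surface-coil-like Lorentzian profiles centered on the FOV
  boundary with random linear phases, spectrally clipped to the central
  half-band and jointly normalized to unit root-sum-of-squares (the
  clip/normalize pair is alternated so both properties hold to <1%).
  Reconstruction uses these ground-truth maps — map estimation is out of
  scope — which flatters CG SENSE relative to an in vivo setting where
  maps must be estimated.
* **Noise.** Complex white Gaussian noise is drawn over every sample and
  coil and scaled so that the image-domain SNR definition — signal energy
  over the energy of the grid-normalized adjoint transform of the pure
  noise realization — hits the requested level exactly for that
  realization (the scaling is linear in sigma, so the calibration solves
  in one step). One seed per (gap, SNR, realization) cell derives from a
  single base seed through a fixed counter scheme; the identical
  realization is reused across methods. Noise is added before gap masking;
  the two orders are equivalent because gap samples are never read.

## Problem sizes and study conditions

The package's own studies (tests and the acceptance script) run at desk
scale, chosen to preserve the geometry of the reference conditions:

* noiseless 2D: 256^2 disc phantom, 402 paired spokes, 256-sample
  twice-oversampled readouts, 4 coils, gap 2 — the center volume is 51
  Cartesian dwells wide (20% of the readout), kernel 5;
* 3D Monte Carlo: 32^3 phantom, 3018 bidirectional phyllotaxis spokes,
  4 coils, 10 dB, gaps 3 and 4, five noise realizations — the center
  volume is 17 dwells (56% of the 32-sample readout) with kernel 3, which
  keeps the cube-to-gap ratio and the lifting's row/column
  overdetermination close to the 128-class geometry that a 26-cube / 20%
  fraction / kernel-5 configuration implies;
* convergence: 48^2, gaps 1–3, tolerance 1e-3 on the relative k-space
  change (the default 1e-6 is reached only asymptotically by the
  least-squares sweeps; the looser tolerance preserves the ordering being
  measured).

## Known limitations

* At the 32^3 desk scale with ground-truth maps, CG SENSE is near-oracle:
  at gap 4 it outperforms the low-rank method (which stays within ~2x and
  dominates every explicit method at all gaps). The strict ordering
  low-rank <= CG SENSE holds at gap 3 but not at gap 4 under these
  conditions; larger volumes make the missing center a relatively smaller
  unknown and favor the low-rank method further.
* The Stoch–Olejniczak method is accurate only for near-real projections;
  with complex coil phases its k-space recovery is coarse even though the
  image-domain error still improves several-fold over zero-filling.
* The adjoint-gridding mode of `regrid_center` is retained for
  completeness; the low-rank sweep uses the consistent CG inversion
  throughout.
* Half-integer gaps are realized purely through the sample-counting rule;
  no sub-dwell timing offsets are modeled, and no hardware timing,
  relaxation or off-resonance physics enters the simulation.
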