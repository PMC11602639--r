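---
title: "Rigid registration and motion quantification for 3D fat navigators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid registration and motion quantification for 3D fat navigators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatnavr)
```

## Background

Prospective motion correction updates the scanner's acquisition coordinate
frame *during* a scan, so that data acquired after a head movement are still
sampled in the head's frame of reference. Fat navigators (FatNavs) make this
practical at high field: a fat-selective excitation produces a rapid,
low-resolution 3D image in which essentially all signal comes from the
subcutaneous scalp fat — a bright shell on a dark background — while leaving
the water magnetisation used by the host sequence undisturbed. Embedding one
navigator per host measurement (every N × TR) and registering each navigator
to the first yields a stream of rigid-body pose estimates that drive frame
updates.

`fatnavr` implements the offline machinery of such a pipeline: the phantom
and benchmark generator, the similarity metrics, the registration algorithm,
the motion-score metrics, image-sharpness quantification, and a
measurement-level simulator of the correction loop.

## The registration model

Head motion is modelled as a 6-parameter rigid-body transform: rotations
about the Z, then Y, then X axis (degrees, counterclockwise positive) and a
translation in mm, applied translate-then-rotate about the volume centre.
Acting on a point $p$ relative to the centre $c$:

$$ M(p) = R\,(p - c + t) + c, \qquad R = R_x R_y R_z. $$

Because the parameters are centre-relative, composition and inversion reduce
to closed forms that do not involve the centre coordinates:
$\mathrm{compose}(a, b) = (R_a R_b,\; t_b + R_b^{\top} t_a)$ and
$\mathrm{invert}(t) = (R^{\top}, -R\,t)$. Both are exact; `compose(t,
invert(t))` is the identity to machine precision.

The registration cost is the concordance correlation coefficient (CCC)

$$ \rho_C = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2}, $$

with population ($1/n$) variance and covariance normalisation. Unlike the
Pearson correlation, $\rho_C$ penalises mean and variance disagreement, and
unlike RMSE it is bounded and contrast-calibrated; on navigator data its
profile around the optimum is single-peaked where SSIM shows many local
extrema (compare `metric_profile()` curves and `count_local_maxima()`).
SSIM is provided in the standard Wang et al. form — Gaussian window of 11
samples with $\sigma = 1.5$ voxels, border-clipped and renormalised,
$C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, $C_3 = C_2/2$, mean aggregation — with
the dynamic range $L$ taken from the first (reference) image; that choice is
the metric's one asymmetry and is documented rather than hidden.

### The search

`register_rigid()` mirrors a scanner-integrated design that favours
determinism and bounded runtime over generic optimisation:

1. **Sub-volume selection.** The fixed volume is partitioned into cubic
   blocks (16 voxels edge by default) and the 8 brightest-mean blocks are
   kept. On a fat navigator these land on the scalp shell, where all
   registration-relevant signal lives. An empty volume falls back to
   whole-volume registration with a warning.
2. **Centroid initialisation.** The translation starts at the difference of
   intensity centroids, clipped to the search bounds.
3. **Joint rotation seed.** On a near-spherical head the three rotation
   parameters couple: the 1-D profile of any single angle, with the others
   wrong, is shallow and often peaks near zero. Before the per-axis
   refinement (and again at the start of the second pass) a coarse 3-D
   sweep over rotation combinations (±8° in 4° steps around the current
   estimate by default) therefore picks the basin to refine.
4. **Sequential per-axis grid search.** Each parameter in turn (tx, ty, tz,
   then rz, ry, rx) is refined by a coarse 1-D grid (2 mm / 2°) followed by
   a fine grid (0.25 mm / 0.25°) around the coarse optimum, evaluating CCC
   over the sub-volumes with trilinear interpolation. The first pass scans
   the full bound (±25 mm, ±20°); later passes search locally around the
   current estimate. Up to 3 passes are run; convergence is declared when no
   parameter moves by more than the fine step (0.25 mm / 0.25°) in a pass —
   a grid search quantised to the fine step cannot improve below that
   resolution, so a tighter tolerance would only misreport convergence.
5. **Simplex polish.** Axis-by-axis moves cannot follow the oblique valleys
   of the cost surface, and a false joint optimum (good translations
   compensating wrong rotations) can trap the grid stage with a similarity
   only a little below the true optimum. A bounded Nelder–Mead refinement
   from the grid result makes the missing coordinated moves; it is kept
   only if it improves the metric, so the result never regresses.
6. **Tie-breaking.** Grid ties go to the smaller parameter magnitude and
   every stage is deterministic, so results are bit-reproducible.

Interpolation during the search is trilinear for speed; synthetic data
generation uses cubic. The asymmetry is deliberate and mirrors the
constraint that online registration must be cheap while offline simulation
should be accurate.

The sequential search is a coordinate descent on a non-separable objective:
it is accurate in a limited range of motion (the regime prospective
correction operates in, since residual motion between consecutive updates is
small) and is permitted to fail for large oblique rotations. Failure is
surfaced, not hidden: a result whose final CCC falls below `metric_floor`
(0.5 by default) is flagged `converged = FALSE`. `register_oracle()`
provides an exhaustive 6-D grid evaluation (capped at $10^7$ points) as an
independent check on small volumes.

## Motion scores

A rigid transform is summarised by the Tisdall-style motion score

$$ \text{score} = \Delta R + \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}, $$

where $\Delta R$ is the worst-case displacement of a point on a 64 mm-radius
sphere (a proxy for the head) under the rotation. For a rotation of total
angle $\theta$ this maximum is exactly $2 r \sin(\theta/2)$, attained on the
great circle perpendicular to the rotation axis; the closed form is verified
against brute-force maximisation over sampled sphere points in the tests.
Registration error against a known ground truth is the **residual motion
score**: the motion score of $T_d \cdot T_{gt}^{-1}$, which is zero exactly
when the detected transform equals the truth. The sphere is centred at the
rotation centre (the volume centre); translations enter through the norm of
the transform's translation parameters, which is invariant to the rotation
convention since $\lVert R t \rVert = \lVert t \rVert$.

## The synthetic benchmark

Real navigator volumes cannot ship with the package, so the generator
substitutes a digital phantom that captures the feature registration
actually uses: a bright ellipsoidal shell (scalp fat) with three asymmetric
blobs (facial fat pads, breaking rotational symmetry) on a dark background,
plus rectified Gaussian noise emulating a magnitude reconstruction. Defaults
follow the 2 mm isotropic whole-head protocol: 128 × 128 × 88 matrix over a
256 × 256 × 176 mm field of view, shell intensity 100, noise SD 5 (an SNR of
20 relative to the shell, typical of an accelerated navigator).

The benchmark protocol draws, for each motion range ±5, ±10 and ±15
degrees/voxels, uniformly random transforms — three angles in ±range
degrees, three translations in ±range voxels converted to mm, drawn
independently per axis and applied simultaneously — and applies them in
image space: translation first, then rotations about Z, Y, X with cubic
(Keys) interpolation, output cropped to the input grid, and voxels exposed
at the edges filled with noise matched to the background of the reference
(mean and SD outside an Otsu-derived, one-voxel-dilated head mask). The
default protocol of 33 volumes × 10 transforms yields 330 pairs per range.
One top-level seed derives per-pair substreams, so any single pair is
reproducible in isolation from its recorded seed.

What the phantom does *not* emulate: reconstruction artefacts from
undersampling, fat-excitation physics, B0-induced distortion, and the
anatomical variability of real heads. Passing the recovery tests therefore
demonstrates the correctness and precision of the search on well-posed
navigator-like inputs, not robustness to all in vivo image quality.

## Sharpness metrics

Correction quality on summed images is quantified two ways:

- **Variance of the Laplacian**: the 5-point stencil
  $[[0,1,0],[1,-4,1],[0,1,0]]$ applied per slice over the interior (valid)
  region, then the variance of the response. Constant and affine images give
  exactly 0; the measure is offset-invariant, scales with the square of an
  intensity scaling, and decreases monotonically under Gaussian blur. Since
  its absolute value depends on image content, the corrected/uncorrected
  *ratio* is reported. Severe artefacts can inflate the variance — the
  package asserts blur monotonicity only. Per-slice evaluation is the
  default (host images are multi-slice); a 3D 7-point variant is provided.
- **Edge-profile width**: on a 1D profile across a dark band (such as the
  cerebral falx), each flank of the dip is normalised between its local
  plateau (100%) and the dip minimum (0%), and the distance between the 75%
  and 25% crossings is found by linear interpolation between samples. The
  steeper flank is reported by default. A monotone profile is treated as a
  single edge — for a sigmoid $1/(1+e^{-x/s})$ the width is exactly
  $2 s \ln 3$, which the tests verify by dense sampling.

## The prospective-loop simulator

`simulate_acquisition()` plays a pose trace through the correction loop at
the measurement level. Motion is piecewise constant between measurements
(matching the instruction given to volunteers to re-pose between navigators
and hold still otherwise); intra-measurement motion and k-space effects are
out of scope, because the evaluation level — summed measurements and their
sharpness — operates on images. For each measurement the navigator is the
phantom resampled at its apparent pose in the current acquisition frame
(plus seeded rectified Gaussian noise), registered to the first navigator;
the detected transform is composed into the frame before the next corrected
measurement. Update latency below one measurement is not modelled and is
exposed as an informational protocol field. Three policies are supported:
correct every measurement, the alternating paradigm (odd measurements
corrected, even acquired in the original frame — the scheme used to compare
corrected and uncorrected images under one motion pattern), and no updates.

Timing identities follow directly from the protocol: updates every
$N \times TR$ (43.008 s for N = 256, TR = 168 ms; 167.424 s for N = 192,
TR = 872 ms — displayed rounded to whole seconds) and an added scan time of
one navigator per measurement (7 × 1.23 s = 8.61 s; 5 × 1.23 s = 6.15 s).

## Numerical choices and degenerate inputs

- Resampled intensities are clamped at zero: the carrier is a magnitude
  image, and the clamp keeps the non-negativity invariant despite the small
  negative ringing cubic interpolation can introduce at sharp edges.
- Points sampled outside the source grid are filled (noise or constant);
  inside the grid, cubic interpolation replicates edge voxels.
- CCC errors on jointly constant, equal-mean inputs (zero denominator);
  registration refuses constant images outright.
- The Euler-angle extraction used by `compose()`/`invert()` is exact away
  from the ±90° pitch lock; at the lock the Z/X split is not unique and the
  convention puts the whole in-plane rotation into X. Head motion never
  approaches this regime.
- All stochastic components (phantom noise, transform draws, background
  fill, navigator noise) run off explicit seeds; identical seeds give
  bit-identical outputs.

## Problem sizes used by the test-suite and acceptance script

The package's own verification uses scaled problem sizes chosen to exercise
every code path at full fidelity: 64³-voxel, 2 mm phantoms (50 noiseless
±5-range pairs) for parameter recovery, where ≥ 90% of pairs must reach a
residual motion score below 2 mm (one voxel); 16³ volumes for exhaustive
oracle comparisons; 48³ phantoms, 5 measurements and 10 seeds for the
simulator, where the median corrected/uncorrected sharpness ratio must
exceed 1 and a perfect-pose oracle must recover the zero-motion sum within
2% mean absolute error. The dataset-protocol count (330 pairs per range from
33 × 10) is exercised at 16³ resolution, since the count is
resolution-independent while 330 full-resolution volumes would be needlessly
heavy for a correctness check.

## A worked example

```{r example, eval = FALSE}
library(fatnavr)

# a 2 mm navigator-like phantom and a known motion
ref <- generate_phantom(phantom_spec(shape = c(64, 64, 64), spacing = 2,
                                     noise_sd = 0, seed = 1))
truth <- rigid_transform(rot_deg = c(3, -2, 1), trans_mm = c(4, -6, 2))
mov <- apply_rigid_transform(ref, truth)

res <- register_rigid(ref, mov)
res$transform
residual_motion_score(res$transform, truth) # mm; < 2 mm is sub-voxel
motion_score(truth)$score                   # severity of the motion itself
```

## Known limitations

- The phantom is a geometric stand-in; absolute benchmark numbers (times,
  residual scores) characterise this implementation on phantoms, not any
  scanner implementation on in vivo navigators.
- The sequential-axis search can miss large combined rotations (±15-range
  benchmarks exercise this deliberately); such results are reported with
  `converged = FALSE` rather than suppressed.
- SSIM and RMSE are provided for metric comparison; only CCC is tuned for
  driving the registration.
- The simulator is image-space only: ghosting, steady-state disturbance and
  k-space-segment-level update timing are outside its scope.
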