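# fatnavr

Rigid registration and motion quantification for 3D fat-navigator (FatNav)
MRI.

Prospective motion correction steers the scanner's acquisition frame during
a brain scan so that data collected after a head movement are still sampled
in the head's frame. Fat navigators make the pose measurement cheap: a
fat-selective excitation yields a rapid, low-resolution 3D image whose
signal is confined to the bright subcutaneous scalp fat, acquired once per
host measurement (every N × TR) without disturbing the water signal.
`fatnavr` provides the offline machinery of such a pipeline for method
developers and evaluators:

- **Registration** (`register_rigid()`): a deterministic rigid 3D algorithm
  that selects bright sub-volumes, initialises the translation from
  intensity centroids, seeds the rotations with a joint coarse sweep, and
  refines each parameter in turn by coarse-then-fine 1-D grid searches,
  maximising the concordance correlation coefficient

  ρ_C = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²),

  with SSIM and RMSE available for comparison (`ccc()`, `ssim()`, `rmse()`,
  `metric_profile()`), and an exhaustive-grid oracle (`register_oracle()`)
  for verification.
- **Transform algebra and motion scores** (`rigid_transform()`, `compose()`,
  `invert()`): 6-parameter rigid motions (Z/Y/X rotations in degrees,
  translations in mm, about the volume centre), with the motion score
  ΔR + √(Δx² + Δy² + Δz²), where ΔR = 2·r·sin(θ/2) is the worst-case
  displacement on a 64 mm-radius sphere, and the residual motion score of
  T_d · T_gt⁻¹ as registration error (`motion_score()`,
  `residual_motion_score()`).
- **Synthetic benchmark** (`generate_phantom()`, `make_synthetic_dataset()`):
  FatNav-like shell phantoms subjected to uniformly random rigid transforms
  in ±5 / ±10 / ±15 degrees/voxels ranges (33 volumes × 10 transforms = 330
  pairs per range by default), with exact ground truth, NIfTI/JSON/CSV
  export, and benchmarking (`benchmark_registration()`,
  `run_synthetic_benchmark()`, `run_resolution_study()`).
- **Sharpness metrics** (`variance_of_laplacian()`, `sharpness_ratio()`,
  `profile_edge_width()`): Laplacian-variance sharpness and its
  corrected/uncorrected ratio, and the 75%→25% edge-profile width in mm.
- **Prospective-loop simulator** (`simulate_acquisition()`): a moving
  phantom, one navigator per measurement, frame updates from detected
  transforms, the alternating corrected/uncorrected measurement paradigm,
  and navigator timing (`navigator_update_interval()`, `added_scan_time()`).

Volumes are read and written as NIfTI-1 (via RNifti), transforms as JSON,
protocols as YAML/JSON, results as CSV/JSON.

## Worked example

```r
library(fatnavr)

# a 2 mm navigator-like phantom and a known rigid motion
ref   <- generate_phantom(phantom_spec(shape = c(64, 64, 64), spacing = 2,
                                       noise_sd = 0, seed = 1))
truth <- rigid_transform(rot_deg = c(3, -2, 1), trans_mm = c(4, -6, 2))
mov   <- apply_rigid_transform(ref, truth)

motion_score(truth)
#> motion score 11.646 mm (deltaR 4.163 + |t| 7.483)

res <- register_rigid(ref, mov)
res$transform
#> <rigid_transform> rot ZYX = (3.4000, -1.5143, 0.8931) deg, trans = (3.981, -5.997, 2.020) mm, center = volume_center

residual_motion_score(res$transform, truth)
#> [1] 0.7426865
```

The motion score says the injected movement would displace a point on a
64 mm head sphere by up to ~11.6 mm; registration recovers the transform
with a residual error of ~0.74 mm — well below the 2 mm voxel.

## Documentation

The methods vignette (`vignettes/fatnav-motion-correction.Rmd`) describes
the registration model and its assumptions, what the phantom generator does
and does not emulate, the numerical choices, and known limitations.
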