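# Synthetic registration benchmark: ground-truthed pairs of navigator-like
# phantoms under uniformly random rigid transforms, following the protocol of
# the prospective-FatNav validation study (33 source volumes x 10 random
# transforms per motion range; ranges +/-5, +/-10, +/-15 degrees/voxels with
# rotations and translations drawn simultaneously).

#' Draw a uniformly random rigid transform in a degrees/voxels range
#'
#' Each of the three rotation angles is drawn from Uniform(-range, range)
#' degrees and each translation from Uniform(-range, range) *voxels*,
#' converted to mm with the per-axis voxel spacing. Uses R's RNG stream, so
#' wrap in `set.seed()`/`withr::with_seed()` for reproducibility.
#'
#' @param range_deg_vox half-width of the motion range in degrees/voxels
#'   (> 0); the study protocol uses 5, 10 and 15.
#' @param spacing voxel size in mm (scalar or length 3).
#' @return A [rigid_transform()].
#' @export
sample_random_transform <- function(range_deg_vox, spacing = c(2, 2, 2)) {
  if (!is.numeric(range_deg_vox) || length(range_deg_vox) != 1L ||
      range_deg_vox <= 0)
    stop("`range_deg_vox` must be a positive scalar")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  rot <- runif(3, -range_deg_vox, range_deg_vox)
  trans_vox <- runif(3, -range_deg_vox, range_deg_vox)
  rigid_transform(rot, trans_vox * spacing)
}

#' A ground-truthed synthetic registration pair
#'
#' @param reference,moved [volume3d()] objects of identical shape/spacing.
#' @param ground_truth the [rigid_transform()] that produced `moved` from
#'   `reference`.
#' @param range_label the motion-range label (degrees/voxels half-width).
#' @param pair_id identifier string.
#' @param seed the per-pair RNG seed used to draw the transform and noise.
#' @return A list of class `synthetic_pair`.
#' @export
synthetic_pair <- function(reference, moved, ground_truth, range_label,
                           pair_id = NA_character_, seed = NA_integer_) {
  stopifnot(is_volume3d(reference), is_volume3d(moved),
            inherits(ground_truth, "rigid_transform"))
  if (!identical(reference$shape, moved$shape) ||
      !isTRUE(all.equal(reference$spacing, moved$spacing)))
    stop("`moved` must match the shape and spacing of `reference`")
  structure(list(reference = reference, moved = moved,
                 ground_truth = ground_truth, range_label = range_label,
                 pair_id = pair_id, seed = seed),
            class = "synthetic_pair")
}

# per-pair substream seeds derived once from the top-level seed, so any single
# pair is reproducible in isolation from its recorded seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a ground-truthed synthetic registration dataset
#'
#' For each motion range, draws `n_transforms_per_volume` uniformly random
#' rigid transforms for each of `n_volumes` phantom volumes and applies them
#' in image space (translation, then Z/Y/X rotations, cubic interpolation),
#' filling exposed voxels with noise matched to the reference background. The
#' untransformed phantom is the reference of every pair. The study protocol —
#' 33 volumes x 10 transforms — yields 330 pairs per range.
#'
#' @param n_volumes number of distinct phantom volumes (>= 1).
#' @param n_transforms_per_volume random transforms per volume (>= 1).
#' @param ranges motion-range half-widths in degrees/voxels.
#' @param base_specs optional list of [phantom_spec()]s, recycled over
#'   volumes; by default phantoms vary slightly in shell geometry and noise
#'   seed across volumes.
#' @param seed top-level seed; per-pair substreams are derived from it.
#' @param out_dir optional directory: volumes are written as NIfTI, transforms
#'   as JSON, plus a `manifest.csv` (columns `pair_id`, `range_label`,
#'   `reference_path`, `moved_path`, `transform_path`, `seed`).
#' @return A list of [synthetic_pair()]s with attribute `manifest` (data
#'   frame).
#' @export
make_synthetic_dataset <- function(n_volumes = 33L,
                                   n_transforms_per_volume = 10L,
                                   ranges = c(5, 10, 15),
                                   base_specs = NULL,
                                   seed = 1L,
                                   out_dir = NULL) {
  n_volumes <- as.integer(n_volumes)
  n_transforms_per_volume <- as.integer(n_transforms_per_volume)
  if (n_volumes < 1L || n_transforms_per_volume < 1L)
    stop("`n_volumes` and `n_transforms_per_volume` must be >= 1")
  if (length(ranges) < 1L || any(ranges <= 0))
    stop("`ranges` must be positive")
  if (is.null(base_specs)) {
    vol_seeds <- derive_seeds(seed + 1L, n_volumes)
    base_specs <- lapply(seq_len(n_volumes), function(v) {
      sp <- phantom_spec(seed = vol_seeds[v])
      scale <- 0.92 + 0.16 * ((v - 1) %% 7) / 6 # per-subject head size
      sp$outer_semiaxes_mm <- sp$outer_semiaxes_mm * scale
      sp$inner_semiaxes_mm <- sp$inner_semiaxes_mm * scale
      sp
    })
  }
  n_pairs <- n_volumes * n_transforms_per_volume * length(ranges)
  pair_seeds <- derive_seeds(seed, n_pairs)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pairs <- vector("list", n_pairs)
  manifest <- vector("list", n_pairs)
  idx <- 0L
  for (ri in seq_along(ranges)) {
    rng <- ranges[ri]
    for (v in seq_len(n_volumes)) {
      spec <- base_specs[[((v - 1L) %% length(base_specs)) + 1L]]
      ref <- generate_phantom(spec)
      bg <- if (spec$noise_sd > 0) estimate_background_stats(ref)
            else list(mean = 0, sd = 0)
      ref_path <- NA_character_
      if (!is.null(out_dir)) {
        ref_path <- file.path(out_dir, sprintf("vol%03d_ref.nii.gz", v))
        if (ri == 1L) write_volume(ref, ref_path)
      }
      for (k in seq_len(n_transforms_per_volume)) {
        idx <- idx + 1L
        pid <- sprintf("r%g_v%03d_t%02d", rng, v, k)
        pr <- withr::with_seed(pair_seeds[idx], {
          gt <- sample_random_transform(rng, spec$spacing)
          moved <- apply_rigid_transform(ref, gt, bg$mean, bg$sd)
          list(gt = gt, moved = moved)
        })
        pairs[[idx]] <- synthetic_pair(ref, pr$moved, pr$gt, rng, pid,
                                       pair_seeds[idx])
        mov_path <- tr_path <- NA_character_
        if (!is.null(out_dir)) {
          mov_path <- file.path(out_dir, paste0(pid, "_moved.nii.gz"))
          tr_path <- file.path(out_dir, paste0(pid, "_gt.json"))
          write_volume(pr$moved, mov_path)
          write_transform(pr$gt, tr_path)
        }
        manifest[[idx]] <- data.frame(
          pair_id = pid, range_label = rng, reference_path = ref_path,
          moved_path = mov_path, transform_path = tr_path,
          seed = pair_seeds[idx])
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(pairs, manifest = manifest)
}
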