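# Sub-volume CCC registration: sub-volume selection, parameter recovery
# against known ground truth, and agreement with the exhaustive-grid oracle.

test_that("sub-volume selection targets the bright shell", {
  v <- tiny_phantom(c(32, 32, 32), noise_sd = 0)
  cfg <- registration_config(n_subvolumes = 8L, subvolume_edge = 8L)
  boxes <- select_subvolumes(v, cfg)
  expect_equal(nrow(boxes), 8)
  shell <- v$data > 0
  for (r in seq_len(nrow(boxes))) {
    blk <- v$data[(boxes[r, 1]:boxes[r, 2]) + 1,
                  (boxes[r, 3]:boxes[r, 4]) + 1,
                  (boxes[r, 5]:boxes[r, 6]) + 1]
    expect_gt(sum(blk > 0), 0) # every box intersects the shell
  }
  # a single bright blob attracts the single box
  a <- array(0, c(16, 16, 16)); a[9:12, 9:12, 9:12] <- 50
  b1 <- select_subvolumes(volume3d(a, 2),
                          registration_config(n_subvolumes = 1L,
                                              subvolume_edge = 4L))
  expect_true(b1[1, 1] >= 4 && b1[1, 2] <= 13)
  # degenerate volume falls back to the whole grid with a warning
  expect_warning(
    bz <- select_subvolumes(volume3d(array(0, c(8, 8, 8)), 1),
                            registration_config(subvolume_edge = 4L)),
    "falling back")
  expect_equal(nrow(bz), 1)
  expect_equal(bz[1, ], c(0L, 7L, 0L, 7L, 0L, 7L), ignore_attr = TRUE)
})

test_that("self-registration returns the identity", {
  v <- tiny_phantom(c(32, 32, 32), noise_sd = 0)
  res <- register_rigid(v, v, registration_config(subvolume_edge = 8L))
  expect_lt(motion_score(res$transform)$score, 0.5)
  expect_true(res$converged)
  expect_equal(res$final_metric, 1, tolerance = 1e-6)
})

test_that("known translations and rotations are recovered", {
  v <- generate_phantom(phantom_spec(shape = c(64, 64, 64), spacing = 2,
                                     noise_sd = 0, seed = 1))
  gt_t <- rigid_transform(trans_mm = c(4, -6, 2))
  res_t <- register_rigid(v, apply_rigid_transform(v, gt_t))
  expect_true(all(abs(res_t$transform$trans_mm - gt_t$trans_mm) < 1)) # 0.5 vox
  expect_lt(residual_motion_score(res_t$transform, gt_t), 2)

  gt_r <- rigid_transform(c(5, 0, 0))
  res_r <- register_rigid(v, apply_rigid_transform(v, gt_r))
  expect_lt(abs(res_r$transform$rot_deg[1] - 5), 0.5)
  expect_lt(residual_motion_score(res_r$transform, gt_r), 2)
})

test_that("final metric is consistent with the returned transform", {
  v <- tiny_phantom(c(32, 32, 32), noise_sd = 0)
  mv <- apply_rigid_transform(v, rigid_transform(c(2, 0, 0), c(2, 0, 0)))
  cfg <- registration_config(subvolume_edge = 8L)
  res <- register_rigid(v, mv, cfg)
  boxes <- select_subvolumes(v, cfg)
  fvals <- fatnavr:::box_values(v, boxes)
  mvals <- fatnavr:::sample_moving_boxes(mv, res$transform, boxes)
  expect_equal(res$final_metric, ccc(fvals, mvals), tolerance = 1e-9)
  # returned parameters lie within the configured bounds
  expect_true(all(abs(res$transform$trans_mm) <= cfg$trans_bound_mm))
  expect_true(all(abs(res$transform$rot_deg) <= cfg$rot_bound_deg))
})

test_that("degenerate inputs are rejected", {
  z <- volume3d(array(1, c(8, 8, 8)), 2)
  v <- tiny_phantom(c(8, 8, 8))
  expect_error(register_rigid(z, v), "degenerate")
  expect_error(register_rigid(v, tiny_phantom(c(10, 10, 10))), "shape")
})

test_that("oracle recovers on-grid shifts exactly and register agrees", {
  v <- tiny_phantom(c(16, 16, 16), noise_sd = 0)
  gt <- rigid_transform(trans_mm = c(4, -2, 0)) # on a 2 mm grid
  mv <- apply_rigid_transform(v, gt)
  grid <- list(tx = seq(-6, 6, 2), ty = seq(-6, 6, 2), tz = seq(-6, 6, 2))
  orc <- register_oracle(v, mv, grid)
  expect_equal(orc$transform$trans_mm, gt$trans_mm)
  reg <- register_rigid(v, mv, registration_config(subvolume_edge = 8L))
  expect_equal(round(reg$transform$trans_mm / 2) * 2, orc$transform$trans_mm)
  # refusal on oversized or empty grids
  expect_error(register_oracle(v, mv, list(tx = 1:500, ty = 1:500,
                                           tz = 1:100)), "too large")
  expect_error(register_oracle(v, mv, list()), "non-empty")
  expect_error(register_oracle(v, mv, list(tx = numeric(0))), "empty")
})

test_that("oracle ties break toward the smaller parameter magnitude", {
  v <- tiny_phantom(c(12, 12, 12), noise_sd = 0)
  # every candidate shifts the moving image fully off-grid, so all scores tie
  # at zero; the deterministic winner is the smallest-magnitude (negative
  # first) candidate
  orc <- register_oracle(v, v, list(tx = c(-40, -35, 35, 40)))
  expect_equal(orc$transform$trans_mm, c(-35, 0, 0))
})

test_that("benchmark reports per-pair rows and per-method summaries", {
  specs <- list(phantom_spec(shape = c(24, 24, 24), spacing = 2, noise_sd = 0))
  ds <- make_synthetic_dataset(2, 3, ranges = 5, base_specs = specs, seed = 4)
  cfg <- registration_config(subvolume_edge = 8L)
  out <- benchmark_registration(ds, list(ccc = cfg))
  expect_equal(nrow(out$results), 6)
  expect_equal(nrow(out$summary), 1)
  expect_named(out$results,
               c("pair_id", "method", "range_label",
                 "residual_motion_score_mm", "elapsed_s", "final_metric",
                 "converged", "error"))
  # registration reduces motion: mean residual < mean ground-truth score
  gt_scores <- vapply(ds, function(p) motion_score(p$ground_truth)$score,
                      numeric(1))
  expect_lt(out$summary$mean_residual_motion_score_mm, mean(gt_scores))
})
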