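# Prospective correction loop: timing identities, measurement combination,
# and end-to-end correction behaviour.

t1_protocol <- function(n = 5, policy = "every_measurement")
  acquisition_protocol(tr_ms = 168, n_kspace_lines = 256, n_measurements = n,
                       nav_duration_s = 1.23, update_policy = policy)

test_that("navigator timing identities reproduce the protocol numbers", {
  t1 <- acquisition_protocol(168, 256, 7, 1.23)
  t2s <- acquisition_protocol(872, 192, 5, 1.23)
  expect_equal(navigator_update_interval(t1), 43.008)
  expect_equal(format_seconds(navigator_update_interval(t1)), 43)
  expect_equal(navigator_update_interval(t2s), 167.424)
  expect_equal(format_seconds(navigator_update_interval(t2s)), 167)
  expect_equal(added_scan_time(t1), 8.61)
  expect_equal(added_scan_time(t2s), 6.15)
  expect_equal(navigator_update_interval(
    acquisition_protocol(1000, 1, 1, 0)), 1)
  expect_equal(added_scan_time(acquisition_protocol(1000, 1, 3, 0)), 0)
  expect_error(acquisition_protocol(-1, 256, 7), "positive")
  expect_error(acquisition_protocol(168, 256, 0), "n_measurements")
})

test_that("protocols round-trip through YAML and JSON", {
  p <- t1_protocol(7, "every_other_measurement")
  fy <- tempfile(fileext = ".yaml"); fj <- tempfile(fileext = ".json")
  write_protocol(p, fy); write_protocol(p, fj)
  expect_equal(unclass(read_protocol(fy)), unclass(p))
  expect_equal(unclass(read_protocol(fj)), unclass(p))
  unlink(c(fy, fj))
})

test_that("measurement combination follows the odd/even-plus-reference scheme", {
  meas <- lapply(1:7, function(i) volume3d(array(i, c(4, 4, 2)), 1))
  odd <- combine_measurements(meas, "odd_plus_ref")
  expect_equal(odd$data[1, 1, 1], 1 + 3 + 5 + 7)
  even <- combine_measurements(meas, "even_plus_ref")
  expect_equal(even$data[1, 1, 1], 1 + 2 + 4 + 6)
  all7 <- combine_measurements(meas, "all")
  expect_equal(all7$data[1, 1, 1], sum(1:7))
  # sum(all) = sum(odd_plus_ref) + sum(even_plus_ref) - reference
  expect_equal(all7$data, odd$data + even$data - meas[[1]]$data)
  one <- combine_measurements(meas[1], "odd_plus_ref")
  expect_equal(one$data, meas[[1]]$data)
  expect_error(combine_measurements(list()), "non-empty")
  bad <- list(meas[[1]], volume3d(array(0, c(3, 3, 3)), 1))
  expect_error(combine_measurements(bad, "all"), "mismatch")
})

test_that("motion traces construct and round-trip as JSON", {
  tr <- step_motion_trace(5, change_at = 3,
                          pose = rigid_transform(c(2, 0, 0), c(5, 0, 0)))
  expect_equal(tr$n, 5)
  expect_equal(tr$poses[[2]]$trans_mm, c(0, 0, 0))
  expect_equal(tr$poses[[3]]$trans_mm, c(5, 0, 0))
  f <- tempfile(fileext = ".json")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$n, 5)
  for (i in 1:5) {
    expect_equal(tr2$poses[[i]]$rot_deg, tr$poses[[i]]$rot_deg)
    expect_equal(tr2$poses[[i]]$trans_mm, tr$poses[[i]]$trans_mm)
  }
  unlink(f)
})

test_that("zero motion gives identical sums and zero scores", {
  ph <- tiny_phantom(c(32, 32, 32), noise_sd = 0)
  still <- motion_trace(replicate(3, rigid_transform(), simplify = FALSE))
  rep <- simulate_acquisition(ph, still, t1_protocol(3), seed = 1,
                              nav_noise_sd = 0)
  expect_equal(rep$corrected_sum$data, rep$uncorrected_sum$data,
               tolerance = 1e-12)
  expect_true(all(rep$per_measurement$detected_score < 1e-9))
})

test_that("disabled updates give exactly equal sums", {
  ph <- tiny_phantom(c(32, 32, 32), noise_sd = 0)
  rep <- simulate_acquisition(ph, step_motion_trace(3), t1_protocol(3, "none"),
                              seed = 1, nav_noise_sd = 2)
  expect_identical(rep$corrected_sum$data, rep$uncorrected_sum$data)
})

test_that("step motion is corrected and sharpens the summed image", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), spacing = 2,
                                      noise_sd = 0, seed = 1))
  tr <- step_motion_trace(5, change_at = 3)
  rep <- simulate_acquisition(ph, tr, t1_protocol(5), seed = 7,
                              nav_noise_sd = 2)
  expect_gt(rep$sharpness_ratio, 1)
  # the step is detected at measurement 3 and the frame follows it
  expect_equal(rep$per_measurement$detected_score[3], 5, tolerance = 0.5)
  expect_lt(rep$per_measurement$residual_score[3], 1)
})

test_that("the perfect-pose oracle recovers the zero-motion sum", {
  ph <- tiny_phantom(c(32, 32, 32), noise_sd = 0)
  tr <- step_motion_trace(4, change_at = 2,
                          pose = rigid_transform(c(3, 0, 0), c(5, -4, 2)))
  rep <- simulate_acquisition(ph, tr, t1_protocol(4), seed = 1,
                              nav_noise_sd = 0, use_true_pose = TRUE)
  zero_sum <- 4 * ph$data
  mae <- mean(abs(rep$corrected_sum$data - zero_sum)) / max(ph$data)
  expect_lt(mae, 0.02)
})

test_that("alternating policy corrects odd and spares even measurements", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), spacing = 2,
                                      noise_sd = 0, seed = 2))
  tr <- step_motion_trace(5, change_at = 2)
  rep <- simulate_acquisition(ph, tr, t1_protocol(5, "every_other_measurement"),
                              seed = 3, nav_noise_sd = 2)
  expect_gt(rep$sharpness_ratio, 1)
  expect_false(rep$per_measurement$corrected[2])
  expect_true(rep$per_measurement$corrected[3])
})
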