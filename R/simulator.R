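# Measurement-level simulation of the prospective correction loop: a moving
# phantom, a navigator before every measurement, frame updates from detected
# transforms, and the alternating corrected/uncorrected measurement paradigm
# used to visualise correction performance in vivo.

#' Host-sequence acquisition protocol
#'
#' Timing and update-policy parameters of the host sequence into which
#' navigators are embedded every `N x TR` (one navigator per measurement).
#'
#' @param tr_ms repetition time in ms.
#' @param n_kspace_lines k-space lines per measurement (N).
#' @param n_measurements number of measurements (>= 1).
#' @param nav_duration_s navigator acquisition time in seconds.
#' @param update_policy `"every_measurement"`, `"every_other_measurement"`
#'   (odd measurements corrected, even acquired in the original frame), or
#'   `"none"`.
#' @param update_latency_s reconstruction + registration delay; updates take
#'   effect at the next measurement boundary, so this is informational.
#' @return A list of class `acquisition_protocol`.
#' @examples
#' t1 <- acquisition_protocol(tr_ms = 168, n_kspace_lines = 256,
#'                            n_measurements = 7, nav_duration_s = 1.23)
#' navigator_update_interval(t1) # 43.008 s
#' added_scan_time(t1)           # 8.61 s
#' @export
acquisition_protocol <- function(tr_ms, n_kspace_lines, n_measurements,
                                 nav_duration_s = 1.23,
                                 update_policy = "every_measurement",
                                 update_latency_s = 3) {
  update_policy <- match.arg(update_policy,
                             c("every_measurement", "every_other_measurement",
                               "none"))
  if (tr_ms <= 0 || n_kspace_lines <= 0 || nav_duration_s < 0 ||
      update_latency_s < 0)
    stop("protocol times must be positive (navigator duration may be 0)")
  if (n_measurements < 1) stop("`n_measurements` must be >= 1")
  structure(list(tr_ms = tr_ms, n_kspace_lines = n_kspace_lines,
                 n_measurements = as.integer(n_measurements),
                 nav_duration_s = nav_duration_s,
                 update_policy = update_policy,
                 update_latency_s = update_latency_s),
            class = "acquisition_protocol")
}

#' Navigator timing quantities of a protocol
#'
#' `navigator_update_interval` is the time between motion updates, `N x TR`
#' in seconds (e.g. 43.008 s for N = 256, TR = 168 ms, displayed as 43 s);
#' `added_scan_time` is the total scan-time cost of embedding one navigator
#' per measurement, `n_measurements x nav_duration_s` (e.g. 7 x 1.23 s =
#' 8.61 s). Use [format_seconds()] for display rounding.
#'
#' @param p an [acquisition_protocol()].
#' @return seconds (exact, unrounded).
#' @export
navigator_update_interval <- function(p) {
  stopifnot(inherits(p, "acquisition_protocol"))
  p$n_kspace_lines * p$tr_ms / 1000
}

#' @rdname navigator_update_interval
#' @export
added_scan_time <- function(p) {
  stopifnot(inherits(p, "acquisition_protocol"))
  p$n_measurements * p$nav_duration_s
}

#' @rdname navigator_update_interval
#' @param x time in seconds.
#' @export
format_seconds <- function(x) round(x)

#' Read / write an acquisition protocol (YAML or JSON)
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_protocol` returns an [acquisition_protocol()].
#' @export
read_protocol <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(acquisition_protocol, x)
}

#' @rdname read_protocol
#' @param p an [acquisition_protocol()].
#' @export
write_protocol <- function(p, path) {
  x <- unclass(p)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Motion trace: one true head pose per measurement
#'
#' @param poses list of [rigid_transform()]s, one per measurement (pose is
#'   constant within a measurement).
#' @return A list of class `motion_trace`.
#' @export
motion_trace <- function(poses) {
  if (!all(vapply(poses, inherits, logical(1), "rigid_transform")))
    stop("`poses` must be a list of rigid_transform objects")
  structure(list(poses = poses, n = length(poses)), class = "motion_trace")
}

#' Step-motion trace
#'
#' Pose is identity up to (not including) `change_at`, then jumps to the
#' given pose and stays there — the piecewise-constant motion a volunteer
#' instructed to reposition once between measurements produces.
#'
#' @param n_measurements number of measurements.
#' @param change_at first measurement acquired in the new pose.
#' @param pose the new pose (default 5 mm translation along x).
#' @return A [motion_trace()].
#' @export
step_motion_trace <- function(n_measurements, change_at = 3,
                              pose = rigid_transform(trans_mm = c(5, 0, 0))) {
  motion_trace(lapply(seq_len(n_measurements), function(m) {
    if (m >= change_at) pose else rigid_transform()
  }))
}

#' Read / write a motion trace as JSON
#' @param path file path.
#' @return `read_trace` returns a [motion_trace()].
#' @export
read_trace <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  motion_trace(lapply(seq_len(nrow(x)), function(i) {
    rigid_transform(unlist(x$rot_deg[i]), unlist(x$trans_mm[i]))
  }))
}

#' @rdname read_trace
#' @param trace a [motion_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(measurement = seq_len(trace$n))
  df$rot_deg <- lapply(trace$poses, `[[`, "rot_deg")
  df$trans_mm <- lapply(trace$poses, `[[`, "trans_mm")
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' Combine measurements into a summed image
#'
#' Voxel-wise sum over a subset of measurements. The reference (first)
#' measurement is always included in the odd/even schemes, mirroring the
#' alternating corrected/uncorrected display: `odd_plus_ref` sums
#' measurements 1, 3, 5, ...; `even_plus_ref` sums 1, 2, 4, 6, ...
#'
#' @param measurements non-empty list of [volume3d()]s (or arrays) of
#'   identical shape.
#' @param scheme `"odd_plus_ref"`, `"even_plus_ref"` or `"all"`.
#' @return A [volume3d()] (if inputs are volumes) or array.
#' @export
combine_measurements <- function(measurements, scheme = "all") {
  scheme <- match.arg(scheme, c("odd_plus_ref", "even_plus_ref", "all"))
  if (length(measurements) == 0L) stop("`measurements` must be non-empty")
  n <- length(measurements)
  idx <- switch(scheme,
                all = seq_len(n),
                odd_plus_ref = seq(1L, n, by = 2L),
                even_plus_ref = if (n >= 2L) c(1L, seq(2L, n, by = 2L)) else 1L)
  arrs <- lapply(measurements[idx], metric_data)
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d)) stop("measurement shape mismatch")
  acc <- Reduce(`+`, arrs)
  if (is_volume3d(measurements[[1]]))
    volume3d(acc, measurements[[1]]$spacing)
  else acc
}

#' Simulate a prospectively corrected acquisition
#'
#' Plays a motion trace through the correction loop. For each measurement m:
#' a navigator is rendered as the phantom at its current true pose seen in
#' the current acquisition frame (plus Gaussian noise), registered to the
#' reference navigator (the first one), and — depending on the update policy
#' — the detected transform is composed into the acquisition frame before the
#' next corrected measurement. The host image of each measurement is rendered
#' in its governing frame; corrected and uncorrected sums are assembled for
#' comparison. With `update_policy = "every_other_measurement"` the corrected
#' sum is the reference plus odd measurements (acquired in the updated frame)
#' and the uncorrected sum the reference plus even measurements (original
#' frame), the alternating paradigm; with `"every_measurement"` every
#' measurement is corrected and an uncorrected twin is rendered for
#' comparison; with `"none"` the two sums are identical.
#'
#' @param phantom a [volume3d()], the object being imaged (reference pose).
#' @param trace a [motion_trace()] with one pose per measurement.
#' @param protocol an [acquisition_protocol()].
#' @param reg_cfg a [registration_config()] for navigator registration.
#' @param seed RNG seed for navigator noise.
#' @param nav_noise_sd SD of additive navigator noise (rectified), in the
#'   phantom's intensity units.
#' @param use_true_pose if `TRUE`, bypass registration and feed the true pose
#'   to the correction loop (perfect-registration oracle).
#' @return A list of class `simulation_report`: `per_measurement` data frame
#'   (measurement, detected/true motion scores, residual score after
#'   correction, converged flag), `corrected_sum` and `uncorrected_sum`
#'   volumes, `sharpness_ratio` (central-slice Laplacian-variance ratio of
#'   corrected to uncorrected sum), and `timing` (update interval and added
#'   scan time).
#' @export
simulate_acquisition <- function(phantom, trace, protocol,
                                 reg_cfg = registration_config(),
                                 seed = 1L, nav_noise_sd = 2,
                                 use_true_pose = FALSE) {
  stopifnot(is_volume3d(phantom), inherits(trace, "motion_trace"),
            inherits(protocol, "acquisition_protocol"))
  M <- protocol$n_measurements
  if (trace$n < M) stop("trace must cover all measurements")
  policy <- protocol$update_policy

  render <- function(pose, frame, noise_sd = 0) {
    eff <- compose(invert(frame), pose)
    out <- apply_rigid_transform(phantom, eff, 0, 0)
    if (noise_sd > 0) {
      out$data <- abs(out$data + rnorm(length(out$data), 0, noise_sd))
      dim(out$data) <- out$shape
    }
    out
  }

  withr::with_seed(as.integer(seed), {
    id <- rigid_transform()
    frame <- id
    ref_nav <- render(trace$poses[[1]], id, nav_noise_sd)
    corrected <- vector("list", M)
    uncorrected <- vector("list", M)
    rows <- vector("list", M)
    for (m in seq_len(M)) {
      pose <- trace$poses[[m]]
      nav <- if (m == 1L) ref_nav else render(pose, frame, nav_noise_sd)
      detected_ok <- TRUE
      if (use_true_pose) {
        det <- compose(invert(frame), pose) # apparent pose in current frame
      } else {
        res <- tryCatch(register_rigid(ref_nav, nav, reg_cfg),
                        error = function(e) NULL)
        # a detection is usable when its similarity clears the metric floor,
        # even if the pass loop had not fully settled
        score <- if (is.null(res)) -Inf
                 else if (reg_cfg$metric == "RMSE") -res$final_metric
                 else res$final_metric
        detected_ok <- score >= reg_cfg$metric_floor
        det <- if (detected_ok) res$transform else id
      }
      # apparent (detected) motion in the current frame; update the frame
      # before acquiring this measurement when the policy corrects it
      update_now <- switch(policy,
                           every_measurement = TRUE,
                           every_other_measurement = (m %% 2L == 1L) && m > 1L,
                           none = FALSE)
      if (update_now && detected_ok) frame <- compose(frame, det)

      governing <- if (policy == "every_other_measurement" && m %% 2L == 0L)
        id else frame
      img_corr <- render(pose, if (policy == "none") id else governing)
      img_unc <- if (policy == "none") img_corr else render(pose, id)
      corrected[[m]] <- img_corr
      uncorrected[[m]] <- img_unc
      resid_pose <- compose(invert(frame), pose)
      rows[[m]] <- data.frame(
        measurement = m,
        true_score = motion_score(pose)$score,
        detected_score = motion_score(det)$score,
        residual_score = motion_score(resid_pose)$score,
        corrected = update_now || (policy == "every_measurement"),
        registration_ok = detected_ok)
    }
    corrected_sum <- if (policy == "every_other_measurement")
      combine_measurements(corrected, "odd_plus_ref")
    else combine_measurements(corrected, "all")
    uncorrected_sum <- if (policy == "every_other_measurement")
      combine_measurements(uncorrected, "even_plus_ref")
    else combine_measurements(uncorrected, "all")
    mid <- ceiling(phantom$shape[3] / 2)
    sr <- tryCatch(sharpness_ratio(corrected_sum, uncorrected_sum, slice = mid),
                   error = function(e) NA_real_)
    structure(list(per_measurement = do.call(rbind, rows),
                   corrected_sum = corrected_sum,
                   uncorrected_sum = uncorrected_sum,
                   sharpness_ratio = sr,
                   timing = list(
                     update_interval_s = navigator_update_interval(protocol),
                     added_scan_time_s = added_scan_time(protocol))),
              class = "simulation_report")
  })
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("<simulation_report> %d measurements, sharpness ratio %.3f\n",
              nrow(x$per_measurement), x$sharpness_ratio))
  print(x$per_measurement, row.names = FALSE)
  invisible(x)
}
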