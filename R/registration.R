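#' Configuration of the sub-volume rigid registration search
#'
#' Parameters of the sequential per-axis search: the algorithm selects bright
#' sub-volumes (the scalp-fat shell carries essentially all navigator signal),
#' initialises the translation from the intensity-centroid difference, and
#' then alternates coarse-then-fine 1-D grid searches over tx, ty, tz, rz,
#' ry, rx, maximising the similarity metric (CCC or SSIM; RMSE is minimised)
#' summed over the sub-volumes with trilinear interpolation.
#'
#' @param metric `"CCC"` (default), `"SSIM"` or `"RMSE"`.
#' @param n_subvolumes number of sub-volumes to select.
#' @param subvolume_edge sub-volume edge length in voxels (clamped to the
#'   volume extent).
#' @param trans_bound_mm,rot_bound_deg half-width of the search range per
#'   parameter.
#' @param coarse_step_mm,fine_step_mm,coarse_step_deg,fine_step_deg grid steps
#'   for the coarse and fine 1-D searches.
#' @param rot_init_span_deg,rot_init_step_deg span and step of the joint
#'   (3-D) coarse rotation initialisation evaluated once before the per-axis
#'   rotation refinement; rotations couple on a near-spherical head, so a
#'   joint seed prevents the axis-by-axis search from stalling at zero. Set
#'   the span to 0 to disable.
#' @param max_passes maximum number of full passes over the six parameters.
#' @param tol_mm,tol_deg convergence tolerance on per-pass parameter change;
#'   defaults equal the fine step, the resolution below which the grid search
#'   cannot improve.
#' @param polish run a bounded Nelder-Mead simplex refinement from the grid
#'   result (default `TRUE`). The sequential per-axis search cannot make
#'   coordinated rotation-translation moves and can settle in a false joint
#'   optimum on near-symmetric heads; the simplex stage escapes such valleys
#'   at the cost of roughly one extra second per registration.
#' @param metric_floor result is flagged non-converged if the final
#'   (maximised) metric falls below this floor; defaults to 0.5 for CCC and
#'   no floor otherwise.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(metric = "CCC",
                                n_subvolumes = 8L,
                                subvolume_edge = 16L,
                                trans_bound_mm = 25,
                                rot_bound_deg = 20,
                                coarse_step_mm = 2, fine_step_mm = 0.25,
                                coarse_step_deg = 2, fine_step_deg = 0.25,
                                rot_init_span_deg = 8, rot_init_step_deg = 4,
                                max_passes = 3L,
                                tol_mm = 0.25, tol_deg = 0.25,
                                polish = TRUE,
                                metric_floor = NULL) {
  metric <- match.arg(metric, c("CCC", "SSIM", "RMSE"))
  if (fine_step_mm > coarse_step_mm || fine_step_deg > coarse_step_deg)
    stop("fine steps must not exceed coarse steps")
  if (trans_bound_mm <= 0 || rot_bound_deg <= 0) stop("search bounds must be > 0")
  if (tol_mm <= 0 || tol_deg <= 0) stop("tolerances must be > 0")
  if (is.null(metric_floor))
    metric_floor <- if (metric == "CCC") 0.5 else -Inf
  structure(list(metric = metric,
                 n_subvolumes = as.integer(n_subvolumes),
                 subvolume_edge = as.integer(subvolume_edge),
                 trans_bound_mm = trans_bound_mm, rot_bound_deg = rot_bound_deg,
                 coarse_step_mm = coarse_step_mm, fine_step_mm = fine_step_mm,
                 coarse_step_deg = coarse_step_deg, fine_step_deg = fine_step_deg,
                 rot_init_span_deg = rot_init_span_deg,
                 rot_init_step_deg = rot_init_step_deg,
                 max_passes = as.integer(max_passes),
                 tol_mm = tol_mm, tol_deg = tol_deg,
                 polish = isTRUE(polish),
                 metric_floor = metric_floor),
            class = "registration_config")
}

#' Select bright sub-volumes for registration
#'
#' Partitions the volume into non-overlapping cubic blocks of
#' `cfg$subvolume_edge` voxels and returns the `cfg$n_subvolumes` blocks of
#' highest mean intensity — on a fat navigator these land on the bright scalp
#' shell. If the volume carries no signal (all blocks essentially zero), the
#' whole volume is returned as a single box with a warning.
#'
#' @param vol a [volume3d()].
#' @param cfg a [registration_config()].
#' @return Integer matrix with one row per box and columns `i0, i1, j0, j1,
#'   k0, k1` (0-based inclusive voxel bounds).
#' @export
select_subvolumes <- function(vol, cfg) {
  stopifnot(is_volume3d(vol))
  d <- vol$shape
  e <- min(cfg$subvolume_edge, d)
  starts <- lapply(d, function(dd) seq(1L, dd - e + 1L, by = e))
  grid <- expand.grid(i = starts[[1]], j = starts[[2]], k = starts[[3]])
  means <- vapply(seq_len(nrow(grid)), function(r) {
    mean(vol$data[grid$i[r]:(grid$i[r] + e - 1L),
                  grid$j[r]:(grid$j[r] + e - 1L),
                  grid$k[r]:(grid$k[r] + e - 1L)])
  }, numeric(1))
  if (max(means) <= 1e-8 * max(1, max(vol$data))) {
    warning("no bright blocks found; falling back to whole-volume registration")
    return(matrix(c(0L, d[1] - 1L, 0L, d[2] - 1L, 0L, d[3] - 1L), nrow = 1))
  }
  take <- order(means, decreasing = TRUE)[seq_len(min(cfg$n_subvolumes, nrow(grid)))]
  boxes <- t(vapply(take, function(r) {
    c(grid$i[r] - 1L, grid$i[r] + e - 2L,
      grid$j[r] - 1L, grid$j[r] + e - 2L,
      grid$k[r] - 1L, grid$k[r] + e - 2L)
  }, integer(6)))
  storage.mode(boxes) <- "integer"
  boxes
}

# fixed-image values over the boxes, in the same order cpp_sample_boxes uses
box_values <- function(vol, boxes) {
  unlist(lapply(seq_len(nrow(boxes)), function(r) {
    as.numeric(vol$data[(boxes[r, 1]:boxes[r, 2]) + 1L,
                        (boxes[r, 3]:boxes[r, 4]) + 1L,
                        (boxes[r, 5]:boxes[r, 6]) + 1L])
  }), use.names = FALSE)
}

# internal maximised score: metric value for CCC/SSIM, negated for RMSE
metric_score_fn <- function(metric) {
  switch(metric,
         CCC = function(f, m) ccc(f, m),
         SSIM = function(f, m) ssim(f, m),
         RMSE = function(f, m) -rmse(f, m))
}

centroid_mm <- function(vol) {
  s <- sum(vol$data)
  if (s <= 0) return(rep(NA_real_, 3))
  cm <- vapply(1:3, function(ax) {
    marg <- apply(vol$data, ax, sum)
    sum(marg * seq_along(marg)) / s
  }, numeric(1))
  (cm - 1) * vol$spacing
}

#' Rigid registration by sequential per-axis CCC search
#'
#' Registers `moving` to `fixed` with the sub-volume algorithm: (i) the
#' translation is initialised from the difference of intensity centroids;
#' (ii) each of the six parameters in turn (tx, ty, tz, then rz, ry, rx) is
#' optimised by a coarse grid search over the full bound followed by a fine
#' grid around the best coarse value, evaluating the metric over the selected
#' sub-volumes with trilinear interpolation; (iii) passes repeat until the
#' largest parameter change falls below tolerance or `max_passes` is reached.
#' Grid ties break toward the smaller parameter magnitude, making results
#' deterministic.
#'
#' The sequential search is intended for a limited range of motion; for large
#' oblique rotations it may fail to reach the optimum, in which case the
#' result is flagged `converged = FALSE` when the final metric falls below
#' `cfg$metric_floor`.
#'
#' @param fixed,moving [volume3d()] objects of identical shape and spacing.
#' @param cfg a [registration_config()].
#' @return A list of class `registration_result`: `transform`
#'   ([rigid_transform()]), `final_metric` (raw metric at the returned
#'   transform), `passes_used`, `elapsed_time` (s), `converged`.
#' @examples
#' ref <- generate_phantom(phantom_spec(shape = c(32, 32, 32), noise_sd = 0))
#' mov <- apply_rigid_transform(ref, rigid_transform(trans_mm = c(4, 0, 0)))
#' register_rigid(ref, mov)$transform
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config()) {
  stopifnot(is_volume3d(fixed), is_volume3d(moving))
  if (!identical(fixed$shape, moving$shape) ||
      !isTRUE(all.equal(fixed$spacing, moving$spacing)))
    stop("`fixed` and `moving` must share shape and spacing")
  if (diff(range(fixed$data)) == 0 || diff(range(moving$data)) == 0)
    stop("degenerate (constant) image cannot be registered")
  t0 <- proc.time()[["elapsed"]]
  boxes <- select_subvolumes(fixed, cfg)
  fvals <- box_values(fixed, boxes)
  score_fn <- metric_score_fn(cfg$metric)
  eval_par <- function(par) {
    t <- rigid_transform(par[4:6], par[1:3])
    score_fn(fvals, sample_moving_boxes(moving, t, boxes))
  }

  # centroid initialisation, clipped to the search bounds
  init_t <- centroid_mm(moving) - centroid_mm(fixed)
  if (any(!is.finite(init_t))) init_t <- c(0, 0, 0)
  init_t <- pmin(pmax(init_t, -cfg$trans_bound_mm), cfg$trans_bound_mm)
  par <- c(init_t, 0, 0, 0)
  best <- eval_par(par)

  bounds <- c(rep(cfg$trans_bound_mm, 3), rep(cfg$rot_bound_deg, 3))
  coarse <- c(rep(cfg$coarse_step_mm, 3), rep(cfg$coarse_step_deg, 3))
  fine <- c(rep(cfg$fine_step_mm, 3), rep(cfg$fine_step_deg, 3))
  tol <- c(rep(cfg$tol_mm, 3), rep(cfg$tol_deg, 3))

  line_search <- function(par, ax, cand) {
    cand <- cand[abs(cand) <= bounds[ax] + 1e-9]
    cand <- cand[order(abs(cand), cand)] # ties -> smaller magnitude
    vals <- vapply(cand, function(v) { p <- par; p[ax] <- v; eval_par(p) },
                   numeric(1))
    list(value = cand[which.max(vals)], score = max(vals))
  }

  # joint coarse rotation seed: 1-D rotation profiles are shallow and
  # mutually coupled on a near-spherical head, so the per-axis search alone
  # can stall at zero; a single coarse 3-D sweep provides a basin to refine
  joint_rot_seed <- function(par) {
    span <- min(cfg$rot_init_span_deg, cfg$rot_bound_deg)
    if (span <= 0) return(par)
    g <- seq(-span, span, by = cfg$rot_init_step_deg)
    g <- g[order(abs(g), g)]
    cand <- as.matrix(expand.grid(rz = par[4] + g, ry = par[5] + g,
                                  rx = par[6] + g))
    keep <- apply(abs(cand) <= cfg$rot_bound_deg + 1e-9, 1, all)
    cand <- cand[keep, , drop = FALSE]
    vals <- apply(cand, 1, function(rot) {
      p <- par; p[4:6] <- rot; eval_par(p)
    })
    par[4:6] <- cand[which.max(vals), ]
    par
  }

  passes <- 0L
  for (pass in seq_len(cfg$max_passes)) {
    passes <- pass
    old <- par
    if (pass == 1L) { # settle translations coarsely before any rotation
      for (ax in 1:3) {
        cg <- seq(-bounds[ax], bounds[ax], by = coarse[ax])
        par[ax] <- line_search(par, ax, unique(c(cg, par[ax])))$value
      }
    }
    if (pass <= 2L) par <- joint_rot_seed(par)
    for (ax in 1:6) {
      # pass 1 scans the full bound; later passes refine locally
      cgrid <- if (pass == 1L)
        seq(-bounds[ax], bounds[ax], by = coarse[ax])
      else
        seq(par[ax] - 3 * coarse[ax], par[ax] + 3 * coarse[ax], by = coarse[ax])
      cr <- line_search(par, ax, unique(c(cgrid, par[ax])))
      fgrid <- seq(cr$value - coarse[ax], cr$value + coarse[ax], by = fine[ax])
      fr <- line_search(par, ax, unique(c(fgrid, cr$value)))
      par[ax] <- fr$value
      best <- fr$score
    }
    if (all(abs(par - old) <= tol + 1e-12)) break
  }
  converged <- all(abs(par - old) <= tol + 1e-12)

  if (cfg$polish) {
    clip <- function(p) pmin(pmax(p, -bounds), bounds)
    opt <- stats::optim(par, function(p) -eval_par(clip(p)),
                        method = "Nelder-Mead",
                        control = list(maxit = 300L))
    cand <- clip(opt$par)
    cand_score <- eval_par(cand)
    if (cand_score > best) {
      par <- cand
      best <- cand_score
    }
  }

  raw_metric <- if (cfg$metric == "RMSE") -best else best
  if (best < cfg$metric_floor) converged <- FALSE

  structure(list(transform = rigid_transform(par[4:6], par[1:3]),
                 final_metric = raw_metric,
                 passes_used = passes,
                 elapsed_time = proc.time()[["elapsed"]] - t0,
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> metric %.5f, %d pass(es), %.2f s, %s\n",
              x$final_metric, x$passes_used, x$elapsed_time,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

#' Exhaustive-grid registration oracle
#'
#' Evaluates the metric at every point of a full 6-D parameter grid and
#' returns the global grid optimum. Intended as a verification oracle on
#' small volumes (16^3-32^3) with coarse grids; the evaluation count is
#' capped at 1e7. Ties break toward the smaller parameter magnitude
#' (lexicographically over `tx, ty, tz, rz, ry, rx`).
#'
#' @inheritParams register_rigid
#' @param grid named list of candidate values for any of `tx`, `ty`, `tz`
#'   (mm), `rz`, `ry`, `rx` (degrees); omitted parameters are fixed at 0.
#' @param metric `"CCC"`, `"SSIM"` or `"RMSE"`.
#' @return A `registration_result` (with `passes_used = 1`).
#' @export
register_oracle <- function(fixed, moving, grid, metric = "CCC") {
  stopifnot(is_volume3d(fixed), is_volume3d(moving))
  metric <- match.arg(metric, c("CCC", "SSIM", "RMSE"))
  nm <- c("tx", "ty", "tz", "rz", "ry", "rx")
  if (length(grid) == 0L || any(!names(grid) %in% nm))
    stop("`grid` must be a non-empty named list over ",
         paste(nm, collapse = ", "))
  if (any(vapply(grid, length, integer(1)) == 0L))
    stop("empty parameter grid")
  full <- setNames(lapply(nm, function(p) {
    v <- grid[[p]]
    if (is.null(v) || length(v) == 0L) 0 else as.numeric(v)
  }), nm)
  n_eval <- prod(vapply(full, length, numeric(1)))
  if (n_eval < 1) stop("empty parameter grid")
  if (n_eval > 1e7) stop("grid too large (", format(n_eval), " evaluations)")
  cand <- expand.grid(full, KEEP.OUT.ATTRS = FALSE)
  # lexicographic magnitude ordering so strict improvement = tie-break rule
  ord <- do.call(order, c(lapply(nm, function(p) abs(cand[[p]])),
                          lapply(nm, function(p) cand[[p]])))
  cand <- cand[ord, , drop = FALSE]
  d <- fixed$shape
  boxes <- matrix(c(0L, d[1] - 1L, 0L, d[2] - 1L, 0L, d[3] - 1L), nrow = 1)
  storage.mode(boxes) <- "integer"
  fvals <- box_values(fixed, boxes)
  score_fn <- metric_score_fn(metric)
  t0 <- proc.time()[["elapsed"]]
  best <- -Inf; best_row <- NULL
  for (r in seq_len(nrow(cand))) {
    t <- rigid_transform(as.numeric(cand[r, 4:6]), as.numeric(cand[r, 1:3]))
    s <- score_fn(fvals, sample_moving_boxes(moving, t, boxes))
    if (s > best) { best <- s; best_row <- cand[r, ] }
  }
  structure(list(transform = rigid_transform(as.numeric(best_row[4:6]),
                                             as.numeric(best_row[1:3])),
                 final_metric = if (metric == "RMSE") -best else best,
                 passes_used = 1L,
                 elapsed_time = proc.time()[["elapsed"]] - t0,
                 converged = TRUE),
            class = "registration_result")
}

#' Benchmark registration configurations on a synthetic dataset
#'
#' Runs each configuration on each ground-truthed pair and reports the
#' residual motion score (mm), elapsed time, final metric and convergence
#' flag per pair, plus per-method means. Registration failures are recorded
#' per row, not fatal.
#'
#' @param pairs list of [synthetic_pair()]s.
#' @param cfgs named list of [registration_config()]s (names become the
#'   `method` column; unnamed configs are named after their metric).
#' @return A list with `results` and `summary` data frames. `results` has
#'   columns `pair_id`, `method`, `range_label`, `residual_motion_score_mm`,
#'   `elapsed_s`, `final_metric`, `converged`, `error`.
#' @export
benchmark_registration <- function(pairs, cfgs = list(registration_config())) {
  if (length(pairs) == 0L) stop("`pairs` must be non-empty")
  if (is.null(names(cfgs)))
    names(cfgs) <- vapply(cfgs, function(cf) cf$metric, character(1))
  rows <- list()
  for (m in names(cfgs)) {
    for (p in pairs) {
      res <- tryCatch(register_rigid(p$reference, p$moved, cfgs[[m]]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = p$pair_id, method = m, range_label = p$range_label,
          residual_motion_score_mm = NA_real_, elapsed_s = NA_real_,
          final_metric = NA_real_, converged = FALSE,
          error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = p$pair_id, method = m, range_label = p$range_label,
          residual_motion_score_mm =
            residual_motion_score(res$transform, p$ground_truth),
          elapsed_s = res$elapsed_time, final_metric = res$final_metric,
          converged = res$converged, error = NA_character_)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$method), function(g) {
    data.frame(method = g$method[1],
               n = nrow(g),
               mean_residual_motion_score_mm =
                 mean(g$residual_motion_score_mm, na.rm = TRUE),
               mean_elapsed_s = mean(g$elapsed_s, na.rm = TRUE),
               frac_converged = mean(g$converged))
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
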