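#' Run the social-distance estimation pipeline
#'
#' Orchestrates the per-frame stages: localize each detected pose to a
#' ground anchor with a quality flag, discard anchors outside the ROI,
#' transform to top-view metres, smooth/track with the flag-adaptive Kalman
#' filter and GNN tracker (optional), then compute pairwise distances,
#' violations, the anomaly series, and the time-averaged occupancy and crowd
#' density maps with the overcrowding segmentation.
#'
#' @param poses Long pose tibble (`frame`, `person`, `joint`, `u`, `v`) or a
#'   path readable by [read_pose_frames()].
#' @param scene A [scene_config()].
#' @param params A [tracker_params()].
#' @param method Localization method, `"proposed"` or `"basic"`.
#' @param tracking If `FALSE`, raw localized positions are used downstream
#'   (the untracked variant).
#' @param frame_skip Keep every `frame_skip`-th frame (1 = all frames);
#'   kept frames are renumbered consecutively.
#' @param n_frames Total frame count (defaults to the largest frame index).
#' @param r Safety distance; defaults to the scene's.
#' @param torso_sign Passed to [localize_frames()].
#' @return Object of class `crowd_run`: a list with tibbles `results`
#'   (frame, id, x, y, flag, violating), `series` (per-frame n, violations,
#'   anomaly), `pairs`, density grids `odm`, `cdm`, `region`, and the
#'   settings used.
#' @examples
#' sc <- simulate_scene(sim_config(n_subjects = 3, n_frames = 40, seed = 7))
#' run <- run_pipeline(sc$poses, sc$scene)
#' glance(run)
#' @export
run_pipeline <- function(poses, scene, params = tracker_params(),
                         method = c("proposed", "basic"), tracking = TRUE,
                         frame_skip = 1, n_frames = NULL,
                         r = scene$safety_distance, torso_sign = 1) {
  method <- match.arg(method)
  if (is.character(poses)) poses <- read_pose_frames(poses)
  if (is.null(n_frames)) n_frames <- if (nrow(poses)) max(poses$frame) else 1L
  if (frame_skip > 1) {
    kept <- seq(1L, n_frames, by = frame_skip)
    poses <- poses[poses$frame %in% kept, , drop = FALSE]
    poses$frame <- match(poses$frame, kept)
    n_frames <- length(kept)
  }
  located <- localize_frames(poses, method = method, torso_sign = torso_sign)
  located <- filter_roi(located, scene$roi)
  defined <- !is.na(located$u) & !is.na(located$v)
  located$x <- NA_real_; located$y <- NA_real_
  if (any(defined)) {
    tv <- image_to_topview(located[defined, c("u", "v")], scene)
    located$x[defined] <- tv$x
    located$y[defined] <- tv$y
  }
  if (tracking) {
    tracked <- track_frames(located[c("frame", "x", "y", "flag")], scene,
                            params, n_frames = n_frames)
    subjects <- tibble::tibble(frame = tracked$frame, id = tracked$track_id,
                               x = tracked$x, y = tracked$y, flag = tracked$flag)
  } else {
    raw <- located[defined, , drop = FALSE]
    subjects <- tibble::tibble(frame = raw$frame, id = raw$person,
                               x = raw$x, y = raw$y, flag = raw$flag)
  }
  va <- violation_analytics(subjects[c("frame", "id", "x", "y")], r,
                            n_frames = n_frames)
  results <- dplyr::left_join(
    subjects, va$subjects[c("frame", "id", "violating")],
    by = c("frame", "id")
  )
  odm <- averaged_density_map(results, scene, n_frames = n_frames)
  cdm <- averaged_density_map(results, scene, weight = "violating",
                              n_frames = n_frames)
  structure(
    list(results = results, series = va$frames, pairs = va$pairs,
         odm = odm, cdm = cdm, region = threshold_cdm(cdm),
         scene = scene, params = params,
         settings = list(method = method, tracking = tracking,
                         frame_skip = frame_skip, n_frames = n_frames, r = r)),
    class = "crowd_run"
  )
}

#' @export
print.crowd_run <- function(x, ...) {
  cat("<crowd_run> ", x$settings$n_frames, " frames, ",
      dplyr::n_distinct(x$results$id), " subjects/tracks, method '",
      x$settings$method, "', tracking ", x$settings$tracking, "\n", sep = "")
  cat("  anomaly frames: ", sum(x$series$anomaly), " of ",
      nrow(x$series), " (r = ", x$settings$r, " m)\n", sep = "")
  invisible(x)
}

#' Evaluate a pipeline run against ground truth
#'
#' Computes the full metric suite: person detection rate, localization
#' relative error, violation-detection classification metrics, violations
#' count rate, and (optionally) crowd-map correlation and overcrowding-
#' region IOU against the same analytics applied to the ground truth. With
#' a vector `r` the metrics are reported per safety distance; the
#' conventional sweep is `r = seq(1, 2.5, by = 0.05)`.
#'
#' @param run A `crowd_run` from [run_pipeline()].
#' @param truth Tibble `frame`, `id`, `x`, `y` in metres.
#' @param r Safety distance(s) in metres; defaults to the run's.
#' @param maps Compute CDM correlation / region IOU (the costly part) --
#'   default `TRUE` for scalar `r`, `FALSE` for sweeps.
#' @return Tibble with one row per safety distance and columns `r`, `pdr`,
#'   `loc_error`, `accuracy`, `precision`, `recall`, `f1`, `vcr`, `corr`,
#'   `iou`.
#' @export
evaluate_run <- function(run, truth, r = run$settings$r,
                         maps = length(r) == 1) {
  stopifnot(inherits(run, "crowd_run"))
  n_frames <- run$settings$n_frames
  est <- run$results[c("frame", "id", "x", "y")]
  pdr_val <- pdr(frame_counts(truth, n_frames), frame_counts(est, n_frames))
  err <- localization_error(truth, est, n_frames = n_frames)
  purrr::map_dfr(r, function(ri) {
    va_true <- violation_analytics(truth[c("frame", "id", "x", "y")], ri,
                                   n_frames = n_frames)
    va_est <- violation_analytics(est, ri, n_frames = n_frames)
    cls <- violation_classification(va_true$frames$anomaly,
                                    va_est$frames$anomaly)
    row <- tibble::tibble(
      r = ri, pdr = pdr_val, loc_error = err,
      accuracy = cls$accuracy, precision = cls$precision,
      recall = cls$recall, f1 = cls$f1,
      vcr = vcr(va_true$frames$violations, va_est$frames$violations),
      corr = NA_real_, iou = NA_real_
    )
    if (maps) {
      cdm_true <- averaged_density_map(va_true$subjects, run$scene,
                                       weight = "violating", n_frames = n_frames)
      cdm_est <- averaged_density_map(va_est$subjects, run$scene,
                                      weight = "violating", n_frames = n_frames)
      agr <- map_agreement(cdm_true, cdm_est)
      row$corr <- agr$corr
      row$iou <- agr$iou
    }
    row
  })
}

frame_counts <- function(df, n_frames) {
  as.integer(table(factor(df$frame, levels = seq_len(n_frames))))
}

#' Safety-distance sweep grid
#'
#' The conventional guideline range: 1 m to 2.5 m in 0.05 m steps
#' (31 values).
#'
#' @return Numeric vector of safety distances.
#' @export
safety_sweep <- function() seq(1, 2.5, by = 0.05)

#' Persist the outputs of a pipeline run
#'
#' Writes the frame-result table, the per-frame series, the averaged
#' occupancy/crowd density grids and the thresholded region grid as plain
#' text into `dir`.
#'
#' @param run A `crowd_run`.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest of written files, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    results = file.path(dir, "frame_results.csv"),
    series = file.path(dir, "series.csv"),
    odm = file.path(dir, "odm.txt"),
    cdm = file.path(dir, "cdm.txt"),
    region = file.path(dir, "region.txt")
  )
  write_frame_results(run$results, paths["results"])
  readr::write_csv(run$series, paths["series"])
  write_density_grid(run$odm, paths["odm"])
  write_density_grid(run$cdm, paths["cdm"])
  write_density_grid(run$region, paths["region"])
  invisible(tibble::tibble(output = names(paths), path = unname(paths)))
}
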