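#' Read per-frame pose detections
#'
#' Two source layouts are supported:
#'
#' * `"openpose"`: a directory of per-frame JSON files (sorted by file
#'   name), each with a `people` array whose `pose_keypoints_2d` field holds
#'   75 numbers (25 x/y/confidence triplets in BODY_25 order). Joints whose
#'   confidence is at or below `conf_threshold` (default 0) are treated as
#'   absent, and 0-based BODY_25 indices become the package's 1-based
#'   indices.
#' * `"table"`: a delimited file with columns `frame`, `person`, `joint`,
#'   `u`, `v`, one row per present joint (the format [write_poses()] emits).
#'
#' @param path Directory (openpose) or file (table) path.
#' @param format `"auto"` (directory implies openpose), `"openpose"` or
#'   `"table"`.
#' @param conf_threshold Presence threshold on the OpenPose confidence;
#'   joints with confidence strictly above it are kept.
#' @return Long pose tibble `frame`, `person`, `joint`, `u`, `v`.
#' @export
read_pose_frames <- function(path, format = c("auto", "openpose", "table"),
                             conf_threshold = 0) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "openpose" else "table"
  }
  if (format == "table") {
    poses <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("frame", "person", "joint", "u", "v")
    if (!all(need %in% names(poses))) {
      stop("pose table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    return(tibble::as_tibble(poses[need]))
  }
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) stop("no .json files in ", path, call. = FALSE)
  frames <- purrr::imap(files, function(f, idx) {
    doc <- tryCatch(jsonlite::read_json(f, simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed JSON in ", basename(f), ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    people <- doc$people
    if (length(people) == 0) return(NULL)
    purrr::imap(people, function(p, m) {
      kp <- as.numeric(unlist(p$pose_keypoints_2d))
      if (length(kp) != 75) {
        stop("expected 75 keypoint values (25 joints) in ", basename(f),
             ", person ", m, "; got ", length(kp), call. = FALSE)
      }
      u <- kp[seq(1, 75, 3)]; v <- kp[seq(2, 75, 3)]; conf <- kp[seq(3, 75, 3)]
      present <- conf > conf_threshold
      tibble::tibble(frame = idx, person = m, joint = which(present),
                     u = u[present], v = v[present])
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(frames)
}

#' Write a long pose table to CSV
#'
#' @param poses Tibble with columns `frame`, `person`, `joint`, `u`, `v`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path) {
  readr::write_csv(poses[c("frame", "person", "joint", "u", "v")], path)
  invisible(path)
}

#' Ground-truth positions from bounding-box annotations
#'
#' Box annotations localize a person by the bottom mid-point of the box;
#' vertically over-sized boxes put that point below the true ground
#' position, so the anchor is raised by `uplift` times the box height. With
#' a scene configuration the pixel anchor is also mapped to top-view metres.
#'
#' @param boxes Tibble with columns `frame`, `id`, `left`, `top`, `width`,
#'   `height` (pixels; `top` is the smaller v).
#' @param uplift Fraction of the box height in `[0, 1)` to raise the bottom
#'   mid-point by.
#' @param scene Optional [scene_config()]; adds metric `x`, `y` columns.
#' @return Tibble `frame`, `id`, `u`, `v` (and `x`, `y` when `scene` is
#'   given).
#' @export
ground_truth_from_boxes <- function(boxes, uplift = 0, scene = NULL) {
  stopifnot(uplift >= 0, uplift < 1)
  if (any(boxes$height <= 0) || any(boxes$width <= 0)) {
    stop("degenerate bounding box: width and height must be positive",
         call. = FALSE)
  }
  out <- tibble::tibble(
    frame = boxes$frame, id = boxes$id,
    u = boxes$left + boxes$width / 2,
    v = boxes$top + boxes$height * (1 - uplift)
  )
  if (!is.null(scene)) {
    out <- dplyr::bind_cols(out, image_to_topview(out, scene))
  }
  out
}

#' Write or read per-frame tracking results
#'
#' Deterministic delimited text ordered by frame then track id, with the
#' columns `frame`, `track_id`, `x_m`, `y_m`, `flag`, `violating` (0/1).
#' Frames without tracks simply contribute no rows.
#'
#' @param results Tibble with columns `frame`, `id` (or `track_id`), `x`,
#'   `y`, `flag`, `violating`.
#' @param path Output file.
#' @return `path` invisibly; `read_frame_results()` returns the tibble with
#'   the writer's column names mapped back to `frame`, `track_id`, `x`, `y`,
#'   `flag`, `violating`.
#' @export
write_frame_results <- function(results, path) {
  id_col <- if ("track_id" %in% names(results)) "track_id" else "id"
  out <- tibble::tibble(
    frame = results$frame,
    track_id = results[[id_col]],
    x_m = results$x, y_m = results$y,
    flag = if ("flag" %in% names(results)) results$flag else NA_integer_,
    violating = as.integer(results$violating)
  )
  out <- dplyr::arrange(out, .data$frame, .data$track_id)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_frame_results
#' @export
read_frame_results <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(frame = df$frame, track_id = df$track_id,
                 x = df$x_m, y = df$y_m, flag = df$flag,
                 violating = df$violating)
}

#' Read ground-truth positions
#'
#' @param path CSV with columns `frame`, `id`, `x`, `y` (metres).
#' @return Tibble with those columns.
#' @export
read_ground_truth <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::as_tibble(df[c("frame", "id", "x", "y")])
}
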