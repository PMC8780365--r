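#' Ground-position estimation from 25-joint poses
#'
#' Both localizers reduce a detected skeleton to a single ground anchor
#' `(u, v)` in image pixels together with error-state flags describing how
#' the anchor was obtained:
#'
#' * `flag = 1`: position estimated directly from the feet joints,
#' * `flag = 2`: position inferred from fallback joints (knees, hips, torso),
#' * `flag = 0`: subject detected but the position is unresolvable,
#' * `flag = NA`: subject not detected at all (no pose row for the frame).
#'
#' The overall flag combines the per-coordinate flags: `NA` if either is
#' `NA`, `0` if either is `0`, `1` only if both are `1`, else `2`.
#'
#' `localize_frames()` is the tidy entry point: it takes a long pose table
#' (one row per present joint, columns `frame`, `person`, `joint`, `u`, `v`;
#' joints are 1-based BODY_25 indices, so 2 = neck, 9 = mid-hip, 10/13 =
#' right/left hip, 11/14 = knees, 12/15 = ankles, 20-22 left toe/small-toe/
#' heel, 23-25 the right counterparts) and returns one row per detection.
#'
#' The basic method requires at least `min_joints` (13) present joints and
#' at least one foot joint; its horizontal coordinate is the mean of the
#' present nose/neck/mid-hip abscissae (or the mid-range of all present
#' abscissae when none of those is present) and its vertical coordinate the
#' mean of the present feet ordinates. The proposed strategy drops those
#' requirements, walking an ordered case list over feet, knee, hip and torso
#' joints for `u` and falling back on a torso-length extrapolation for `v`:
#' when only neck and mid-hip are present, `v = v9 + (0.85/0.6) (v9 - v2)`,
#' placing the inferred ground below the hip (set `torso_sign = -1` for the
#' opposite, literally printed, sign).
#'
#' @param poses Tibble with columns `frame`, `person`, `joint`, `u`, `v`;
#'   only present joints appear as rows.
#' @param method `"proposed"` (default) or `"basic"`.
#' @param torso_sign `+1` (default) extrapolates the ground below the hip;
#'   `-1` reproduces the literal printed formula.
#' @param min_joints Minimum number of present joints for the basic method.
#' @return Tibble with one row per (`frame`, `person`): `u`, `v` (pixels, NA
#'   when unresolved), `flag_u`, `flag_v`, `flag`, `n_joints`.
#' @export
localize_frames <- function(poses, method = c("proposed", "basic"),
                            torso_sign = 1, min_joints = 13) {
  method <- match.arg(method)
  stopifnot(all(c("frame", "person", "joint", "u", "v") %in% names(poses)))
  if (nrow(poses) == 0) {
    return(tibble::tibble(frame = integer(), person = integer(),
                          u = double(), v = double(), flag_u = integer(),
                          flag_v = integer(), flag = integer(),
                          n_joints = integer()))
  }
  fun <- if (method == "proposed") {
    function(j, u, v) localize_proposed_one(j, u, v, torso_sign)
  } else {
    function(j, u, v) localize_basic_one(j, u, v, min_joints)
  }
  poses |>
    dplyr::group_by(.data$frame, .data$person) |>
    dplyr::summarise(res = list(fun(.data$joint, .data$u, .data$v)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
}

FEET_JOINTS <- c(12L, 15L, 20L, 21L, 22L, 23L, 24L, 25L)
LEFT_FOOT <- c(15L, 20L, 21L, 22L)
RIGHT_FOOT <- c(12L, 23L, 24L, 25L)

localize_basic_one <- function(joint, u, v, min_joints = 13) {
  feet <- joint %in% FEET_JOINTS
  if (length(joint) < min_joints || !any(feet)) {
    return(list(u = NA_real_, v = NA_real_, flag_u = 0L, flag_v = 0L,
                flag = 0L, n_joints = length(joint)))
  }
  core <- joint %in% c(1L, 2L, 9L)
  um <- if (any(core)) mean(u[core]) else (min(u) + max(u)) / 2
  vm <- mean(v[feet])
  list(u = um, v = vm, flag_u = 1L, flag_v = 1L, flag = 1L,
       n_joints = length(joint))
}

localize_proposed_one <- function(joint, u, v, torso_sign = 1) {
  g <- function(k) u[match(k, joint)]
  gv <- function(k) v[match(k, joint)]
  has <- function(k) k %in% joint
  la <- joint %in% LEFT_FOOT
  rb <- joint %in% RIGHT_FOOT
  alpha <- if (any(la)) mean(u[la]) else NA_real_
  beta <- if (any(rb)) mean(u[rb]) else NA_real_

  # u cases, strictly in printed order (first match wins)
  if (!is.na(alpha) && !is.na(beta)) {
    um <- (alpha + beta) / 2; fu <- 1L
  } else if (!is.na(alpha) && has(11L)) {
    um <- (alpha + g(11L)) / 2; fu <- 2L
  } else if (has(14L) && !is.na(beta)) {
    um <- (g(14L) + beta) / 2; fu <- 2L
  } else if (has(11L) && has(14L)) {
    um <- (g(11L) + g(14L)) / 2; fu <- 2L
  } else if (has(10L) && has(14L)) {
    um <- (g(10L) + g(14L)) / 2; fu <- 2L
  } else if (has(11L) && has(13L)) {
    um <- (g(11L) + g(13L)) / 2; fu <- 2L
  } else if (has(10L) && has(13L)) {
    um <- (g(10L) + g(13L)) / 2; fu <- 2L
  } else if (has(2L) && has(9L)) {
    um <- (g(2L) + g(9L)) / 2; fu <- 2L
  } else if (!is.na(alpha) || !is.na(beta)) {
    um <- mean(u[la | rb]); fu <- 2L
  } else {
    um <- NA_real_; fu <- 0L
  }

  # v cases
  feet <- joint %in% FEET_JOINTS
  if (any(feet)) {
    vm <- mean(v[feet]); fv <- 1L
  } else if (has(2L) && has(9L)) {
    vm <- gv(9L) + torso_sign * (0.85 / 0.6) * (gv(9L) - gv(2L)); fv <- 2L
  } else {
    vm <- NA_real_; fv <- 0L
  }

  list(u = um, v = vm, flag_u = fu, flag_v = fv,
       flag = flag_overall(fu, fv), n_joints = length(joint))
}

#' Combine per-coordinate error-state flags
#'
#' Vectorized: `NA` dominates, then `0`, then `1` requires both ones,
#' anything else is `2`.
#'
#' @param flag_u,flag_v Integer vectors with values in `NA, 0, 1, 2`.
#' @return Integer vector of overall flags.
#' @export
flag_overall <- function(flag_u, flag_v) {
  dplyr::case_when(
    is.na(flag_u) | is.na(flag_v) ~ NA_integer_,
    flag_u == 0L | flag_v == 0L ~ 0L,
    flag_u == 1L & flag_v == 1L ~ 1L,
    .default = 2L
  )
}

#' Drop localized positions outside the region of interest
#'
#' Rows with a defined `(u, v)` that falls strictly outside the ROI polygon
#' are removed. Rows with undefined coordinates (flag 0 detections) are
#' retained, because their flags still inform the tracker's lifecycle.
#' Boundary points count as inside.
#'
#' @param located Tibble with columns `u`, `v` (possibly NA).
#' @param roi Two-column polygon matrix, as in [scene_config()].
#' @return The filtered tibble.
#' @export
filter_roi <- function(located, roi) {
  if (nrow(located) == 0) return(located)
  inside <- point_in_polygon(located$u, located$v, roi)
  located[is.na(inside) | inside, , drop = FALSE]
}
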