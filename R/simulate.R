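#' Synthetic surveillance-scene configuration
#'
#' Describes a ground-truthed synthetic scene: pedestrians performing
#' near-constant-velocity walks on a rectangular arena, rendered as 25-joint
#' stick figures through a pinhole camera, with optional per-joint Gaussian
#' pixel noise, independent per-joint dropout, and structured occlusion
#' rectangles in the image (regions that swallow every joint projected into
#' them, emulating pillars or foreground objects).
#'
#' Body proportions are fixed to a 0.85 leg : 0.6 torso split of the
#' (configurable) stature unit, matching the torso-to-lower-body ratio the
#' localization fallback assumes. Paired limb joints are placed symmetrically
#' along the ground direction of constant camera depth, which makes the
#' noiseless feet-midpoint localization exactly invertible through the
#' projective camera.
#'
#' @param n_subjects Number of pedestrians.
#' @param arena Length-2 arena extent (metres); subjects reflect at the
#'   boundaries.
#' @param speed_mean,speed_sd Walking speed distribution (metres/frame).
#' @param turn_rate Per-frame probability of drawing a new heading/speed.
#' @param stature Stature scale: leg length `0.85 * stature`, torso
#'   `0.6 * stature` metres.
#' @param camera A [camera_geometry()] viewing the arena.
#' @param scale Image-to-real scale \eqn{\alpha_s} shared by the simulator
#'   and the derived scene homography.
#' @param px_noise Gaussian pixel noise standard deviation applied to every
#'   projected joint coordinate.
#' @param p_drop Independent per-joint dropout probability in `[0, 1]`.
#' @param occluders List of image rectangles `c(umin, vmin, umax, vmax)`;
#'   joints projected inside any of them are removed.
#' @param n_frames Number of simulated frames.
#' @param fps Nominal frame rate recorded in the scene config.
#' @param seed Mandatory integer seed; the whole scene is a deterministic
#'   function of the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5, arena = c(12, 10), speed_mean = 0.12,
                       speed_sd = 0.03, turn_rate = 0.02, stature = 1,
                       camera = camera_geometry(), scale = 1,
                       px_noise = 0, p_drop = 0, occluders = list(),
                       n_frames = 200, fps = 10, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility", call. = FALSE)
  stopifnot(n_subjects >= 1, all(arena > 0), speed_mean >= 0, speed_sd >= 0,
            turn_rate >= 0, turn_rate <= 1, p_drop >= 0, p_drop <= 1,
            px_noise >= 0, n_frames >= 1)
  structure(
    list(n_subjects = n_subjects, arena = as.numeric(arena),
         speed_mean = speed_mean, speed_sd = speed_sd, turn_rate = turn_rate,
         stature = stature, camera = camera, scale = scale,
         px_noise = px_noise, p_drop = p_drop, occluders = occluders,
         n_frames = as.integer(n_frames), fps = fps, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Structured occluders for the default camera view
#'
#' Two image rectangles emulating common occlusion patterns under the
#' default [camera_geometry()]: a full-height pillar in the middle of the
#' view (subjects passing behind it vanish entirely) and a horizontal band
#' at feet height (subjects behind it lose their feet joints, forcing the
#' torso fallback).
#'
#' @return List of `c(umin, vmin, umax, vmax)` rectangles for
#'   [sim_config()]'s `occluders`.
#' @export
standard_occluders <- function() {
  list(c(500, 0, 620, 960), c(0, 430, 1280, 470))
}

#' Simulate near-constant-velocity pedestrian trajectories
#'
#' Subjects start uniformly inside the arena with random headings and
#' Gaussian speeds; each frame they continue straight, occasionally
#' (`turn_rate`) redraw heading and speed, and reflect at the arena
#' boundaries. Deterministic given the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `frame`, `id`, `x`, `y`, `vx`, `vy`.
#' @export
simulate_trajectories <- function(cfg) {
  withr::with_seed(cfg$seed, simulate_trajectories_impl(cfg))
}

simulate_trajectories_impl <- function(cfg) {
  n <- cfg$n_subjects
  ax <- cfg$arena[1]; ay <- cfg$arena[2]
  margin <- min(0.5, ax / 4, ay / 4)
  x <- stats::runif(n, margin, ax - margin)
  y <- stats::runif(n, margin, ay - margin)
  draw_vel <- function(k) {
    th <- stats::runif(k, 0, 2 * pi)
    sp <- pmax(0, stats::rnorm(k, cfg$speed_mean, cfg$speed_sd))
    cbind(sp * cos(th), sp * sin(th))
  }
  vel <- draw_vel(n)
  out <- vector("list", cfg$n_frames)
  for (t in seq_len(cfg$n_frames)) {
    out[[t]] <- tibble::tibble(frame = t, id = seq_len(n), x = x, y = y,
                               vx = vel[, 1], vy = vel[, 2])
    turn <- stats::runif(n) < cfg$turn_rate
    if (any(turn)) vel[turn, ] <- draw_vel(sum(turn))
    x <- x + vel[, 1]; y <- y + vel[, 2]
    # reflect at the arena boundaries
    flip_x <- x < 0 | x > ax
    flip_y <- y < 0 | y > ay
    x <- pmin(pmax(x, -x), 2 * ax - pmax(x, -x))
    y <- pmin(pmax(y, -y), 2 * ay - pmax(y, -y))
    vel[flip_x, 1] <- -vel[flip_x, 1]
    vel[flip_y, 2] <- -vel[flip_y, 2]
  }
  dplyr::bind_rows(out)
}

# 25-joint stick figure: offsets along the constant-depth ground direction
# (column `d`, metres) and heights (column `z`, stature units)
skeleton_template <- function() {
  tibble::tribble(
    ~joint, ~d,     ~z,
    1L,     0,      1.55,   # nose
    2L,     0,      1.45,   # neck
    3L,     0.15,   1.40,   # r shoulder
    4L,     0.20,   1.15,   # r elbow
    5L,     0.22,   0.95,   # r wrist
    6L,    -0.15,   1.40,   # l shoulder
    7L,    -0.20,   1.15,   # l elbow
    8L,    -0.22,   0.95,   # l wrist
    9L,     0,      0.85,   # mid hip
    10L,    0.10,   0.85,   # r hip
    11L,    0.10,   0.425,  # r knee
    12L,    0.10,   0,      # r ankle
    13L,   -0.10,   0.85,   # l hip
    14L,   -0.10,   0.425,  # l knee
    15L,   -0.10,   0,      # l ankle
    16L,    0.03,   1.57,   # r eye
    17L,   -0.03,   1.57,   # l eye
    18L,    0.05,   1.55,   # r ear
    19L,   -0.05,   1.55,   # l ear
    20L,   -0.12,   0,      # l big toe
    21L,   -0.14,   0,      # l small toe
    22L,   -0.08,   0,      # l heel
    23L,    0.12,   0,      # r big toe
    24L,    0.14,   0,      # r small toe
    25L,    0.08,   0       # r heel
  )
}

# unit ground direction along which camera depth is constant
constant_depth_direction <- function(cam) {
  d <- c(-cam$R[3, 2], cam$R[3, 1])
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) return(c(1, 0))  # nadir view: any ground direction works
  d / nd
}

#' Render trajectories into noisy, occluded pose detections
#'
#' Builds the 25-joint stick figure above every ground-truth position,
#' projects all joints through the pinhole camera, adds Gaussian pixel
#' noise, then removes joints by independent dropout and by membership in
#' the structured occlusion rectangles. Subjects left with no joints in a
#' frame are omitted from it (a missed detection). Stochastic stages draw
#' from the configuration seed (offset so they do not replay the trajectory
#' draws).
#'
#' @param truth Trajectory tibble from [simulate_trajectories()].
#' @param cfg A [sim_config()].
#' @return Long pose tibble `frame`, `person`, `joint`, `u`, `v`.
#' @export
synthesize_poses <- function(truth, cfg) {
  withr::with_seed(cfg$seed + 1L, synthesize_poses_impl(truth, cfg))
}

synthesize_poses_impl <- function(truth, cfg) {
  tmpl <- skeleton_template()
  d <- constant_depth_direction(cfg$camera)
  nj <- nrow(tmpl)
  # world coordinates of every joint of every (frame, person)
  big <- truth[rep(seq_len(nrow(truth)), each = nj), c("frame", "id", "x", "y")]
  big$joint <- rep(tmpl$joint, times = nrow(truth))
  off <- rep(tmpl$d, times = nrow(truth))
  big$wx <- big$x + off * d[1]
  big$wy <- big$y + off * d[2]
  big$wz <- rep(tmpl$z, times = nrow(truth)) * cfg$stature
  px <- project_world_to_image(
    data.frame(x = big$wx, y = big$wy, z = big$wz), cfg$camera, cfg$scale
  )
  u <- px$u; v <- px$v
  if (cfg$px_noise > 0) {
    u <- u + stats::rnorm(length(u), 0, cfg$px_noise)
    v <- v + stats::rnorm(length(v), 0, cfg$px_noise)
  }
  keep <- rep(TRUE, length(u))
  if (cfg$p_drop > 0) keep <- stats::runif(length(u)) >= cfg$p_drop
  for (rect in cfg$occluders) {
    keep <- keep & !(u >= rect[1] & u <= rect[3] & v >= rect[2] & v <= rect[4])
  }
  tibble::tibble(frame = big$frame, person = big$id, joint = big$joint,
                 u = u, v = v)[keep, , drop = FALSE]
}

#' Simulate a complete ground-truthed scene
#'
#' Convenience wrapper: trajectories, pose detections, and the matching
#' [scene_config()] (ROI = projected arena corners, homography derived from
#' the simulated camera, density grid covering the arena with a 2 m pad).
#'
#' @param cfg A [sim_config()].
#' @param safety_distance Safety distance stored in the scene config.
#' @param map_resolution,cell_size Density-map bandwidth and grid cell
#'   (metres).
#' @return List of class `crowd_scene` with elements `poses`, `truth`,
#'   `scene`, `config`.
#' @export
simulate_scene <- function(cfg, safety_distance = 2, map_resolution = 1,
                           cell_size = 0.1) {
  truth <- simulate_trajectories(cfg)
  poses <- synthesize_poses(truth, cfg)
  scene <- scene_from_sim(cfg, safety_distance, map_resolution, cell_size)
  structure(list(poses = poses, truth = truth, scene = scene, config = cfg),
            class = "crowd_scene")
}

#' @rdname simulate_scene
#' @export
scene_from_sim <- function(cfg, safety_distance = 2, map_resolution = 1,
                           cell_size = 0.1) {
  ax <- cfg$arena[1]; ay <- cfg$arena[2]
  corners <- data.frame(x = c(0, ax, ax, 0), y = c(0, 0, ay, ay))
  scene_config(
    roi = as.matrix(project_world_to_image(cbind(corners, z = 0), cfg$camera,
                                           cfg$scale)),
    homography = homography_from_camera(cfg$camera, cfg$scale),
    scale = cfg$scale,
    safety_distance = safety_distance,
    map_resolution = map_resolution,
    cell_size = cell_size,
    xlim = c(-2, ax + 2), ylim = c(-2, ay + 2),
    fps = cfg$fps
  )
}

#' Script a scene with known violation timing
#'
#' Interpolates per-subject waypoints linearly into full trajectories, so
#' the ground-truth inter-personal distances -- and therefore the violation
#' intervals -- are known in closed form, then renders poses like
#' [simulate_scene()].
#'
#' @param waypoints Tibble with columns `id`, `frame`, `x`, `y`; each
#'   subject needs waypoints covering the frame range.
#' @param cfg A [sim_config()] providing camera, noise and frame count.
#' @return A `crowd_scene` list (see [simulate_scene()]).
#' @export
make_violation_scenario <- function(waypoints, cfg) {
  frames <- seq_len(cfg$n_frames)
  truth <- waypoints |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        frame = frames,
        x = stats::approx(df$frame, df$x, xout = frames, rule = 2)$y,
        y = stats::approx(df$frame, df$y, xout = frames, rule = 2)$y
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame, .data$id)
  truth$vx <- 0; truth$vy <- 0
  poses <- synthesize_poses(truth, cfg)
  scene <- scene_from_sim(cfg)
  structure(list(poses = poses, truth = truth, scene = scene, config = cfg),
            class = "crowd_scene")
}

#' Write a simulated scene to plain-text files
#'
#' Emits `poses.csv`, `truth.csv` and `scene.json` into `dir`, the same
#' formats the readers in the package consume.
#'
#' @param scene_sim A `crowd_scene` from [simulate_scene()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene_sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_poses(scene_sim$poses, file.path(dir, "poses.csv"))
  readr::write_csv(scene_sim$truth[c("frame", "id", "x", "y")],
                   file.path(dir, "truth.csv"))
  write_scene_config(scene_sim$scene, file.path(dir, "scene.json"))
  invisible(dir)
}
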