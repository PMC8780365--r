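test_that("trajectories are deterministic, bounded and speed-faithful", {
  cfg <- sim_config(n_subjects = 4, n_frames = 50, seed = 61)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$x >= 0 & t1$x <= cfg$arena[1]))
  expect_true(all(t1$y >= 0 & t1$y <= cfg$arena[2]))

  # zero speed: everyone stays put
  still <- simulate_trajectories(sim_config(n_subjects = 3, n_frames = 20,
                                            speed_mean = 0, speed_sd = 0, seed = 62))
  expect_equal(dplyr::n_distinct(still[c("id", "x", "y")]), 3)

  # empirical per-step displacement matches the configured speed
  cfg3 <- sim_config(n_subjects = 100, n_frames = 101, speed_mean = 0.12,
                     speed_sd = 0.02, turn_rate = 0, arena = c(400, 400),
                     seed = 63)
  tr <- simulate_trajectories(cfg3)
  step <- tr |>
    dplyr::arrange(.data$id, .data$frame) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(d = mean(sqrt(diff(x)^2 + diff(y)^2)))
  se <- 0.02 / sqrt(100)
  expect_lt(abs(mean(step$d) - 0.12), 3 * se)
})

test_that("noiseless rendering is exactly invertible by the localizer", {
  cfg <- sim_config(n_subjects = 4, n_frames = 20, seed = 64)
  truth <- simulate_trajectories(cfg)
  poses <- synthesize_poses(truth, cfg)
  loc <- localize_frames(poses)
  expect_true(all(loc$flag == 1L))
  ground_px <- project_world_to_image(cbind(truth[c("x", "y")], z = 0),
                                      cfg$camera, cfg$scale)
  key <- paste(truth$frame, truth$id)
  ord <- match(paste(loc$frame, loc$person), key)
  expect_lt(max(abs(loc$u - ground_px$u[ord])), 0.5)
  expect_lt(max(abs(loc$v - ground_px$v[ord])), 0.5)

  # and through the homography, top-view positions match the truth
  sc <- scene_from_sim(cfg)
  tv <- image_to_topview(loc[c("u", "v")], sc)
  expect_lt(max(abs(tv$x - truth$x[ord]), abs(tv$y - truth$y[ord])), 1e-3)
})

test_that("dropout and occlusion produce the documented failure modes", {
  cfg_all <- sim_config(n_subjects = 3, n_frames = 10, p_drop = 1, seed = 65)
  expect_equal(nrow(synthesize_poses(simulate_trajectories(cfg_all), cfg_all)), 0)

  # an occluder covering exactly the feet forces the torso fallback
  cfg <- sim_config(n_subjects = 1, n_frames = 5, speed_mean = 0, speed_sd = 0,
                    seed = 66)
  truth <- simulate_trajectories(cfg)
  clean <- synthesize_poses(truth, cfg)
  feet <- clean[clean$joint %in% c(12, 15, 20:25), ]
  knees_up <- clean[!clean$joint %in% c(11, 12, 14, 15, 20:25), ]
  band <- c(min(feet$u) - 1, min(feet$v) - 1, max(feet$u) + 1, max(feet$v) + 1)
  # the band must not clip the torso for the fallback to engage
  expect_gt(min(feet$v), max(knees_up$v))
  cfg_occ <- sim_config(n_subjects = 1, n_frames = 5, speed_mean = 0,
                        speed_sd = 0, occluders = list(band), seed = 66)
  occluded <- synthesize_poses(simulate_trajectories(cfg_occ), cfg_occ)
  loc <- localize_frames(occluded)
  expect_true(all(loc$flag_v == 2L))
  expect_true(all(loc$flag == 2L))
})

test_that("the share of feet-based flags falls as dropout rises", {
  frac_flag1 <- function(p_drop, seed) {
    cfg <- sim_config(n_subjects = 5, n_frames = 40, p_drop = p_drop, seed = seed)
    loc <- localize_frames(synthesize_poses(simulate_trajectories(cfg), cfg))
    if (nrow(loc) == 0) return(0)
    mean(loc$flag == 1L)
  }
  for (seed in 67:69) {
    f <- vapply(c(0, 0.5, 0.9), frac_flag1, double(1), seed = seed)
    expect_true(all(diff(f) <= 1e-9))
  }
})

test_that("scripted scenarios hit their closed-form violation switch points", {
  # two subjects converging from 4 m apart to 1 m over 31 frames; with
  # r = 2 the gap first reaches 2 m at frame 21
  wp <- tibble::tibble(id = c(1, 1, 2, 2), frame = c(1, 31, 1, 31),
                       x = c(4, 5.5, 8, 6.5), y = 5)
  cfg <- sim_config(n_subjects = 2, n_frames = 31, seed = 70)
  scn <- make_violation_scenario(wp, cfg)
  va <- violation_analytics(scn$truth[c("frame", "id", "x", "y")], r = 2,
                            n_frames = 31)
  expect_equal(va$frames$anomaly, c(rep(0L, 20), rep(1L, 11)))

  # parallel walkers at a fixed 3 m never violate r = 2
  wp2 <- tibble::tibble(id = c(1, 1, 2, 2), frame = c(1, 20, 1, 20),
                        x = c(2, 8, 2, 8), y = c(3, 3, 6, 6))
  scn2 <- make_violation_scenario(wp2, sim_config(n_subjects = 2, n_frames = 20,
                                                  seed = 71))
  va2 <- violation_analytics(scn2$truth[c("frame", "id", "x", "y")], r = 2,
                             n_frames = 20)
  expect_true(all(va2$frames$anomaly == 0L))

  # a three-subject cluster inside r yields all three pairs
  wp3 <- tibble::tibble(id = rep(1:3, each = 2), frame = rep(c(1, 5), 3),
                        x = rep(c(5, 5.5, 6), each = 2), y = rep(c(5, 5.8, 5), each = 2))
  scn3 <- make_violation_scenario(wp3, sim_config(n_subjects = 3, n_frames = 5,
                                                  seed = 72))
  va3 <- violation_analytics(scn3$truth[c("frame", "id", "x", "y")], r = 2,
                             n_frames = 5)
  expect_true(all(va3$frames$violations == 3))
})

test_that("identical configurations write bit-identical scene files", {
  cfg <- sim_config(n_subjects = 3, n_frames = 15, px_noise = 2, p_drop = 0.2,
                    seed = 73)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scene(simulate_scene(cfg), d1)
  write_scene(simulate_scene(cfg), d2)
  for (f in c("poses.csv", "truth.csv", "scene.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})
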