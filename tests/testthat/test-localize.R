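# literal transcription of the basic estimator, kept independent of the
# package implementation for the dual-route check
basic_oracle <- function(joint, u, v) {
  feet <- c(12, 15, 20, 21, 22, 23, 24, 25)
  if (length(joint) < 13 || !any(joint %in% feet)) return(c(NA_real_, NA_real_))
  core <- c(1, 2, 9)
  um <- if (any(joint %in% core)) mean(u[joint %in% core]) else (min(u) + max(u)) / 2
  vm <- mean(v[joint %in% feet])
  c(um, vm)
}

test_that("basic localization follows the feet-and-core-joint rules", {
  # 13 joints incl. both ankles at v = 200, nose/neck/midhip at u = 10/11/12
  p <- pose_tbl(c(1, 2, 9, 12, 15, 3, 4, 5, 6, 7, 8, 10, 11),
                u = c(10, 11, 12, 30, 40, 1, 1, 1, 1, 1, 1, 1, 1),
                v = c(5, 6, 7, 200, 200, 1, 1, 1, 1, 1, 1, 1, 1))
  res <- localize_frames(p, method = "basic")
  expect_equal(res$u, 11)
  expect_equal(res$v, 200)
  expect_equal(res$flag, 1L)

  # 12 present joints: below the minimum, undefined with flags 0
  p12 <- p[-1, ]
  res12 <- localize_frames(p12, method = "basic")
  expect_true(is.na(res12$u))
  expect_equal(res12$flag, 0L)

  # no core joints: mid-range of all horizontal coordinates
  p2 <- pose_tbl(c(3:8, 10:15, 20), u = c(0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 100, 50),
                 v = seq(13))
  res2 <- localize_frames(p2, method = "basic")
  expect_equal(res2$u, (0 + 100) / 2)
})

test_that("basic localization matches an independent literal transcription", {
  withr::with_seed(42, {
    for (k in 1:200) {
      p <- random_pose()
      res <- localize_frames(p, method = "basic")
      orc <- basic_oracle(p$joint, p$u, p$v)
      expect_equal(c(res$u, res$v), orc, tolerance = 1e-12)
    }
  })
})

test_that("proposed u-estimate averages the two feet when both are seen", {
  p <- pose_tbl(c(15, 20, 12, 23), u = c(100, 102, 110, 112), v = c(1, 1, 1, 1))
  res <- localize_frames(p)
  expect_equal(res$u, 106)
  expect_equal(res$flag_u, 1L)
  expect_equal(res$flag_v, 1L)
})

test_that("torso fallback extrapolates the ground below the hip", {
  p <- pose_tbl(c(2, 9), u = c(50, 50), v = c(100, 160))
  res <- localize_frames(p)
  expect_equal(res$v, 160 + (0.85 / 0.6) * 60)
  expect_equal(res$flag_v, 2L)
  expect_equal(res$flag, 2L)
  # the literally printed sign places it above the hip instead
  lit <- localize_frames(p, torso_sign = -1)
  expect_equal(lit$v, 160 + (0.85 / 0.6) * (100 - 160))
})

test_that("poses with no covered joints are unresolvable", {
  p <- pose_tbl(c(4, 5, 7, 8), u = 1:4, v = 1:4)  # wrists and elbows only
  res <- localize_frames(p)
  expect_true(is.na(res$u) && is.na(res$v))
  expect_equal(c(res$flag_u, res$flag_v, res$flag), c(0L, 0L, 0L))
})

test_that("every u-case of the ordered fallback list is reachable", {
  u_of <- function(joint, u) {
    localize_frames(pose_tbl(joint, u, v = rep(1, length(u))))
  }
  # case 1: both feet
  expect_equal(u_of(c(15, 12), c(10, 20))$flag_u, 1L)
  # case 2: left foot + right knee
  r <- u_of(c(15, 20, 11), c(10, 14, 30)); expect_equal(r$u, (12 + 30) / 2); expect_equal(r$flag_u, 2L)
  # case 3: left knee + right foot
  r <- u_of(c(14, 12, 23), c(8, 20, 24)); expect_equal(r$u, (8 + 22) / 2)
  # case 4: both knees
  r <- u_of(c(11, 14), c(10, 30)); expect_equal(r$u, 20)
  # case 5: right hip + left knee
  r <- u_of(c(10, 14), c(12, 28)); expect_equal(r$u, 20)
  # case 6: right knee + left hip
  r <- u_of(c(11, 13), c(14, 26)); expect_equal(r$u, 20)
  # case 7: both hips
  r <- u_of(c(10, 13), c(16, 24)); expect_equal(r$u, 20)
  # case 8: torso (neck + midhip)
  r <- u_of(c(2, 9), c(18, 22)); expect_equal(r$u, 20); expect_equal(r$flag_u, 2L)
  # case 9: any single-side feet
  r <- u_of(c(20, 21), c(10, 14)); expect_equal(r$u, 12); expect_equal(r$flag_u, 2L)
  # case 10: nothing covered
  r <- u_of(c(1, 4), c(1, 2)); expect_equal(r$flag_u, 0L)
})

test_that("u-cases resolve in printed order (first match wins)", {
  # left foot + right knee satisfies both case 2 and the any-feet case 9;
  # the case-2 average must win over the feet-only mean
  p <- pose_tbl(c(15, 11), u = c(10, 50), v = c(1, 1))
  res <- localize_frames(p)
  expect_equal(res$u, 30)   # case 2; case 9 would give 10
  # knees + hips present: case 4 (knees) precedes case 7 (hips)
  p2 <- pose_tbl(c(11, 14, 10, 13), u = c(10, 20, 100, 200), v = rep(1, 4))
  expect_equal(localize_frames(p2)$u, 15)
})

test_that("overall flag combines coordinate flags exhaustively", {
  vals <- c(NA_integer_, 0L, 1L, 2L)
  for (fu in vals) for (fv in vals) {
    expected <- if (is.na(fu) || is.na(fv)) NA_integer_
      else if (fu == 0L || fv == 0L) 0L
      else if (fu == 1L && fv == 1L) 1L
      else 2L
    expect_identical(flag_overall(fu, fv), expected)
  }
})

test_that("proposed localization dominates the basic method", {
  withr::with_seed(7, {
    for (k in 1:100) {
      p <- random_pose()
      b <- localize_frames(p, method = "basic")
      pr <- localize_frames(p)
      if (!is.na(b$u)) expect_false(is.na(pr$u))
      if (!is.na(b$v)) expect_false(is.na(pr$v))
    }
  })
})

test_that("mirroring the pose mirrors u and leaves v and flags unchanged", {
  W <- 1280
  withr::with_seed(8, {
    for (k in 1:50) {
      p <- random_pose()
      res <- localize_frames(p)
      pm <- p; pm$u <- W - pm$u
      resm <- localize_frames(pm)
      if (!is.na(res$u)) expect_equal(resm$u, W - res$u, tolerance = 1e-9)
      expect_equal(resm$v, res$v)
      expect_identical(resm[c("flag_u", "flag_v", "flag")],
                       res[c("flag_u", "flag_v", "flag")])
    }
  })
})

test_that("ROI filtering keeps inside and undefined positions, drops outside", {
  roi <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  df <- tibble::tibble(u = c(5, 50, NA), v = c(5, 50, NA), flag = c(1L, 1L, 0L))
  out <- filter_roi(df, roi)
  expect_equal(nrow(out), 2)
  expect_true(any(is.na(out$u)))

  # non-convex polygon against an independent winding-number oracle
  poly <- cbind(c(0, 4, 4, 2, 2, 0), c(0, 0, 4, 4, 2, 2))
  withr::with_seed(9, {
    px <- runif(500, -1, 5); py <- runif(500, -1, 5)
    mine <- point_in_polygon(px, py, poly)
    orc <- vapply(seq_along(px), function(i) winding_inside(px[i], py[i], poly),
                  logical(1))
    expect_identical(mine, orc)
  })
})
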