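test_that("pairwise distances are plain Euclidean metres", {
  pos <- tibble::tibble(id = 1:2, x = c(0, 3), y = c(0, 4))
  d <- pairwise_distances(pos)
  expect_equal(d$distance, 5)
  expect_equal(nrow(pairwise_distances(pos[1, ])), 0)

  withr::with_seed(41, {
    pos <- tibble::tibble(id = 1:50, x = runif(50, 0, 20), y = runif(50, 0, 20))
    d <- pairwise_distances(pos)
    # brute force over all pairs
    for (k in sample(nrow(d), 40)) {
      i <- match(d$id_i[k], pos$id); j <- match(d$id_j[k], pos$id)
      expect_equal(d$distance[k],
                   sqrt((pos$x[i] - pos$x[j])^2 + (pos$y[i] - pos$y[j])^2))
    }
    expect_equal(nrow(d), choose(50, 2))
  })
})

test_that("violation counting is inclusive at the safety distance", {
  # three collinear subjects spaced exactly r: pairs 1-2 and 2-3 violate
  pos <- tibble::tibble(id = 1:3, x = c(0, 2, 4), y = 0)
  cv <- count_violations(pos, r = 2)
  expect_equal(cv$V, 2)
  expect_equal(cv$psi$psi, c(1L, 1L, 1L))

  far <- tibble::tibble(id = 1:3, x = c(0, 10, 20), y = 0)
  cv2 <- count_violations(far, r = 2)
  expect_equal(cv2$V, 0)
  expect_equal(anomaly_label(cv2$V), 0L)

  withr::with_seed(42, {
    for (k in 1:50) {
      n <- sample(2:8, 1)
      pos <- tibble::tibble(id = seq_len(n), x = runif(n, 0, 6), y = runif(n, 0, 6))
      r <- runif(1, 0.5, 3)
      cv <- count_violations(pos, r)
      ref <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (sqrt((pos$x[i] - pos$x[j])^2 + (pos$y[i] - pos$y[j])^2) <= r) ref <- ref + 1
      }
      expect_equal(cv$V, ref)
    }
  })
})

test_that("anomaly labels flag any positive violation count", {
  expect_identical(anomaly_label(c(0, 1, 7)), c(0L, 1L, 1L))
})

test_that("instantaneous maps are unit-mass Gaussian mixtures", {
  sc <- flat_scene(extent = 12, map_resolution = 1, cell_size = 0.1)
  one <- instantaneous_map(tibble::tibble(x = 6, y = 6), sc)
  expect_equal(grid_mass(one), 1, tolerance = 0.01)
  # peak at the subject's cell
  peak <- which(one$values == max(one$values), arr.ind = TRUE)
  expect_equal(one$x[peak[1, 1]], 6, tolerance = 2 * sc$cell_size)
  expect_equal(one$y[peak[1, 2]], 6, tolerance = 2 * sc$cell_size)

  # no violators: the crowd map is identically zero
  pos <- tibble::tibble(x = c(2, 9), y = c(2, 9), psi = c(0, 0))
  cdm <- instantaneous_map(pos, sc, weight = "psi")
  expect_true(all(cdm$values == 0))

  # empty frame: all-zero grid
  expect_true(all(instantaneous_map(pos[0, ], sc)$values == 0))
})

test_that("maps are translation-equivariant up to grid snapping", {
  sc <- flat_scene(extent = 20, map_resolution = 1, cell_size = 0.5)
  a <- instantaneous_map(tibble::tibble(x = 5, y = 5), sc)
  b <- instantaneous_map(tibble::tibble(x = 8, y = 6.5), sc)  # shift by (3, 1.5)
  shift_cells <- c(3, 1.5) / sc$cell_size
  nx <- length(a$x); ny <- length(a$y)
  expect_equal(a$values[1:(nx - 6), 1:(ny - 3)],
               b$values[7:nx, 4:ny], tolerance = 1e-12)
})

test_that("averaged maps equal the online running mean and dilute with empty frames", {
  sc <- flat_scene(extent = 10, map_resolution = 1, cell_size = 0.25)
  subj <- tibble::tibble(frame = rep(1:4, each = 2), id = rep(1:2, 4),
                         x = rep(c(3, 7), 4), y = rep(c(3, 7), 4))
  avg <- averaged_density_map(subj, sc, n_frames = 4)
  single <- instantaneous_map(subj[subj$frame == 1, ], sc)
  expect_equal(avg$values, single$values, tolerance = 1e-12)

  # online accumulation equals the batch average
  acc <- instantaneous_map(subj[subj$frame == 1, ], sc)
  for (t in 2:4) acc <- accumulate_map(acc, instantaneous_map(subj[subj$frame == t, ], sc), t)
  expect_equal(acc$values, avg$values, tolerance = 1e-12)

  # an empty frame contributes a zero map and dilutes the average
  avg5 <- averaged_density_map(subj, sc, n_frames = 5)
  expect_equal(avg5$values, avg$values * 4 / 5, tolerance = 1e-12)

  # frame order does not matter
  perm <- subj[order(-subj$frame), ]
  expect_equal(averaged_density_map(perm, sc, n_frames = 4)$values, avg$values)
})

test_that("the crowd map never exceeds the occupancy map", {
  sc <- flat_scene(extent = 10, map_resolution = 1, cell_size = 0.25)
  withr::with_seed(43, {
    subj <- tibble::tibble(frame = rep(1:5, each = 3), id = rep(1:3, 5),
                           x = runif(15, 0, 10), y = runif(15, 0, 10),
                           violating = sample(0:1, 15, replace = TRUE))
  })
  odm <- averaged_density_map(subj, sc, n_frames = 5)
  cdm <- averaged_density_map(subj, sc, weight = "violating", n_frames = 5)
  expect_true(all(cdm$values <= odm$values + 1e-12))
})

test_that("region segmentation keeps half the mass with at most one extra cell", {
  sc <- flat_scene(extent = 10, map_resolution = 1, cell_size = 0.5)
  # uniform map: exactly the smallest prefix of tied cells
  uni <- new_grid_for_test(sc, value = 1)
  reg <- threshold_cdm(uni)
  share <- 1 / length(uni$values)
  expect_gte(attr(reg, "retained"), 0.5)
  expect_lte(attr(reg, "retained"), 0.5 + share)

  # single Gaussian: a centred compact region holding ~50% of the mass
  g <- instantaneous_map(tibble::tibble(x = 5, y = 5), sc)
  rg <- threshold_cdm(g)
  frac <- sum(g$values[rg$values > 0]) / sum(g$values)
  expect_gte(frac, 0.5)
  expect_lte(frac, 0.5 + max(g$values) / sum(g$values))
  peak <- which(g$values == max(g$values), arr.ind = TRUE)
  expect_true(all(rg$values[peak] == 1))

  # all-zero map: empty region
  zero <- instantaneous_map(tibble::tibble(x = double(), y = double()), sc)
  expect_true(all(threshold_cdm(zero)$values == 0))
})

test_that("per-frame analytics include empty frames and an idempotent mask", {
  subj <- tibble::tibble(frame = c(1, 1, 3, 3), id = c(1, 2, 1, 2),
                         x = c(0, 1, 0, 10), y = 0)
  va <- violation_analytics(subj, r = 2, n_frames = 4)
  expect_equal(va$frames$frame, 1:4)
  expect_equal(va$frames$n, c(2, 0, 2, 0))
  expect_equal(va$frames$violations, c(1, 0, 0, 0))
  expect_equal(va$frames$anomaly, c(1L, 0L, 0L, 0L))
  # mask recomputation from the pair set agrees
  pairs1 <- va$pairs[va$pairs$frame == 1 & va$pairs$violating, ]
  ids <- unique(c(pairs1$id_i, pairs1$id_j))
  expect_setequal(va$subjects$id[va$subjects$frame == 1 & va$subjects$violating == 1],
                  ids)
  # subject order does not change the count
  va2 <- violation_analytics(subj[order(-subj$id), ], r = 2, n_frames = 4)
  expect_equal(va2$frames$violations, va$frames$violations)
})
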