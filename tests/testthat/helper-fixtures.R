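# small constructors shared across the suite

pose_tbl <- function(joint, u, v, frame = 1L, person = 1L) {
  tibble::tibble(frame = frame, person = person, joint = as.integer(joint),
                 u = u, v = v)
}

# scene with an identity homography: pixels are metres
flat_scene <- function(extent = 100, ...) {
  scene_config(
    roi = cbind(c(0, extent, extent, 0), c(0, 0, extent, extent)),
    homography = diag(3), xlim = c(0, extent), ylim = c(0, extent), ...
  )
}

new_grid_for_test <- function(scene, value = 1) {
  g <- instantaneous_map(tibble::tibble(x = double(), y = double()), scene)
  g$values[] <- value
  g
}

random_pose <- function(n_present = NULL) {
  k <- if (is.null(n_present)) sample(1:25, 1) else n_present
  j <- sort(sample(1:25, k))
  pose_tbl(j, u = stats::runif(k, 0, 1280), v = stats::runif(k, 0, 960))
}

# independent winding-number (angle-sum) point-in-polygon oracle
winding_inside <- function(x, y, poly) {
  vx <- poly[, 1] - x; vy <- poly[, 2] - y
  n <- nrow(poly)
  ang <- 0
  on_boundary <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- c(vx[i], vy[i]); b <- c(vx[j], vy[j])
    cr <- a[1] * b[2] - a[2] * b[1]
    dt <- a[1] * b[1] + a[2] * b[2]
    if (abs(cr) < 1e-12 && dt <= 1e-12) on_boundary <- TRUE
    ang <- ang + atan2(cr, dt)
  }
  on_boundary || abs(ang) > pi
}

# exhaustive assignment oracle: maximize feasible matches, then minimize
# total cost, by recursive enumeration (rows pick an unused column or none)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(matches = -1L, total = Inf, sol = rep(NA_integer_, n))
  recurse <- function(i, used, sol, matches, total) {
    if (i > n) {
      if (matches > best$matches ||
          (matches == best$matches && total < best$total - 1e-12)) {
        best <<- list(matches = matches, total = total, sol = sol)
      }
      return(invisible())
    }
    recurse(i + 1L, used, sol, matches, total)  # leave row i unassigned
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <- TRUE; sol[i] <- j
        recurse(i + 1L, used, sol, matches + 1L, total + cost[i, j])
        used[j] <- FALSE; sol[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, m), rep(NA_integer_, n), 0L, 0)
  best
}

assignment_total <- function(cost, sol) {
  idx <- which(!is.na(sol))
  sum(cost[cbind(idx, sol[idx])])
}
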