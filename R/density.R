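#' Occupancy and crowd density maps
#'
#' A density grid discretizes the top-view extent of the scene into square
#' cells; the instantaneous map of a frame places a unit-mass isotropic 2D
#' Gaussian kernel of bandwidth `map_resolution` at each subject's ground
#' position, weights it (1 for the occupancy map, the violation mask `psi`
#' for the crowd map), and averages over the `n` subjects present. Frames
#' without subjects contribute all-zero maps. The averaged map is the
#' arithmetic mean over frames 1..T.
#'
#' Grids are evaluated at cell centres and stored as a matrix with rows
#' indexing x and columns indexing y.
#'
#' @name density-maps
NULL

new_density_grid <- function(scene, values = NULL) {
  xc <- seq(scene$xlim[1] + scene$cell_size / 2, scene$xlim[2], by = scene$cell_size)
  yc <- seq(scene$ylim[1] + scene$cell_size / 2, scene$ylim[2], by = scene$cell_size)
  if (is.null(values)) values <- matrix(0, length(xc), length(yc))
  stopifnot(nrow(values) == length(xc), ncol(values) == length(yc))
  structure(list(values = values, x = xc, y = yc, cell = scene$cell_size,
                 origin = c(scene$xlim[1], scene$ylim[1])),
            class = "density_grid")
}

#' @describeIn density-maps Instantaneous density map of one frame.
#' @param positions Tibble with columns `x`, `y` (metres); optionally a
#'   weight column named by `weight`.
#' @param scene A [scene_config()] (provides extent, cell size, bandwidth).
#' @param weight Name of a 0/1 (or general non-negative) weight column, or
#'   `NULL` for unit weights (occupancy map).
#' @export
instantaneous_map <- function(positions, scene, weight = NULL) {
  grid <- new_density_grid(scene)
  n <- nrow(positions)
  if (n == 0) return(grid)
  w <- if (is.null(weight)) rep(1, n) else positions[[weight]]
  delta <- scene$map_resolution
  vals <- grid$values
  for (i in seq_len(n)) {
    if (w[i] == 0) next
    vals <- vals + w[i] * outer(stats::dnorm(grid$x, positions$x[i], delta),
                                stats::dnorm(grid$y, positions$y[i], delta))
  }
  grid$values <- vals / n
  grid
}

#' @describeIn density-maps Time-averaged map over a subject stream.
#'   `subjects` holds all frames' positions; frames 1..`n_frames` with no
#'   rows count as zero maps in the average (so the 1/T semantics of the
#'   running mean is preserved).
#' @param subjects Tibble with columns `frame`, `x`, `y` and optionally the
#'   weight column.
#' @param n_frames Number of frames averaged over.
#' @export
averaged_density_map <- function(subjects, scene, weight = NULL,
                                 n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(subjects)) max(subjects$frame) else 0L
  }
  stopifnot(n_frames >= 1)
  grid <- new_density_grid(scene)
  # fold the per-frame 1/n and the frame average 1/T into per-row weights
  df <- subjects
  df$..w <- if (is.null(weight)) 1 else df[[weight]]
  nper <- table(factor(df$frame, levels = seq_len(n_frames)))
  df$..w <- df$..w / as.numeric(nper[as.character(df$frame)])
  delta <- scene$map_resolution
  vals <- grid$values
  for (i in seq_len(nrow(df))) {
    if (df$..w[i] == 0) next
    vals <- vals + df$..w[i] * outer(stats::dnorm(grid$x, df$x[i], delta),
                                     stats::dnorm(grid$y, df$y[i], delta))
  }
  grid$values <- vals / n_frames
  grid
}

#' @describeIn density-maps Online update of a running average map:
#'   `avg + (new - avg) / t` after `t` frames.
#' @param avg,new `density_grid` objects (the running average and the new
#'   instantaneous map).
#' @param t Frame count including the new frame.
#' @export
accumulate_map <- function(avg, new, t) {
  stopifnot(t >= 1, all(dim(avg$values) == dim(new$values)))
  avg$values <- avg$values + (new$values - avg$values) / t
  avg
}

#' Total kernel mass of a density grid
#'
#' Sum of cell values times the cell area; 1 for a fully contained
#' unit-weight single-subject instantaneous map.
#'
#' @param grid A `density_grid`.
#' @return Scalar mass.
#' @export
grid_mass <- function(grid) sum(grid$values) * grid$cell^2

#' Segment overcrowded regions from a crowd density map
#'
#' Cells are ranked by value (stable descending order) and the smallest
#' prefix whose cumulative mass reaches 50% of the map's total mass is
#' retained; the threshold `gamma` is the value of the last retained cell.
#' An all-zero map yields an empty region.
#'
#' @param grid A `density_grid` (typically the averaged crowd density map).
#' @param energy Fraction of the total mass to retain (default 0.5).
#' @return A `density_grid` of 0/1 indicators with attributes `gamma` (the
#'   threshold) and `retained` (the retained mass fraction).
#' @export
threshold_cdm <- function(grid, energy = 0.5) {
  v <- as.vector(grid$values)
  total <- sum(v)
  out <- grid
  if (total <= 0) {
    out$values[] <- 0
    attr(out, "gamma") <- NA_real_
    attr(out, "retained") <- 0
    return(out)
  }
  ord <- order(v, decreasing = TRUE)
  k <- which(cumsum(v[ord]) >= energy * total)[1]
  sel <- ord[seq_len(k)]
  ind <- numeric(length(v))
  ind[sel] <- 1
  out$values <- matrix(ind, nrow(grid$values), ncol(grid$values))
  attr(out, "gamma") <- v[ord[k]]
  attr(out, "retained") <- sum(v[sel]) / total
  out
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>", nrow(x$values), "x", ncol(x$values), "cells of",
      x$cell, "m; mass", format(grid_mass(x), digits = 4), "\n")
  invisible(x)
}

#' Convert a density grid to a tidy tibble
#'
#' @param x A `density_grid`.
#' @param ... Unused.
#' @return Tibble with columns `x`, `y`, `value` (one row per cell).
#' @export
as_tibble.density_grid <- function(x, ...) {
  xc <- x$x; yc <- x$y; vals <- as.vector(x$values)
  tibble::tibble(
    x = rep(xc, times = length(yc)),
    y = rep(yc, each = length(xc)),
    value = vals
  )
}

#' Write or read a density grid as delimited text
#'
#' A 3-line `#`-prefixed header records the origin, cell size and shape,
#' followed by the value matrix (rows = x cells) as comma-separated text.
#'
#' @param grid A `density_grid`.
#' @param path File path.
#' @export
write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# origin: ", grid$origin[1], ",", grid$origin[2]),
    paste0("# cell: ", grid$cell),
    paste0("# shape: ", nrow(grid$values), ",", ncol(grid$values))
  ), con)
  utils::write.table(grid$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  hdr <- readLines(path, n = 3)
  num <- function(line) as.numeric(strsplit(sub("^# [a-z]+: ", "", line), ",")[[1]])
  origin <- num(hdr[1]); cell <- num(hdr[2]); shape <- num(hdr[3])
  vals <- as.matrix(utils::read.table(path, sep = ",", skip = 3))
  dimnames(vals) <- NULL
  stopifnot(all(dim(vals) == shape))
  xc <- origin[1] + cell * (seq_len(shape[1]) - 0.5)
  yc <- origin[2] + cell * (seq_len(shape[2]) - 0.5)
  structure(list(values = vals, x = xc, y = yc, cell = cell, origin = origin),
            class = "density_grid")
}
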