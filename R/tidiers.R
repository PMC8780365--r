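#' Tidy a pipeline run
#'
#' @param x A `crowd_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-frame result tibble (`frame`, `id`, `x`, `y`, `flag`,
#'   `violating`).
#' @export
tidy.crowd_run <- function(x, ...) x$results

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.crowd_run
#' @return One-row tibble: frame count, distinct subjects/tracks, total
#'   violating pairs, anomaly-frame fraction, and the retained mass of the
#'   overcrowding region.
#' @export
glance.crowd_run <- function(x, ...) {
  tibble::tibble(
    n_frames = x$settings$n_frames,
    n_subjects = dplyr::n_distinct(x$results$id),
    mean_per_frame = mean(x$series$n),
    violation_pairs = sum(x$series$violations),
    anomaly_rate = mean(x$series$anomaly),
    region_cells = sum(x$region$values > 0),
    tracking = x$settings$tracking,
    r = x$settings$r
  )
}

#' @export
tidy.density_grid <- function(x, ...) as_tibble.density_grid(x)
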