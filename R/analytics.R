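#' Pairwise inter-personal distances
#'
#' All `i < j` Euclidean distances between the supplied top-view positions,
#' in metres.
#'
#' @param positions Tibble with columns `id`, `x`, `y`.
#' @return Tibble with columns `id_i`, `id_j`, `distance`.
#' @export
pairwise_distances <- function(positions) {
  n <- nrow(positions)
  if (n < 2) {
    return(tibble::tibble(id_i = positions$id[0], id_j = positions$id[0],
                          distance = double()))
  }
  d <- stats::dist(cbind(positions$x, positions$y))
  idx <- utils::combn(n, 2)
  tibble::tibble(
    id_i = positions$id[idx[1, ]],
    id_j = positions$id[idx[2, ]],
    distance = as.numeric(d)
  )
}

#' Count social-distance violations in one frame
#'
#' A pair violates when its distance is at or below the safety distance `r`
#' (inclusive). Returns the pair count `V`, the violating pairs, and the
#' per-subject binary mask `psi` (1 when the subject belongs to at least one
#' violating pair).
#'
#' @param positions Tibble with columns `id`, `x`, `y`.
#' @param r Safety distance in metres.
#' @return List with elements `V` (integer), `pairs` (tibble `id_i`, `id_j`,
#'   `distance`, `violating`), and `psi` (tibble `id`, `psi`).
#' @export
count_violations <- function(positions, r) {
  stopifnot(r > 0)
  pairs <- pairwise_distances(positions)
  pairs$violating <- pairs$distance <= r
  viol_ids <- unique(c(pairs$id_i[pairs$violating], pairs$id_j[pairs$violating]))
  list(
    V = sum(pairs$violating),
    pairs = pairs,
    psi = tibble::tibble(id = positions$id,
                         psi = as.integer(positions$id %in% viol_ids))
  )
}

#' Binary anomaly label from a violation count
#'
#' @param V Integer vector of per-frame violation counts.
#' @return Integer vector: 1 where `V > 0`, else 0.
#' @export
anomaly_label <- function(V) as.integer(V > 0)

#' Per-frame violation analytics over a tracked position stream
#'
#' Applies [count_violations()] to every frame, including frames with no
#' reported subjects (which yield zero counts), and derives the binary
#' anomaly series.
#'
#' @param subjects Tibble with columns `frame`, `id`, `x`, `y`.
#' @param r Safety distance in metres.
#' @param n_frames Total number of frames (defaults to the largest index
#'   present); frames 1..n_frames all appear in the output.
#' @return List of tibbles: `frames` (`frame`, `n`, `violations`,
#'   `violators`, `anomaly`), `pairs` (per-frame pair table), and `subjects`
#'   (input plus the `violating` mask).
#' @export
violation_analytics <- function(subjects, r, n_frames = NULL) {
  stopifnot(all(c("frame", "id", "x", "y") %in% names(subjects)))
  if (is.null(n_frames)) {
    n_frames <- if (nrow(subjects)) max(subjects$frame) else 0L
  }
  by_frame <- split(subjects, factor(subjects$frame, levels = seq_len(n_frames)))
  per <- purrr::imap(by_frame, function(df, fr) {
    fr <- as.integer(fr)
    cv <- count_violations(df, r)
    list(
      frame = tibble::tibble(frame = fr, n = nrow(df), violations = cv$V,
                             violators = sum(cv$psi$psi), anomaly = anomaly_label(cv$V)),
      pairs = dplyr::mutate(cv$pairs, frame = fr, .before = 1),
      subjects = dplyr::mutate(df, violating = cv$psi$psi[match(df$id, cv$psi$id)])
    )
  })
  list(
    frames = dplyr::bind_rows(purrr::map(per, "frame")),
    pairs = dplyr::bind_rows(purrr::map(per, "pairs")),
    subjects = dplyr::bind_rows(purrr::map(per, "subjects"))
  )
}
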