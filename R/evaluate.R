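#' Person detection rate
#'
#' `PDR = 1 - mean(|N_t - Nhat_t| / (N_t + 1))` over frames; 1 when the
#' estimated per-frame person counts match the true counts everywhere.
#'
#' @param n_true,n_est Equal-length integer vectors of per-frame counts.
#' @return Scalar in (-Inf, 1].
#' @export
pdr <- function(n_true, n_est) {
  stopifnot(length(n_true) == length(n_est))
  1 - mean(abs(n_true - n_est) / (n_true + 1))
}

#' Violations count rate
#'
#' `VCR = 1 - mean(|V_t - Vhat_t| / (V_t + 1))` over frames.
#'
#' @param v_true,v_est Equal-length integer vectors of per-frame violation
#'   counts.
#' @return Scalar in (-Inf, 1].
#' @export
vcr <- function(v_true, v_est) {
  stopifnot(length(v_true) == length(v_est))
  1 - mean(abs(v_true - v_est) / (v_true + 1))
}

#' Localization relative error
#'
#' Per frame, estimated positions are associated with true positions by the
#' optimal (Munkres) assignment on Euclidean distance; the frame term is the
#' mean relative error `||p - phat|| / ||p||` over matched pairs plus a
#' count-mismatch penalty: `N_t` when no estimate exists, `Nhat_t` when no
#' truth exists, `|N_t - Nhat_t| / N_t` otherwise (0 when both are empty).
#' The reported error is the mean over frames. A small `eps` guards the
#' relative-error denominator for subjects at the world origin.
#'
#' @param truth Tibble with columns `frame`, `id`, `x`, `y` (metres).
#' @param est Tibble with columns `frame`, `x`, `y` (any id column is
#'   ignored; association is purely geometric).
#' @param n_frames Frames 1..n_frames are evaluated (default: largest frame
#'   index in either input).
#' @param eps Denominator guard in metres.
#' @return Scalar mean relative error (unitless).
#' @export
localization_error <- function(truth, est, n_frames = NULL, eps = 1e-9) {
  if (is.null(n_frames)) {
    n_frames <- max(c(truth$frame, est$frame, 0L))
  }
  tr <- split(truth, factor(truth$frame, levels = seq_len(n_frames)))
  es <- split(est, factor(est$frame, levels = seq_len(n_frames)))
  terms <- vapply(seq_len(n_frames), function(t) {
    a <- tr[[t]]; b <- es[[t]]
    nt <- nrow(a); ne <- nrow(b)
    if (nt == 0 && ne == 0) return(0)
    if (ne == 0) return(nt)
    if (nt == 0) return(ne)
    D <- outer(seq_len(ne), seq_len(nt), function(i, j) {
      sqrt((b$x[i] - a$x[j])^2 + (b$y[i] - a$y[j])^2)
    })
    match_col <- assign_detections(D)
    matched <- which(!is.na(match_col))
    rel <- vapply(matched, function(i) {
      j <- match_col[i]
      D[i, j] / (sqrt(a$x[j]^2 + a$y[j]^2) + eps)
    }, double(1))
    mean(rel) + abs(nt - ne) / nt
  }, double(1))
  mean(terms)
}

#' Binary violation-detection classification metrics
#'
#' Confusion-matrix accuracy, precision, recall and F1 of the predicted
#' anomaly series against the true one.
#'
#' @param s_true,s_pred Equal-length binary (0/1) vectors.
#' @return One-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
violation_classification <- function(s_true, s_pred) {
  stopifnot(length(s_true) == length(s_pred))
  tp <- sum(s_true == 1 & s_pred == 1)
  tn <- sum(s_true == 0 & s_pred == 0)
  fp <- sum(s_true == 0 & s_pred == 1)
  fn <- sum(s_true == 1 & s_pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    accuracy = (tp + tn) / length(s_true),
    precision = precision, recall = recall, f1 = f1
  )
}

#' Agreement between two averaged crowd density maps
#'
#' Pearson correlation over the flattened cells plus the intersection-over-
#' union of the 50%-mass thresholded regions (cell-count ratio). A map with
#' zero variance yields `NA` correlation with a warning. Two empty regions
#' have IOU 1 by convention (identical segmentations).
#'
#' @param map_true,map_pred `density_grid` objects on the same geometry.
#' @return One-row tibble with columns `corr`, `iou`.
#' @export
map_agreement <- function(map_true, map_pred) {
  stopifnot(all(dim(map_true$values) == dim(map_pred$values)))
  a <- as.vector(map_true$values); b <- as.vector(map_pred$values)
  corr <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance density map; correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(a, b)
  }
  ra <- threshold_cdm(map_true)$values > 0
  rb <- threshold_cdm(map_pred)$values > 0
  uni <- sum(ra | rb)
  iou <- if (uni == 0) 1 else sum(ra & rb) / uni
  tibble::tibble(corr = corr, iou = iou)
}
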