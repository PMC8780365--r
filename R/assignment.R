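#' Optimal linear assignment (Munkres / shortest augmenting path)
#'
#' Solves the rectangular min-cost one-to-one assignment problem with the
#' Jonker-Volgenant shortest-augmenting-path algorithm (O(n^3)). Entries of
#' `Inf` mark infeasible (gated) pairs: the solver first maximizes the
#' number of feasible matches, then minimizes their total cost, and reports
#' everything else as unassigned.
#'
#' @param cost Numeric matrix (rows = detections, columns = tracks); `Inf`
#'   entries are infeasible.
#' @return Integer vector of length `nrow(cost)`: the column matched to each
#'   row, `NA` where the row is unassigned.
#' @examples
#' assign_detections(rbind(c(1, 10), c(10, 1)))
#' @export
assign_detections <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  if (any(is.na(cost) & !is.infinite(cost))) {
    stop("`cost` must not contain NA; use Inf for infeasible pairs", call. = FALSE)
  }
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0) return(rep(NA_integer_, n))
  big <- (max(abs(finite)) + 1) * (max(n, m) + 1) * 8
  k <- max(n, m)
  # pad to square; dummy rows/columns cost 0 so they absorb the unmatched
  C <- matrix(0, k, k)
  C[seq_len(n), seq_len(m)] <- pmin(cost, big)
  sol <- lap_square(C)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && is.finite(cost[i, j])) out[i] <- j
  }
  out
}

# square LAP by shortest augmenting path with dual potentials
lap_square <- function(C) {
  n <- nrow(C)
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1)        # column potentials, v[1] is the virtual column 0
  p <- integer(n + 1)        # p[j + 1]: row currently matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- C[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[p[j + 1]] <- j
  out
}
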