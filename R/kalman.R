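#' Constant-velocity Kalman filter primitives
#'
#' The state is `x = [x, x_dot, y, y_dot]` in metres and metres/frame. The
#' transition is block-diagonal constant velocity with a unit frame step and
#' the process noise follows the discrete white-acceleration model
#' `q * [[1/3, 1/2], [1/2, 1]]` per axis. Measurements are the two position
#' components with isotropic variance `sigma_sq` chosen from the detection's
#' quality flag.
#'
#' @name kalman
NULL

#' @describeIn kalman Kalman filter state: 4-state mean and 4x4 covariance.
#' @param x Numeric length-4 state mean.
#' @param P 4x4 covariance matrix (symmetric positive semi-definite).
#' @export
kf_state <- function(x, P) {
  x <- as.numeric(x)
  stopifnot(length(x) == 4, all(dim(P) == c(4, 4)))
  structure(list(x = x, P = (P + t(P)) / 2), class = "kf_state")
}

#' @describeIn kalman Constant-velocity transition matrix.
#' @param dt Time step in frames.
#' @export
cv_transition <- function(dt = 1) {
  matrix(c(1, dt, 0, 0,
           0, 1, 0, 0,
           0, 0, 1, dt,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' @describeIn kalman White-acceleration process-noise matrix.
#' @param q Process-noise intensity (m^2 / frame^3).
#' @export
cv_process_noise <- function(q = 0.05, dt = 1) {
  blk <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  Q <- matrix(0, 4, 4)
  Q[1:2, 1:2] <- blk
  Q[3:4, 3:4] <- blk
  Q
}

# 2x4 position-selection measurement matrix
measurement_matrix <- function() {
  rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
}

#' @describeIn kalman Time update: `x <- F x`, `P <- F P F' + Q`.
#' @param state A [kf_state()].
#' @param F_mat State-transition matrix.
#' @param Q Process-noise matrix.
#' @export
kf_predict <- function(state, F_mat = cv_transition(), Q = cv_process_noise()) {
  kf_state(F_mat %*% state$x, F_mat %*% state$P %*% t(F_mat) + Q)
}

#' @describeIn kalman Measurement update. `y` is the measured `(x, y)`
#'   position or `NULL` when the measurement is missing, in which case the
#'   posterior equals the prior (the filter coasts on its prediction).
#' @param y Length-2 measurement or `NULL`.
#' @param sigma_sq Measurement variance (m^2), isotropic.
#' @export
kf_update <- function(state, y, sigma_sq) {
  if (is.null(y) || anyNA(y)) return(state)
  stopifnot(sigma_sq > 0)
  Hm <- measurement_matrix()
  S <- Hm %*% state$P %*% t(Hm) + diag(sigma_sq, 2)
  K <- state$P %*% t(Hm) %*% solve(S)
  innov <- as.numeric(y) - as.numeric(Hm %*% state$x)
  x <- state$x + as.numeric(K %*% innov)
  P <- (diag(4) - K %*% Hm) %*% state$P
  kf_state(x, P)
}

# innovation statistics of a candidate measurement against a predicted state:
# squared Mahalanobis distance, log-determinant of S and the Gaussian
# log-density of the innovation
innovation_stats <- function(state, y, sigma_sq) {
  Hm <- measurement_matrix()
  S <- Hm %*% state$P %*% t(Hm) + diag(sigma_sq, 2)
  innov <- as.numeric(y) - as.numeric(Hm %*% state$x)
  Sinv <- solve(S)
  d2 <- as.numeric(innov %*% Sinv %*% innov)
  logdet <- determinant(S, logarithm = TRUE)$modulus[1]
  list(d2 = d2, logdet = logdet,
       loglik = -0.5 * (2 * log(2 * pi) + logdet + d2))
}
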