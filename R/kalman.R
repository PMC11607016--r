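#' Kalman filter configuration
#'
#' Per-track linear-Gaussian motion model used to carry an instrument over
#' frames where the detector misses it. The default mode is a
#' constant-velocity model on an 8-dimensional state
#' `(x, y, w, h, vx, vy, vw, vh)`; the observation selects `(x, y, w, h)`.
#' Process and measurement noise both default to a standard deviation of
#' 2 pixels: localization error is expected to be a few pixels and the
#' deviation from linear motion small.
#'
#' A `random_walk` mode (4-dimensional state, identity transition) is
#' provided as a fallback reading of a 4x4 transition matrix; it carries no
#' velocity, so the edge-exit "moving outward" test never fires in that mode.
#'
#' @param process_noise_std Process noise standard deviation, pixels
#'   (default 2); applied to every state component.
#' @param measurement_noise_std Measurement noise standard deviation, pixels
#'   (default 2).
#' @param mode `"cv"` (constant velocity, default) or `"random_walk"`.
#' @param dt Time step, frames (fixed default 1; variable-rate video is out
#'   of scope).
#'
#' @return A list of class `kalman_config`.
#' @export
kalman_config <- function(process_noise_std = 2,
                          measurement_noise_std = 2,
                          mode = c("cv", "random_walk"),
                          dt = 1) {
  mode <- match.arg(mode)
  if (process_noise_std <= 0 || measurement_noise_std <= 0)
    stop("noise standard deviations must be positive")
  structure(list(process_noise_std = process_noise_std,
                 measurement_noise_std = measurement_noise_std,
                 mode = mode, dt = dt),
            class = "kalman_config")
}

kf_dim <- function(config) if (config$mode == "cv") 8L else 4L

kf_transition <- function(config) {
  d <- kf_dim(config)
  F_ <- diag(d)
  if (config$mode == "cv")
    for (i in 1:4) F_[i, i + 4] <- config$dt
  F_
}

kf_observation <- function(config) {
  d <- kf_dim(config)
  H <- matrix(0, 4, d)
  H[cbind(1:4, 1:4)] <- 1
  H
}

# enforce exact symmetry after updates (guards against numerical drift)
symmetrize <- function(P) (P + t(P)) / 2

#' Initialize a Kalman state from a detected box
#'
#' Position components of the mean are set to the box; velocity components
#' (constant-velocity mode) start at zero. The covariance is diagonal with
#' the measurement-noise variance on positions and a 10x inflated prior on
#' the unobserved velocities, so the first few corrections dominate them.
#'
#' @param box Box `(x, y, w, h)`.
#' @param config A [kalman_config()].
#' @return A list of class `kalman_state` with elements `mean` and `cov`.
#' @export
kf_init <- function(box, config = kalman_config()) {
  validate_bbox(box)
  d <- kf_dim(config)
  r2 <- config$measurement_noise_std^2
  mean <- c(unname(box[1:4]), rep(0, d - 4L))
  var <- c(rep(r2, 4), rep(10 * r2, d - 4L))
  structure(list(mean = mean, cov = diag(var, d)), class = "kalman_state")
}

#' Kalman predict step
#'
#' Advances the state mean by the transition model (position += velocity
#' in constant-velocity mode) and the covariance by `F P F' + Q`.
#'
#' @param s A `kalman_state`.
#' @param config A [kalman_config()].
#' @return The predicted `kalman_state`.
#' @export
kf_predict <- function(s, config = kalman_config()) {
  F_ <- kf_transition(config)
  Q <- diag(config$process_noise_std^2, kf_dim(config))
  structure(list(mean = as.numeric(F_ %*% s$mean),
                 cov = symmetrize(F_ %*% s$cov %*% t(F_) + Q)),
            class = "kalman_state")
}

#' Kalman correct step
#'
#' Standard linear update of a predicted state with an observed box, using
#' the Joseph-form covariance update for numerical stability. The posterior
#' covariance never exceeds the prior on the observed subspace.
#'
#' @param s A predicted `kalman_state`.
#' @param z Observed box `(x, y, w, h)`.
#' @param config A [kalman_config()].
#' @return The corrected `kalman_state`.
#' @export
kf_correct <- function(s, z, config = kalman_config()) {
  if (length(z) < 4 || !all(is.finite(z[1:4])))
    stop("invalid observation: measurement must be four finite numbers")
  d <- kf_dim(config)
  H <- kf_observation(config)
  R <- diag(config$measurement_noise_std^2, 4)
  innov <- unname(z[1:4]) - as.numeric(H %*% s$mean)
  S <- H %*% s$cov %*% t(H) + R
  K <- s$cov %*% t(H) %*% solve(S)
  mean <- s$mean + as.numeric(K %*% innov)
  IKH <- diag(d) - K %*% H
  cov <- IKH %*% s$cov %*% t(IKH) + K %*% R %*% t(K)
  structure(list(mean = mean, cov = symmetrize(cov)), class = "kalman_state")
}

#' Extract the box estimate from a Kalman state
#'
#' Width and height are floored at 1 pixel so the estimate always satisfies
#' the box invariants even if the filter drifts.
#'
#' @param s A `kalman_state`.
#' @return A box `(x, y, w, h)`.
#' @export
kf_box <- function(s) {
  c(x = s$mean[1], y = s$mean[2],
    w = max(1, s$mean[3]), h = max(1, s$mean[4]))
}

#' Extract the velocity estimate from a Kalman state
#'
#' @param s A `kalman_state`.
#' @return `(vx, vy, vw, vh)` in pixels/frame; zeros in random-walk mode.
#' @export
kf_velocity <- function(s) {
  if (length(s$mean) >= 8) s$mean[5:8] else rep(0, 4)
}
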