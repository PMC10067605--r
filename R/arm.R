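#' Arm state of the generative process
#'
#' The true state of the limb: joint angles and their first moment.
#'
#' @param theta 3-vector of joint angles, radians.
#' @param theta_dot 3-vector of angular velocities, radians per step.
#' @return object of class `arm_state`.
#' @export
arm_state <- function(theta, theta_dot = c(0, 0, 0)) {
  stopifnot(length(theta) == 3, length(theta_dot) == 3)
  structure(list(theta = as.numeric(theta), theta_dot = as.numeric(theta_dot)),
            class = "arm_state")
}

#' Noisy velocity-level dynamics step
#'
#' The motor efferents set the first moment of the joint angles up to
#' zero-centered Gaussian motor noise: `theta_dot <- action + w_a`, then
#' `theta <- clamp(theta + theta_dot * dt)`. Angles are hard-clamped at the
#' joint limits and the stored velocity is zeroed at a limit.
#'
#' @param state an [arm_state()].
#' @param action 3-vector of velocity commands, radians per step.
#' @param geometry an [arm_geometry()] (for the joint limits).
#' @param sigma_a motor noise standard deviation, radians per step.
#' @param dt integration step (1 step by default).
#' @param seed optional integer seed for a reproducible noise draw.
#' @return the updated `arm_state`.
#' @export
step_dynamics <- function(state, action, geometry, sigma_a = 0.02, dt = 1,
                          seed = NULL) {
  if (any(!is.finite(action)) || length(action) != 3)
    stop("action must be a finite 3-vector")
  if (sigma_a < 0) stop("sigma_a must be nonnegative")
  w <- with_seed(seed, if (sigma_a > 0) rnorm(3, 0, sigma_a) else numeric(3))
  theta_dot <- action + w
  raw <- state$theta + theta_dot * dt
  theta <- clamp_angles(geometry, raw)
  theta_dot[theta != raw] <- 0
  arm_state(theta, theta_dot)
}
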