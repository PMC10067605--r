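#' Moving-target specification for tracking tasks
#'
#' A target that drifts at constant speed and reflects elastically at the
#' workspace borders.
#'
#' @param position initial center, pixels.
#' @param velocity 2-vector, pixels per step.
#' @param bounds reflection rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param radius disc radius, pixels.
#' @export
moving_target <- function(position, velocity, bounds, radius = 5) {
  stopifnot(length(position) == 2, length(velocity) == 2,
            length(bounds) == 4)
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 bounds = as.numeric(bounds), radius = radius),
            class = "moving_target")
}

trial_log_columns <- function() {
  c("step", "moving",
    paste0("theta", 1:3), paste0("mu", 1:9), paste0("mu_prime", 1:9),
    paste0("action", 1:3),
    "hand_x", "hand_y", "target_x", "target_y",
    "belief_hand_x", "belief_hand_y", "est_target_x", "est_target_y",
    "dist", "perception_dist", "eps_sp_norm", "eps_sv_norm", "free_energy",
    "grad_mu_arm", "grad_mu_target", "grad_mu_prime_arm",
    "grad_mu_prime_target")
}

#' Run a single trial of the active inference agent
#'
#' Simulates one trial: the hand starts on the home button with the belief
#' initialized at that posture (all three blocks), a target appears, and the
#' perception/action cycle runs for `n_steps`. Movement onset follows the
#' chosen policy; while movement is disabled the attractor gain is held at
#' zero (no active intentions) and the limb is stationary.
#'
#' @param geometry an [arm_geometry()].
#' @param model a visual model ([analytic_visual_model()] or a trained VAE).
#' @param precisions a [precision_config()].
#' @param target a [target_spec()] or [moving_target()].
#' @param n_steps trial length, steps.
#' @param onset `"fixed"` (movement starts at `delay`), `"immediate"`,
#'   `"dynamic"` (starts when the target-belief update norm stays below
#'   `onset_threshold` for `onset_persist` steps) or `"never"`.
#' @param delay delay period for the fixed policy, steps.
#' @param onset_threshold,onset_persist dynamic-policy criterion.
#' @param seed integer seed for all in-trial noise.
#' @param target_visible draw the target?
#' @param theta0,mu0 optional initial true posture and belief (default: the
#'   home posture).
#' @param engine `"cpp"` (fast runner) or `"r"` (reference R loop; identical
#'   on noiseless trials, used for validation).
#' @return tibble trial log (one row per step) of class
#'   `flexreach_trial_log`; attributes `diverged` and `config`.
#' @export
run_trial <- function(geometry, model, precisions, target, n_steps = 300,
                      onset = c("fixed", "immediate", "dynamic", "never"),
                      delay = 100, onset_threshold = 0.01, onset_persist = 5,
                      seed = 1, target_visible = TRUE, theta0 = NULL,
                      mu0 = NULL, engine = c("cpp", "r")) {
  onset <- match.arg(onset)
  engine <- match.arg(engine)
  hb <- home_posture(geometry)
  if (is.null(theta0)) theta0 <- hb
  if (is.null(mu0)) mu0 <- c(theta0, theta0, hb)
  is_moving <- inherits(target, "moving_target")

  if (engine == "r")
    return(run_trial_r(geometry, model, precisions, target, n_steps, onset,
                       delay, onset_threshold, onset_persist, seed,
                       target_visible, theta0, mu0))

  model_type <- if (inherits(model, "vae_visual_model")) "vae" else "analytic"
  pars <- list(
    theta0 = theta0, mu0 = mu0, mu_prime0 = rep(0, 9),
    moving = is_moving,
    theta_target = if (is_moving)
      inverse_kinematics(geometry, target$position)$theta
    else target$theta_target,
    radius = target$radius,
    target_visible = target_visible,
    alpha = precisions$alpha, beta = precisions$beta,
    lambda = precisions$lambda, pi_vt = precisions$pi_vt,
    visual_gain = precisions$visual_gain, belief_lr = precisions$belief_lr,
    dt_action = precisions$dt_action, dt = precisions$dt,
    sigma_p = precisions$sigma_p, sigma_v = precisions$sigma_v,
    sigma_a = precisions$sigma_a,
    model_type = model_type,
    blur_limb = if (model_type == "analytic") model$blur_limb else 0,
    blur_target = if (model_type == "analytic") model$blur_target else 0,
    halo_amp = if (model_type == "analytic") model$halo_amp else 0,
    frame_pad = if (model_type == "analytic") model$frame_pad else 0L,
    halo_width = if (model_type == "analytic") model$halo_width else 20,
    occlusion = if (model_type == "analytic") model$occlusion else TRUE,
    control = precisions$control,
    onset = onset, delay = as.integer(delay),
    onset_threshold = onset_threshold,
    onset_persist = as.integer(onset_persist),
    n_steps = as.integer(n_steps), seed = as.integer(seed),
    range_prior = precisions$range_prior,
    divergence_guard = precisions$divergence_guard)
  if (model_type == "vae") pars$weights <- model$weights
  if (is_moving) {
    pars$target_pos <- target$position
    pars$target_vel <- target$velocity
    pars$target_bounds <- target$bounds
  }
  m <- cpp_simulate_trial(unclass(geometry), pars)
  log <- tibble::as_tibble(stats::setNames(as.data.frame(m),
                                           trial_log_columns()))
  attr(log, "diverged") <- isTRUE(attr(m, "diverged"))
  attr(log, "onset") <- onset
  class(log) <- c("flexreach_trial_log", class(log))
  log
}

# Reference R implementation of the trial loop (module-level operations
# composed step by step). Noise uses R's RNG, so stochastic trials are not
# draw-for-draw identical to the cpp engine; noiseless trials are.
run_trial_r <- function(geometry, model, precisions, target, n_steps, onset,
                        delay, onset_threshold, onset_persist, seed,
                        target_visible, theta0, mu0) {
  is_moving <- inherits(target, "moving_target")
  set <- intention_set(precisions$beta)
  belief <- generalized_belief(mu0)
  theta <- theta0
  action <- c(0, 0, 0)
  active <- onset == "immediate"
  below <- 0L
  rows <- vector("list", n_steps)
  if (is_moving) {
    tpos <- target$position; tvel <- target$velocity
    th_t <- inverse_kinematics(geometry, tpos)$theta
  } else {
    th_t <- target$theta_target
    tpos <- hand_position(geometry, th_t)
  }
  set.seed(seed)
  diverged <- FALSE
  for (s in seq_len(n_steps)) {
    obs_img <- if (is_moving) # disc drawn at the exact true center
      render_target_at(geometry, theta, tpos, target$radius)
    else
      render_scene(geometry, theta, target_spec(th_t, target$radius),
                   target_visible)
    if (precisions$sigma_p > 0)
      s_p <- theta + rnorm(3, 0, precisions$sigma_p)
    else s_p <- theta
    if (precisions$sigma_v > 0)
      obs_img <- pmin(pmax(obs_img + rnorm(length(obs_img), 0,
                                           precisions$sigma_v), 0), 1)
    obs <- list(proprio = s_p, visual = obs_img)

    err <- sensory_errors(obs, belief, model)
    eps_s <- sensory_contribution(err, belief, model, precisions)
    if (precisions$range_prior > 0) {
      lims_lo <- rep(geometry$lower, 3)
      lims_hi <- rep(geometry$upper, 3)
      eps_s <- eps_s + precisions$range_prior *
        (pmin(pmax(belief$mu, lims_lo), lims_hi) - belief$mu)
    }
    lam <- if (active) precisions$lambda else 0
    E_i <- intention_errors(set, belief$mu)
    de <- dynamics_error(belief$mu_prime, E_i, lam, beta = precisions$beta)
    mu_dot <- belief$mu_prime + eps_s
    fe <- free_energy_log(err$proprio, err$visual, de$eps_mu, precisions,
                          mu_dot = mu_dot, eps_i = de$eps_i)
    hand <- hand_position(geometry, theta)
    bel_hand <- hand_position(geometry, belief$mu[1:3])
    est_tgt <- hand_position(geometry, belief$mu[4:6])
    rows[[s]] <- c(s, as.numeric(active), theta, belief$mu,
                   belief$mu_prime, action, hand, tpos, bel_hand, est_tgt,
                   sqrt(sum((hand - tpos)^2)), sqrt(sum((est_tgt - tpos)^2)),
                   sqrt(sum(err$proprio^2)), sqrt(sum(err$visual^2)),
                   fe$F, fe$grad_norms)

    if (!active) {
      if (onset == "fixed" && s >= delay) active <- TRUE
      if (onset == "dynamic") {
        below <- if (fe$grad_norms["mu_target"] < onset_threshold)
          below + 1L else 0L
        if (below >= onset_persist) active <- TRUE
      }
    }

    belief <- tryCatch(
      belief_update(belief, eps_s, de$eps_i, precisions$belief_lr),
      flexreach_divergence = function(e) NULL)
    if (is.null(belief) ||
        max(abs(belief$mu)) >
          precisions$divergence_guard * max(geometry$upper - geometry$lower)) {
      diverged <- TRUE
      break
    }

    if (active) {
      inc <- if (precisions$control == "full")
        action_update_full(eps_s, precisions$dt_action)
      else
        action_update_proprio(err$proprio, precisions$alpha,
                              precisions$dt_action)
      action <- action + inc
      st <- step_dynamics(arm_state(theta), action, geometry,
                          precisions$sigma_a, precisions$dt)
      theta <- st$theta
      action[st$theta_dot == 0 & action != 0] <- 0 # anti-windup at a stop
    }
    if (is_moving) {
      for (d in 1:2) {
        tpos[d] <- tpos[d] + tvel[d]
        lo <- target$bounds[2 * d - 1]; hi <- target$bounds[2 * d]
        if (tpos[d] < lo) { tpos[d] <- 2 * lo - tpos[d]; tvel[d] <- -tvel[d] }
        if (tpos[d] > hi) { tpos[d] <- 2 * hi - tpos[d]; tvel[d] <- -tvel[d] }
      }
      th_t <- cpp_ik(unclass(geometry), tpos, th_t, 5, 1.0, 1e-3)$theta
    }
  }
  m <- do.call(rbind, rows)
  log <- tibble::as_tibble(stats::setNames(as.data.frame(m),
                                           trial_log_columns()))
  attr(log, "diverged") <- diverged
  attr(log, "onset") <- onset
  class(log) <- c("flexreach_trial_log", class(log))
  log
}

# render only the target disc at an arbitrary pixel center (R layout)
render_target_at <- function(geometry, theta, center, radius) {
  # a one-off: use the renderer with an artificial posture is not possible
  # for arbitrary centers, so rasterize the disc directly
  W <- geometry$img_width; H <- geometry$img_height
  img <- cpp_render(unclass(geometry), theta, theta, radius, FALSE, TRUE,
                    0, 0) # limb only
  xs <- matrix(rep(seq_len(W) - 0.5, H), W)
  ys <- matrix(rep(seq_len(H) - 0.5, each = W), W)
  disc <- (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
  limb <- img[3, , ]
  img[1, , ] <- as.numeric(disc) * (1 - limb)
  img
}
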