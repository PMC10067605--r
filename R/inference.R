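#' Precision and integration configuration
#'
#' Bundles the precision parameterization and the numerical step sizes of
#' the inference loop.
#'
#' * `alpha` balances proprioceptive (`1 - alpha`) versus visual (`alpha`)
#'   precision for the arm belief and scales the action update
#'   (`alpha = 0`: proprioception only; `alpha = 1`: vision only, action
#'   frozen).
#' * `beta` balances the reach versus home intentions.
#' * `lambda` is the attractor gain: the expected velocity toward an
#'   intended state is `lambda` times its prediction error.
#' * `pi_vt` / `pi_vh` are the visual precisions of the target and home
#'   blocks (the home button is invisible and memorized, so `pi_vh = 0`).
#' * `visual_gain` is the per-pixel precision scale of the visual channel;
#'   it converts summed image-space errors into belief-space units
#'   commensurate with proprioceptive errors.
#' * `belief_lr` is the integration step of the belief update, `dt_action`
#'   the action integration constant, `dt` the world step.
#' * `sigma_p`, `sigma_v`, `sigma_a`: proprioceptive (rad), visual pixel
#'   (intensity) and motor (rad/step) noise standard deviations.
#'
#' @param alpha,beta,lambda,pi_vt,pi_vh,visual_gain,belief_lr,dt_action,dt
#'   see above.
#' @param sigma_p,sigma_v,sigma_a noise magnitudes.
#' @param control `"proprio"` (reflex-arc action from proprioceptive errors
#'   only) or `"full"` (action from the complete weighted sensory
#'   contribution).
#' @param range_prior gain of the joint-range prior on the belief: beliefs
#'   outside the joint limits are pulled back with this gain (a VAE trained
#'   only on in-range postures carries this prior implicitly; the analytic
#'   rasterizer extrapolates smoothly and needs it explicitly, otherwise
#'   target inference can settle on an unreachable kinematic branch).
#' @param divergence_guard abort a trial when any belief component exceeds
#'   this multiple of the largest joint range.
#' @return object of class `precision_config`.
#' @export
precision_config <- function(alpha = 0.5, beta = 0.1, lambda = 0.5,
                             pi_vt = 10, pi_vh = 0, visual_gain = 5e-4,
                             belief_lr = 0.15, dt_action = 1, dt = 1,
                             sigma_p = 0.01, sigma_v = 0.01, sigma_a = 0.02,
                             control = c("proprio", "full"),
                             range_prior = 1, divergence_guard = 10) {
  control <- match.arg(control)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (lambda < 0 || pi_vt < 0 || pi_vh < 0 || visual_gain < 0)
    stop("precisions must be nonnegative")
  if (any(c(sigma_p, sigma_v, sigma_a) < 0))
    stop("noise standard deviations must be nonnegative")
  structure(list(alpha = alpha, beta = beta, lambda = lambda, pi_vt = pi_vt,
                 pi_vh = pi_vh, visual_gain = visual_gain,
                 belief_lr = belief_lr, dt_action = dt_action, dt = dt,
                 sigma_p = sigma_p, sigma_v = sigma_v, sigma_a = sigma_a,
                 control = control, range_prior = range_prior,
                 divergence_guard = divergence_guard),
            class = "precision_config")
}

#' Generalized belief over arm, target and home postures
#'
#' Orders 0 and 1 of the belief, each a 9-vector partitioned into arm
#' (1:3), target (4:6) and home (7:9) joint-angle blocks.
#'
#' @param mu 9-vector, radians.
#' @param mu_prime 9-vector, radians per step.
#' @export
generalized_belief <- function(mu, mu_prime = rep(0, 9)) {
  stopifnot(length(mu) == 9, length(mu_prime) == 9,
            all(is.finite(mu)), all(is.finite(mu_prime)))
  structure(list(mu = as.numeric(mu), mu_prime = as.numeric(mu_prime)),
            class = "generalized_belief")
}

#' @export
print.generalized_belief <- function(x, ...) {
  b <- belief_blocks(x)
  cat("<generalized_belief>\n  arm   ", signif(b$arm, 3), "\n  target",
      signif(b$target, 3), "\n  home  ", signif(b$home, 3), "\n")
  invisible(x)
}

#' Split a belief vector into its blocks
#' @param x a `generalized_belief` or a 9-vector.
#' @return list with `arm`, `target`, `home`.
#' @export
belief_blocks <- function(x) {
  mu <- if (inherits(x, "generalized_belief")) x$mu else as.numeric(x)
  list(arm = mu[1:3], target = mu[4:6], home = mu[7:9])
}

#' Sensory predictions from the belief
#'
#' Proprioception predicts the arm block directly (`G_p mu = mu_a`); vision
#' predicts the decoded scene of the (arm, target) blocks. The home block
#' generates no prediction: it is memorized, not sensed.
#'
#' @param belief a [generalized_belief()].
#' @param model a visual model (see [vm_decode()]).
#' @return list with `proprio` (3-vector) and `visual` (image).
#' @export
sensory_predict <- function(belief, model) {
  list(proprio = belief$mu[1:3],
       visual = vm_decode(model, belief$mu[1:6]))
}

#' Sensory prediction errors
#'
#' @param observation list with `proprio` (3-vector) and `visual` (image).
#' @inheritParams sensory_predict
#' @return list with `proprio` and `visual` error terms.
#' @export
sensory_errors <- function(observation, belief, model) {
  p <- sensory_predict(belief, model)
  list(proprio = observation$proprio - p$proprio,
       visual = as.numeric(observation$visual) - as.numeric(p$visual))
}

#' Precision-weighted sensory contribution in belief space
#'
#' Injects the proprioceptive error into the arm block via `t(G_p)` with
#' weight `1 - alpha`, and distributes the visual pullback over the belief
#' blocks with weights `alpha` (arm rows) and `pi_vt` (target rows); the
#' home block receives no visual term. The pullback is scaled by
#' `visual_gain`, the per-pixel visual precision.
#'
#' @param errors list from [sensory_errors()].
#' @inheritParams sensory_predict
#' @param precisions a [precision_config()].
#' @return 9-vector `eps_s`.
#' @export
sensory_contribution <- function(errors, belief, model, precisions) {
  pb <- vm_pullback(model, belief$mu[1:6], errors$visual) +
    vm_frame_term(model, belief$mu[1:6])
  pb <- precisions$visual_gain * pb
  c((1 - precisions$alpha) * errors$proprio + precisions$alpha * pb[1:3],
    precisions$pi_vt * pb[4:6],
    rep(0, 3))
}

#' Generalized belief update (direct form)
#'
#' One gradient step on free energy in generalized coordinates, first-order
#' truncation: `mu <- mu + lr (mu_prime + eps_s)`;
#' `mu_prime <- mu_prime + lr eps_i`. The backward dynamics error at order 0
#' is neglected (its impact is much smaller than the forward term); the
#' `backward_term` flag restores it for experimentation, using the supplied
#' intention set to form the dynamics Jacobians.
#'
#' @param belief a [generalized_belief()].
#' @param eps_s 9-vector sensory contribution.
#' @param eps_i 9-vector intention (first-order) contribution.
#' @param belief_lr integration step.
#' @param backward_term include the order-0 backward dynamics term?
#' @param set,lambda,gains required when `backward_term = TRUE`.
#' @return the updated belief; signals a condition of class
#'   `flexreach_divergence` on non-finite updates.
#' @export
belief_update <- function(belief, eps_s, eps_i, belief_lr = 0.15,
                          backward_term = FALSE, set = NULL, lambda = NULL,
                          gains = NULL) {
  mu_dot <- belief$mu_prime + eps_s
  if (backward_term) {
    stopifnot(!is.null(set), !is.null(lambda))
    E_i <- intention_errors(set, belief$mu)
    de <- dynamics_error(belief$mu_prime, E_i, lambda, gains = gains)
    if (is.null(gains)) gains <- de_gains_default(ncol(E_i))
    for (k in seq_along(set$mappings)) {
      Fk <- lambda * (set$mappings[[k]] - diag(9))
      mu_dot <- mu_dot + gains[k] * as.numeric(crossprod(Fk, de$eps_mu[, k]))
    }
  }
  mu <- belief$mu + belief_lr * mu_dot
  mu_prime <- belief$mu_prime + belief_lr * eps_i
  if (any(!is.finite(mu)) || any(!is.finite(mu_prime)))
    stop(structure(class = c("flexreach_divergence", "error", "condition"),
                   list(message = "belief update diverged (non-finite)",
                        call = sys.call())))
  generalized_belief(mu, mu_prime)
}

de_gains_default <- function(K) if (K == 2) c(0.9, 0.1) else rep(1 / K, K)

#' Generalized belief update via error-unit relaxation (neural form)
#'
#' Implements the update with explicit prediction-error units: each unit's
#' activity relaxes as `eps_dot = (signal - prediction) - precision * eps`
#' until its fixed point `eps* = (signal - prediction) / precision`, after
#' which the belief integrates the precision-free error signals through the
#' generative-model transposes. This path coincides with the direct form
#' exactly at unit precisions with `lambda = 0` (the neural form includes
#' the backward dynamics term that the direct form truncates, and its error
#' units converge to precision-divided rather than precision-multiplied
#' errors).
#'
#' @param belief a [generalized_belief()].
#' @param observation list with `proprio` and `visual`.
#' @param model a visual model.
#' @param precisions a [precision_config()].
#' @param set an [intention_set()].
#' @param gains explicit intention gains (defaults to
#'   `c(1 - beta, beta)`).
#' @param relax_steps,relax_rate,relax_tol relaxation schedule for the error
#'   units; non-convergence within the budget signals a condition.
#' @return list with the updated `belief` and the converged error units
#'   (`eps_sp`, `eps_sv`, `eps_mu`).
#' @export
belief_update_neural <- function(belief, observation, model, precisions,
                                 set = intention_set(precisions$beta),
                                 gains = NULL,
                                 relax_steps = 5000, relax_rate = 0.2,
                                 relax_tol = 1e-8) {
  if (is.null(gains)) gains <- c(1 - precisions$beta, precisions$beta)
  pi_p <- 1 - precisions$alpha
  pi_v <- precisions$alpha * precisions$visual_gain
  err <- sensory_errors(observation, belief, model)
  E_i <- intention_errors(set, belief$mu)
  f <- precisions$lambda * E_i
  d_mu <- belief$mu_prime - f      # drive of the dynamics error units

  eps_sp <- numeric(3)
  eps_sv <- numeric(length(err$visual))
  eps_mu <- matrix(0, 9, ncol(E_i))
  ok <- FALSE
  for (i in seq_len(relax_steps)) {
    d1 <- err$proprio - pi_p * eps_sp
    d2 <- err$visual - pi_v * eps_sv
    d3 <- d_mu - sweep(eps_mu, 2, gains, `*`)
    eps_sp <- eps_sp + relax_rate * d1
    eps_sv <- eps_sv + relax_rate * d2
    eps_mu <- eps_mu + relax_rate * d3
    if (max(abs(d1), abs(d3)) < relax_tol && max(abs(d2)) < relax_tol) {
      ok <- TRUE
      break
    }
  }
  if (!ok)
    stop(structure(class = c("flexreach_relaxation", "error", "condition"),
                   list(message = "error-unit relaxation did not converge",
                        call = sys.call())))
  pb <- vm_pullback(model, belief$mu[1:6], eps_sv)
  mu_dot <- belief$mu_prime + c(eps_sp, rep(0, 6)) + pb_expand(pb)
  for (k in seq_along(set$mappings)) {
    Fk <- precisions$lambda * (set$mappings[[k]] - diag(9))
    mu_dot <- mu_dot + as.numeric(crossprod(Fk, eps_mu[, k]))
  }
  mup_dot <- -rowSums(eps_mu)
  bel <- generalized_belief(belief$mu + precisions$belief_lr * mu_dot,
                            belief$mu_prime + precisions$belief_lr * mup_dot)
  list(belief = bel, eps_sp = eps_sp, eps_sv = eps_sv, eps_mu = eps_mu)
}

pb_expand <- function(pb) c(pb[1:3], pb[4:6], rep(0, 3))

#' Action updates
#'
#' `action_update_proprio` is the reflex-arc pathway: the action increment
#' is `-dt_action (1 - alpha) eps_sp`, so proprioceptive prediction errors
#' are suppressed by movement and `alpha = 1` freezes action entirely.
#' `action_update_full` maps the complete weighted sensory contribution to
#' the actuators through the (transposed Moore-Penrose) inverse of the
#' proprioceptive map, which for the joint-angle belief is simply the arm
#' block: increment `-dt_action * eps_s[1:3]`.
#'
#' @param eps_sp 3-vector proprioceptive error.
#' @param alpha proprioceptive/visual balance.
#' @param dt_action action integration constant.
#' @return 3-vector action increment (to be added to the running action).
#' @export
action_update_proprio <- function(eps_sp, alpha, dt_action = 1) {
  if (any(!is.finite(eps_sp))) stop("eps_sp must be finite")
  -dt_action * (1 - alpha) * eps_sp
}

#' @rdname action_update_proprio
#' @param eps_s 9-vector weighted sensory contribution.
#' @export
action_update_full <- function(eps_s, dt_action = 1) {
  if (any(!is.finite(eps_s))) stop("eps_s must be finite")
  -dt_action * eps_s[1:3]
}

#' Free energy (Gaussian, constants dropped) and gradient norms
#'
#' One half of the precision-weighted sum of squared prediction errors,
#' together with the per-block norms of the free-energy gradients with
#' respect to the generalized belief (the quantities tracked in the
#' free-energy-minimization analyses).
#'
#' @param eps_sp,eps_sv sensory errors.
#' @param eps_mu 9 x K dynamics errors.
#' @param precisions a [precision_config()].
#' @param gains intention gains (defaults to `c(1 - beta, beta)`).
#' @param mu_dot,eps_i optional belief-update directions; when supplied the
#'   per-block gradient norms are included.
#' @return list with `F`, `terms` (named), and optionally `grad_norms`.
#' @export
free_energy_log <- function(eps_sp, eps_sv, eps_mu, precisions,
                            gains = NULL, mu_dot = NULL, eps_i = NULL) {
  if (is.null(gains)) gains <- c(1 - precisions$beta, precisions$beta)
  eps_mu <- as.matrix(eps_mu)
  terms <- c(
    proprio = 0.5 * (1 - precisions$alpha) * sum(eps_sp^2),
    visual = 0.5 * precisions$alpha * precisions$visual_gain * sum(eps_sv^2),
    dynamics = 0.5 * sum(gains * colSums(eps_mu^2)))
  out <- list(F = sum(terms), terms = terms)
  if (!is.null(mu_dot) && !is.null(eps_i))
    out$grad_norms <- c(
      mu_arm = sqrt(sum(mu_dot[1:3]^2)),
      mu_target = sqrt(sum(mu_dot[4:6]^2)),
      mu_prime_arm = sqrt(sum(eps_i[1:3]^2)),
      mu_prime_target = sqrt(sum(eps_i[4:6]^2)))
  out
}
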