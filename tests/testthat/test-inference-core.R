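test_that("sensory predictions follow the belief layout; the home block is
           memorized, not sensed", {
  g <- fx_geometry()
  m <- fx_model()
  mu <- c(fx_home(), fx_targets9()$theta[[1]], fx_home())
  bel <- generalized_belief(mu)
  p <- sensory_predict(bel, m)
  expect_equal(p$proprio, mu[1:3])
  expect_equal(as.numeric(p$visual), as.numeric(vm_decode(m, mu[1:6])))
  mu2 <- mu
  mu2[7:9] <- mu[7:9] + 0.5
  p2 <- sensory_predict(generalized_belief(mu2), m)
  expect_equal(p2$proprio, p$proprio)
  expect_identical(as.numeric(p2$visual), as.numeric(p$visual))
})

test_that("sensory contribution: precision-weighted routing of errors", {
  set.seed(3)
  B <- matrix(rnorm(36) * 0.2, 6, 6)
  m <- linear_visual_model(B)
  bel <- generalized_belief(rnorm(9))
  obs <- list(proprio = rnorm(3), visual = rnorm(6))
  err <- sensory_errors(obs, bel, m)
  # alpha = 0, pi_vt = 0: pure proprioception
  p00 <- precision_config(alpha = 0, pi_vt = 0, visual_gain = 1,
                          range_prior = 0)
  cs <- sensory_contribution(err, bel, m, p00)
  expect_equal(cs, c(err$proprio, rep(0, 6)))
  # alpha = 0, pi_vt > 0: arm follows proprioception, target follows vision
  # (movement in darkness with a lit target)
  p01 <- precision_config(alpha = 0, pi_vt = 2, visual_gain = 1,
                          range_prior = 0)
  cs2 <- sensory_contribution(err, bel, m, p01)
  pb <- vm_pullback(m, bel$mu[1:6], err$visual)
  expect_equal(cs2[1:3], err$proprio)
  expect_equal(cs2[4:6], 2 * pb[4:6])
  expect_equal(cs2[7:9], rep(0, 3))
  # zero errors give a zero vector
  obs0 <- list(proprio = bel$mu[1:3],
               visual = vm_decode(m, bel$mu[1:6]))
  err0 <- sensory_errors(obs0, bel, m)
  expect_equal(sensory_contribution(err0, bel, m, p01), rep(0, 9))
})

test_that("belief update is stationary at equilibrium and flags divergence", {
  bel <- generalized_belief(1:9 / 10)
  out <- belief_update(bel, rep(0, 9), rep(0, 9), 0.15)
  expect_equal(out$mu, bel$mu)
  expect_equal(out$mu_prime, bel$mu_prime)
  expect_error(belief_update(bel, rep(Inf, 9), rep(0, 9), 0.1),
               class = "flexreach_divergence")
})

test_that("static linear-Gaussian case: the belief fixed point equals the
           generalized least-squares solution (1e-6)", {
  set.seed(2)
  g <- fx_geometry()
  alpha <- 0.4
  p <- precision_config(alpha = alpha, pi_vt = alpha, visual_gain = 1,
                        lambda = 0, sigma_p = 0, sigma_v = 0,
                        range_prior = 0)
  B <- matrix(rnorm(36) * 0.5, 6, 6)
  m <- linear_visual_model(B)
  sp <- rnorm(3)
  sv <- rnorm(6)
  bel <- generalized_belief(rep(0, 9))
  for (i in 1:20000) {
    err <- sensory_errors(list(proprio = sp, visual = sv), bel, m)
    eps_s <- sensory_contribution(err, bel, m, p)
    bel <- belief_update(bel, eps_s, rep(0, 9), 0.2)
  }
  A <- rbind(cbind(diag(3), matrix(0, 3, 3)) * sqrt(1 - alpha),
             B * sqrt(alpha))
  y <- c(sp * sqrt(1 - alpha), sv * sqrt(alpha))
  sol <- qr.solve(crossprod(A), crossprod(A, y))
  expect_lt(max(abs(bel$mu[1:6] - sol)) / max(abs(sol)), 1e-6)
})

test_that("neural error units converge to precision-divided errors and the
           path matches the direct update at unit precisions (1e-6)", {
  set.seed(12)
  bel <- generalized_belief(rnorm(9), rnorm(9))
  set <- intention_set(0.5)
  # fixed-point law eps* = (s - g(mu)) / pi
  p2 <- precision_config(alpha = 0.3, visual_gain = 2, lambda = 0.2,
                         range_prior = 0)
  B <- matrix(rnorm(24) * 0.3, 4, 6)
  m <- linear_visual_model(B)
  obs <- list(proprio = rnorm(3), visual = rnorm(4))
  nr <- belief_update_neural(bel, obs, m, p2, set)
  err <- sensory_errors(obs, bel, m)
  expect_equal(nr$eps_sp, err$proprio / (1 - p2$alpha), tolerance = 1e-7)
  expect_equal(nr$eps_sv, err$visual / (p2$alpha * p2$visual_gain),
               tolerance = 1e-7)
  # zero observation error: zero unit activity
  obs0 <- list(proprio = bel$mu[1:3], visual = vm_decode(m, bel$mu[1:6]))
  p0 <- precision_config(alpha = 0.3, visual_gain = 2, lambda = 0,
                         range_prior = 0)
  nr0 <- belief_update_neural(bel, obs0, m, p0,
                              intention_set(gains = c(1, 1)),
                              gains = c(1, 1))
  expect_lt(max(abs(nr0$eps_sp)), 1e-7)
  expect_lt(max(abs(nr0$eps_sv)), 1e-7)
  # unit precisions, lambda = 0, proprioception only: exact agreement
  p1 <- precision_config(alpha = 0, visual_gain = 1, lambda = 0,
                         belief_lr = 0.15, range_prior = 0)
  mz <- linear_visual_model(matrix(0, 2, 6))
  obsz <- list(proprio = rnorm(3), visual = rep(0, 2))
  errz <- sensory_errors(obsz, bel, mz)
  eps_s <- sensory_contribution(errz, bel, mz, p1)
  E_i <- intention_errors(set, bel$mu)
  de <- dynamics_error(bel$mu_prime, E_i, 0, gains = c(1, 1))
  direct <- belief_update(bel, eps_s, de$eps_i, p1$belief_lr)
  neural <- belief_update_neural(bel, obsz, mz, p1, set, gains = c(1, 1))
  expect_lt(max(abs(direct$mu - neural$belief$mu)), 1e-6)
  expect_lt(max(abs(direct$mu_prime - neural$belief$mu_prime)), 1e-6)
})

test_that("action updates: zero error, frozen at alpha 1, scalar case and
           the proprio/full consistency limit", {
  expect_equal(action_update_proprio(rep(0, 3), 0.5), rep(0, 3))
  expect_equal(action_update_proprio(c(1, -2, 3), 1), rep(0, 3))
  expect_equal(action_update_proprio(c(0.3, 0, 0), 0.5, 1)[1], -0.15)
  # with no visual error the full update reduces to the proprioceptive one
  eps_sp <- c(0.1, -0.2, 0.05)
  alpha <- 0.3
  eps_s <- c((1 - alpha) * eps_sp, rep(0, 6))
  expect_equal(action_update_full(eps_s, 1),
               action_update_proprio(eps_sp, alpha, 1))
  expect_equal(action_update_full(rep(0, 9)), rep(0, 3))
})

test_that("full control descends the image error (one-step line search)", {
  g <- fx_geometry()
  m <- fx_model()
  theta <- fx_home()
  mu <- c(theta + c(0.06, -0.04, 0.05), fx_targets9()$theta[[5]])
  obs <- render_scene(g, theta, target_spec(fx_targets9()$theta[[5]], 5))
  E <- function(th) {
    o <- render_scene(g, th, target_spec(fx_targets9()$theta[[5]], 5))
    0.5 * sum((as.numeric(o) - as.numeric(vm_decode(m, mu)))^2)
  }
  p <- precision_config(alpha = 1, visual_gain = 5e-4, range_prior = 0)
  bel <- generalized_belief(c(mu, theta))
  err <- sensory_errors(list(proprio = theta, visual = obs), bel, m)
  inc <- action_update_full(sensory_contribution(err, bel, m, p), 1)
  e0 <- E(theta)
  improved <- any(vapply(c(1, 0.5, 0.25, 0.1), function(s)
    E(theta + s * inc) < e0, logical(1)))
  expect_true(improved)
})

test_that("free energy is the precision-weighted quadratic form", {
  p <- precision_config(alpha = 0.4, visual_gain = 0.5, beta = 0.3,
                        range_prior = 0)
  expect_equal(free_energy_log(rep(0, 3), rep(0, 10),
                               matrix(0, 9, 2), p)$F, 0)
  set.seed(5)
  eps_sp <- rnorm(3)
  eps_sv <- rnorm(10)
  eps_mu <- matrix(rnorm(18), 9, 2)
  fe <- free_energy_log(eps_sp, eps_sv, eps_mu, p)
  fe2 <- free_energy_log(2 * eps_sp, eps_sv, eps_mu, p)
  expect_equal(fe2$terms[["proprio"]], 4 * fe$terms[["proprio"]])
  # independent Gaussian negative log-likelihood oracle (constants dropped)
  pis <- c(rep(1 - p$alpha, 3), rep(p$alpha * p$visual_gain, 10),
           rep(1 - p$beta, 9), rep(p$beta, 9))
  eps <- c(eps_sp, eps_sv, eps_mu[, 1], eps_mu[, 2])
  keep <- pis > 0
  nll <- -sum(dnorm(eps[keep], 0, 1 / sqrt(pis[keep]), log = TRUE)) -
    0.5 * sum(log(2 * pi / pis[keep]))
  expect_equal(fe$F, nll, tolerance = 1e-10)
})

test_that("one agent cycle: delay immobility, target-gradient decay and the
           arm-gradient spike at movement onset", {
  g <- fx_geometry()
  m <- fx_model()
  p <- noiseless()
  tgt <- target_spec(fx_targets9()$theta[[5]], 5)
  log <- run_trial(g, m, p, tgt, n_steps = 160, delay = 100, seed = 1)
  # during the delay the true arm never moves and the intention gradient
  # at order 1 stays exactly zero
  th0 <- unlist(log[1, c("theta1", "theta2", "theta3")])
  for (s in 1:100)
    expect_equal(unname(unlist(log[s, c("theta1", "theta2", "theta3")])),
                 unname(th0))
  expect_equal(max(abs(log$grad_mu_prime_arm[1:99])), 0)
  # free-energy gradients of the target belief decay during the delay
  expect_lt(log$grad_mu_target[95], 0.05 * log$grad_mu_target[3])
  # the arm gradients spike when action starts
  expect_gt(max(log$grad_mu_prime_arm[101:110]),
            10 * max(log$grad_mu_prime_arm[1:99]))
})

test_that("after convergence with active intentions the hand is on target", {
  g <- fx_geometry()
  m <- fx_model()
  log <- run_trial(g, m, noiseless(), target_spec(fx_targets9()$theta[[2]], 5),
                   seed = 1)
  expect_lte(log$dist[300], 10)
})
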