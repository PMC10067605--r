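test_that("forward kinematics: zero-angle chain is collinear with full span", {
  g <- fx_geometry()
  pts <- forward_kinematics(g, c(0, 0, 0))
  expect_equal(unname(pts[, 2]), rep(g$base[2], 4))
  expect_equal(unname(pts[4, 1] - pts[1, 1]), sum(g$lengths))
})

test_that("forward kinematics matches an independent rotation-matrix oracle", {
  g <- fx_geometry()
  cases <- list(c(pi / 2, -pi / 2, 0), c(0.3, 1.1, -0.4), c(-1, 2, 0.5))
  for (th in cases)
    expect_equal(unname(forward_kinematics(g, th)),
                 fk_rotation_oracle(g, th), tolerance = 1e-12)
})

test_that("forward kinematics preserves segment lengths and the reach bound", {
  g <- fx_geometry()
  set.seed(1)
  for (i in 1:50) {
    th <- runif(3, -pi, pi)
    pts <- forward_kinematics(g, th)
    seg <- sqrt(rowSums((pts[-1, ] - pts[-4, ])^2))
    expect_equal(unname(seg), g$lengths, tolerance = 1e-10)
    expect_lte(sqrt(sum((pts[4, ] - pts[1, ])^2)), sum(g$lengths) + 1e-9)
  }
})

test_that("forward kinematics rejects non-finite input", {
  expect_error(forward_kinematics(fx_geometry(), c(0, NA, 0)), "finite")
  expect_error(forward_kinematics(fx_geometry(), c(0, Inf, 0)), "finite")
})

test_that("dynamics step: null action leaves the state unchanged", {
  g <- fx_geometry()
  st <- arm_state(fx_home())
  out <- step_dynamics(st, c(0, 0, 0), g, sigma_a = 0)
  expect_equal(out$theta, st$theta)
})

test_that("dynamics step without noise is exact Euler integration", {
  g <- fx_geometry()
  mid <- (g$lower + g$upper) / 2
  a <- c(0.01, -0.02, 0.005)
  out <- step_dynamics(arm_state(mid), a, g, sigma_a = 0, dt = 2)
  expect_equal(out$theta, mid + 2 * a)
})

test_that("clamping never produces angles outside the joint limits", {
  g <- fx_geometry()
  st <- arm_state(g$upper - 0.01)
  for (i in 1:30) {
    st <- step_dynamics(st, c(0.5, 0.5, 0.5), g, sigma_a = 0.1,
                        seed = i)
    expect_true(all(st$theta >= g$lower - 1e-12))
    expect_true(all(st$theta <= g$upper + 1e-12))
  }
})

test_that("motor noise is zero-centered (Monte-Carlo over 1e4 steps)", {
  g <- fx_geometry()
  mid <- (g$lower + g$upper) / 2
  sigma <- 0.02
  set.seed(99)
  dots <- replicate(1e4,
    step_dynamics(arm_state(mid), c(0, 0, 0), g, sigma_a = sigma)$theta_dot)
  for (j in 1:3) {
    se <- sigma / sqrt(ncol(dots))
    expect_lt(abs(mean(dots[j, ])), 4 * se)
  }
})

test_that("the package normal samplers pass distributional checks", {
  for (fast in c(TRUE, FALSE)) {
    x <- flexreach:::cpp_rng_normal(2e4, 313, fast)
    expect_lt(abs(mean(x)), 4 / sqrt(2e4))
    expect_lt(abs(sd(x) - 1), 0.02)
    expect_gt(stats::ks.test(unique(x), pnorm)$p.value, 0.001)
  }
})

test_that("sampled configurations are uniform within the joint limits", {
  g <- fx_geometry()
  m <- sample_configuration(g, 1e4, seed = 5)
  for (j in 1:3) {
    expect_gte(min(m[, j]), g$lower[j])
    expect_lte(max(m[, j]), g$upper[j])
    # KS distance below the 1% critical value
    p <- stats::ks.test(m[, j], "punif", g$lower[j], g$upper[j])$p.value
    expect_gt(p, 0.01)
  }
  expect_identical(m, sample_configuration(g, 1e4, seed = 5))
  expect_false(all(m == sample_configuration(g, 1e4, seed = 6)))
})

test_that("inverse kinematics reaches random workspace points within limits", {
  g <- fx_geometry()
  set.seed(3)
  for (i in 1:20) {
    th <- sample_configuration(g)
    p <- hand_position(g, th)
    ik <- inverse_kinematics(g, p)
    expect_true(ik$converged)
    expect_lt(sqrt(sum((hand_position(g, ik$theta) - p)^2)), 0.5)
    expect_true(all(ik$theta >= g$lower & ik$theta <= g$upper))
  }
})

test_that("geometry validation enforces the stated invariants", {
  expect_error(arm_geometry(lengths = c(0, 29, 29)), "positive")
  expect_error(arm_geometry(lower = c(1, 0, 0), upper = c(0.5, 1, 1)),
               "lower limit")
  expect_error(arm_geometry(base = c(500, 12)), "image frame")
})
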