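test_that("delayed-reaching bookkeeping: targets x repetitions trials, limb
           locked through the delay", {
  g <- fx_geometry()
  tr <- run_delayed_reaching(g, fx_model(), precision_config(),
                             repetitions = 2, n_steps = 150, delay = 60,
                             seed = 11, keep_logs = TRUE)
  expect_equal(nrow(tr), 18)
  expect_s3_class(tr, "flexreach_trials")
  for (log in tr$log[c(1, 9, 18)]) {
    th0 <- unlist(log[1, c("theta1", "theta2", "theta3")])
    for (s in c(20, 40, 60))
      expect_equal(unname(unlist(log[s, c("theta1", "theta2", "theta3")])),
                   unname(th0))
    expect_equal(which(log$moving > 0)[1], 61)
  }
})

test_that("with the attractor disabled for the whole trial the hand never
           leaves the home button", {
  g <- fx_geometry()
  log <- run_trial(g, fx_model(), precision_config(),
                   target_spec(fx_targets9()$theta[[5]], 5),
                   onset = "never", n_steps = 120, seed = 2)
  th0 <- unlist(log[1, c("theta1", "theta2", "theta3")])
  expect_equal(unname(unlist(log[120, c("theta1", "theta2", "theta3")])),
               unname(th0))
  expect_false(compute_reach_metrics(log)$reach_success)
})

test_that("fixed onset policy is definitionally the delayed-reaching task", {
  g <- fx_geometry()
  tg <- fx_targets9()[c(1, 5), ]
  a <- run_with_onset_policy(g, fx_model(), precision_config(),
                             policy = "fixed", targets = tg,
                             repetitions = 2, n_steps = 150, delay = 50,
                             seed = 3)
  b <- run_delayed_reaching(g, fx_model(), precision_config(), targets = tg,
                            repetitions = 2, n_steps = 150, delay = 50,
                            seed = 3)
  expect_equal(dplyr::select(a, -"policy"), b, tolerance = 1e-12)
})

test_that("onset policies: immediate acts from the start; the dynamic
           criterion fires no later than the fixed delay (noiseless)", {
  g <- fx_geometry()
  p <- noiseless()
  tg <- fx_targets9()[c(2, 8), ]
  im <- run_with_onset_policy(g, fx_model(), p, policy = "immediate",
                              targets = tg, seed = 5, keep_logs = TRUE)
  expect_true(all(im$onset_step == 1))
  expect_true(all(vapply(im$log, function(l) all(l$moving == 1),
                         logical(1))))
  dyn <- run_with_onset_policy(g, fx_model(), p, policy = "dynamic",
                               targets = tg, seed = 5)
  fix <- run_with_onset_policy(g, fx_model(), p, policy = "fixed",
                               targets = tg, delay = 100, seed = 5)
  expect_true(all(dyn$onset_step <= fix$onset_step))
})

test_that("tracking: reflected constant-speed target with bounded path", {
  g <- fx_geometry()
  tr <- run_tracking(g, fx_model(), precision_config(), n_trials = 3,
                     speed = 0.1, n_steps = 300, seed = 9,
                     keep_logs = TRUE)
  expect_equal(nrow(tr), 3)
  for (log in tr$log) {
    steps <- sqrt(diff(log$target_x)^2 + diff(log$target_y)^2)
    expect_lte(sum(steps), 30 + 1e-6)       # 0.1 px/step for 300 steps
    # displacement equals the speed except across a reflection fold,
    # where the path doubles back but the speed magnitude is preserved
    expect_true(all(steps <= 0.1 + 1e-9))
    expect_gte(mean(abs(steps - 0.1) < 1e-9), 0.95)
  }
})

test_that("sweeps: one trial per target per level, shared targets, and
           level-order invariance of the summary", {
  g <- fx_geometry()
  p <- precision_config()
  s1 <- run_sweep(g, fx_model(), p, param = "alpha", levels = c(0, 0.5),
                  n_targets = 4, n_steps = 120, delay = 40, seed = 21)
  expect_equal(nrow(s1$trials), 8)
  expect_equal(as.integer(table(s1$trials$level)), c(4L, 4L))
  s2 <- run_sweep(g, fx_model(), p, param = "alpha", levels = c(0.5, 0),
                  n_targets = 4, n_steps = 120, delay = 40, seed = 21)
  expect_equal(s1$summary, s2$summary, tolerance = 1e-12)
})

test_that("identical seeds and configuration reproduce summaries exactly", {
  g <- fx_geometry()
  run <- function() {
    tr <- run_delayed_reaching(g, fx_model(), precision_config(),
                               targets = fx_targets9()[c(3, 7), ],
                               repetitions = 2, n_steps = 120, delay = 40,
                               seed = 99)
    summarize_trials(tr)
  }
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(run(), f1, row.names = FALSE)
  write.csv(run(), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
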