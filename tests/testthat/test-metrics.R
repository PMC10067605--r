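scripted_log <- function(d, perc = NULL) {
  tibble::tibble(step = seq_along(d), moving = 1, dist = d,
                 perception_dist = if (is.null(perc)) d else perc)
}

test_that("constant zero distance: immediate success with zero error,
           stability and time", {
  m <- compute_reach_metrics(scripted_log(rep(0, 50)))
  expect_true(m$reach_success)
  expect_equal(m$reach_error, 0)
  expect_equal(m$reach_time, 0)
  expect_equal(m$reach_stability, 0)
})

test_that("first passage: a descending series crossing the criterion", {
  d <- seq(20, 5, length.out = 31) # crosses 10 exactly at index 21
  m <- compute_reach_metrics(scripted_log(d), criterion = 10)
  expect_true(m$reach_success)
  expect_equal(m$reach_time, 20)
  expect_equal(m$reach_error, 5)
  expect_equal(m$reach_stability, sd(d[21:31]))
})

test_that("criterion boundary is inclusive; just-above distances fail", {
  ok <- compute_reach_metrics(scripted_log(rep(10, 20)))
  expect_true(ok$reach_success)
  bad <- compute_reach_metrics(scripted_log(rep(10.1, 20)))
  expect_false(bad$reach_success)
  expect_true(is.na(bad$reach_stability))
  expect_true(is.na(bad$reach_time))
})

test_that("success is judged at trial end: an early visit that drifts away
           does not count", {
  d <- c(seq(20, 5, length.out = 20), seq(5, 25, length.out = 20))
  m <- compute_reach_metrics(scripted_log(d))
  expect_false(m$reach_success)
  expect_equal(m$reach_error, 25)
})

test_that("perception metrics mirror reach metrics on the estimate series
           and ignore the arm belief", {
  d <- seq(30, 2, length.out = 40)
  log1 <- scripted_log(rep(50, 40), perc = d)
  log1$mu1 <- 0
  log2 <- log1
  log2$mu1 <- 99 # arm-belief content must not matter
  a <- compute_perception_metrics(log1)
  b <- compute_perception_metrics(log2)
  expect_equal(a, b)
  expect_true(a$perception_success)
  expect_equal(a$perception_time, which(d <= 10)[1] - 1)
})

test_that("empty logs are rejected", {
  expect_error(compute_reach_metrics(tibble::tibble(dist = numeric(0))),
               "empty")
})

test_that("summaries: hand-computed accuracy and degenerate cases", {
  all0 <- dplyr::bind_rows(lapply(1:5, function(i)
    trial_metrics(scripted_log(rep(0, 10)))))
  s <- summarize_trials(all0)
  expect_equal(s$mean[s$measure == "reach_accuracy"], 100)
  expect_equal(s$mean[s$measure == "reach_error"], 0)
  # 4 hand-built trials, 3 successes -> 75%
  four <- dplyr::bind_rows(
    trial_metrics(scripted_log(rep(1, 10))),
    trial_metrics(scripted_log(rep(2, 10))),
    trial_metrics(scripted_log(rep(3, 10))),
    trial_metrics(scripted_log(rep(30, 10))))
  s4 <- summarize_trials(four)
  expect_equal(s4$mean[s4$measure == "reach_accuracy"], 75)
  expect_equal(s4$n[s4$measure == "reach_time"], 3L)
})

test_that("bootstrap and normal CIs agree within 20% relative width", {
  set.seed(77)
  fake <- tibble::tibble(
    reach_success = TRUE, reach_error = rnorm(200, 5, 1),
    reach_time = rnorm(200, 120, 10), reach_stability = rnorm(200, 2, 0.3),
    perception_success = TRUE, perception_error = rnorm(200, 1, 0.2),
    perception_time = rnorm(200, 60, 5),
    perception_stability = rnorm(200, 0.5, 0.1))
  sn <- summarize_trials(fake, method = "normal")
  sb <- summarize_trials(fake, method = "bootstrap", boot_n = 2000)
  for (msr in c("reach_error", "reach_time", "perception_error")) {
    wn <- with(subset(sn, measure == msr), ci_hi - ci_lo)
    wb <- with(subset(sb, measure == msr), ci_hi - ci_lo)
    expect_lt(abs(wn - wb) / wn, 0.2)
  }
})

test_that("metrics are pure functions of the log (recomputation matches)", {
  g <- fx_geometry()
  log <- run_trial(g, fx_model(), precision_config(),
                   target_spec(fx_targets9()$theta[[1]], 5), seed = 31,
                   n_steps = 150, delay = 50)
  a <- trial_metrics(log)
  b <- trial_metrics(log)
  expect_identical(a, b)
})
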