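# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_geometry <- function() {
  if (is.null(.fx$geometry)) .fx$geometry <- arm_geometry()
  .fx$geometry
}

fx_model <- function() {
  if (is.null(.fx$model))
    .fx$model <- analytic_visual_model(fx_geometry())
  .fx$model
}

fx_home <- function() {
  if (is.null(.fx$home)) .fx$home <- home_posture(fx_geometry())
  .fx$home
}

fx_targets9 <- function() {
  if (is.null(.fx$targets9)) .fx$targets9 <- place_nine_targets(fx_geometry())
  .fx$targets9
}

# small but usable convolutional visual model, trained once and reused
fx_vae <- function() {
  if (is.null(.fx$vae)) {
    g <- fx_geometry()
    ds <- generate_dataset(g, 250, seed = 71)
    .fx$vae <- train_visual_model(
      ds, g,
      visual_model_config(epochs = 3, encoder_sd = 0.1,
                          channels = c(c0 = 12, c1 = 6, c2 = 6, c3 = 6,
                                       e1 = 6, e2 = 8)),
      seed = 71)
    .fx$vae_data <- ds
  }
  .fx$vae
}

fx_vae_data <- function() {
  fx_vae()
  .fx$vae_data
}

# random reachable-and-visible target set shared by heavier tests
fx_random_targets <- function(n = 60) {
  key <- paste0("targets", n)
  if (is.null(.fx[[key]])) {
    t <- sample_reachable_targets(fx_geometry(), n, seed = 17)
    t$radius <- 5
    .fx[[key]] <- t
  }
  .fx[[key]]
}

noiseless <- function(...) {
  precision_config(sigma_p = 0, sigma_v = 0, sigma_a = 0, ...)
}

# independent 2-D rotation-matrix forward kinematics used as an oracle
fk_rotation_oracle <- function(geometry, theta) {
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  p <- geometry$base
  R <- diag(2)
  out <- matrix(NA_real_, 4, 2)
  out[1, ] <- p
  for (i in 1:3) {
    R <- R %*% rot(theta[i])
    p <- p + as.numeric(R %*% c(geometry$lengths[i], 0))
    out[i + 1, ] <- p
  }
  out
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
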