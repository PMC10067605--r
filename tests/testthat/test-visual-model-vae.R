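# Convolutional visual model: supervised training, decode/encode quality at
# reduced scale, adjoint correctness, and the qualitative effects of the
# fixed recognition-density variance. Sizes here are deliberately small; the
# same code paths scale to the full 20000-sample / 100-epoch regime.

small_channels <- c(c0 = 12, c1 = 6, c2 = 6, c3 = 6, e1 = 6, e2 = 8)

test_that("training reduces the loss and beats the untrained decoder", {
  g <- fx_geometry()
  vm <- fx_vae()
  tr <- tidy(vm)
  expect_true(all(diff(tr$loss) < 0))
  # held-out reconstruction against the untrained initialization
  hold <- generate_dataset(g, 12, seed = 404)
  l2 <- function(model) {
    mean(vapply(seq_len(nrow(hold)), function(i) {
      img <- render_scene(g, hold$theta_arm[[i]],
                          target_spec(hold$theta_target[[i]], hold$radius[i]))
      dec <- vm_decode(model, c(hold$theta_arm[[i]], hold$theta_target[[i]]))
      sum((as.numeric(img) - as.numeric(dec))^2)
    }, numeric(1)))
  }
  vm0 <- vm
  vm0$weights <- flexreach:::cpp_vae_init(12, 6, 6, 6, 6, 8, 71)
  expect_lt(l2(vm), l2(vm0))
})

test_that("seeded training is deterministic", {
  g <- fx_geometry()
  ds <- generate_dataset(g, 80, seed = 5)
  cfg <- visual_model_config(epochs = 2, channels = small_channels)
  a <- train_visual_model(ds, g, cfg, seed = 13)
  b <- train_visual_model(ds, g, cfg, seed = 13)
  expect_equal(utils::tail(tidy(a)$loss, 1), utils::tail(tidy(b)$loss, 1),
               tolerance = 1e-12)
  mu <- c(ds$theta_arm[[1]], ds$theta_target[[1]])
  expect_identical(as.numeric(vm_decode(a, mu)), as.numeric(vm_decode(a, mu)))
  expect_equal(as.numeric(vm_decode(a, mu)), as.numeric(vm_decode(b, mu)),
               tolerance = 1e-12)
})

test_that("non-finite training loss raises a training-failure error", {
  g <- fx_geometry()
  ds <- generate_dataset(g, 8, seed = 6)
  w <- flexreach:::cpp_vae_init(12, 6, 6, 6, 6, 8, 1)
  w$dec_fc_W[1, 1] <- NaN  # tanh saturates Inf, NaN propagates
  arm <- t(vapply(ds$theta_arm, identity, numeric(3)))
  tgt <- t(vapply(ds$theta_target, identity, numeric(3)))
  expect_error(
    flexreach:::cpp_vae_train(w, unclass(g), arm, tgt, ds$radius,
                              1L, 8L, 1e-3, 0.1, 100, 1L),
    "diverged")
})

test_that("VAE pullback matches finite differences (1e-3)", {
  vm <- fx_vae()
  ds <- fx_vae_data()
  g <- fx_geometry()
  mu <- c(ds$theta_arm[[2]], ds$theta_target[[2]])
  sv <- as.numeric(render_scene(g, ds$theta_arm[[3]],
                                target_spec(ds$theta_target[[3]], 6)))
  err <- sv - as.numeric(vm_decode(vm, mu))
  pb <- vm_pullback(vm, mu, err)
  loss <- function(x) 0.5 * sum((sv - as.numeric(vm_decode(vm, x)))^2)
  h <- 1e-5
  fd <- vapply(1:6, function(j) {
    up <- mu; up[j] <- up[j] + h
    dn <- mu; dn[j] <- dn[j] - h
    (loss(up) - loss(dn)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(pb + fd)) / max(abs(pb)), 1e-3)
  z <- array(0, c(3, 128, 96))
  expect_equal(vm_pullback(vm, mu, z), rep(0, 6))
})

test_that("the encoder regresses joint angles from images", {
  vm <- fx_vae()
  g <- fx_geometry()
  ds <- fx_vae_data()
  errs <- vapply(1:10, function(i) {
    img <- render_scene(g, ds$theta_arm[[i]],
                        target_spec(ds$theta_target[[i]], ds$radius[i]))
    zh <- vm_encode(vm, img)
    mean(abs(zh - c(ds$theta_arm[[i]], ds$theta_target[[i]])))
  }, numeric(1))
  # crude at this scale, but far better than the ~0.9 rad error of a
  # range-midpoint guess
  expect_lt(mean(errs), 0.6)
})

test_that("reconstruction improves with the training-set size", {
  g <- fx_geometry()
  hold <- generate_dataset(g, 10, seed = 505)
  l2_hold <- function(model) {
    mean(vapply(seq_len(nrow(hold)), function(i) {
      img <- render_scene(g, hold$theta_arm[[i]],
                          target_spec(hold$theta_target[[i]], hold$radius[i]))
      dec <- vm_decode(model, c(hold$theta_arm[[i]], hold$theta_target[[i]]))
      sum((as.numeric(img) - as.numeric(dec))^2)
    }, numeric(1)))
  }
  sizes <- c(60, 240, 900)
  res <- vapply(sizes, function(n) {
    mean(vapply(1:2, function(s) {
      ds <- generate_dataset(g, n, seed = 100 + s)
      vm <- train_visual_model(ds, g,
        visual_model_config(epochs = 3, channels = small_channels),
        seed = 100 + s)
      l2_hold(vm)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(res[3], res[1])       # large beats small
  expect_lt(res[2], res[1] * 1.1) # middle does not regress
})

test_that("large recognition variance degrades reconstruction; two-level
           gradient fields are tabulated", {
  g <- fx_geometry()
  ds <- generate_dataset(g, 220, seed = 33)
  train_sd <- function(sd) train_visual_model(
    ds, g, visual_model_config(epochs = 3, encoder_sd = sd,
                               channels = small_channels), seed = 33)
  vm_mid <- train_sd(0.25)
  vm_high <- train_sd(0.9)
  hold <- generate_dataset(g, 10, seed = 606)
  l2 <- function(model) mean(vapply(seq_len(nrow(hold)), function(i) {
    img <- render_scene(g, hold$theta_arm[[i]],
                        target_spec(hold$theta_target[[i]], hold$radius[i]))
    dec <- vm_decode(model, c(hold$theta_arm[[i]], hold$theta_target[[i]]))
    sum((as.numeric(img) - as.numeric(dec))^2)
  }, numeric(1)))
  # over the upper half of the variance range reconstruction worsens
  expect_gt(l2(vm_high), l2(vm_mid))
  gf <- dplyr::bind_rows(
    gradient_field(vm_mid, g, n_points = 9, model_id = "mid"),
    gradient_field(vm_high, g, n_points = 9, model_id = "high"))
  expect_setequal(unique(gf$model_id), c("mid", "high"))
  expect_equal(nrow(gf), 2 * 3 * 9)
  expect_true(all(is.finite(gf$gradient)))
})

test_that("smoother visual models support more accurate reaching than
           sharp ones (recognition-variance analogue)", {
  # the analytic rasterizer's target blur plays the role of the decoder
  # smoothness induced by the recognition-density variance: a nearly hard
  # model gives sharp, short-range gradients and poor reaching, a
  # mid-range blur reaches reliably
  g <- fx_geometry()
  p <- precision_config()
  tg <- fx_targets9()
  acc <- vapply(c(1, 14), function(b) {
    m <- analytic_visual_model(g, blur_target = b)
    tr <- run_delayed_reaching(g, m, p, targets = tg[c(2, 5, 8), ],
                               repetitions = 2, seed = 7)
    mean(tr$reach_success)
  }, numeric(1))
  expect_gte(acc[2], acc[1])
})

test_that("a trained model round-trips through its checkpoint file", {
  vm <- fx_vae()
  path <- withr::local_tempfile(fileext = ".rds")
  save_visual_model(vm, path)
  back <- load_visual_model(path)
  mu <- rep(1, 6)
  expect_equal(as.numeric(vm_decode(back, mu)),
               as.numeric(vm_decode(vm, mu)))
  expect_equal(glance(back)$n_train, glance(vm)$n_train)
})

test_that("tidy and glance summarize the training run", {
  vm <- fx_vae()
  td <- tidy(vm)
  expect_true(all(c("epoch", "loss", "recon_loss", "latent_loss") %in%
                    names(td)))
  gl <- glance(vm)
  expect_equal(gl$epochs, 3L)
  expect_gt(gl$n_parameters, 1000)
})
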