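#' Visual generative model interface
#'
#' A visual model maps the 6-d (arm, target) joint-angle belief to a
#' predicted scene image (`vm_decode`) and pulls image-space errors back into
#' the belief space through the transpose of its Jacobian (`vm_pullback`).
#' Three implementations ship with the package: the convolutional VAE
#' ([train_visual_model()]), a differentiable soft rasterizer with an exact
#' analytic adjoint ([analytic_visual_model()]), and a linear map
#' ([linear_visual_model()]) used for closed-form checks.
#'
#' @param model a visual model object.
#' @param mu_visual 6-vector: arm block then target block, radians.
#' @param image_error array shaped like the model's output.
#' @return `vm_decode`: the predicted image; `vm_pullback`: a 6-vector, the
#'   reverse-mode product of the decoder Jacobian transpose with
#'   `image_error`.
#' @export
vm_decode <- function(model, mu_visual) UseMethod("vm_decode")

#' @rdname vm_decode
#' @export
vm_pullback <- function(model, mu_visual, image_error)
  UseMethod("vm_pullback")

#' @rdname vm_decode
#' @details `vm_frame_term` returns the gradient contribution of the
#'   model's prediction mass lying outside the camera frame (the model
#'   predicts on an unbounded plane while out-of-view pixels observe
#'   nothing); it is zero for models whose output is inherently confined to
#'   the frame.
#' @export
vm_frame_term <- function(model, mu_visual) UseMethod("vm_frame_term")

#' @export
vm_frame_term.default <- function(model, mu_visual) numeric(6)

# ---------------------------------------------------------------------------
# analytic model: soft rasterizer
# ---------------------------------------------------------------------------

#' Analytic visual model (differentiable soft rasterizer)
#'
#' Renders limb and target with logistic (blurred) edges so that the image is
#' smooth in the joint angles, and computes the exact adjoint of that mapping
#' analytically. The target blob combines a narrow logistic core (a stiff,
#' accurate equilibrium at the true center) with a faint wide Gaussian halo
#' that, like a high-variance decoder, extends the spatial range over which
#' image errors produce informative belief gradients. As the blurs shrink
#' (and with the halo off) the decode converges to the hard render of
#' [render_scene()].
#'
#' @param geometry an [arm_geometry()].
#' @param radius target radius the model assumes, px.
#' @param blur_limb,blur_target edge softness, px.
#' @param halo_amp,halo_width amplitude (intensity) and width (px) of an
#'   optional extra long-range capture halo; `halo_amp = 0` disables it
#'   (the wide logistic core already provides long-range gradients).
#' @param frame_pad width (px) of the out-of-frame band over which the
#'   frame-suppression gradient ([vm_frame_term()]) is accumulated; `0`
#'   disables the term.
#' @param occlusion model the limb's occlusion of the target in the decode?
#'   Off by default: an explicitly occlusion-aware decoder makes the target
#'   gradient try to hide the predicted blob behind the limb (both sit at
#'   the hand at trial start), which traps the target belief; a decoder
#'   that predicts the target plane unoccluded loses a little fidelity when
#'   the limb really covers the target but keeps the gradient field
#'   informative everywhere.
#' @return object of class `analytic_visual_model`.
#' @export
analytic_visual_model <- function(geometry, radius = 5, blur_limb = 2,
                                  blur_target = 14, halo_amp = 0,
                                  halo_width = 20, frame_pad = 60,
                                  occlusion = FALSE) {
  stopifnot(blur_limb > 0, blur_target > 0, halo_amp >= 0, halo_width > 0)
  structure(list(geometry = geometry, radius = radius,
                 blur_limb = blur_limb, blur_target = blur_target,
                 halo_amp = halo_amp, halo_width = halo_width,
                 frame_pad = as.integer(frame_pad), occlusion = occlusion),
            class = c("analytic_visual_model", "flexreach_visual_model"))
}

#' @export
vm_frame_term.analytic_visual_model <- function(model, mu_visual) {
  if (model$frame_pad <= 0) return(numeric(6))
  as.numeric(cpp_frame_suppression(unclass(model$geometry),
                                   as.numeric(mu_visual), model$radius,
                                   model$blur_target, model$halo_amp,
                                   model$halo_width, model$frame_pad))
}

#' @export
vm_decode.analytic_visual_model <- function(model, mu_visual) {
  img <- cpp_render(unclass(model$geometry), mu_visual[1:3], mu_visual[4:6],
                    model$radius, TRUE, FALSE, model$blur_limb,
                    model$blur_target, model$halo_amp, model$halo_width,
                    model$occlusion)
  class(img) <- c("scene_image", class(img))
  img
}

#' @export
vm_pullback.analytic_visual_model <- function(model, mu_visual, image_error) {
  as.numeric(cpp_soft_pullback(unclass(model$geometry),
                               as.numeric(mu_visual),
                               as.numeric(image_error), model$radius,
                               model$blur_limb, model$blur_target,
                               model$halo_amp, model$halo_width,
                               model$occlusion))
}

# ---------------------------------------------------------------------------
# linear model: closed-form checks
# ---------------------------------------------------------------------------

#' Linear visual model
#'
#' `decode(mu) = B mu + offset`, `pullback(e) = t(B) e`. Used as a stand-in
#' sensor in linear-Gaussian fixed-point checks where the exact posterior is
#' available by direct solve.
#'
#' @param B an `m x 6` matrix.
#' @param offset length-`m` numeric (default zero).
#' @export
linear_visual_model <- function(B, offset = NULL) {
  B <- as.matrix(B)
  stopifnot(ncol(B) == 6)
  if (is.null(offset)) offset <- numeric(nrow(B))
  structure(list(B = B, offset = offset),
            class = c("linear_visual_model", "flexreach_visual_model"))
}

#' @export
vm_decode.linear_visual_model <- function(model, mu_visual) {
  as.numeric(model$B %*% mu_visual + model$offset)
}

#' @export
vm_pullback.linear_visual_model <- function(model, mu_visual, image_error) {
  as.numeric(crossprod(model$B, as.numeric(image_error)))
}

# ---------------------------------------------------------------------------
# VAE
# ---------------------------------------------------------------------------

#' Visual-model (VAE) configuration
#'
#' Architecture and training hyper-parameters for the convolutional visual
#' model. The latent dimension is fixed at 6 (arm + target angles). The
#' recognition-density standard deviation `encoder_sd` is fixed, not
#' learned; during training it jitters the latent input of the decoder,
#' which smooths both the decoded images and their gradients (in normalized
#' latent units where each joint range spans 2).
#'
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param encoder_sd fixed recognition-density standard deviation.
#' @param latent_weight weight of the encoder's latent regression loss
#'   relative to the image reconstruction loss.
#' @param channels named integers: feature channels `c0` (dense stage),
#'   `c1`, `c2` (transposed convolutions), `c3` (smoothing convolution),
#'   `e1`, `e2` (encoder).
#' @export
visual_model_config <- function(epochs = 100, batch = 32, lr = 1e-3,
                                encoder_sd = 0.1, latent_weight = 100,
                                channels = c(c0 = 16, c1 = 8, c2 = 8,
                                             c3 = 8, e1 = 8, e2 = 8)) {
  stopifnot(encoder_sd > 0, epochs >= 1, batch >= 1)
  structure(list(latent_dim = 6L, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr,
                 encoder_sd = encoder_sd, latent_weight = latent_weight,
                 channels = channels),
            class = "visual_model_config")
}

#' Train the convolutional visual model
#'
#' Supervised training of the VAE on rendered body-target configurations:
#' the decoder (one dense layer, two transposed convolutions, two smoothing
#' convolutions) reconstructs the scene from the true normalized joint
#' angles perturbed by the fixed recognition-density noise, while the
#' encoder (two convolutions plus a dense readout) regresses the angles from
#' the image. Optimized with Adam; images are re-rendered on the fly from
#' the dataset's angle labels (bit-identical to stored images).
#'
#' @param dataset tibble from [generate_dataset()] (images optional).
#' @param geometry an [arm_geometry()] with the standard 128 x 96 frame.
#' @param config a [visual_model_config()].
#' @param seed integer seed for initialization, latent jitter and shuffling.
#' @return object of class `vae_visual_model`; see [tidy()] / [glance()]
#'   methods for the training trace.
#' @export
train_visual_model <- function(dataset, geometry,
                               config = visual_model_config(), seed = 1) {
  stopifnot(nrow(dataset) >= 1)
  ch <- config$channels
  w0 <- cpp_vae_init(ch["c0"], ch["c1"], ch["c2"], ch["c3"], ch["e1"],
                     ch["e2"], seed)
  arm <- t(vapply(dataset$theta_arm, identity, numeric(3)))
  tgt <- t(vapply(dataset$theta_target, identity, numeric(3)))
  fit <- cpp_vae_train(w0, unclass(geometry), arm, tgt, dataset$radius,
                       config$epochs, config$batch, config$lr,
                       config$encoder_sd, config$latent_weight, seed)
  structure(
    list(weights = fit$weights, geometry = geometry, config = config,
         loss = tibble::tibble(epoch = seq_along(fit$loss),
                               loss = as.numeric(fit$loss),
                               recon_loss = as.numeric(fit$recon_loss),
                               latent_loss = as.numeric(fit$latent_loss)),
         meta = list(seed = seed, n = nrow(dataset),
                     epochs = config$epochs,
                     encoder_sd = config$encoder_sd)),
    class = c("vae_visual_model", "flexreach_visual_model"))
}

#' @export
vm_decode.vae_visual_model <- function(model, mu_visual) {
  img <- cpp_vae_decode(model$weights, unclass(model$geometry),
                        as.numeric(mu_visual))
  class(img) <- c("scene_image", class(img))
  img
}

#' @export
vm_pullback.vae_visual_model <- function(model, mu_visual, image_error) {
  as.numeric(cpp_vae_pullback(model$weights, unclass(model$geometry),
                              as.numeric(mu_visual),
                              as.numeric(image_error)))
}

#' Encode an image to joint angles with the VAE encoder
#' @param model a `vae_visual_model`.
#' @param image a scene image.
#' @return 6-vector of joint angles, radians.
#' @export
vm_encode <- function(model, image) {
  stopifnot(inherits(model, "vae_visual_model"))
  as.numeric(cpp_vae_encode(model$weights, unclass(model$geometry),
                            as.numeric(image)))
}

#' @export
print.vae_visual_model <- function(x, ...) {
  cat("<vae_visual_model> trained on", x$meta$n, "configurations,",
      x$meta$epochs, "epochs, encoder sd", x$meta$encoder_sd, "\n",
      "final loss", signif(utils::tail(x$loss$loss, 1), 4), "\n")
  invisible(x)
}

#' @export
tidy.vae_visual_model <- function(x, ...) x$loss

#' @export
glance.vae_visual_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  tibble::tibble(
    n_train = x$meta$n, epochs = x$meta$epochs,
    encoder_sd = x$meta$encoder_sd, n_parameters = np,
    final_loss = utils::tail(x$loss$loss, 1),
    final_recon_loss = utils::tail(x$loss$recon_loss, 1),
    final_latent_loss = utils::tail(x$loss$latent_loss, 1))
}

#' Save / load a trained visual model
#'
#' Checkpoints the weights together with geometry, configuration and
#' training metadata in a single file.
#'
#' @param model a `vae_visual_model`.
#' @param path checkpoint file path.
#' @export
save_visual_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_visual_model
#' @export
load_visual_model <- function(path) readRDS(path)

# ---------------------------------------------------------------------------
# gradient-field analysis
# ---------------------------------------------------------------------------

#' Marginal visual gradient field
#'
#' For each swept joint, renders the scene at configurations along the
#' joint's range, computes the image error against a fixed reference
#' configuration, and pulls it back into the belief space at the swept
#' configuration. The recorded value is the swept joint's own gradient
#' component: for a smooth well-behaved model it is positive below the
#' reference angle and negative above it (a restoring field).
#'
#' @param model a visual model.
#' @param geometry an [arm_geometry()].
#' @param reference 6-vector (arm, target) reference configuration; defaults
#'   to mid-range joints with the target at the arm's hand.
#' @param block sweep the `"arm"` joints or the `"target"` joints.
#' @param n_points sweep resolution per joint.
#' @param model_id optional label column (useful when comparing
#'   encoder-variance levels).
#' @return tibble with `joint`, `angle`, `gradient`, `model_id`.
#' @export
gradient_field <- function(model, geometry, reference = NULL,
                           block = "arm", n_points = 41, model_id = NA) {
  if (is.null(reference)) {
    mid <- (geometry$lower + geometry$upper) / 2
    reference <- c(mid, mid)
  }
  ref_img <- vm_decode(model, reference)
  off <- if (block == "arm") 0L else 3L
  joints <- c("neck", "shoulder", "elbow")
  res <- purrr::map_dfr(1:3, function(j) {
    grid <- seq(geometry$lower[j], geometry$upper[j], length.out = n_points)
    g <- vapply(grid, function(a) {
      mu <- reference
      mu[off + j] <- a
      err <- as.numeric(ref_img) - as.numeric(vm_decode(model, mu))
      vm_pullback(model, mu, err)[off + j]
    }, numeric(1))
    tibble::tibble(joint = joints[j], angle = grid, gradient = g)
  })
  res$reference <- reference[off + match(res$joint, joints)]
  res$model_id <- model_id
  class(res) <- c("flexreach_gradient_field", class(res))
  res
}
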