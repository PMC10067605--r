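#' Target specification
#'
#' A target is encoded by the posture whose hand position is the target
#' center ("the posture of the arm touching the target"), plus a visual
#' radius. Training sets use radii in 5..12 px; evaluation uses 5 px.
#'
#' @param theta_target 3-vector of joint angles, radians.
#' @param radius disc radius, pixels.
#' @return object of class `target_spec`.
#' @export
target_spec <- function(theta_target, radius = 5) {
  stopifnot(length(theta_target) == 3, is.finite(radius), radius > 0)
  structure(list(theta_target = as.numeric(theta_target),
                 radius = as.numeric(radius)), class = "target_spec")
}

#' Render the visual scene
#'
#' Deterministic rasterization of limb and target into the three-plane
#' 128 x 96 sensorium. The limb (blue plane, index 3) is three filled
#' rectangles with circular joints and tips; the target (red plane, index 1)
#' is a filled disc centered at the hand position of the target posture. The
#' limb is drawn last and occludes the target; plane 2 is unused background.
#'
#' @param geometry an [arm_geometry()].
#' @param theta_arm limb posture, radians.
#' @param target a [target_spec()].
#' @param target_visible draw the target? (`FALSE` renders an empty red
#'   plane, e.g. during inter-trial intervals).
#' @return a `scene_image`: numeric array `c(3, width, height)` in `[0, 1]`.
#' @export
render_scene <- function(geometry, theta_arm, target, target_visible = TRUE) {
  if (any(!is.finite(theta_arm)))
    stop("theta_arm must be finite")
  img <- cpp_render(unclass(geometry), as.numeric(theta_arm),
                    target$theta_target, target$radius, target_visible,
                    TRUE, 0, 0)
  class(img) <- c("scene_image", class(img))
  img
}

#' Validate a scene image
#' @param img object to check.
#' @param geometry an [arm_geometry()].
#' @return `TRUE` invisibly, or an error.
#' @export
validate_scene_image <- function(img, geometry = arm_geometry()) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 ||
      !all(d == c(3, geometry$img_width, geometry$img_height)))
    stop("scene image must have dim c(3, ", geometry$img_width, ", ",
         geometry$img_height, ")")
  if (any(!is.finite(img)) || any(img < 0) || any(img > 1))
    stop("scene intensities must lie in [0, 1]")
  invisible(TRUE)
}

#' The nine reach targets of the reference experiment
#'
#' Builds a 3 x 3 grid of peripersonal targets: three directions symmetric
#' about the body midline at three depths, measured from the resting shoulder
#' (torso vertical). Each grid point is converted to a target posture by
#' inverse kinematics; unreachable grid points raise an error.
#'
#' @param geometry an [arm_geometry()].
#' @param depths distances from the resting shoulder, pixels.
#' @param angles_deg directions from the resting shoulder, degrees
#'   (90 = straight ahead).
#' @param radius target radius, pixels.
#' @return tibble with `target_id`, `x`, `y`, `theta` (list-column of
#'   postures), `radius`.
#' @export
place_nine_targets <- function(geometry, depths = c(26, 36, 46),
                               angles_deg = c(60, 90, 120), radius = 5) {
  shoulder <- geometry$base + c(0, geometry$lengths[1])
  grid <- expand.grid(depth = depths, angle = angles_deg * pi / 180)
  xs <- shoulder[1] + grid$depth * cos(grid$angle)
  ys <- shoulder[2] + grid$depth * sin(grid$angle)
  thetas <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ik <- inverse_kinematics(geometry, c(xs[i], ys[i]))
    if (!ik$converged)
      stop("target grid point (", round(xs[i], 1), ", ", round(ys[i], 1),
           ") is unreachable under the configured geometry")
    thetas[[i]] <- ik$theta
  }
  tibble::tibble(target_id = seq_len(nrow(grid)), x = xs, y = ys,
                 theta = thetas, radius = radius)
}

#' Generate a dataset of random body-target configurations
#'
#' Draws arm and target postures uniformly over the operational space (one
#' uniform draw per joint within its limits) with target radii uniform in
#' `radius_range`, optionally materializing the rendered scene for each
#' record. This is the training-set factory for the visual model.
#'
#' @param geometry an [arm_geometry()].
#' @param n number of records.
#' @param radius_range target radius range, pixels.
#' @param seed optional integer seed.
#' @param images materialize rendered images as a list-column? (For large
#'   `n` keep `FALSE`; training re-renders deterministically from angles.)
#' @return tibble with `theta_arm`, `theta_target` (list-columns), `radius`,
#'   and optionally `image`.
#' @export
generate_dataset <- function(geometry, n, radius_range = c(5, 12),
                             seed = NULL, images = FALSE) {
  stopifnot(n >= 1)
  dat <- with_seed(seed, {
    arm <- sample_configuration(geometry, n)
    tgt <- sample_configuration(geometry, n)
    if (n == 1) { arm <- matrix(arm, 1); tgt <- matrix(tgt, 1) }
    rad <- runif(n, radius_range[1], radius_range[2])
    list(arm = arm, tgt = tgt, rad = rad)
  })
  out <- tibble::tibble(
    theta_arm = lapply(seq_len(n), function(i) dat$arm[i, ]),
    theta_target = lapply(seq_len(n), function(i) dat$tgt[i, ]),
    radius = dat$rad)
  if (images)
    out$image <- purrr::map(seq_len(n), function(i)
      render_scene(geometry, out$theta_arm[[i]],
                   target_spec(out$theta_target[[i]], out$radius[i])))
  out
}

#' Write / read a dataset directory
#'
#' Datasets are stored as a plain directory: `angles.csv` with the joint
#' angles and radii, and (when images were materialized) one lossless PNG
#' per record under `images/`. Hard-edge renders are binary masks, so the
#' PNG round trip is exact.
#'
#' @param dataset a tibble from [generate_dataset()].
#' @param dir directory to create.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ang <- data.frame(
    t(vapply(dataset$theta_arm, identity, numeric(3))),
    t(vapply(dataset$theta_target, identity, numeric(3))),
    radius = dataset$radius)
  names(ang) <- c(paste0("arm", 1:3), paste0("tgt", 1:3), "radius")
  write.csv(ang, file.path(dir, "angles.csv"), row.names = FALSE)
  if (!is.null(dataset$image)) {
    rlang::check_installed("png")
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    for (i in seq_len(nrow(dataset))) {
      img <- dataset$image[[i]]
      # scene (3, W, H) -> H x W x 3 raster
      arr <- aperm(unclass(img), c(3, 2, 1))
      png::writePNG(arr, file.path(dir, "images",
                                   sprintf("img_%05d.png", i)))
    }
  }
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  ang <- read.csv(file.path(dir, "angles.csv"))
  n <- nrow(ang)
  out <- tibble::tibble(
    theta_arm = lapply(seq_len(n), function(i) as.numeric(ang[i, 1:3])),
    theta_target = lapply(seq_len(n), function(i) as.numeric(ang[i, 4:6])),
    radius = ang$radius)
  imgdir <- file.path(dir, "images")
  if (dir.exists(imgdir)) {
    rlang::check_installed("png")
    out$image <- lapply(seq_len(n), function(i) {
      arr <- png::readPNG(file.path(imgdir, sprintf("img_%05d.png", i)))
      img <- aperm(arr, c(3, 2, 1))
      class(img) <- c("scene_image", class(img))
      img
    })
  }
  out
}
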