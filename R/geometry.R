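#' Planar 3-DoF limb geometry
#'
#' Defines the simulated upper limb: a torso segment attached to an anchored
#' neck, an upper arm and a lower arm, drawn inside a fixed 128 x 96 pixel
#' camera frame whose coordinates coincide with workspace coordinates. Angles
#' are relative joint angles in radians; the absolute orientation of segment
#' \eqn{i} is the cumulative sum of the first \eqn{i} joint angles, so a
#' vertical torso corresponds to a neck angle of \eqn{\pi/2}.
#'
#' Default proportions (torso : upper : lower = 1 : 0.9 : 0.9, full extension
#' spanning about 70\% of the image width) and joint ranges (neck vertical
#' +/- 45 deg, shoulder -30..150 deg, elbow 0..150 deg) reproduce a
#' macaque-like peripersonal workspace in which a 3 x 3 grid of reach targets
#' is comfortably reachable.
#'
#' @param lengths segment lengths in pixels (torso, upper arm, lower arm).
#' @param lower,upper joint limits in radians (neck, shoulder, elbow).
#' @param base anchored neck position in pixels.
#' @param widths segment half-widths in pixels (visual rendering only).
#' @param img_width,img_height camera frame size in pixels.
#' @return An object of class `arm_geometry`.
#' @export
#' @examples
#' g <- arm_geometry()
#' forward_kinematics(g, c(pi / 2, pi / 4, pi / 4))
arm_geometry <- function(lengths = c(32, 29, 29),
                         lower = c(pi / 4, -pi / 6, 0),
                         upper = c(3 * pi / 4, 5 * pi / 6, 5 * pi / 6),
                         base = c(64, 12),
                         widths = c(5, 3.5, 2.5),
                         img_width = 128L, img_height = 96L) {
  stopifnot(length(lengths) == 3, length(lower) == 3, length(upper) == 3,
            length(base) == 2, length(widths) == 3)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all segment lengths must be strictly positive")
  if (any(lower >= upper))
    stop("each joint's lower limit must be below its upper limit")
  if (base[1] < 0 || base[1] > img_width || base[2] < 0 || base[2] > img_height)
    stop("base_position must lie inside the image frame")
  structure(
    list(lengths = as.numeric(lengths), lower = as.numeric(lower),
         upper = as.numeric(upper), base = as.numeric(base),
         widths = as.numeric(widths), img_width = as.integer(img_width),
         img_height = as.integer(img_height)),
    class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("<arm_geometry> segments", paste(round(x$lengths, 1), collapse = "/"),
      "px, frame", x$img_width, "x", x$img_height,
      ", neck at (", x$base[1], ",", x$base[2], ")\n")
  invisible(x)
}

#' Direct kinematics of the limb chain
#'
#' Maps joint angles to the chain of 2-D points (neck, shoulder, elbow, hand):
#' point \eqn{i+1} = point \eqn{i} + L_i (cos \sum_{j \le i} \theta_j,
#' sin \sum_{j \le i} \theta_j).
#'
#' @param geometry an [arm_geometry()].
#' @param theta 3-vector of joint angles in radians.
#' @return A 4 x 2 matrix with rows neck, shoulder, elbow, hand.
#' @export
forward_kinematics <- function(geometry, theta) {
  if (length(theta) != 3 || any(!is.finite(theta)))
    stop("theta must be a finite 3-vector")
  phi <- cumsum(theta)
  pts <- matrix(0, 4, 2, dimnames = list(
    c("neck", "shoulder", "elbow", "hand"), c("x", "y")))
  pts[1, ] <- geometry$base
  for (i in 1:3)
    pts[i + 1, ] <- pts[i, ] + geometry$lengths[i] * c(cos(phi[i]), sin(phi[i]))
  pts
}

#' Hand position for a posture
#' @inheritParams forward_kinematics
#' @return numeric length-2 (x, y) in pixels.
#' @export
hand_position <- function(geometry, theta) {
  forward_kinematics(geometry, theta)["hand", ]
}

#' Clamp joint angles to their limits
#' @inheritParams forward_kinematics
#' @export
clamp_angles <- function(geometry, theta) {
  pmin(pmax(theta, geometry$lower), geometry$upper)
}

#' Draw joint configurations uniformly within the joint limits
#'
#' Each joint angle is drawn independently and uniformly within its limits,
#' which is how training/target configurations span the operational space.
#'
#' @inheritParams forward_kinematics
#' @param n number of configurations.
#' @param seed optional integer; if given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return an `n` x 3 matrix of joint angles (a plain 3-vector if `n = 1`).
#' @export
sample_configuration <- function(geometry, n = 1, seed = NULL) {
  draw <- function() {
    m <- vapply(1:3, function(j)
      runif(n, geometry$lower[j], geometry$upper[j]), numeric(n))
    if (n == 1) as.numeric(m) else m
  }
  with_seed(seed, draw())
}

#' Damped-least-squares inverse kinematics for the hand
#'
#' Finds a within-limits posture whose hand lies at `target_xy`. Used only on
#' the generative-process side (placing targets, the home button, moving
#' targets); the agent itself never inverts kinematics explicitly. Several
#' fixed starting postures are tried to avoid local minima.
#'
#' @inheritParams forward_kinematics
#' @param target_xy hand position to reach, pixels.
#' @param theta_init optional starting posture (tried first).
#' @param tol acceptance tolerance on the hand error, pixels.
#' @param max_iter iterations per start.
#' @return list with `theta`, `error` (px) and `converged`.
#' @export
inverse_kinematics <- function(geometry, target_xy, theta_init = NULL,
                               tol = 0.5, max_iter = 200) {
  mid <- (geometry$lower + geometry$upper) / 2
  starts <- list(mid,
                 mid + c(0.3, 0.4, -0.4), mid - c(0.3, 0.4, -0.4),
                 mid + c(-0.2, 0.5, 0.5), mid + c(0.2, -0.5, 0.6))
  if (!is.null(theta_init)) starts <- c(list(as.numeric(theta_init)), starts)
  best <- NULL
  for (s in starts) {
    r <- cpp_ik(unclass(geometry), as.numeric(target_xy), s, max_iter, 1.0, tol)
    if (is.null(best) || r$error < best$error) best <- r
    if (best$error < tol) break
  }
  list(theta = as.numeric(best$theta), error = best$error,
       converged = best$error < tol)
}

#' Home-button posture
#'
#' The trial start posture: the hand rests on a home button placed on the
#' body midline in front of the neck (at 45% of the limb length by default).
#'
#' @inheritParams forward_kinematics
#' @param offset distance of the home button from the neck, as a fraction of
#'   total limb length.
#' @return 3-vector of joint angles.
#' @export
home_posture <- function(geometry, offset = 0.45) {
  hb <- geometry$base + c(0, offset * sum(geometry$lengths))
  ik <- inverse_kinematics(geometry, hb, tol = 0.25)
  if (!ik$converged)
    stop("home-button position is not reachable under this geometry")
  ik$theta
}

#' Home-button position in pixels
#' @inheritParams home_posture
#' @export
home_position <- function(geometry, offset = 0.45) {
  geometry$base + c(0, offset * sum(geometry$lengths))
}

#' Sample reachable target locations covering the operational space
#'
#' Rejection-samples hand positions uniformly over the reachable workspace:
#' candidate points are drawn uniformly in the workspace bounding box and
#' kept when inverse kinematics finds a within-limits posture within `tol`.
#' Candidates whose disc is mostly hidden behind the resting limb are also
#' rejected (`visible_frac`): the camera is positioned for full vision of
#' peripersonal targets, so targets tucked behind the torso are not part of
#' the task's operational space.
#'
#' @inheritParams forward_kinematics
#' @param n number of targets.
#' @param seed optional integer seed.
#' @param tol IK acceptance tolerance, px.
#' @param margin border margin inside the image frame, px.
#' @param visible_frac minimum fraction of target pixels visible past the
#'   limb in the trial-start posture (`0` disables the check).
#' @param radius target radius used for the visibility check, px.
#' @return tibble with columns `target_id`, `x`, `y`, `theta` (list of
#'   3-vectors).
#' @export
sample_reachable_targets <- function(geometry, n, seed = NULL, tol = 0.5,
                                     margin = 6, visible_frac = 0.5,
                                     radius = 5) {
  bb <- workspace_bbox(geometry)
  bb[c("xmin", "ymin")] <- pmax(bb[c("xmin", "ymin")], margin)
  bb["xmax"] <- min(bb["xmax"], geometry$img_width - margin)
  bb["ymax"] <- min(bb["ymax"], geometry$img_height - margin)
  hb <- if (visible_frac > 0) home_posture(geometry) else NULL
  sample_one <- function() {
    repeat {
      p <- c(runif(1, bb["xmin"], bb["xmax"]), runif(1, bb["ymin"], bb["ymax"]))
      ik <- inverse_kinematics(geometry, p, tol = tol)
      if (!ik$converged) next
      if (visible_frac > 0) {
        with_limb <- cpp_render(unclass(geometry), hb, ik$theta, radius,
                                TRUE, TRUE, 0, 0)
        alone <- cpp_render(unclass(geometry), rep(-20, 3), ik$theta, radius,
                            TRUE, TRUE, 0, 0)
        if (sum(with_limb[1, , ]) < visible_frac * sum(alone[1, , ])) next
      }
      return(list(x = p[1], y = p[2], theta = ik$theta))
    }
  }
  res <- with_seed(seed, purrr::map(seq_len(n), function(i) sample_one()))
  tibble::tibble(
    target_id = seq_len(n),
    x = purrr::map_dbl(res, "x"),
    y = purrr::map_dbl(res, "y"),
    theta = purrr::map(res, "theta"))
}

# bounding box of the hand workspace, from a coarse scan over joint space
workspace_bbox <- function(geometry, per_joint = 12) {
  gr <- lapply(1:3, function(j)
    seq(geometry$lower[j], geometry$upper[j], length.out = per_joint))
  xs <- ys <- numeric(0)
  for (a in gr[[1]]) for (b in gr[[2]]) for (cc in gr[[3]]) {
    h <- geometry$base
    phi <- cumsum(c(a, b, cc))
    h <- h + c(sum(geometry$lengths * cos(phi)), sum(geometry$lengths * sin(phi)))
    xs <- c(xs, h[1]); ys <- c(ys, h[2])
  }
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}
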