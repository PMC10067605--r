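#' Plot a scene image
#'
#' Renders the three-plane scene as an RGB raster with the origin at the
#' bottom-left (workspace convention).
#'
#' @param img a `scene_image`.
#' @return a ggplot object.
#' @export
plot_scene <- function(img) {
  d <- dim(img)
  df <- expand.grid(x = seq_len(d[2]), y = seq_len(d[3]))
  df$col <- grDevices::rgb(as.numeric(img[1, , ]), as.numeric(img[2, , ]),
                           as.numeric(img[3, , ]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$col)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flexreach_trial_log <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "step", reach = "dist",
                  perception = "perception_dist"),
    -"step", names_to = "measure", values_to = "distance")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$distance,
                                   color = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 10, linetype = "dotted") +
    ggplot2::labs(x = "time step", y = "L2 distance (px)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flexreach_sweep <- function(object, ...) {
  df <- dplyr::filter(object$summary, !is.na(.data$mean))
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$mean, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = object$param, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flexreach_trials <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::any_of(c("reach_error", "reach_time",
                                          "reach_stability",
                                          "perception_error"))),
    dplyr::everything(), names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::theme_minimal()
}

#' Gradient-field panels (one per joint)
#' @param object a [gradient_field()] tibble.
#' @param ... unused.
#' @export
autoplot.flexreach_gradient_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$angle, .data$gradient,
                                       color = factor(.data$model_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$reference),
                        linetype = "dotted", color = "red") +
    ggplot2::facet_wrap(~joint, scales = "free") +
    ggplot2::labs(x = "joint angle (rad)", y = "belief gradient",
                  color = "model") +
    ggplot2::theme_minimal()
}
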