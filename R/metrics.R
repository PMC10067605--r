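#' Reach metrics from a trial log
#'
#' The four reach measures: success (final hand-target distance within the
#' criterion, boundary inclusive), error (final distance), time (first step
#' at which the criterion holds) and stability (standard deviation of the
#' distance from first reach to trial end; defined only for successful
#' trials).
#'
#' @param log a trial log (tibble with `dist` per step) or any data frame
#'   with a distance series.
#' @param criterion reach criterion, pixels.
#' @param series column to analyze.
#' @param prefix name prefix of the returned fields.
#' @return one-row tibble `<prefix>_success`, `<prefix>_error`,
#'   `<prefix>_time`, `<prefix>_stability`.
#' @export
compute_reach_metrics <- function(log, criterion = 10, series = "dist",
                                  prefix = "reach") {
  d <- log[[series]]
  if (is.null(d) || length(d) == 0) stop("empty trial log")
  ok <- !is.na(d)
  if (!any(ok)) stop("trial log contains no distances")
  diverged <- isTRUE(attr(log, "diverged")) || any(!ok)
  final <- d[max(which(ok))]
  success <- !diverged && final <= criterion
  first <- which(d <= criterion)[1]
  stability <- if (success) sd(d[first:length(d)]) else NA_real_
  if (success && first == length(d)) stability <- 0
  # time counts the steps needed: 0 when the criterion holds immediately
  out <- tibble::tibble(success = success,
                        error = if (diverged) NA_real_ else final,
                        time = if (success) first - 1 else NA_real_,
                        stability = stability)
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Perception metrics from a trial log
#'
#' The same four measures applied to the target-estimation error: the L2
#' distance between the true target location and the hand position of the
#' target belief passed through the forward model (logged as
#' `perception_dist`).
#'
#' @inheritParams compute_reach_metrics
#' @export
compute_perception_metrics <- function(log, criterion = 10) {
  compute_reach_metrics(log, criterion, series = "perception_dist",
                        prefix = "perception")
}

#' All eight trial measures
#'
#' @inheritParams compute_reach_metrics
#' @return one-row tibble with the reach and perception fields plus
#'   `diverged` and the movement-onset step (`NA` if movement never
#'   started).
#' @export
trial_metrics <- function(log, criterion = 10) {
  onset_step <- which(log$moving > 0)[1]
  dplyr::bind_cols(
    compute_reach_metrics(log, criterion),
    compute_perception_metrics(log, criterion),
    tibble::tibble(diverged = isTRUE(attr(log, "diverged")),
                   onset_step = onset_step))
}

#' Summarize trial metrics with confidence intervals
#'
#' Per group: accuracy (percent of successful trials), mean error over all
#' completed trials, and mean time/stability over successful trials, each
#' with a 95\% confidence interval (normal approximation by default;
#' `method = "bootstrap"` resamples trials).
#'
#' @param metrics tibble of per-trial measures (rows = trials).
#' @param group_vars optional character vector of grouping columns.
#' @param conf confidence level.
#' @param method `"normal"` or `"bootstrap"`.
#' @param boot_n bootstrap resamples.
#' @return tibble, one row per group x measure, with `mean`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
summarize_trials <- function(metrics, group_vars = NULL, conf = 0.95,
                             method = c("normal", "bootstrap"),
                             boot_n = 1000) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - conf) / 2)
  one_group <- function(df) {
    specs <- list(
      reach_accuracy = list(x = 100 * as.numeric(df$reach_success)),
      reach_error = list(x = df$reach_error),
      reach_time = list(x = df$reach_time[df$reach_success]),
      reach_stability = list(x = df$reach_stability[df$reach_success]),
      perception_accuracy = list(x = 100 * as.numeric(df$perception_success)),
      perception_error = list(x = df$perception_error),
      perception_time = list(x = df$perception_time[df$perception_success]),
      perception_stability =
        list(x = df$perception_stability[df$perception_success]))
    purrr::map_dfr(names(specs), function(nm) {
      x <- specs[[nm]]$x
      x <- x[!is.na(x)]
      n <- length(x)
      if (n == 0)
        return(tibble::tibble(measure = nm, mean = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_, n = 0L))
      m <- mean(x)
      if (method == "normal") {
        se <- if (n > 1) sd(x) / sqrt(n) else 0
        lo <- m - z * se; hi <- m + z * se
      } else {
        bm <- vapply(seq_len(boot_n), function(i)
          mean(x[sample.int(n, n, replace = TRUE)]), numeric(1))
        qs <- quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2))
        lo <- qs[1]; hi <- qs[2]
      }
      tibble::tibble(measure = nm, mean = m, ci_lo = lo, ci_hi = hi,
                     n = as.integer(n))
    })
  }
  if (is.null(group_vars))
    return(one_group(metrics))
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::group_modify(function(df, key) one_group(df)) |>
    dplyr::ungroup()
}
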