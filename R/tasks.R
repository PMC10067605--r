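#' Delayed reaching experiment
#'
#' The reference protocol: the hand rests on the home button, one of the
#' nine grid targets lights up, a pure perception phase of `delay` steps
#' follows (attractor gain held at zero, the limb stationary), and then the
#' limb moves under full active inference until the trial ends. The full
#' protocol is 9 targets x 100 repetitions = 900 trials of 300 steps.
#'
#' @param geometry an [arm_geometry()].
#' @param model a visual model.
#' @param precisions a [precision_config()].
#' @param targets tibble of targets ([place_nine_targets()] by default or
#'   [sample_reachable_targets()] output); needs `target_id`, `theta` and
#'   optionally `radius`.
#' @param repetitions trials per target.
#' @param n_steps,delay trial clock, steps.
#' @param criterion reach criterion, px.
#' @param seed base seed; per-trial seeds are derived deterministically.
#' @param radius default target radius when `targets` has none.
#' @param keep_logs keep full per-step logs as a list-column? (memory!)
#' @param engine trial engine, see [run_trial()].
#' @return tibble of per-trial metrics of class `flexreach_trials` with one
#'   row per trial (`target_id`, `rep`, `seed`, the eight measures,
#'   `diverged`, `onset_step`, and optionally `log`).
#' @export
run_delayed_reaching <- function(geometry, model, precisions,
                                 targets = NULL, repetitions = 100,
                                 n_steps = 300, delay = 100, criterion = 10,
                                 seed = 1, radius = 5, keep_logs = FALSE,
                                 engine = "cpp") {
  run_task(geometry, model, precisions, targets, repetitions, n_steps,
           onset = "fixed", delay = delay, criterion = criterion,
           seed = seed, radius = radius, keep_logs = keep_logs,
           engine = engine)
}

#' Reaching with a movement-onset policy
#'
#' Same protocol as [run_delayed_reaching()] but movement onset follows the
#' selected policy: `"immediate"` (act from the first step), `"dynamic"`
#' (act once the target-belief update norm stays below `onset_threshold`
#' for `onset_persist` steps) or `"fixed"` (act after `delay` steps, the
#' delayed-reaching default).
#'
#' @inheritParams run_delayed_reaching
#' @param policy onset policy.
#' @param onset_threshold,onset_persist dynamic-policy criterion.
#' @export
run_with_onset_policy <- function(geometry, model, precisions,
                                  policy = c("immediate", "dynamic", "fixed"),
                                  targets = NULL, repetitions = 1,
                                  n_steps = 300, delay = 100,
                                  onset_threshold = 0.01, onset_persist = 5,
                                  criterion = 10, seed = 1, radius = 5,
                                  keep_logs = FALSE, engine = "cpp") {
  policy <- match.arg(policy)
  out <- run_task(geometry, model, precisions, targets, repetitions, n_steps,
                  onset = policy, delay = delay,
                  onset_threshold = onset_threshold,
                  onset_persist = onset_persist, criterion = criterion,
                  seed = seed, radius = radius, keep_logs = keep_logs,
                  engine = engine)
  out$policy <- policy
  out
}

#' Dynamic target tracking
#'
#' The target starts at a random reachable location, drifts at `speed`
#' px/step in a uniformly random direction, and reflects elastically at the
#' workspace borders. Belief and action run continuously from the first
#' step (no perception-only phase).
#'
#' @inheritParams run_delayed_reaching
#' @param n_trials number of tracking trials.
#' @param speed target speed, px/step.
#' @export
run_tracking <- function(geometry, model, precisions, n_trials = 10,
                         speed = 0.1, n_steps = 300, criterion = 10,
                         seed = 1, radius = 5, keep_logs = FALSE,
                         engine = "cpp") {
  seeds <- derive_seeds(seed, c("targets", "trials"))
  starts <- sample_reachable_targets(geometry, n_trials,
                                     seed = seeds["targets"])
  dirs <- with_seed(seeds["targets"] + 1,
                    runif(n_trials, 0, 2 * pi))
  bb <- workspace_bbox(geometry)
  bounds <- c(max(bb["xmin"], radius), min(bb["xmax"], geometry$img_width - radius),
              max(bb["ymin"], radius), min(bb["ymax"], geometry$img_height - radius))
  rows <- purrr::map(seq_len(n_trials), function(i) {
    tgt <- moving_target(c(starts$x[i], starts$y[i]),
                         speed * c(cos(dirs[i]), sin(dirs[i])), bounds,
                         radius)
    log <- run_trial(geometry, model, precisions, tgt, n_steps = n_steps,
                     onset = "immediate", seed = seeds["trials"] + i,
                     engine = engine)
    met <- trial_metrics(log, criterion)
    met$trial <- i
    met$seed <- seeds["trials"] + i
    if (keep_logs) met$log <- list(log)
    met
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flexreach_trials", class(out))
  out
}

#' Parameter sweep over precision, control or onset levels
#'
#' Runs one trial per target per level, with the target set drawn once and
#' shared across levels (and the per-trial noise seeds shared too, so level
#' contrasts are paired). Levels may sweep a precision parameter
#' (`"alpha"`, `"lambda"`, `"pi_vt"`), the motor-control scheme
#' (`"control"`: proprio/full), or the onset policy (`"onset"`). Two extra
#' pseudo-levels are recognized for `"alpha"`: `"BL"` runs the noiseless
#' baseline (alpha = 0, no proprioceptive noise).
#'
#' @inheritParams run_delayed_reaching
#' @param param swept parameter name.
#' @param levels vector of levels (numeric, or character for
#'   control/onset/BL).
#' @param n_targets random reachable targets per level.
#' @param model_factory for sweeps that need one model per level (e.g.
#'   encoder variance), a `function(level)` returning a visual model.
#' @return object of class `flexreach_sweep`: list with `$trials` (all
#'   per-trial metrics) and `$summary` (per level x measure).
#' @export
run_sweep <- function(geometry, model, precisions,
                      param = c("alpha", "lambda", "pi_vt", "control",
                                "onset", "encoder_sd"),
                      levels, n_targets = 1000, n_steps = 300, delay = 100,
                      criterion = 10, seed = 1, radius = 5,
                      model_factory = NULL, engine = "cpp") {
  param <- match.arg(param)
  seeds <- derive_seeds(seed, c("targets", "trials"))
  targets <- sample_reachable_targets(geometry, n_targets,
                                      seed = seeds["targets"])
  targets$radius <- radius
  run_level <- function(lv) {
    prec <- precisions
    mdl <- model
    onset <- "fixed"
    if (param == "alpha") {
      if (identical(lv, "BL")) {
        prec$alpha <- 0; prec$sigma_p <- 0
      } else prec$alpha <- as.numeric(lv)
    } else if (param == "lambda") prec$lambda <- as.numeric(lv)
    else if (param == "pi_vt") prec$pi_vt <- as.numeric(lv)
    else if (param == "control") prec$control <- as.character(lv)
    else if (param == "onset") onset <- as.character(lv)
    else if (param == "encoder_sd") mdl <- model_factory(as.numeric(lv))
    res <- run_task(geometry, mdl, prec, targets, repetitions = 1,
                    n_steps = n_steps, onset = onset, delay = delay,
                    criterion = criterion, seed = seeds["trials"],
                    radius = radius, engine = engine)
    res$level <- as.character(lv)
    res
  }
  trials <- dplyr::bind_rows(lapply(levels, run_level))
  summary <- summarize_trials(trials, group_vars = "level")
  structure(list(param = param, trials = trials, summary = summary),
            class = "flexreach_sweep")
}

#' @export
print.flexreach_sweep <- function(x, ...) {
  cat("<flexreach_sweep> over", x$param, "with",
      length(unique(x$trials$level)), "levels,",
      nrow(x$trials), "trials\n")
  print(x$summary, n = 20)
  invisible(x)
}

# shared driver: one trial per (target, repetition)
run_task <- function(geometry, model, precisions, targets, repetitions,
                     n_steps, onset, delay = 100, onset_threshold = 0.01,
                     onset_persist = 5, criterion = 10, seed = 1,
                     radius = 5, keep_logs = FALSE, engine = "cpp") {
  if (is.null(targets)) targets <- place_nine_targets(geometry)
  if (is.null(targets$radius)) targets$radius <- radius
  seeds <- derive_seeds(seed, c("trials"))
  grid <- expand.grid(rep = seq_len(repetitions),
                      ti = seq_len(nrow(targets)))
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    ti <- grid$ti[g]; rp <- grid$rep[g]
    trial_seed <- (seeds["trials"] + 7919 * (ti - 1) + rp) %% 2147483647
    tgt <- target_spec(targets$theta[[ti]], targets$radius[ti])
    log <- run_trial(geometry, model, precisions, tgt, n_steps = n_steps,
                     onset = onset, delay = delay,
                     onset_threshold = onset_threshold,
                     onset_persist = onset_persist,
                     seed = as.integer(trial_seed), engine = engine)
    met <- trial_metrics(log, criterion)
    met$target_id <- targets$target_id[ti]
    met$rep <- rp
    met$seed <- as.integer(trial_seed)
    # arm belief error: true vs believed hand position at trial end
    last <- nrow(log)
    met$belief_error <- sqrt((log$hand_x[last] - log$belief_hand_x[last])^2 +
                             (log$hand_y[last] - log$belief_hand_y[last])^2)
    if (keep_logs) met$log <- list(log)
    met
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flexreach_trials", class(out))
  out
}
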