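#' Configuration of a transformed up-down staircase
#'
#' The motion tasks estimate thresholds with an adaptive 2-up-1-down
#' staircase: after `n_up` (2) consecutive correct responses the stimulus is
#' made one step harder, after each incorrect response one step easier. This
#' transformed up-down rule converges at the stimulus level where
#' P(correct) = 0.5^(1/2) ~ 70.7%. Steps are multiplicative (levels span
#' large dynamic ranges and coherence is bounded by 1): harder multiplies the
#' level by `1 - scaling_factor`, easier divides by it. The staircase stops
#' at the `n_reversals_stop`-th reversal (a trial at which the step direction
#' changes) and the threshold is the mean level of the last
#' `n_reversals_average` reversals.
#'
#' `late_scaling_factor`, when set, replaces `scaling_factor` for all steps
#' taken from the `late_from_reversal`-th reversal onwards (the motion-speed
#' task shrinks its steps to 0.25 from the fifth reversal).
#'
#' @param start_level initial stimulus level.
#' @param scaling_factor proportional step size in (0, 1); default 0.33.
#' @param late_scaling_factor optional second step size (see above).
#' @param late_from_reversal reversal count from which the late factor is
#'   active.
#' @param n_reversals_stop reversals at which the staircase terminates.
#' @param n_reversals_average reversals averaged into the threshold
#'   (<= `n_reversals_stop`).
#' @param n_up consecutive correct responses required to step harder.
#' @param bounds numeric length-2; levels are clipped to this legal range.
#' @param harder direction of a "harder" step: `"down"` (lower coherence,
#'   smaller speed difference) or `"up"`.
#' @param step_type `"multiplicative"` (default) or `"additive"`.
#' @return object of class `staircase_config`.
#' @export
staircase_config <- function(start_level, scaling_factor = 0.33,
                             late_scaling_factor = NULL,
                             late_from_reversal = 5L,
                             n_reversals_stop = 8L, n_reversals_average = 4L,
                             n_up = 2L, bounds = c(1e-6, Inf),
                             harder = c("down", "up"),
                             step_type = c("multiplicative", "additive")) {
  harder <- match.arg(harder)
  step_type <- match.arg(step_type)
  stopifnot(start_level > 0,
            scaling_factor > 0, scaling_factor < 1,
            is.null(late_scaling_factor) ||
              (late_scaling_factor > 0 && late_scaling_factor < 1),
            n_reversals_average <= n_reversals_stop,
            n_up >= 1, length(bounds) == 2L, bounds[1L] < bounds[2L],
            start_level >= bounds[1L], start_level <= bounds[2L])
  structure(list(start_level = start_level, scaling_factor = scaling_factor,
                 late_scaling_factor = late_scaling_factor,
                 late_from_reversal = as.integer(late_from_reversal),
                 n_reversals_stop = as.integer(n_reversals_stop),
                 n_reversals_average = as.integer(n_reversals_average),
                 n_up = as.integer(n_up), bounds = bounds, harder = harder,
                 step_type = step_type),
            class = "staircase_config")
}

#' Staircase presets for the motion tasks
#'
#' Global motion: coherence staircase starting at 1.0 (100% coherent dots),
#' scaling factor 0.33, bounded in (0, 1]. Motion speed: speed-difference
#' staircase starting at 17.0 deg/s, scaling factor 0.33 shrinking to 0.25
#' from the fifth reversal; the legal range is open above (published
#' speed-difference cutoffs exceed the starting level, so easier-than-start
#' levels must be reachable).
#'
#' @name staircase_presets
#' @export
gm_staircase_config <- function() {
  staircase_config(start_level = 1.0, scaling_factor = 0.33,
                   bounds = c(1e-4, 1.0))
}

#' @rdname staircase_presets
#' @export
ms_staircase_config <- function() {
  staircase_config(start_level = 17.0, scaling_factor = 0.33,
                   late_scaling_factor = 0.25, late_from_reversal = 5L,
                   bounds = c(1e-3, Inf))
}

#' Start a fresh staircase trace
#'
#' @param cfg a [staircase_config()].
#' @return object of class `staircase_trace` holding the ordered trials
#'   (`levels`, `responses`), `reversal_levels`, the pending `current_level`,
#'   and a `terminated` flag.
#' @export
staircase_new <- function(cfg) {
  stopifnot(inherits(cfg, "staircase_config"))
  structure(list(levels = numeric(0), responses = logical(0),
                 reversal_trials = integer(0), reversal_levels = numeric(0),
                 current_level = cfg$start_level, n_consec_correct = 0L,
                 last_dir = NA_character_, terminated = FALSE),
            class = "staircase_trace")
}

#' Advance a staircase by one trial
#'
#' Records the response at the pending level and applies the up-down rule.
#' The consecutive-correct counter resets after every step (and after every
#' error). A reversal is logged at the level of the trial on which the step
#' direction changed; logging the reversal precedes the step-size choice, so
#' the step taken on the reversal trial that activates the late scaling
#' factor already uses it (the first level after that reversal is "after" it).
#'
#' @param state a `staircase_trace` (not yet terminated).
#' @param cfg the [staircase_config()] driving it.
#' @param correct logical response at `state$current_level`.
#' @return updated `staircase_trace`.
#' @export
staircase_step <- function(state, cfg, correct) {
  stopifnot(inherits(state, "staircase_trace"), inherits(cfg, "staircase_config"))
  if (state$terminated) stop("staircase already terminated")
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))

  trial <- length(state$levels) + 1L
  state$levels <- c(state$levels, state$current_level)
  state$responses <- c(state$responses, correct)

  dir <- NULL
  if (correct) {
    state$n_consec_correct <- state$n_consec_correct + 1L
    if (state$n_consec_correct >= cfg$n_up) dir <- "harder"
  } else {
    dir <- "easier"
  }
  if (is.null(dir)) return(state)

  state$n_consec_correct <- 0L
  if (!is.na(state$last_dir) && state$last_dir != dir) {
    state$reversal_trials <- c(state$reversal_trials, trial)
    state$reversal_levels <- c(state$reversal_levels, state$current_level)
    if (length(state$reversal_levels) >= cfg$n_reversals_stop) {
      state$terminated <- TRUE
      state$last_dir <- dir
      return(state)
    }
  }
  state$last_dir <- dir

  s <- cfg$scaling_factor
  if (!is.null(cfg$late_scaling_factor) &&
      length(state$reversal_levels) >= cfg$late_from_reversal)
    s <- cfg$late_scaling_factor

  lv <- state$current_level
  sgn <- if ((dir == "harder") == (cfg$harder == "down")) -1 else 1
  lv <- if (cfg$step_type == "multiplicative") {
    if (sgn < 0) lv * (1 - s) else lv / (1 - s)
  } else {
    lv + sgn * s
  }
  state$current_level <- min(max(lv, cfg$bounds[1L]), cfg$bounds[2L])
  state
}

#' Run a staircase against a responder
#'
#' @param cfg a [staircase_config()].
#' @param respond function(level) -> logical; e.g. a closure over an
#'   [observer_model()] or a recorded response sequence.
#' @param max_trials safety cap.
#' @return terminated `staircase_trace` (or the partial trace at the cap).
#' @export
staircase_run <- function(cfg, respond, max_trials = 10000L) {
  st <- staircase_new(cfg)
  while (!st$terminated && length(st$levels) < max_trials)
    st <- staircase_step(st, cfg, isTRUE(respond(st$current_level)))
  st
}

#' Replay a recorded response sequence through the staircase rule
#'
#' Reconstructs the full trace (levels, reversals, threshold) bit-exactly
#' from a stored correct/incorrect sequence, the form trial-level data is
#' archived in.
#'
#' @param cfg a [staircase_config()].
#' @param responses logical vector in trial order.
#' @return `staircase_trace` after consuming the responses (stops early at
#'   termination).
#' @export
staircase_replay <- function(cfg, responses) {
  st <- staircase_new(cfg)
  for (r in responses) {
    if (st$terminated) break
    st <- staircase_step(st, cfg, isTRUE(r))
  }
  st
}

#' Threshold from a terminated staircase
#'
#' Arithmetic mean of the last `n_reversals_average` reversal levels.
#'
#' @param trace a terminated `staircase_trace`.
#' @param cfg its [staircase_config()].
#' @return threshold estimate (stimulus units).
#' @export
staircase_threshold <- function(trace, cfg) {
  stopifnot(inherits(trace, "staircase_trace"), inherits(cfg, "staircase_config"))
  if (!trace$terminated)
    stop(sprintf("staircase not terminated: %d of %d reversals reached",
                 length(trace$reversal_levels), cfg$n_reversals_stop))
  mean(utils::tail(trace$reversal_levels, cfg$n_reversals_average))
}

#' @export
print.staircase_trace <- function(x, ...) {
  cat(sprintf("Staircase trace: %d trials, %d reversals%s\n",
              length(x$levels), length(x$reversal_levels),
              if (x$terminated) " (terminated)" else ""))
  invisible(x)
}
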