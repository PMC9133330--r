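#' Draw standardized scores for a healthy reference population
#'
#' Samples `n` individuals from the multivariate standard-normal latent model
#' of a [reference_model()]. Each column is marginally N(0, 1); the empirical
#' inter-task correlations converge to the model's matrix as `n` grows.
#'
#' Sampling uses the Cholesky factor when the matrix is positive definite and
#' an eigendecomposition (negative eigenvalues clipped at zero, tolerance
#' 1e-10) for the semi-definite boundary cases such as perfect correlation.
#'
#' @param model a [reference_model()].
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed; identical seeds give identical tables.
#' @return numeric matrix `n` x tasks with task-name columns.
#' @export
generate_reference_scores <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "reference_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a count >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  R <- model$correlation
  p <- ncol(R)
  fac <- tryCatch(chol(R), error = function(e) NULL)
  z <- matrix(stats::rnorm(n * p), n, p)
  x <- if (!is.null(fac)) {
    z %*% fac
  } else {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-10)
      stop(sprintf("correlation not PSD (smallest eigenvalue %.3e)", min(e$values)))
    z %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
  }
  colnames(x) <- model$task_names
  x
}

#' Planted-impairment specification for synthetic patient cohorts
#'
#' Ground-truth description of a simulated patient group: which functions are
#' impaired and by how much, in standardized units.
#'
#' @param affected_functions character vector of function names in the model.
#' @param shift mean decrement applied to every task of an affected function,
#'   in z-units (>= 0; 0 reproduces the reference population).
#' @param n_patients cohort size (>= 1).
#' @param seed integer seed.
#' @export
impairment_spec <- function(affected_functions = character(), shift = 0,
                            n_patients = 1L, seed = 1L) {
  stopifnot(shift >= 0, n_patients >= 1)
  structure(list(affected_functions = affected_functions, shift = shift,
                 n_patients = as.integer(n_patients), seed = as.integer(seed)),
            class = "impairment_spec")
}

#' Generate a patient cohort with planted impairment
#'
#' Draws reference-distribution scores and subtracts `spec$shift` from every
#' task belonging to an affected function, so that the probability of a score
#' below a cutoff `z` on an affected task is `pnorm(z + shift)` by the normal
#' tail. Ground truth is attached for parameter-recovery tests.
#'
#' @param model a [reference_model()].
#' @param spec an [impairment_spec()].
#' @return list with `scores` (matrix n x tasks), `impaired_tasks` (logical,
#'   by task) and `spec`.
#' @export
generate_patient_cohort <- function(model, spec) {
  stopifnot(inherits(model, "reference_model"), inherits(spec, "impairment_spec"))
  unknown <- setdiff(spec$affected_functions, names(model$tasks))
  if (length(unknown))
    stop("unknown function(s): ", paste(unknown, collapse = ", "))
  scores <- generate_reference_scores(model, spec$n_patients, seed = spec$seed)
  impaired <- model$grouping %in% spec$affected_functions
  names(impaired) <- model$task_names
  scores[, impaired] <- scores[, impaired, drop = FALSE] - spec$shift
  list(scores = scores, impaired_tasks = impaired, spec = spec)
}

#' Simulated psychophysical observer
#'
#' Stands in for a participant in an adaptive staircase task. Probability of
#' a correct response at stimulus `level` is
#' `guess + (1 - guess - lapse) * F(level)` with `F` a cumulative Gaussian in
#' log stimulus level: `pnorm(slope * (log(level) - log(true_threshold)))`.
#' Larger levels (more coherence, larger speed difference) are easier.
#'
#' @param true_threshold level at which `F` = 0.5 (midpoint of the
#'   psychometric function, before guess/lapse scaling).
#' @param slope steepness per log-unit (> 0).
#' @param guess_rate lower asymptote (0.5 for two-alternative tasks).
#' @param lapse_rate lapse probability in `[0, 0.1]`.
#' @export
observer_model <- function(true_threshold, slope, guess_rate = 0.5,
                           lapse_rate = 0.02) {
  stopifnot(true_threshold > 0, slope > 0,
            guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate <= 0.1)
  structure(list(true_threshold = true_threshold, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = "observer_model")
}

#' @rdname observer_model
#' @param obs an `observer_model`.
#' @param level stimulus level (> 0).
#' @return `observer_p_correct()`: probability of a correct response;
#'   `simulate_observer_response()`: a single logical draw.
#' @export
observer_p_correct <- function(obs, level) {
  stopifnot(inherits(obs, "observer_model"), all(level > 0))
  f <- stats::pnorm(obs$slope * (log(level) - log(obs$true_threshold)))
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) * f
}

#' @rdname observer_model
#' @export
simulate_observer_response <- function(obs, level) {
  stats::runif(length(level)) < observer_p_correct(obs, level)
}

#' Stimulus level at which an observer reaches a criterion probability
#'
#' Inverts the observer's psychometric function: the level where P(correct)
#' equals `p_target`. The 2-up-1-down staircase rule converges at
#' P(correct) = sqrt(1/2) ~ 0.707, so `observer_criterion_level(obs)` is the
#' quantity the reversal-mean threshold estimates.
#'
#' @inheritParams observer_p_correct
#' @param p_target criterion probability, strictly between `guess_rate` and
#'   `1 - lapse_rate`.
#' @export
observer_criterion_level <- function(obs, p_target = sqrt(0.5)) {
  stopifnot(inherits(obs, "observer_model"))
  f <- (p_target - obs$guess_rate) / (1 - obs$guess_rate - obs$lapse_rate)
  if (f <= 0 || f >= 1) stop("p_target outside the observer's attainable range")
  obs$true_threshold * exp(stats::qnorm(f) / obs$slope)
}

#' Simulate visual-search reaction times
#'
#' Serial-search generative model: the reaction time of a search trial is the
#' motor response time plus a scan time proportional to the expected number
#' of pictures inspected before the target, `(n_distracters + 1) / 2` under
#' random serial inspection of `n_distracters + 1` pictures. RTs are
#' lognormal around that median (`sigma` on the log scale), so the trial
#' median targets `motor_median + scan_per_item * (n_distracters + 1) / 2`
#' exactly; medians, the pipeline's statistic, are what the family is chosen
#' to get right. False alarms are flagged independently at `error_rate`.
#'
#' @param motor_median median simple reaction time, seconds.
#' @param scan_per_item seconds of scan time per inspected picture (>= 0;
#'   0 reproduces the simple reaction-time task).
#' @param n_distracters distracters on screen (0 for the reaction-time task).
#' @param n_trials number of trials.
#' @param error_rate false-alarm probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @param sigma lognormal log-scale spread.
#' @return data.frame with columns `rt` (seconds), `false_alarm` (logical).
#' @export
generate_search_rts <- function(motor_median, scan_per_item, n_distracters,
                                n_trials, error_rate = 0.05, seed = NULL,
                                sigma = 0.3) {
  stopifnot(motor_median > 0, scan_per_item >= 0, n_distracters >= 0,
            n_trials >= 1, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  med <- motor_median + scan_per_item * (n_distracters + 1) / 2
  rt <- med * exp(sigma * stats::rnorm(n_trials))
  fa <- stats::runif(n_trials) < error_rate
  data.frame(rt = rt, false_alarm = fa)
}
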