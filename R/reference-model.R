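#' Correlated healthy reference model for a test battery
#'
#' A `reference_model` describes the latent joint distribution of standardized
#' task scores in the healthy reference population: a set of task names
#' grouped into functions (object recognition, motion perception, visual
#' attention, visuomotor skills) and a correlation matrix over the tasks.
#' Individual scores are modelled as multivariate standard normal with this
#' correlation, so a score below `qnorm(p)` falls below the population's
#' p-th percentile by construction.
#'
#' The true inter-task correlations of a given normative sample are data, not
#' theory; the matrix here is an input. [default_reference_model()] ships a
#' clearly synthetic exchangeable stand-in (see its help).
#'
#' @param tasks named list: function name -> character vector of task names.
#'   Task names must be unique across functions.
#' @param correlation symmetric positive-semidefinite matrix with unit
#'   diagonal, dimnames equal to the task names (any order).
#' @return object of class `reference_model` with elements `tasks`,
#'   `task_names`, `grouping` (task -> function), `correlation`.
#' @seealso [generate_reference_scores()], [base_rate_counts()]
#' @export
reference_model <- function(tasks, correlation) {
  stopifnot(is.list(tasks), length(tasks) >= 1L)
  task_names <- unlist(tasks, use.names = FALSE)
  if (anyDuplicated(task_names))
    stop("task names must be unique across functions")
  correlation <- as.matrix(correlation)
  p <- length(task_names)
  if (!all(dim(correlation) == p))
    stop("correlation must be ", p, "x", p)
  if (is.null(dimnames(correlation))) {
    dimnames(correlation) <- list(task_names, task_names)
  } else {
    if (!setequal(rownames(correlation), task_names))
      stop("correlation dimnames do not match task names")
    correlation <- correlation[task_names, task_names]
  }
  if (max(abs(correlation - t(correlation))) > 1e-12)
    stop("correlation matrix is not symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf(
      "correlation matrix is not positive semi-definite (smallest eigenvalue %.3e)",
      min(ev)))
  grouping <- rep(names(tasks), lengths(tasks))
  names(grouping) <- task_names
  structure(
    list(tasks = tasks, task_names = task_names, grouping = grouping,
         correlation = correlation),
    class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("Reference model:", length(x$task_names), "tasks in",
      length(x$tasks), "functions\n")
  for (f in names(x$tasks))
    cat("  ", f, ": ", paste(x$tasks[[f]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Exchangeable correlation matrix by function block
#'
#' Builds a correlation matrix with one correlation for task pairs within the
#' same function and another for pairs in different functions.
#'
#' @param tasks named list as in [reference_model()].
#' @param rho_within,rho_between correlations in `[-1, 1]`.
#' @return correlation matrix with task dimnames.
#' @export
exchangeable_correlation <- function(tasks, rho_within = 0.3, rho_between = 0.1) {
  task_names <- unlist(tasks, use.names = FALSE)
  fun <- rep(names(tasks), lengths(tasks))
  p <- length(task_names)
  m <- matrix(rho_between, p, p, dimnames = list(task_names, task_names))
  for (f in unique(fun)) {
    i <- which(fun == f)
    m[i, i] <- rho_within
  }
  diag(m) <- 1
  m
}

#' Default battery layout and synthetic reference correlations
#'
#' The seven-task battery analysed by the pipeline: five object recognition
#' subtasks (VISM, NOISE, OVERL, VIEW, DEVOS), three motion tasks (GM, MDF,
#' MS), three visual-search load conditions standing in for the attention
#' task, and two visuomotor tasks (BEERY, MOSAICS).
#'
#' The correlation matrix is a synthetic stand-in (the normative samples'
#' correlations are unpublished): exchangeable, `rho_within` within a
#' function and `rho_between` across functions. The default 0.3/0.1 places
#' the >=1-of-5 base rate at the 5th percentile between the independence
#' value 22.6% and the perfect-correlation value 5%, the regime implied by
#' published base rates near 20%. Override with your own matrix (or
#' [read_reference_model()]) whenever empirical correlations are available.
#'
#' @inheritParams exchangeable_correlation
#' @return a [reference_model()].
#' @export
default_reference_model <- function(rho_within = 0.3, rho_between = 0.1) {
  tasks <- list(
    object_recognition = c("VISM", "NOISE", "OVERL", "VIEW", "DEVOS"),
    motion             = c("GM", "MDF", "MS"),
    attention          = c("SEARCH5", "SEARCH10", "SEARCH20"),
    visuomotor         = c("BEERY", "MOSAICS"))
  reference_model(tasks, exchangeable_correlation(tasks, rho_within, rho_between))
}

#' Read a reference model from a YAML config file
#'
#' Expected layout:
#' ```yaml
#' tasks:
#'   object_recognition: [VISM, NOISE]
#'   motion: [GM]
#' correlation:
#'   rho_within: 0.3        # exchangeable form, or
#'   rho_between: 0.1
#' # correlation: matrix: [[1, 0.2], [0.2, 1], ...] with rows in task order
#' ```
#'
#' @param path YAML file path.
#' @return a [reference_model()].
#' @export
read_reference_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tasks)) stop("config missing 'tasks'")
  tasks <- lapply(cfg$tasks, as.character)
  corr <- cfg$correlation
  m <- if (!is.null(corr$matrix)) {
    do.call(rbind, lapply(corr$matrix, as.numeric))
  } else {
    exchangeable_correlation(tasks,
                             rho_within  = corr$rho_within  %||% 0.3,
                             rho_between = corr$rho_between %||% 0.1)
  }
  reference_model(tasks, m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
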