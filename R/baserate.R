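#' Monte Carlo base rate for multi-test abnormality counts
#'
#' On a battery of correlated tests, the expected proportion of the *healthy*
#' population showing at least `k_min` scores below a standardized cutoff —
#' the base rate — is well above the single-test percentile and depends on
#' the inter-test correlations. It is estimated by simulating standardized
#' score vectors from the reference model and counting individuals meeting
#' the criterion.
#'
#' All `k_min` values are evaluated on one shared simulant matrix, so the
#' estimates are exactly non-increasing in `k_min` for a given seed, and a
#' single seeded call is bit-reproducible.
#'
#' @param model a [reference_model()].
#' @param z_threshold standardized cutoff; `qnorm(0.05)` = -1.645 for the 5th
#'   percentile, `qnorm(0.10)` = -1.282 for the 10th.
#' @param k_min integer vector of minimum abnormal counts (>= 1).
#' @param n_sims Monte Carlo draws (>= 1e4; default 1e6 puts the standard
#'   error at or below 0.0005 for proportions near 0.2).
#' @param seed optional integer seed.
#' @param tasks optional subset of model task names to restrict the battery.
#' @return object of class `base_rate_estimate`: data.frame with columns
#'   `criterion`, `proportion`, `se` (binomial Monte Carlo SE), `n_sims`.
#' @examples
#' m <- reference_model(list(f = paste0("t", 1:5)), diag(5))
#' base_rate_counts(m, k_min = 1, n_sims = 1e4, seed = 1)  # ~ 1 - 0.95^5
#' @export
base_rate_counts <- function(model, z_threshold = stats::qnorm(0.05),
                             k_min = 1L, n_sims = 1e6, seed = NULL,
                             tasks = NULL) {
  stopifnot(n_sims >= 1e4, all(k_min >= 1))
  scores <- generate_reference_scores(model, n_sims, seed = seed)
  if (!is.null(tasks)) {
    stopifnot(all(tasks %in% colnames(scores)))
    scores <- scores[, tasks, drop = FALSE]
  }
  counts <- rowSums(scores < z_threshold)
  .base_rate_result(counts, k_min, n_sims, sprintf(">=%d abnormal", k_min))
}

#' Monte Carlo base rate for weak-function counts
#'
#' Per simulated individual a function is weak iff at least one of its tasks
#' scores below `z_threshold`; the base rate is the proportion with at least
#' `m_min` weak functions.
#'
#' @inheritParams base_rate_counts
#' @param grouping named list: function name -> task names (defaults to the
#'   model's grouping); every group must be non-empty.
#' @param m_min integer vector of minimum weak-function counts (>= 0).
#' @export
base_rate_functions <- function(model, grouping = model$tasks,
                                z_threshold = stats::qnorm(0.10),
                                m_min = 2L, n_sims = 1e6, seed = NULL) {
  stopifnot(n_sims >= 1e4, all(m_min >= 0))
  if (any(lengths(grouping) == 0L)) stop("empty function group")
  unknown <- setdiff(unlist(grouping), model$task_names)
  if (length(unknown))
    stop("grouping names tasks not in the model: ",
         paste(unknown, collapse = ", "))
  scores <- generate_reference_scores(model, n_sims, seed = seed)
  weak <- vapply(grouping, function(tk)
    rowSums(scores[, tk, drop = FALSE] < z_threshold) >= 1L,
    logical(nrow(scores)))
  counts <- rowSums(weak)
  .base_rate_result(counts, m_min, n_sims, sprintf(">=%d weak functions", m_min))
}

.base_rate_result <- function(counts, crit, n_sims, labels) {
  p <- vapply(crit, function(k) mean(counts >= k), numeric(1))
  structure(data.frame(criterion = labels, p = p,
                       se = sqrt(p * (1 - p) / n_sims), n_sims = n_sims),
            class = c("base_rate_estimate", "data.frame"))
}

#' Closed-form base rate under independence
#'
#' Exact Poisson-binomial tail P(X >= k) for independent tests with marginal
#' flag probabilities `marginals`; the verification oracle for the Monte
#' Carlo engine (at identity correlation the two must agree to Monte Carlo
#' error).
#'
#' @param marginals per-test probabilities in `[0, 1]`.
#' @param k_min minimum count (vectorised).
#' @return numeric vector of tail probabilities.
#' @examples
#' base_rate_independent(rep(0.05, 5), 1)  # 1 - 0.95^5 = 0.2262
#' @export
base_rate_independent <- function(marginals, k_min) {
  stopifnot(all(marginals >= 0), all(marginals <= 1))
  pmf <- 1  # distribution of the count, built by convolution
  for (p in marginals) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  cdf <- cumsum(pmf)
  vapply(k_min, function(k) {
    if (k <= 0) 1 else if (k > length(marginals)) 0 else 1 - cdf[k]
  }, numeric(1))
}

#' Attainable range of a weak-function base rate over correlation
#'
#' Treats the three dorsal functions as single latent normal variables with
#' fixed weak-rates (`marginals`), imposes an exchangeable correlation
#' `rho`, and estimates P(at least `m_min` weak) by Monte Carlo at each
#' value of a `rho` grid. Used to bracket published base rates whose exact
#' reference correlations are unavailable.
#'
#' @param marginals function-level weak probabilities.
#' @param m_min minimum number of weak functions.
#' @param rho grid of exchangeable correlations in `[0, 1]`.
#' @param n_sims draws per grid point.
#' @param seed integer seed (shared normal draws across the grid).
#' @return data.frame `rho`, `proportion`.
#' @export
base_rate_rho_sweep <- function(marginals, m_min = 2L,
                                rho = seq(0, 1, by = 0.05),
                                n_sims = 1e5, seed = NULL) {
  stopifnot(all(marginals > 0), all(marginals < 1), all(rho >= 0), all(rho <= 1))
  if (!is.null(seed)) set.seed(seed)
  p <- length(marginals)
  zs <- stats::qnorm(marginals)
  common <- stats::rnorm(n_sims)
  uniq <- matrix(stats::rnorm(n_sims * p), n_sims, p)
  prop <- vapply(rho, function(r) {
    x <- sqrt(r) * common + sqrt(1 - r) * uniq
    mean(rowSums(sweep(x, 2L, zs, `<`)) >= m_min)
  }, numeric(1))
  data.frame(rho = rho, proportion = prop)
}

#' @export
print.base_rate_estimate <- function(x, ...) {
  cat("Monte Carlo base rate (", x$n_sims[1L], " draws):\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-22s %6.2f%%  (SE %.3f%%)\n",
                x$criterion[i], 100 * x$p[i], 100 * x$se[i]))
  invisible(x)
}
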