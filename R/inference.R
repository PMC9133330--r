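#' One-sample binomial test against a fixed base rate
#'
#' Tests whether an observed proportion of flagged patients exceeds the
#' population base rate `p0`, treated as a fixed number. The primary p-value
#' is the exact one-sided binomial tail P(X >= successes); a score-test z is
#' reported as a secondary descriptive (with optional continuity correction —
#' published z values for these designs vary with that choice and do not pin
#' it down).
#'
#' @param successes,n counts, `0 <= successes <= n`.
#' @param p0 base rate in (0, 1).
#' @param continuity apply a continuity correction of 0.5/n to the z
#'   statistic.
#' @return list of class `battery_test`: `method`, `statistic` (z),
#'   `p_one_sided` (greater), `p_two_sided`, `exact`, `estimate`.
#' @examples
#' binomial_vs_baserate(3, 10, 0.1)$p_one_sided   # 0.0702
#' @export
binomial_vs_baserate <- function(successes, n, p0, continuity = FALSE) {
  stopifnot(successes >= 0, successes <= n, n >= 1)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  p_one <- stats::pbinom(successes - 1L, n, p0, lower.tail = FALSE)
  p_two <- stats::binom.test(successes, n, p = p0)$p.value
  phat <- successes / n
  cc <- if (continuity) 0.5 / n else 0
  z <- (phat - p0 - sign(phat - p0) * cc) / sqrt(p0 * (1 - p0) / n)
  .battery_test("one-sample binomial (exact tail)", statistic = c(z = z),
                p_one_sided = p_one, p_two_sided = p_two, exact = TRUE,
                estimate = phat)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param successes,n counts.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` proportions; always contains
#'   `successes/n`.
#' @examples
#' round(100 * exact_binomial_ci(29, 46), 1)  # 47.5 76.8
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(successes >= 0, successes <= n, n >= 1)
  ci <- stats::binom.test(successes, n, conf.level = level)$conf.int
  c(lower = ci[1L], upper = ci[2L])
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test for small samples. The one-sided p-value is the
#' hypergeometric tail in the direction of the observed association (larger
#' first-cell odds when `ad > bc`); the two-sided p-value sums the
#' probabilities of all tables, at fixed margins, no more probable than the
#' observed one (the probability-mass convention).
#'
#' @param tab 2x2 matrix of non-negative counts, rows = groups, columns =
#'   outcome present/absent; or the count `a` with `b`, `c`, `d` given.
#' @param b,c,d remaining cells when `tab` is given as a scalar.
#' @return `battery_test` with the conditional odds-ratio MLE as statistic.
#' @examples
#' fisher_exact(13, 5, 3, 8)$p_one_sided  # 0.0234
#' @export
fisher_exact <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(tab)) tab <- matrix(c(tab, b, c, d), 2L, 2L, byrow = TRUE)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate margin: no association is possible; p = 1")
    return(.battery_test("Fisher's exact", statistic = c(odds_ratio = NA),
                         p_one_sided = 1, p_two_sided = 1, exact = TRUE))
  }
  dir <- if (tab[1, 1] * tab[2, 2] >= tab[1, 2] * tab[2, 1]) "greater" else "less"
  one <- stats::fisher.test(tab, alternative = dir)
  two <- stats::fisher.test(tab)
  .battery_test("Fisher's exact",
                statistic = c(odds_ratio = unname(two$estimate)),
                p_one_sided = one$p.value, p_two_sided = two$p.value,
                exact = TRUE)
}

#' Mann-Whitney U test with midranks and tie-corrected z
#'
#' U is computed from rank sums using midranks for ties; the reported U is
#' the smaller of the two group statistics, as conventionally printed. The z
#' statistic uses the normal approximation with tie-corrected variance and
#' no continuity correction, signed so that a first sample tending to lower
#' ranks gives negative z. P-values are exact — from the null U distribution
#' when there are no ties and `n1*n2 <= 400`, or by complete enumeration of
#' group assignments for tied pooled samples up to `choose(n, n1) <= 20000`
#' — and otherwise from the tie-corrected normal approximation.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` (x tends lower) or
#'   `"greater"`.
#' @return `battery_test` with `statistic = c(U = ..., z = ...)`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_one_sided  # 1/choose(6,3) = 0.05
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  mu <- n1 * n2 / 2

  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sig2 > 0) (u1 - mu) / sqrt(sig2) else 0

  has_ties <- any(ties > 1)
  if (sig2 == 0) {                       # every value tied across both samples
    p_less <- p_greater <- 1; p_two <- 1; exact <- TRUE
  } else if (!has_ties && n1 * n2 <= 400) {
    p_less <- stats::pwilcox(u1, n1, n2)
    p_greater <- stats::pwilcox(u2, n1, n2)
    p_two <- min(1, 2 * min(p_less, p_greater))
    exact <- TRUE
  } else if (has_ties && choose(n, n1) <= 20000) {
    idx <- utils::combn(n, n1)
    u1s <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_less <- mean(u1s <= u1 + eps)
    p_greater <- mean(u1s >= u1 - eps)
    p_two <- mean(abs(u1s - mu) >= abs(u1 - mu) - eps)
    exact <- TRUE
  } else {
    p_less <- stats::pnorm(z)
    p_greater <- stats::pnorm(z, lower.tail = FALSE)
    p_two <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  p_one <- switch(alternative, less = p_less, greater = p_greater,
                  two.sided = min(p_less, p_greater))
  .battery_test("Mann-Whitney U", statistic = c(U = u, z = z),
                p_one_sided = p_one, p_two_sided = min(1, p_two),
                exact = exact)
}

.battery_test <- function(method, statistic, p_one_sided, p_two_sided,
                          exact, estimate = NULL) {
  structure(list(method = method, statistic = statistic,
                 p_one_sided = p_one_sided, p_two_sided = p_two_sided,
                 exact = exact, estimate = estimate),
            class = "battery_test")
}

#' @export
print.battery_test <- function(x, ...) {
  st <- paste(sprintf("%s = %.3g", names(x$statistic), x$statistic),
              collapse = ", ")
  cat(sprintf("%s: %s, one-sided p %s, two-sided p %s%s\n", x$method, st,
              format_p(x$p_one_sided), format_p(x$p_two_sided),
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Format a p-value in report style
#'
#' Two decimals with a "<0.01" floor, the convention used in the printed
#' reports; machine-readable output keeps full precision.
#' @param p numeric p-value(s).
#' @export
format_p <- function(p) {
  ifelse(p < 0.005, "<0.01", sprintf("%.2f", p))
}
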