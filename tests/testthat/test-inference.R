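test_that("exact binomial tail against a fixed base rate", {
  r <- binomial_vs_baserate(3, 10, 0.1)
  expect_equal(r$p_one_sided, sum(stats::dbinom(3:10, 10, 0.1)),
               tolerance = 1e-12)
  expect_equal(round(r$p_one_sided, 4), 0.0702)
  # observing exactly the null expectation leaves p near 1/2
  expect_lt(abs(binomial_vs_baserate(200, 1000, 0.2)$p_one_sided - 0.5), 0.05)
  # the study-sized comparison is decisively significant
  expect_lt(binomial_vs_baserate(29, 46, 0.196)$p_one_sided, 0.01)
  expect_error(binomial_vs_baserate(3, 10, 0), "p0")
  # p monotone decreasing in the observed count
  p <- vapply(0:10, function(s) binomial_vs_baserate(s, 10, 0.3)$p_one_sided,
              numeric(1))
  expect_true(all(diff(p) < 0))
  # tail identity: p = 1 - cumulative pmf below the observed count
  expect_equal(binomial_vs_baserate(7, 20, 0.25)$p_one_sided,
               1 - stats::pbinom(6, 20, 0.25), tolerance = 1e-12)
})

test_that("Clopper-Pearson interval matches its beta-quantile closed form", {
  cp <- function(x, n) c(if (x == 0) 0 else stats::qbeta(0.025, x, n - x + 1),
                         if (x == n) 1 else stats::qbeta(0.975, x + 1, n - x))
  for (xn in list(c(29, 46), c(11, 46), c(6, 46), c(0, 12), c(12, 12))) {
    expect_equal(unname(exact_binomial_ci(xn[1], xn[2])), cp(xn[1], xn[2]),
                 tolerance = 1e-9)
  }
  expect_equal(round(100 * exact_binomial_ci(29, 46), 1),
               c(lower = 47.5, upper = 76.8))
  expect_equal(round(100 * exact_binomial_ci(11, 46), 1),
               c(lower = 12.6, upper = 38.8))
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  ci <- exact_binomial_ci(7, 9)
  expect_true(ci[["lower"]] < 7 / 9 && 7 / 9 < ci[["upper"]])
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(17)
  for (par in list(c(30, 0.2), c(46, 0.63))) {
    n <- par[1]; p <- par[2]
    x <- stats::rbinom(1e4, n, p)
    lo <- ifelse(x == 0, 0, stats::qbeta(0.025, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(0.975, x + 1, n - x))
    expect_gte(mean(lo <= p & p <= hi), 0.95)
  }
})

test_that("Fisher's exact test reproduces the enumeration oracle", {
  r <- fisher_exact(13, 5, 3, 8)
  expect_equal(round(r$p_one_sided, 4), 0.0234)
  expect_equal(round(fisher_exact(9, 9, 1, 10)$p_one_sided, 4), 0.0289)
  expect_warning(p0 <- fisher_exact(0, 5, 0, 5), "degenerate")
  expect_equal(p0$p_one_sided, 1)
  set.seed(19)
  for (rep in 1:30) {
    tab <- matrix(stats::rpois(4, sample(1:8, 1)), 2, 2)
    if (sum(tab) > 40 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    o <- oracle_fisher(tab)
    f <- fisher_exact(tab)
    expect_equal(f$p_one_sided, o$one_sided, tolerance = 1e-9)
    expect_equal(f$p_two_sided, o$two_sided, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U: exact small-sample tails and tie handling", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(unname(r$statistic["U"]), 0)
  expect_equal(r$p_one_sided, 1 / choose(6, 3), tolerance = 1e-12)
  expect_true(r$exact)

  same <- mann_whitney_u(c(2, 5, 9), c(2, 5, 9))
  expect_equal(unname(same$statistic["U"]), 3 * 3 / 2)
  expect_equal(unname(same$statistic["z"]), 0)

  tied <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(unname(tied$statistic["U"]), 2)
  expect_equal(tied$p_two_sided, 1)

  allsame <- mann_whitney_u(c(3, 3), c(3, 3, 3))
  expect_equal(allsame$p_two_sided, 1)
  expect_equal(unname(allsame$statistic["z"]), 0)
})

test_that("Mann-Whitney agrees with permutation and distributional oracles", {
  set.seed(23)
  for (rep in 1:10) {
    x <- sample(1:6, 4, replace = TRUE)   # ties likely
    y <- sample(1:6, 4, replace = TRUE)
    o <- oracle_mw(x, y)
    r <- mann_whitney_u(x, y, alternative = "less")
    expect_equal(r$p_one_sided, o$p_less, tolerance = 1e-9)
    expect_equal(r$p_two_sided, o$p_two, tolerance = 1e-9)
  }
  # untied case against the exact null distribution in stats::wilcox.test
  x <- c(0.1, 1.3, 2.2, 2.9); y <- c(0.6, 3.8, 4.4, 4.9, 5.6)
  r <- mann_whitney_u(x, y, alternative = "less")
  w <- stats::wilcox.test(x, y, alternative = "less", exact = TRUE)
  expect_equal(r$p_one_sided, w$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(29)
  x <- stats::rnorm(8); y <- stats::rnorm(9) + 0.5
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  expect_identical(a$statistic, b$statistic)
  expect_identical(a$p_two_sided, b$p_two_sided)
})

test_that("the tie-corrected z matches the reference normal approximation", {
  set.seed(31)
  x <- round(stats::rnorm(25), 1)   # rounding forces ties
  y <- round(stats::rnorm(30, 0.4), 1)
  r <- mann_whitney_u(x, y, alternative = "less")
  w <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                          correct = FALSE)
  expect_false(r$exact)
  expect_equal(r$p_one_sided, w$p.value, tolerance = 1e-9)
  expect_equal(stats::pnorm(unname(r$statistic["z"])), w$p.value,
               tolerance = 1e-9)
})

test_that("p-values format in report style with the <0.01 floor", {
  expect_equal(format_p(c(0.234, 0.0049, 0.02344)), c("0.23", "<0.01", "0.02"))
})
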