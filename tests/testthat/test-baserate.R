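ident5 <- reference_model(list(battery = paste0("t", 1:5)), diag(5))

test_that("closed-form tail matches complete enumeration and known values", {
  expect_equal(base_rate_independent(rep(0.05, 5), 1), 1 - 0.95^5)
  expect_equal(base_rate_independent(rep(0.05, 5), 2),
               1 - 0.95^5 - 5 * 0.05 * 0.95^4)
  expect_equal(base_rate_independent(0.3, 1), 0.3)
  expect_equal(base_rate_independent(rep(1, 4), 3), 1)
  expect_equal(base_rate_independent(c(0.279, 0.211, 0.168), 2),
               0.279 * 0.211 + 0.279 * 0.168 + 0.211 * 0.168 -
                 2 * 0.279 * 0.211 * 0.168, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:10) {
    p <- stats::runif(sample(2:6, 1))
    k <- sample(seq_along(p), 1)
    expect_equal(base_rate_independent(p, k), oracle_poisbin_tail(p, k),
                 tolerance = 1e-12)
  }
})

test_that("Monte Carlo base rate agrees with the independence oracle", {
  est <- base_rate_counts(ident5, k_min = 1:3, n_sims = 1e5, seed = 4)
  truth <- base_rate_independent(rep(0.05, 5), 1:3)
  expect_true(all(abs(est$p - truth) < 4 * pmax(est$se, 1e-4)))
})

test_that("perfect correlation collapses the battery to a single test", {
  ones <- matrix(1, 5, 5)
  m <- reference_model(list(battery = paste0("t", 1:5)), ones)
  est <- base_rate_counts(m, k_min = c(1, 3, 5), n_sims = 5e4, seed = 2)
  # all scores identical within an individual: every criterion has the same
  # rate, the single-test 5%
  expect_equal(est$p[1], est$p[2])
  expect_equal(est$p[2], est$p[3])
  expect_lt(abs(est$p[1] - 0.05), 4 * max(est$se[1], 1e-4))
})

test_that("impossible criteria have probability zero and m_min = 0 is certain", {
  est <- base_rate_counts(ident5, k_min = 6, n_sims = 1e4, seed = 1)
  expect_equal(est$p, 0)
  m <- default_reference_model()
  est2 <- base_rate_functions(m, grouping = m$tasks[c("motion", "attention",
                                                      "visuomotor")],
                              m_min = c(0, 4), n_sims = 1e4, seed = 1)
  expect_equal(est2$p, c(1, 0))
})

test_that("function-level base rate matches its independence closed form", {
  tasks <- list(motion = c("GM", "MDF", "MS"), attention = "SEARCH",
                visuomotor = c("BEERY", "MOSAICS"))
  m <- reference_model(tasks, diag(6))
  est <- base_rate_functions(m, m_min = 1:3, n_sims = 1e5, seed = 8)
  marg <- c(1 - 0.9^3, 1 - 0.9^1, 1 - 0.9^2)  # P(function weak), independent tasks
  truth <- base_rate_independent(marg, 1:3)
  expect_true(all(abs(est$p - truth) < 4 * pmax(est$se, 1e-4)))
})

test_that("estimates are monotone in the criterion on shared draws and reproducible", {
  m <- default_reference_model()
  a <- base_rate_counts(m, k_min = 1:5, n_sims = 2e4, seed = 31,
                        tasks = m$tasks$object_recognition)
  expect_true(all(diff(a$p) <= 0))
  b <- base_rate_counts(m, k_min = 1:5, n_sims = 2e4, seed = 31,
                        tasks = m$tasks$object_recognition)
  expect_identical(a$p, b$p)
  f <- base_rate_functions(m, m_min = 1:3, n_sims = 2e4, seed = 31)
  expect_true(all(diff(f$p) <= 0))
})

test_that("invalid correlation matrices are rejected with the eigenvalue", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(reference_model(list(f = c("a", "b")), bad),
               "eigenvalue")
  expect_error(base_rate_functions(default_reference_model(),
                                   grouping = list(empty = character())),
               "empty")
})

test_that("the correlation sweep spans independence to comonotone limits", {
  marg <- c(0.279, 0.211, 0.168)
  sw <- base_rate_rho_sweep(marg, m_min = 2, rho = c(0, 0.5, 1),
                            n_sims = 5e4, seed = 14)
  mc_se <- sqrt(0.12 * 0.88 / 5e4)
  expect_lt(abs(sw$proportion[1] - base_rate_independent(marg, 2)), 4 * mc_se)
  expect_lt(abs(sw$proportion[3] - sort(marg)[2]), 4 * mc_se)
  expect_true(all(diff(sw$proportion) > 0))  # increasing in rho here
})
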