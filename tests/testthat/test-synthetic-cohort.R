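test_that("reference scores are standard normal with the requested correlation", {
  m <- reference_model(list(battery = paste0("t", 1:5)), diag(5))
  x <- generate_reference_scores(m, 1e6, seed = 101)
  # marginals: Kolmogorov-Smirnov distance to N(0,1) vanishes with n
  for (j in 1:5) {
    ks <- suppressWarnings(stats::ks.test(x[, j], "pnorm"))
    expect_lt(unname(ks$statistic), 0.01)
  }
  # pairwise empirical correlations within Monte Carlo error of zero
  co <- stats::cor(x)
  expect_lt(max(abs(co[upper.tri(co)])), 0.005)
})

test_that("correlated draws reproduce an exchangeable target matrix", {
  tasks <- list(a = c("t1", "t2"), b = c("t3", "t4"))
  m <- reference_model(tasks, exchangeable_correlation(tasks, 0.5, 0.2))
  x <- generate_reference_scores(m, 2e5, seed = 7)
  co <- stats::cor(x)
  expect_equal(co["t1", "t2"], 0.5, tolerance = 0.02)
  expect_equal(co["t1", "t3"], 0.2, tolerance = 0.02)
})

test_that("perfectly correlated tasks give identical scores within individuals", {
  m <- reference_model(list(f = c("a", "b", "c")), matrix(1, 3, 3))
  x <- generate_reference_scores(m, 500, seed = 3)
  expect_lt(max(abs(x[, 1] - x[, 2])), 1e-6)
  expect_lt(max(abs(x[, 1] - x[, 3])), 1e-6)
})

test_that("generators are seed-deterministic and validate inputs", {
  m <- default_reference_model()
  expect_identical(generate_reference_scores(m, 100, seed = 5),
                   generate_reference_scores(m, 100, seed = 5))
  expect_error(generate_reference_scores(m, 0), "count")
  sp <- impairment_spec("motion", shift = 1, n_patients = 50, seed = 9)
  expect_identical(generate_patient_cohort(m, sp)$scores,
                   generate_patient_cohort(m, sp)$scores)
  expect_error(generate_patient_cohort(m, impairment_spec("gustation", 1, 5)),
               "unknown function")
})

test_that("planted shifts move abnormality rates by the normal tail", {
  m <- default_reference_model()
  sp <- impairment_spec("motion", shift = 3, n_patients = 5000, seed = 42)
  coh <- generate_patient_cohort(m, sp)
  z <- stats::qnorm(0.05)
  rate <- mean(coh$scores[, "GM"] < z)
  target <- stats::pnorm(z + 3)                 # 0.912
  expect_lt(abs(rate - target),
            4 * sqrt(target * (1 - target) / 5000))
  # unaffected tasks keep the nominal tail probability
  rate0 <- mean(coh$scores[, "VISM"] < z)
  expect_lt(abs(rate0 - 0.05), 4 * sqrt(0.05 * 0.95 / 5000))
})

test_that("observer psychometric function has the stated asymptotes and midpoint", {
  obs <- observer_model(0.4, slope = 3, guess_rate = 0.5, lapse_rate = 0.04)
  expect_equal(observer_p_correct(obs, 400), 1 - 0.04, tolerance = 1e-6)
  expect_equal(observer_p_correct(obs, 1e-4), 0.5, tolerance = 1e-6)
  expect_equal(observer_p_correct(obs, 0.4), 0.5 + 0.46 * 0.5)
  lvl <- observer_criterion_level(obs, 0.707)
  expect_equal(observer_p_correct(obs, lvl), 0.707, tolerance = 1e-9)
  set.seed(2)
  hits <- mean(replicate(4000, simulate_observer_response(obs, lvl)))
  expect_lt(abs(hits - 0.707), 4 * sqrt(0.707 * 0.293 / 4000))
})

test_that("search RT generator hits the serial-search median model", {
  tr <- generate_search_rts(1.2, 0.15, n_distracters = 9, n_trials = 1e4,
                            error_rate = 0.05, seed = 12)
  target <- 1.2 + 0.15 * (9 + 1) / 2
  expect_lt(abs(stats::median(tr$rt) / target - 1), 0.02)
  expect_lt(abs(mean(tr$false_alarm) - 0.05), 0.01)
  # no scan component: search task medians coincide with the motor median
  tr0 <- generate_search_rts(1.2, 0, n_distracters = 19, n_trials = 1e4,
                             error_rate = 0, seed = 13)
  expect_lt(abs(stats::median(tr0$rt) / 1.2 - 1), 0.02)
  expect_equal(sum(tr0$false_alarm), 0L)
})
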