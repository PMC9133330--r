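test_that("scores are flagged strictly on the worse side of the band cutoff", {
  norms <- default_norm_tables()
  # coherence threshold above the 10th-percentile cutoff (higher is worse)
  f <- classify_score(0.75, "GM", ym_to_months("5y0m"), norms)
  expect_true(as.logical(f))
  expect_equal(attr(f, "cutoff"), 0.69)
  # proportion correct comfortably above the cutoff (lower is worse)
  expect_false(as.logical(classify_score(0.80, "MDF", 72, norms)))
  # ties at the cutoff are not flagged
  expect_false(as.logical(classify_score(0.69, "GM", 60, norms)))
  expect_false(as.logical(classify_score(1, "total_errors", 60, norms)))
  expect_true(as.logical(classify_score(2, "total_errors", 60, norms)))
  expect_true(is.na(classify_score(NA, "GM", 60, norms)))
  expect_error(classify_score(1, "NOPE", 60, norms), "not in norm table")
})

test_that("out-of-range entry ages use the nearest band, ties to the younger", {
  norms <- motion_norms()
  lo <- classify_score(0.75, "GM", ym_to_months("3y0m"), norms)
  expect_equal(attr(lo, "band"), c(51, 55))   # youngest band, cutoff 0.78
  expect_false(as.logical(lo))
  hi <- classify_score(0.75, "GM", ym_to_months("9y0m"), norms)
  expect_equal(attr(hi, "band"), ym_to_months(c("5y10m", "7y4m")))
  expect_true(as.logical(hi))                  # 0.75 > 0.46
  # equidistant between the 55/57 band edges -> younger band
  mid <- classify_score(0.5, "GM", 56, norms)
  expect_equal(attr(mid, "band"), c(51, 55))
})

test_that("norm tables reject overlapping bands and bad directions", {
  df <- data.frame(measure = "X", band_lo = c(10, 20), band_hi = c(25, 30),
                   cutoff = 1, percentile = 10, worse = "higher")
  expect_error(norm_table(df), "overlapping")
  df2 <- data.frame(measure = "X", band_lo = 0, band_hi = 10, cutoff = 1,
                    percentile = 10, worse = "sideways")
  expect_error(norm_table(df2))
})

test_that("function roll-up counts weak functions and general dysfunction", {
  l94 <- c(VISM = FALSE, NOISE = TRUE, OVERL = FALSE, VIEW = NA, DEVOS = FALSE)
  r <- rollup(l94, list(motion = c(TRUE, FALSE), attention = TRUE,
                        visuomotor = FALSE))
  expect_equal(r$n_weak_functions, 2L)
  expect_true(r$general_dysfunction)
  expect_true(r$or_impaired)
  expect_true(r$l94_evaluable)

  r0 <- rollup(l94, list(motion = FALSE, attention = FALSE, visuomotor = FALSE))
  expect_equal(r0$n_weak_functions, 0L)
  expect_false(r0$general_dysfunction)

  r1 <- rollup(l94, list(motion = FALSE, attention = FALSE, visuomotor = TRUE))
  expect_false(r1$general_dysfunction)

  # a function with no completed task excludes the patient from the
  # function-level analysis rather than counting as intact
  rmiss <- rollup(l94, list(motion = TRUE, attention = logical(0),
                            visuomotor = FALSE))
  expect_false(rmiss$functions_evaluable)
  expect_true(is.na(rmiss$general_dysfunction))
})

test_that("adding a task flag never reduces the weak-function count", {
  set.seed(13)
  l94 <- stats::setNames(rep(FALSE, 5), c("VISM", "NOISE", "OVERL", "VIEW", "DEVOS"))
  for (rep in 1:25) {
    ff <- list(motion = sample(c(TRUE, FALSE), 3, TRUE),
               attention = sample(c(TRUE, FALSE), 1),
               visuomotor = sample(c(TRUE, FALSE), 2, TRUE))
    base <- rollup(l94, ff)
    f <- sample(names(ff), 1)
    ff2 <- ff
    ff2[[f]] <- c(ff2[[f]], TRUE)
    more <- rollup(l94, ff2)
    expect_gte(more$n_weak_functions, base$n_weak_functions)
    expect_true(!base$general_dysfunction || more$general_dysfunction)
  }
})

test_that("classification order of tasks within a function is immaterial", {
  l94 <- stats::setNames(rep(FALSE, 5), c("VISM", "NOISE", "OVERL", "VIEW", "DEVOS"))
  ff <- list(motion = c(TRUE, FALSE, FALSE), attention = FALSE,
             visuomotor = c(FALSE, TRUE))
  a <- rollup(l94, ff)
  b <- rollup(l94, lapply(ff, rev))
  expect_identical(a$n_weak_functions, b$n_weak_functions)
  expect_identical(a$function_weak, b$function_weak)
})
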