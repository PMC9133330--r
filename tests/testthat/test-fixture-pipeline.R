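fixed_rates <- list(l94 = c(0.196, 0.0438, 0.0087),
                    functions = c(0.50, 0.118, 0.0095))

count_vector <- function(report) {
  vapply(1:5, function(k) sum(report$patients$n_abnormal_l94 >= k &
                                report$patients$l94_evaluable), integer(1))
}

test_that("engineered cohorts round-trip their count specification exactly", {
  for (ge in list(c(6L, 3L, 1L), c(0L), c(5L, 4L, 2L, 1L, 1L))) {
    sp <- fixture_spec(n_patients = 12L, n_ge_abnormal = ge)
    rep <- run_pipeline(make_fixture_cohort(sp), base_rates = fixed_rates)
    expect_equal(count_vector(rep)[seq_along(ge)], ge)
    expect_equal(rep$l94$n_included, 12L)
  }
})

test_that("inconsistent count specifications are rejected", {
  expect_error(fixture_spec(10, c(3L, 5L)), "non-increasing")
  expect_error(fixture_spec(4, c(5L, 1L)), "more flagged")
  expect_error(fixture_spec(10, c(4L, 2L),
                            subtask_abnormal = c(VISM = 1L, NOISE = 1L,
                                                 OVERL = 1L, VIEW = 1L,
                                                 DEVOS = 1L)),
               "must sum")
})

test_that("the published-results fixture reproduces all of its margins", {
  co <- make_fixture_cohort(paper_fixture_spec())
  rep <- run_pipeline(co, base_rates = fixed_rates)
  rc <- report_counts(rep)
  expect_equal(rc$n_included, 46L)
  expect_equal(c(rc$n_ge1, rc$n_ge2, rc$n_ge3), c(29L, 11L, 6L))
  expect_equal(c(rc$n_vism, rc$n_noise, rc$n_overl, rc$n_view, rc$n_devos),
               c(41L, 45L, 45L, 44L, 40L))
  expect_equal(c(rc$n_impaired, rc$n_normal), c(18L, 11L))
  expect_equal(c(rc$impaired_ge1_weak, rc$impaired_ge2_weak,
                 rc$normal_ge1_weak, rc$normal_ge2_weak), c(13L, 6L, 3L, 1L))
})

test_that("pipeline runs are deterministic and survive a text round-trip", {
  co <- make_fixture_cohort(paper_fixture_spec())
  a <- run_pipeline(co, base_rates = fixed_rates)
  b <- run_pipeline(co, base_rates = fixed_rates)
  expect_identical(report_counts(a), report_counts(b))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  c2 <- read_cohort(dir)
  expect_identical(report_counts(run_pipeline(c2, base_rates = fixed_rates)),
                   report_counts(a))
})

test_that("an empty patient table produces a clean zero-count report", {
  rep <- run_pipeline(list(patients = data.frame(patient_id = character(),
                                                 ca_iq = integer(),
                                                 ca_dorsal = integer(),
                                                 piq = integer())))
  expect_equal(rep$l94$n_included, 0L)
  expect_null(rep$tests)
})

test_that("dropping a patient who fails inclusion leaves others unchanged", {
  co <- make_fixture_cohort(fixture_spec(8L, c(4L, 2L)))
  # reduce the last patient to two administered subtasks: not evaluable
  drop_id <- "P08"
  keep <- !(co$l94_items$patient_id == drop_id &
              co$l94_items$subtask %in% c("VISM", "NOISE", "OVERL"))
  co$l94_items <- co$l94_items[keep, ]
  with_failing <- run_pipeline(co, base_rates = fixed_rates)
  expect_false(with_failing$patients$l94_evaluable[
    with_failing$patients$patient_id == drop_id])

  co2 <- co
  co2$patients <- co2$patients[co2$patients$patient_id != drop_id, ]
  co2$l94_items <- co2$l94_items[co2$l94_items$patient_id != drop_id, ]
  co2$age_equivalents <- co2$age_equivalents[
    co2$age_equivalents$patient_id != drop_id, ]
  without <- run_pipeline(co2, base_rates = fixed_rates)
  a <- with_failing$patients[with_failing$patients$patient_id != drop_id, ]
  rownames(a) <- NULL
  expect_equal(a, without$patients)
  expect_identical(report_counts(with_failing)[c("n_ge1", "n_ge2", "n_ge3")],
                   report_counts(without)[c("n_ge1", "n_ge2", "n_ge3")])
})

test_that("cohort configs load from YAML reference-model files", {
  path <- system.file("extdata", "default_reference_model.yaml",
                      package = "dorsalstream")
  m <- read_reference_model(path)
  expect_s3_class(m, "reference_model")
  expect_equal(m$correlation["VISM", "NOISE"], 0.3)
  expect_equal(m$correlation["VISM", "GM"], 0.1)
  expect_identical(m$correlation, default_reference_model()$correlation)
})
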