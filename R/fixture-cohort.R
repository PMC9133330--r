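#' Specification of an engineered cohort with exact flag margins
#'
#' Describes a cohort by the counts the classification pipeline must
#' reproduce exactly: cohort size, the number of patients with at least
#' 1, 2, 3, ... abnormal L94 subtask scores, per-subtask administered and
#' abnormal counts, and (optionally) the weak-function patterns of the
#' subgroup with complete motion/attention/visuomotor data. Used to
#' reconstruct per-patient data consistent with published marginal counts,
#' and as a round-trip oracle for the pipeline.
#'
#' @param n_patients cohort size.
#' @param n_ge_abnormal non-increasing integer vector: element m is the
#'   number of patients with >= m abnormal L94 subtasks (up to length 5).
#' @param subtask_administered optional named vector (VISM/NOISE/OVERL/
#'   VIEW/DEVOS) of administered counts; missing tasks are assigned to
#'   patients with the fewest flags, at most two per patient so everyone
#'   stays evaluable. Default: all tasks administered to everyone.
#' @param subtask_abnormal optional named vector of abnormal counts per
#'   subtask; must sum to `sum(n_ge_abnormal)`. Default: spread greedily.
#' @param dorsal optional list with data.frames `impaired` and `normal`
#'   (rows = patients of the subgroup with complete function-level data,
#'   mapped to flagged / unflagged patients respectively) and logical
#'   columns `gm`, `mdf`, `ms`, `attention`, `beery`, `mosaics`
#'   (TRUE = planted abnormal, FALSE = normal, NA = task not administered).
#' @return object of class `fixture_spec`.
#' @seealso [make_fixture_cohort()], [paper_fixture_spec()]
#' @export
fixture_spec <- function(n_patients, n_ge_abnormal,
                         subtask_administered = NULL,
                         subtask_abnormal = NULL, dorsal = NULL) {
  n <- as.integer(n_patients)
  ge <- as.integer(n_ge_abnormal)
  if (length(ge) < 1L || length(ge) > 5L)
    stop("n_ge_abnormal must have 1 to 5 elements")
  if (any(diff(ge) > 0L))
    stop("inconsistent spec: counts of >=m abnormal must be non-increasing in m")
  if (ge[1L] > n) stop("inconsistent spec: more flagged patients than patients")
  if (any(ge < 0L)) stop("counts must be non-negative")
  subs <- l94_subtasks()
  if (is.null(subtask_administered))
    subtask_administered <- stats::setNames(rep(n, 5L), subs)
  if (!setequal(names(subtask_administered), subs))
    stop("subtask_administered must be named by the five subtasks")
  subtask_administered <- subtask_administered[subs]
  if (any(subtask_administered > n) || any(subtask_administered < 0))
    stop("administered counts out of range")
  if (!is.null(subtask_abnormal)) {
    if (!setequal(names(subtask_abnormal), subs))
      stop("subtask_abnormal must be named by the five subtasks")
    subtask_abnormal <- subtask_abnormal[subs]
    if (sum(subtask_abnormal) != sum(ge))
      stop("inconsistent spec: subtask abnormal counts must sum to ",
           sum(ge), " (= sum over m of the >=m counts)")
    if (any(subtask_abnormal > subtask_administered))
      stop("inconsistent spec: more abnormal than administered on a subtask")
  }
  structure(list(n_patients = n, n_ge_abnormal = ge,
                 subtask_administered = subtask_administered,
                 subtask_abnormal = subtask_abnormal, dorsal = dorsal),
            class = "fixture_spec")
}

#' The published-results fixture specification
#'
#' The count structure of the study cohort this package's pipeline mirrors:
#' 46 evaluable patients of whom 29/11/6 had >= 1/2/3 abnormal L94 scores;
#' subtask administered counts 41/45/45/44/40 and abnormal counts 4/8/6/13/15
#' (VISM/NOISE/OVERL/VIEW/DEVOS); and a 29-patient subgroup with complete
#' function-level data — 18 with impaired object recognition (13 with >= 1
#' weak function, 6 with >= 2, 2 with 3; motion weak 9 via GM 7/16 and MDF
#' 5/16, attention weak 9, visuomotor weak 3) and 11 without (3 with >= 1
#' weak function, 1 with 2; motion weak 1 via MDF, attention 1,
#' visuomotor 2).
#'
#' @return a [fixture_spec()].
#' @export
paper_fixture_spec <- function() {
  f <- function(x) x  # readability no-op
  impaired <- data.frame(
    #        A1    A2    A3    A4    A5    A6    A7    A8    A9    A10   A11   A12   A13   A14   A15   A16   A17   A18
    gm  = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,TRUE, TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,   NA),
    mdf = c(TRUE, TRUE, TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,TRUE, TRUE, FALSE,FALSE,FALSE,FALSE,NA,   NA,   FALSE,FALSE),
    ms  = c(NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA,   FALSE,FALSE,FALSE,FALSE,FALSE),
    attention = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,FALSE,FALSE,FALSE,TRUE, TRUE, TRUE, FALSE,FALSE,FALSE,FALSE,FALSE),
    beery     = c(TRUE, FALSE,FALSE,FALSE,FALSE,TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    mosaics   = c(TRUE, TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE))
  normal <- data.frame(
    #        B1    B2    B3    B4    B5    B6    B7    B8    B9    B10   B11
    gm  = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA),
    mdf = c(TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,   FALSE),
    ms  = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,   NA),
    attention = c(FALSE,TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    beery     = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    mosaics   = c(TRUE, FALSE,TRUE, FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE))
  fixture_spec(
    n_patients = 46L,
    n_ge_abnormal = c(29L, 11L, 6L),
    subtask_administered = c(VISM = 41L, NOISE = 45L, OVERL = 45L,
                             VIEW = 44L, DEVOS = 40L),
    subtask_abnormal = c(VISM = 4L, NOISE = 8L, OVERL = 6L,
                         VIEW = 13L, DEVOS = 15L),
    dorsal = list(impaired = f(impaired), normal = f(normal)))
}

# Solve the (administered, abnormal) cell assignment for a fixture spec.
# Returns list(administered, abnormal): n x 5 logical matrices.
.fixture_flag_matrices <- function(spec) {
  n <- spec$n_patients
  subs <- l94_subtasks()
  ge <- spec$n_ge_abnormal
  # per-patient flag counts: patients 1.. get the heaviest loads first
  exact <- -diff(c(ge, 0L))            # patients with exactly m flags, m = 1..
  flags_per_patient <- rep(0L, n)
  load <- rep(rev(seq_along(exact)), rev(exact))  # 3,3,...,2,2,...,1,...
  flags_per_patient[seq_along(load)] <- load

  administered <- matrix(TRUE, n, 5L, dimnames = list(NULL, subs))
  miss <- spec$n_patients - spec$subtask_administered
  # missing cells go to the least-flagged patients, at most two per patient
  ord <- order(flags_per_patient, seq_len(n), decreasing = FALSE)
  for (s in subs) {
    need <- miss[[s]]
    for (i in ord) {
      if (need == 0L) break
      if (!administered[i, s]) next
      if (sum(!administered[i, ]) >= 2L) next               # keep >= 3 evaluable
      if (5L - sum(!administered[i, ]) - 1L < flags_per_patient[i]) next
      administered[i, s] <- FALSE
      need <- need - 1L
    }
    if (need > 0L)
      stop("cannot realise administered pattern: no room left for ", s)
  }

  abnormal <- matrix(FALSE, n, 5L, dimnames = list(NULL, subs))
  remaining <- spec$subtask_abnormal
  if (is.null(remaining)) {
    # no per-subtask targets: balance the total load across subtasks
    remaining <- stats::setNames(rep(0L, 5L), subs)
    total <- sum(ge)
    i <- 1L
    while (total > 0L) {
      s <- subs[(i - 1L) %% 5L + 1L]
      if (remaining[[s]] < spec$subtask_administered[[s]]) {
        remaining[[s]] <- remaining[[s]] + 1L
        total <- total - 1L
      }
      i <- i + 1L
      if (i > 10L * sum(ge) + 10L) stop("cannot distribute abnormal flags")
    }
  }
  for (i in order(flags_per_patient, decreasing = TRUE)) {
    m <- flags_per_patient[i]
    if (m == 0L) next
    open <- subs[administered[i, ] & remaining[subs] > 0L]
    if (length(open) < m)
      stop("infeasible abnormal-count pattern at patient ", i)
    pick <- open[order(remaining[open], decreasing = TRUE)][seq_len(m)]
    abnormal[i, pick] <- TRUE
    remaining[pick] <- remaining[pick] - 1L
  }
  if (any(remaining != 0L))
    stop("infeasible abnormal-count pattern: leftover demand on ",
         paste(names(remaining)[remaining != 0L], collapse = ", "))
  list(administered = administered, abnormal = abnormal)
}

# deterministic responder: correct iff level is at or above the target
.threshold_responder <- function(target) function(level) level >= target - 1e-12

# staircase response sequence whose replayed threshold lands near `target`
.staircase_responses <- function(cfg, target) {
  st <- staircase_run(cfg, .threshold_responder(target))
  data.frame(trial = seq_along(st$levels), level = st$levels,
             correct = st$responses)
}

#' Build per-patient input tables realising a fixture specification
#'
#' Constructs item- and trial-level tables that, when run through
#' [run_pipeline()] with the packaged norm tables, reproduce the spec's
#' counts exactly: L94 item responses whose subtask scores fall on the
#' intended side of the (synthetic) 5th-percentile cutoffs, deterministic
#' staircase response sequences whose reversal-mean thresholds land on the
#' intended side of the published motion cutoffs, motion-defined-form item
#' conditions, visual-search trials with the intended median search times,
#' and visuomotor standard scores. All patients share one age profile
#' (CA 6y2m, developmental age ~5y1m) so a single norm band applies;
#' inconclusive items are planted throughout to exercise the exclusion rule.
#'
#' The construction is validated by round-trip in the test-suite: pipeline
#' counts equal the spec counts, for the published spec and for arbitrary
#' consistent ones.
#'
#' @param spec a [fixture_spec()]; default [paper_fixture_spec()].
#' @return cohort list (class `dorsal_cohort`) with data.frames `patients`,
#'   `age_equivalents`, `l94_items`, `mdf_items`, `staircase_trials`,
#'   `search_trials`, `visuomotor`.
#' @export
make_fixture_cohort <- function(spec = paper_fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  mats <- .fixture_flag_matrices(spec)
  n <- spec$n_patients
  ids <- sprintf("P%02d", seq_len(n))

  patients <- data.frame(patient_id = ids, ca_iq = 70L, ca_dorsal = 74L,
                         piq = 80L)
  age_equivalents <- data.frame(patient_id = rep(ids, each = 3L),
                                age_equivalent = rep(c(56L, 58L, 60L), n))
  # entry age = median(56,58,60)/70 * 74 = 61.3 months -> 4y9m-5y8m band

  l94 <- list()
  for (i in seq_len(n)) {
    for (s in l94_subtasks()) {
      if (!mats$administered[i, s]) next
      abn <- mats$abnormal[i, s]
      it <- switch(s,
        VISM = data.frame(item = 1:10, j = ifelse(1:10 <= if (abn) 4 else 9, 1L, NA),
                          k = 1L, control_recognized = TRUE),
        NOISE = rbind(  # six scored items plus one inconclusive
          data.frame(item = 1:6, j = if (abn) 5L else 2L, k = 7L,
                     control_recognized = TRUE),
          data.frame(item = 7L, j = NA, k = 7L, control_recognized = FALSE)),
        OVERL = data.frame(item = 1:6, j = if (abn) 3L else 1L, k = 4L,
                           control_recognized = TRUE),
        VIEW = data.frame(item = 1:16, j = if (abn) c(rep(2L, 8), rep(3L, 8))
                                           else 1L,
                          k = c(rep(3L, 8), rep(4L, 8)),
                          control_recognized = TRUE),
        DEVOS = data.frame(item = 1:43,
                           j = ifelse(1:43 <= if (abn) 17 else 40, 1L, NA),
                           k = 1L, control_recognized = TRUE))
      it$patient_id <- ids[i]
      it$subtask <- s
      l94[[length(l94) + 1L]] <- it
    }
  }
  l94 <- do.call(rbind, l94)[, c("patient_id", "subtask", "item", "j", "k",
                                 "control_recognized")]

  mdf <- list(); stair <- list(); search <- list(); vism <- list()
  flagged <- which(rowSums(mats$abnormal) > 0L)
  unflagged <- setdiff(seq_len(n), flagged)
  if (!is.null(spec$dorsal)) {
    di <- spec$dorsal$impaired; dn <- spec$dorsal$normal
    if (nrow(di) > length(flagged) || nrow(dn) > length(unflagged))
      stop("dorsal subgroup larger than the available flagged/unflagged patients")
    members <- data.frame(
      i = c(flagged[seq_len(nrow(di))], unflagged[seq_len(nrow(dn))]),
      rbind(di, dn))
    gm_cfg <- gm_staircase_config(); ms_cfg <- ms_staircase_config()
    for (r in seq_len(nrow(members))) {
      id <- ids[members$i[r]]
      if (!is.na(members$gm[r])) {
        tr <- .staircase_responses(gm_cfg, if (members$gm[r]) 0.85 else 0.30)
        stair[[length(stair) + 1L]] <- data.frame(patient_id = id, task = "GM", tr)
      }
      if (!is.na(members$ms[r])) {
        tr <- .staircase_responses(ms_cfg, if (members$ms[r]) 30 else 4)
        stair[[length(stair) + 1L]] <- data.frame(patient_id = id, task = "MS", tr)
      }
      if (!is.na(members$mdf[r])) {
        cond <- if (members$mdf[r]) c(rep(c(2L, 3L), 8), 2L, NA)
                else c(rep(c(1L, 1L, 2L), 5), 1L, 1L, NA)
        mdf[[length(mdf) + 1L]] <- data.frame(patient_id = id,
                                              item = seq_along(cond),
                                              condition = cond)
      }
      d4 <- if (members$attention[r]) 3.5 else 1.9
      search[[length(search) + 1L]] <- data.frame(
        patient_id = id,
        condition = c(rep("RT_pre", 5), rep("D4", 10), rep("D9", 10),
                      rep("D19", 10), rep("RT_post", 5)),
        trial = c(1:5, 1:10, 1:10, 1:10, 1:5),
        rt = c(1.3 + 0.01 * ((1:5) - 3), d4 + 0.01 * ((1:10) - 5),
               2.8 + 0.01 * ((1:10) - 5), 4.5 + 0.01 * ((1:10) - 5),
               1.3 + 0.01 * ((1:5) - 3)),
        false_alarm = FALSE)
      if (members$attention[r]) {   # one slip: excluded from medians, under the error cutoff
        k <- length(search)
        search[[k]]$false_alarm[search[[k]]$condition == "D9"][1L] <- TRUE
        search[[k]]$rt[search[[k]]$condition == "D9"][1L] <- 9.9
      }
      vism[[length(vism) + 1L]] <- data.frame(
        patient_id = id, task = c("BEERY", "MOSAICS"),
        standard_score = c(if (members$beery[r]) 75 else 96,
                           if (members$mosaics[r]) 4 else 10))
    }
  }
  structure(list(
    patients = patients, age_equivalents = age_equivalents, l94_items = l94,
    mdf_items = if (length(mdf)) do.call(rbind, mdf) else NULL,
    staircase_trials = if (length(stair)) do.call(rbind, stair) else NULL,
    search_trials = if (length(search)) do.call(rbind, search) else NULL,
    visuomotor = if (length(vism)) do.call(rbind, vism) else NULL),
    class = "dorsal_cohort")
}

#' Write / read a cohort as delimited text
#'
#' One CSV per table in `dir` (`patients.csv`, `age_equivalents.csv`,
#' `l94_items.csv`, `mdf_items.csv`, `staircase_trials.csv`,
#' `search_trials.csv`, `visuomotor.csv`); absent tables are skipped.
#'
#' @param cohort a `dorsal_cohort` list.
#' @param dir directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort)) {
    if (is.null(cohort[[nm]])) next
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tabs <- c("patients", "age_equivalents", "l94_items", "mdf_items",
            "staircase_trials", "search_trials", "visuomotor")
  out <- lapply(tabs, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) utils::read.csv(f, stringsAsFactors = FALSE) else NULL
  })
  names(out) <- tabs
  structure(out, class = "dorsal_cohort")
}
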