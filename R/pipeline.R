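#' Run the full battery analysis on a cohort
#'
#' Orchestrates scoring, developmental-age norm entry, percentile
#' classification, roll-up, group counts, Monte Carlo base rates and the
#' inferential comparisons into one reproducible report:
#'
#' 1. Entry ages from [developmental_age()] (median non-verbal
#'    age-equivalents projected to the assessment date, capped at CA).
#' 2. L94 subtask scores ([score_l94_table()]) classified at the 5th
#'    percentile; patients with fewer than three evaluable subtasks are
#'    excluded from all analyses.
#' 3. Motion thresholds by staircase replay, MDF proportion correct, search
#'    outcomes and visuomotor standard scores, classified at the 10th
#'    percentile.
#' 4. Patient-level [rollup()]: abnormal L94 count, per-function weakness,
#'    general dorsal-stream dysfunction (>= 2 of 3 functions weak). Patients
#'    missing a whole function are excluded from function-level analyses
#'    only.
#' 5. Group summaries: counts/percentages of >= 1/2/3 abnormal L94 scores
#'    with Clopper-Pearson CIs and exact binomial tests against the
#'    battery-level base rates; the function-level split between patients
#'    with and without impaired object recognition, with Fisher's exact
#'    tests and Mann-Whitney comparisons of raw performance levels.
#'
#' Base rates are Monte Carlo estimates from `model` unless fixed values are
#' supplied via `base_rates` (list with vectors `l94` for >= 1,2,3 abnormal
#' and `functions` for >= 1,2,3 weak), mirroring the use of previously
#' published rates as fixed numbers.
#'
#' @param cohort a `dorsal_cohort` list (see [make_fixture_cohort()] /
#'   [read_cohort()]).
#' @param norms a [norm_table()]; default [default_norm_tables()].
#' @param policy a [classification_policy()].
#' @param model [reference_model()] used for base rates.
#' @param base_rates optional fixed base rates (see above).
#' @param n_sims Monte Carlo draws for base rates.
#' @param seed integer seed for the base-rate simulation.
#' @return object of class `dorsal_report`; see the elements `patients`,
#'   `l94`, `groups`, `base_rates`, `tests`.
#' @export
run_pipeline <- function(cohort, norms = default_norm_tables(),
                         policy = classification_policy(),
                         model = default_reference_model(),
                         base_rates = NULL, n_sims = 1e5, seed = 1L) {
  stopifnot(is.list(cohort), !is.null(cohort$patients))
  pts <- cohort$patients
  if (nrow(pts) == 0L)
    return(structure(list(patients = data.frame(), l94 = list(n_included = 0L),
                          groups = NULL, base_rates = NULL, tests = NULL,
                          seed = seed),
                     class = "dorsal_report"))

  entry <- vapply(seq_len(nrow(pts)), function(i) {
    ae <- cohort$age_equivalents
    ae <- ae$age_equivalent[ae$patient_id == pts$patient_id[i]]
    developmental_age(ae, pts$ca_iq[i], pts$ca_dorsal[i], pts$piq[i])$entry_age
  }, numeric(1))
  names(entry) <- pts$patient_id

  l94_scores <- score_l94_table(cohort$l94_items)
  l94_scores$abnormal <- vapply(seq_len(nrow(l94_scores)), function(r)
    as.logical(classify_score(l94_scores$score[r], l94_scores$subtask[r],
                              entry[[l94_scores$patient_id[r]]], norms)),
    logical(1))

  task_rows <- list()  # continuous task outcomes + weak flags, per function
  add_rows <- function(df) task_rows[[length(task_rows) + 1L]] <<- df
  if (!is.null(cohort$staircase_trials) && nrow(cohort$staircase_trials)) {
    th <- score_staircase_table(cohort$staircase_trials)
    add_rows(data.frame(patient_id = th$patient_id, fun = "motion",
                        measure = th$task, value = th$threshold))
  }
  if (!is.null(cohort$mdf_items) && nrow(cohort$mdf_items)) {
    md <- score_mdf_table(cohort$mdf_items)
    add_rows(data.frame(patient_id = md$patient_id, fun = "motion",
                        measure = "MDF", value = md$score))
  }
  if (!is.null(cohort$search_trials) && nrow(cohort$search_trials)) {
    so <- score_search_table(cohort$search_trials)
    add_rows(data.frame(patient_id = so$patient_id, fun = "attention",
                        measure = so$measure, value = so$value))
  }
  if (!is.null(cohort$visuomotor) && nrow(cohort$visuomotor)) {
    vm <- cohort$visuomotor
    add_rows(data.frame(patient_id = vm$patient_id, fun = "visuomotor",
                        measure = vm$task, value = vm$standard_score))
  }
  tasks <- if (length(task_rows)) do.call(rbind, task_rows) else
    data.frame(patient_id = character(), fun = character(),
               measure = character(), value = numeric())
  tasks$weak <- vapply(seq_len(nrow(tasks)), function(r)
    as.logical(classify_score(tasks$value[r], tasks$measure[r],
                              entry[[tasks$patient_id[r]]], norms)),
    logical(1))

  cls <- lapply(pts$patient_id, function(id) {
    lf <- stats::setNames(rep(NA, 5L), l94_subtasks())
    sc <- l94_scores[l94_scores$patient_id == id & l94_scores$evaluable, ]
    lf[sc$subtask] <- sc$abnormal
    tk <- tasks[tasks$patient_id == id, ]
    ff <- split(tk$weak, factor(tk$fun, levels = policy$dorsal_functions))
    rollup(lf, ff, policy)
  })
  patients <- data.frame(
    patient_id = pts$patient_id, entry_age = unname(entry),
    n_abnormal_l94 = vapply(cls, `[[`, 0L, "n_abnormal_l94"),
    or_impaired = vapply(cls, `[[`, NA, "or_impaired"),
    l94_evaluable = vapply(cls, `[[`, NA, "l94_evaluable"),
    motion_weak = vapply(cls, function(x) x$function_weak[["motion"]], NA),
    attention_weak = vapply(cls, function(x) x$function_weak[["attention"]], NA),
    visuomotor_weak = vapply(cls, function(x) x$function_weak[["visuomotor"]], NA),
    functions_evaluable = vapply(cls, `[[`, NA, "functions_evaluable"),
    n_weak_functions = vapply(cls, function(x)
      if (is.na(x$n_weak_functions)) NA_integer_ else x$n_weak_functions,
      NA_integer_),
    general_dysfunction = vapply(cls, `[[`, NA, "general_dysfunction"))

  inc <- patients[patients$l94_evaluable, , drop = FALSE]
  n_inc <- nrow(inc)
  ge <- vapply(1:3, function(k) sum(inc$n_abnormal_l94 >= k), integer(1))
  sub_l94 <- l94_scores[l94_scores$patient_id %in% inc$patient_id &
                          l94_scores$evaluable, ]
  subtask <- do.call(rbind, lapply(l94_subtasks(), function(s) {
    d <- sub_l94[sub_l94$subtask == s, ]
    data.frame(subtask = s, n = nrow(d), abnormal = sum(d$abnormal),
               pct = if (nrow(d)) 100 * sum(d$abnormal) / nrow(d) else NA_real_)
  }))

  if (is.null(base_rates)) {
    br_l94 <- base_rate_counts(model, stats::qnorm(policy$abnormal_percentile / 100),
                               k_min = 1:3, n_sims = n_sims, seed = seed,
                               tasks = model$tasks$object_recognition)
    br_fun <- base_rate_functions(model,
                                  grouping = model$tasks[policy$dorsal_functions],
                                  z_threshold = stats::qnorm(policy$weak_percentile / 100),
                                  m_min = 1:3, n_sims = n_sims, seed = seed + 1L)
    base_rates <- list(l94 = br_l94$p, functions = br_fun$p,
                       detail = list(l94 = br_l94, functions = br_fun))
  }

  ci <- lapply(1:3, function(k) exact_binomial_ci(ge[k], n_inc))
  l94_summary <- list(
    n_included = n_inc,
    n_ge_abnormal = ge,
    pct_ge_abnormal = 100 * ge / n_inc,
    ci_ge_abnormal = do.call(rbind, ci),
    binomial_tests = lapply(1:3, function(k)
      binomial_vs_baserate(ge[k], n_inc, base_rates$l94[k])),
    subtask = subtask)

  sub <- inc[inc$functions_evaluable, , drop = FALSE]
  groups <- NULL; tests <- NULL
  if (nrow(sub)) {
    gi <- sub[sub$or_impaired, , drop = FALSE]
    gn <- sub[!sub$or_impaired, , drop = FALSE]
    grp_counts <- function(g) list(
      n = nrow(g),
      ge1_weak = sum(g$n_weak_functions >= 1L),
      ge2_weak = sum(g$n_weak_functions >= 2L),
      eq3_weak = sum(g$n_weak_functions == 3L),
      motion = sum(g$motion_weak), attention = sum(g$attention_weak),
      visuomotor = sum(g$visuomotor_weak))
    groups <- list(impaired = grp_counts(gi), normal = grp_counts(gn))
    ft <- function(a, na, b, nb) fisher_exact(a, na - a, b, nb - b)
    tk_sub <- tasks[tasks$patient_id %in% sub$patient_id, ]
    task_flag_table <- function(measure) {
      d <- tk_sub[tk_sub$measure == measure & !is.na(tk_sub$weak), ]
      ii <- d$patient_id %in% gi$patient_id
      list(impaired = c(sum(d$weak[ii]), sum(ii)),
           normal = c(sum(d$weak[!ii]), sum(!ii)))
    }
    gm <- task_flag_table("GM")
    tests <- list(
      ge1_weak = ft(groups$impaired$ge1_weak, groups$impaired$n,
                    groups$normal$ge1_weak, groups$normal$n),
      ge2_weak = ft(groups$impaired$ge2_weak, groups$impaired$n,
                    groups$normal$ge2_weak, groups$normal$n),
      motion = ft(groups$impaired$motion, groups$impaired$n,
                  groups$normal$motion, groups$normal$n),
      attention = ft(groups$impaired$attention, groups$impaired$n,
                     groups$normal$attention, groups$normal$n),
      visuomotor = ft(groups$impaired$visuomotor, groups$impaired$n,
                      groups$normal$visuomotor, groups$normal$n),
      gm_task = ft(gm$impaired[1L], gm$impaired[2L],
                   gm$normal[1L], gm$normal[2L]),
      general_vs_baserate = binomial_vs_baserate(
        groups$impaired$ge2_weak, groups$impaired$n, base_rates$functions[2L]),
      levels = .level_comparisons(tk_sub, gi$patient_id, norms))
  }

  structure(list(patients = patients, l94 = l94_summary, groups = groups,
                 base_rates = base_rates, tests = tests, seed = seed),
            class = "dorsal_report")
}

# Mann-Whitney comparisons of raw outcome levels between the impaired and
# normal object-recognition groups; one-sided in the worse-performance
# direction of each measure.
.level_comparisons <- function(tasks, impaired_ids, norms) {
  out <- list()
  for (m in unique(tasks$measure)) {
    d <- tasks[tasks$measure == m & !is.na(tasks$value), ]
    x <- d$value[d$patient_id %in% impaired_ids]
    y <- d$value[!d$patient_id %in% impaired_ids]
    if (length(x) < 2L || length(y) < 2L) next
    worse <- norms$worse[norms$measure == m][1L]
    alt <- if (identical(worse, "lower")) "less" else "greater"
    out[[m]] <- mann_whitney_u(x, y, alternative = alt)
  }
  out
}

#' @export
print.dorsal_report <- function(x, ...) {
  cat("Dorsal-stream battery report\n")
  cat("============================\n")
  n <- x$l94$n_included
  if (!n) { cat("No evaluable patients.\n"); return(invisible(x)) }
  cat(sprintf("Included patients (>= 3 L94 subtasks evaluable): %d\n\n", n))
  for (k in 1:3) {
    ci <- x$l94$ci_ge_abnormal[k, ]
    bt <- x$l94$binomial_tests[[k]]
    cat(sprintf(
      ">= %d abnormal L94 score%s: %d/%d (%.1f%%, 95%% CI %.1f-%.1f%%) vs base rate %.2f%%: z = %.2f, one-sided p %s\n",
      k, if (k > 1) "s" else " ", x$l94$n_ge_abnormal[k], n,
      x$l94$pct_ge_abnormal[k], 100 * ci[["lower"]], 100 * ci[["upper"]],
      100 * x$base_rates$l94[k], bt$statistic[["z"]], format_p(bt$p_one_sided)))
  }
  cat("\nAbnormal scores by subtask:\n")
  s <- x$l94$subtask
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %2d/%2d (%.1f%%)\n", s$subtask[i], s$abnormal[i],
                s$n[i], s$pct[i]))
  if (!is.null(x$groups)) {
    g <- x$groups
    cat(sprintf(
      "\nFunction-level subgroup (all three dorsal functions evaluable): %d patients\n",
      g$impaired$n + g$normal$n))
    cat(sprintf("  impaired object recognition: n = %d; >=1 weak %d (%.1f%%), >=2 weak %d (%.1f%%)\n",
                g$impaired$n, g$impaired$ge1_weak,
                100 * g$impaired$ge1_weak / g$impaired$n, g$impaired$ge2_weak,
                100 * g$impaired$ge2_weak / g$impaired$n))
    cat(sprintf("  normal object recognition:   n = %d; >=1 weak %d (%.1f%%), >=2 weak %d (%.1f%%)\n",
                g$normal$n, g$normal$ge1_weak,
                100 * g$normal$ge1_weak / g$normal$n, g$normal$ge2_weak,
                100 * g$normal$ge2_weak / g$normal$n))
    cat(sprintf("  Fisher one-sided p (>=1 weak): %s; (motion): %s; (attention): %s; (visuomotor): %s\n",
                format_p(x$tests$ge1_weak$p_one_sided),
                format_p(x$tests$motion$p_one_sided),
                format_p(x$tests$attention$p_one_sided),
                format_p(x$tests$visuomotor$p_one_sided)))
    cat(sprintf("  general dysfunction vs base rate %.2f%%: one-sided p %s\n",
                100 * x$base_rates$functions[2L],
                format_p(x$tests$general_vs_baserate$p_one_sided)))
  }
  invisible(x)
}

#' Machine-readable counts from a report
#'
#' Flat named list of the headline counts and percentages, convenient for
#' JSON export and for asserting exact reproduction of a fixture spec.
#'
#' @param report a `dorsal_report`.
#' @export
report_counts <- function(report) {
  out <- list(
    n_included = report$l94$n_included,
    n_ge1 = report$l94$n_ge_abnormal[1L],
    n_ge2 = report$l94$n_ge_abnormal[2L],
    n_ge3 = report$l94$n_ge_abnormal[3L],
    pct_ge1 = report$l94$pct_ge_abnormal[1L],
    pct_ge2 = report$l94$pct_ge_abnormal[2L],
    pct_ge3 = report$l94$pct_ge_abnormal[3L])
  s <- report$l94$subtask
  for (i in seq_len(nrow(s))) {
    out[[paste0("pct_", tolower(s$subtask[i]))]] <- s$pct[i]
    out[[paste0("n_", tolower(s$subtask[i]))]] <- s$n[i]
  }
  if (!is.null(report$groups)) {
    g <- report$groups
    out <- c(out, list(
      n_impaired = g$impaired$n, n_normal = g$normal$n,
      impaired_ge1_weak = g$impaired$ge1_weak,
      impaired_ge2_weak = g$impaired$ge2_weak,
      normal_ge1_weak = g$normal$ge1_weak,
      normal_ge2_weak = g$normal$ge2_weak,
      pct_impaired_ge1_weak = 100 * g$impaired$ge1_weak / g$impaired$n,
      pct_impaired_ge2_weak = 100 * g$impaired$ge2_weak / g$impaired$n,
      pct_normal_ge1_weak = 100 * g$normal$ge1_weak / g$normal$n,
      pct_normal_ge2_weak = 100 * g$normal$ge2_weak / g$normal$n))
  }
  out
}
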