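#' Motion-defined form score
#'
#' Each MDF item is shown in up to three successive conditions of decreasing
#' difficulty (moving contour dots, static contour dots, empty contour).
#' Recognition in condition 1, 2 or 3 scores 1, 0.5 or 0. An object never
#' identified, even in the easiest condition, is inconclusive and excluded.
#' The task score is the mean of the conclusive item scores (a proportion
#' correct).
#'
#' @param conditions integer vector per item: 1, 2, 3, or `NA` for never
#'   recognized. The full task has 18 items (three 6-object subtasks).
#' @return list: `score` (proportion, `NA` if no conclusive items),
#'   `evaluable`, `n_conclusive`, `n_inconclusive`.
#' @examples
#' mdf_score(c(1, 1, 2, 3))$score    # 0.625
#' mdf_score(c(1, NA, 3))$score      # 0.5 over 2 conclusive items
#' @export
mdf_score <- function(conditions) {
  stopifnot(length(conditions) >= 1L)
  ok <- !is.na(conditions)
  if (any(!(conditions[ok] %in% 1:3)))
    stop("conditions must be 1, 2, 3 or NA")
  sc <- c(1, 0.5, 0)[conditions[ok]]
  list(score = if (any(ok)) mean(sc) else NA_real_,
       evaluable = any(ok),
       n_conclusive = sum(ok), n_inconclusive = sum(!ok))
}

#' Score staircase-based motion tasks from a trial-level table
#'
#' Replays each patient's recorded response sequence through the task's
#' staircase configuration ([gm_staircase_config()] for GM,
#' [ms_staircase_config()] for MS) and extracts the reversal-mean threshold.
#' When the table carries recorded `level`s they are checked against the
#' replayed levels; a mismatch means the trace was not produced by the stated
#' rule and is an error.
#'
#' @param trials data.frame with columns `patient_id`, `task` ("GM"/"MS"),
#'   `trial`, `correct`, optionally `level`.
#' @param configs named list of staircase configs by task.
#' @return data.frame: `patient_id`, `task`, `threshold`, `n_trials`,
#'   `n_reversals`, `terminated`.
#' @export
score_staircase_table <- function(trials,
                                  configs = list(GM = gm_staircase_config(),
                                                 MS = ms_staircase_config())) {
  stopifnot(all(c("patient_id", "task", "trial", "correct") %in% names(trials)))
  out <- lapply(split(trials, list(trials$patient_id, trials$task), drop = TRUE),
                function(d) {
                  d <- d[order(d$trial), , drop = FALSE]
                  cfg <- configs[[d$task[1L]]]
                  if (is.null(cfg)) stop("no staircase config for task ", d$task[1L])
                  st <- staircase_replay(cfg, d$correct)
                  n <- length(st$levels)
                  if ("level" %in% names(d) &&
                      any(abs(d$level[seq_len(n)] - st$levels) > 1e-9))
                    stop("recorded levels do not replay under the staircase rule (patient ",
                         d$patient_id[1L], ", task ", d$task[1L], ")")
                  data.frame(patient_id = d$patient_id[1L], task = d$task[1L],
                             threshold = if (st$terminated)
                               staircase_threshold(st, cfg) else NA_real_,
                             n_trials = n,
                             n_reversals = length(st$reversal_levels),
                             terminated = st$terminated)
                })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id, out$task), , drop = FALSE]
}

#' Score motion-defined form from an item-level table
#'
#' @param items data.frame with columns `patient_id`, `condition`
#'   (1/2/3/NA), one row per item.
#' @return data.frame: `patient_id`, `task` ("MDF"), `score`, `evaluable`.
#' @export
score_mdf_table <- function(items) {
  stopifnot(all(c("patient_id", "condition") %in% names(items)))
  out <- lapply(split(items, items$patient_id), function(d) {
    s <- mdf_score(d$condition)
    data.frame(patient_id = d$patient_id[1L], task = "MDF",
               score = s$score, evaluable = s$evaluable)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
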