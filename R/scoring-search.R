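#' Visual-search outcome measures
#'
#' The attention assessment runs a simple reaction-time task (5 trials, the
#' target pops out, so the RT is the motor response time), three search tasks
#' with 4, 9 and 19 distracters (10 trials each), and a closing reaction-time
#' task. Under serial search the reaction time is motor time plus search
#' time, so the outcome per load condition is
#' `median(search RTs) - response_time`, with `response_time` the median over
#' the pooled opening and closing reaction-time trials (pooling is more
#' robust than averaging two 5-trial medians; switchable via `pool_rt`).
#'
#' Trials flagged as false alarms (a wrong picture was touched) are excluded
#' from every median; `total_errors` counts false alarms over the three
#' search conditions. A condition whose trials are all excluded yields `NA`
#' ("missing"), never zero. Negative search times are retained (clamping
#' would bias group medians).
#'
#' @param trials data.frame with columns `condition` (one of `RT_pre`, `D4`,
#'   `D9`, `D19`, `RT_post`), `rt` (seconds, > 0), `false_alarm` (logical).
#' @param pool_rt pool the two reaction-time administrations into one median
#'   (default) or average their medians.
#' @return list of class `search_outcome`: `search_time_5items`,
#'   `search_time_10items`, `search_time_20items`, `response_time` (seconds),
#'   `total_errors`.
#' @examples
#' tr <- data.frame(
#'   condition = c(rep("RT_pre", 3), rep("D9", 3)),
#'   rt = c(1.0, 1.1, 1.2, 2.0, 2.2, 2.4),
#'   false_alarm = FALSE)
#' search_outcome(tr)$search_time_10items  # 2.2 - 1.1 = 1.1
#' @export
search_outcome <- function(trials, pool_rt = TRUE) {
  stopifnot(all(c("condition", "rt", "false_alarm") %in% names(trials)),
            all(trials$rt > 0))
  conds <- c("RT_pre", "D4", "D9", "D19", "RT_post")
  if (!all(trials$condition %in% conds))
    stop("unknown condition(s): ",
         paste(setdiff(unique(trials$condition), conds), collapse = ", "))
  ok <- !trials$false_alarm
  med <- function(cond) {
    x <- trials$rt[ok & trials$condition %in% cond]
    if (length(x)) stats::median(x) else NA_real_
  }
  rt <- if (pool_rt) {
    med(c("RT_pre", "RT_post"))
  } else {
    mean(c(med("RT_pre"), med("RT_post")), na.rm = TRUE)
  }
  if (is.nan(rt)) rt <- NA_real_
  st <- function(cond) {
    m <- med(cond)
    if (is.na(m) || is.na(rt)) NA_real_ else m - rt
  }
  structure(list(
    search_time_5items = st("D4"),
    search_time_10items = st("D9"),
    search_time_20items = st("D19"),
    response_time = rt,
    total_errors = sum(trials$false_alarm &
                         trials$condition %in% c("D4", "D9", "D19"))),
    class = "search_outcome")
}

#' Search outcome measure names, as used in norm tables
#' @export
search_measures <- function() {
  c("search_time_5items", "search_time_10items", "search_time_20items",
    "response_time", "total_errors")
}

#' Score a trial-level search table for many patients
#'
#' @param trials data.frame with columns `patient_id`, `condition`, `trial`,
#'   `rt`, `false_alarm`.
#' @inheritParams search_outcome
#' @return data.frame: one row per patient x measure, columns `patient_id`,
#'   `measure`, `value`.
#' @export
score_search_table <- function(trials, pool_rt = TRUE) {
  stopifnot(all(c("patient_id", "condition", "rt", "false_alarm") %in%
                  names(trials)))
  out <- lapply(split(trials, trials$patient_id), function(d) {
    o <- search_outcome(d, pool_rt = pool_rt)
    data.frame(patient_id = d$patient_id[1L], measure = search_measures(),
               value = unlist(o[search_measures()], use.names = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
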