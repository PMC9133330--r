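#' Age-banded percentile norm tables
#'
#' A norm table maps (measure, age band) to a percentile cutoff, together
#' with the direction that counts as worse performance (`"higher"` for times,
#' thresholds and error counts; `"lower"` for proportion-correct and standard
#' scores). Classification is strict: a value exactly at the cutoff is *not*
#' flagged ("below the percentile").
#'
#' @param df data.frame with columns `measure`, `band_lo`, `band_hi` (months,
#'   inclusive; or year-month strings like "4y9m"), `cutoff`, `percentile`
#'   (5 or 10), `worse` ("higher"/"lower").
#' @return validated data.frame of class `norm_table`, bands ordered and
#'   non-overlapping within each measure.
#' @export
norm_table <- function(df) {
  need <- c("measure", "band_lo", "band_hi", "cutoff", "percentile", "worse")
  stopifnot(all(need %in% names(df)))
  for (col in c("band_lo", "band_hi"))
    if (is.character(df[[col]])) df[[col]] <- ym_to_months(df[[col]])
  stopifnot(all(df$band_lo <= df$band_hi), all(is.finite(df$cutoff)),
            all(df$percentile %in% c(5, 10)),
            all(df$worse %in% c("higher", "lower")))
  df <- df[order(df$measure, df$band_lo), , drop = FALSE]
  for (m in unique(df$measure)) {
    b <- df[df$measure == m, ]
    if (nrow(b) > 1L && any(b$band_lo[-1L] <= b$band_hi[-nrow(b)]))
      stop("overlapping age bands for measure ", m)
  }
  rownames(df) <- NULL
  class(df) <- c("norm_table", "data.frame")
  df
}

#' Read a norm table from a delimited config file
#'
#' @param path CSV with the columns described in [norm_table()].
#' @export
read_norm_table <- function(path) {
  norm_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged norm tables
#'
#' `motion_norms()` and `search_norms()` are the published preliminary 10th
#' percentile cutoffs for the motion tasks (coherence level, MDF proportion
#' correct, speed difference in deg/s) and the visual-search outcomes
#' (search/response times in seconds, total error count) in three age bands
#' (4y3m-4y7m, 4y9m-5y8m, 5y10m-7y4m). `synthetic_l94_norms()` and
#' `synthetic_visuomotor_norms()` are *synthetic* stand-ins: the L94 manual's
#' norms are proprietary and the visuomotor tests are consumed as standard
#' scores, so these tables carry plausible flat cutoffs (L94 subtask score
#' 0.60 at the 5th percentile; Beery VMI standard score 81 and SON-R Mosaics
#' subtest score 6 at the 10th) for pipeline exercise only — substitute real
#' norms via [read_norm_table()] for clinical use.
#'
#' @name packaged_norms
#' @return a [norm_table()].
#' @export
motion_norms <- function() .read_packaged_norms("motion_norms.csv")

#' @rdname packaged_norms
#' @export
search_norms <- function() .read_packaged_norms("search_norms.csv")

#' @rdname packaged_norms
#' @export
synthetic_l94_norms <- function() .read_packaged_norms("synthetic_l94_norms.csv")

#' @rdname packaged_norms
#' @export
synthetic_visuomotor_norms <- function() {
  .read_packaged_norms("synthetic_visuomotor_norms.csv")
}

.read_packaged_norms <- function(file) {
  read_norm_table(system.file("extdata", file, package = "dorsalstream",
                              mustWork = TRUE))
}

#' Combined default norm set for the pipeline
#' @rdname packaged_norms
#' @export
default_norm_tables <- function() {
  norm_table(rbind(motion_norms(), search_norms(), synthetic_l94_norms(),
                   synthetic_visuomotor_norms()))
}

#' Classify one score against age-banded norms
#'
#' Chooses the band containing `entry_age`; when the age is out of range (or
#' falls in a gap) the nearest band is used — the band minimising the
#' distance from the age to the band interval, ties going to the younger
#' band. The flag is set iff the value lies strictly on the worse side of
#' the cutoff.
#'
#' @param value observed score (NA gives an NA flag).
#' @param measure measure name present in `norms`.
#' @param entry_age months (see [developmental_age()]).
#' @param norms a [norm_table()].
#' @return logical flag (TRUE = below the percentile, i.e. abnormal/weak),
#'   with attributes `cutoff` and `band` for reporting.
#' @export
classify_score <- function(value, measure, entry_age, norms) {
  b <- norms[norms$measure == measure, , drop = FALSE]
  if (!nrow(b)) stop("measure not in norm table: ", measure)
  inside <- entry_age >= b$band_lo & entry_age <= b$band_hi
  i <- if (any(inside)) {
    which(inside)[1L]
  } else {
    d <- pmax(b$band_lo - entry_age, entry_age - b$band_hi, 0)
    which.min(d)  # ties resolved to the younger band by band order
  }
  flag <- if (is.na(value)) NA else if (b$worse[i] == "higher")
    value > b$cutoff[i] else value < b$cutoff[i]
  structure(flag, cutoff = b$cutoff[i],
            band = c(b$band_lo[i], b$band_hi[i]))
}

#' Classification policy for the battery
#'
#' Object recognition scores are abnormal below the 5th percentile
#' (z = -1.645); scores on the other functions are weak below the 10th
#' (z = -1.282). A function is weak if at least one of its tasks is flagged;
#' a general dorsal stream dysfunction is at least `general_min_weak` (2) of
#' the three non-object-recognition functions weak.
#'
#' @param abnormal_percentile percentile defining an abnormal object
#'   recognition score.
#' @param weak_percentile percentile defining a weak score on other tasks.
#' @param general_min_weak weak functions required for a general dysfunction.
#' @export
classification_policy <- function(abnormal_percentile = 5,
                                  weak_percentile = 10,
                                  general_min_weak = 2L) {
  stopifnot(abnormal_percentile %in% c(5, 10), weak_percentile %in% c(5, 10))
  structure(list(abnormal_percentile = abnormal_percentile,
                 weak_percentile = weak_percentile,
                 general_min_weak = as.integer(general_min_weak),
                 dorsal_functions = c("motion", "attention", "visuomotor")),
            class = "classification_policy")
}

#' Roll task flags up to patient-level classification
#'
#' @param l94_flags named logical vector over administered L94 subtasks
#'   (TRUE = abnormal, NA = not evaluable).
#' @param function_flags named list: function name -> logical vector of its
#'   task flags (may be empty or absent when no task of that function was
#'   completed).
#' @param policy a [classification_policy()].
#' @return list of class `patient_classification`: `n_abnormal_l94`,
#'   `or_impaired` (>= 1 abnormal L94 task), `l94_evaluable`,
#'   `function_weak` (named logical, NA when a function has no completed
#'   task), `functions_evaluable` (all three completed),
#'   `n_weak_functions`, `general_dysfunction`.
#' @export
rollup <- function(l94_flags, function_flags, policy = classification_policy()) {
  stopifnot(inherits(policy, "classification_policy"))
  l94_eval <- sum(!is.na(l94_flags))
  n_abn <- sum(l94_flags, na.rm = TRUE)
  fw <- vapply(policy$dorsal_functions, function(f) {
    fl <- function_flags[[f]]
    fl <- fl[!is.na(fl)]
    if (!length(fl)) NA else any(fl)
  }, logical(1))
  evaluable <- !anyNA(fw)
  n_weak <- if (evaluable) sum(fw) else NA_integer_
  structure(list(
    n_abnormal_l94 = n_abn,
    or_impaired = n_abn >= 1L,
    l94_evaluable = l94_eval >= 3L,
    function_weak = fw,
    functions_evaluable = evaluable,
    n_weak_functions = n_weak,
    general_dysfunction = if (evaluable) n_weak >= policy$general_min_weak
                          else NA),
    class = "patient_classification")
}
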