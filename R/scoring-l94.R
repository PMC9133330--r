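#' Score one L94 item
#'
#' The L94 object-recognition battery presents each item in a sequence of
#' conditions of decreasing difficulty, the last (easiest) being the control
#' condition. `j` is the 1-based index of the condition at which the object
#' was recognized and `k` the total number of conditions, so graded subtasks
#' score `(k - j) / (k - 1)`: 1 at the hardest condition, 0 when the object
#' was recognized only in the control condition. NOISE has k = 7 noise
#' levels, OVERL k = 4 overlap levels, VIEW k = 3 or 4 view conditions per
#' item. VISM and DEVOS are binary: 1 if the target was recognized, 0 if not.
#'
#' An item whose control condition was failed is *inconclusive*: failure may
#' reflect naming or language rather than perception, so the item is excluded
#' from the subtask score. Inconclusive items are returned as `NA`.
#'
#' @param subtask one of `"VISM"`, `"NOISE"`, `"OVERL"`, `"VIEW"`, `"DEVOS"`.
#' @param j condition index at recognition (1-based), or `NA` if the object
#'   was never recognized in the scored conditions. For binary subtasks, 1 =
#'   recognized in the target condition, `NA` = not recognized.
#' @param k total number of conditions for this item (1 for binary subtasks).
#' @param control_recognized was the control condition passed? (VISM has no
#'   separate control; leave `TRUE`.)
#' @return item score in `[0, 1]`, or `NA` for an inconclusive item.
#' @examples
#' item_score("NOISE", j = 3, k = 7)   # (7-3)/6 = 0.667
#' item_score("VIEW",  j = 4, k = 4)   # recognized only at control: 0
#' item_score("OVERL", j = 2, k = 4, control_recognized = FALSE)  # NA
#' @export
item_score <- function(subtask, j, k, control_recognized = TRUE) {
  subtask <- match.arg(toupper(subtask), l94_subtasks())
  binary <- subtask %in% c("VISM", "DEVOS")
  if (!binary) {
    stopifnot(length(k) == 1L, k >= 2)
    if (is.na(j)) {
      if (isTRUE(control_recognized))
        stop("contradictory item: never recognized but control condition passed")
      return(NA_real_)
    }
    if (j < 1 || j > k) stop("j must be in 1..k")
    if (!isTRUE(control_recognized)) return(NA_real_)
    (k - j) / (k - 1)
  } else {
    if (!isTRUE(control_recognized)) return(NA_real_)
    if (is.na(j)) 0 else 1
  }
}

l94_subtasks <- function() c("VISM", "NOISE", "OVERL", "VIEW", "DEVOS")

#' Score an L94 subtask from its item responses
#'
#' Average of the conclusive item scores; items not recognized in their
#' control condition are excluded. A subtask with no conclusive item is not
#' evaluable.
#'
#' @param items data.frame with columns `subtask`, `j`, `k`,
#'   `control_recognized` (one row per item), all of one subtask.
#' @return list of class `subtask_score`: `subtask`, `score` (NA when not
#'   evaluable), `evaluable`, `n_conclusive`, `n_inconclusive`.
#' @export
subtask_score <- function(items) {
  stopifnot(is.data.frame(items), nrow(items) >= 1L)
  sub <- unique(toupper(items$subtask))
  if (length(sub) != 1L) stop("items must belong to a single subtask")
  ctl <- if ("control_recognized" %in% names(items)) items$control_recognized
         else rep(TRUE, nrow(items))
  sc <- mapply(item_score, items$subtask, items$j, items$k, ctl)
  conclusive <- !is.na(sc)
  structure(list(
    subtask = sub,
    score = if (any(conclusive)) mean(sc[conclusive]) else NA_real_,
    evaluable = any(conclusive),
    n_conclusive = sum(conclusive),
    n_inconclusive = sum(!conclusive)), class = "subtask_score")
}

#' Battery-level evaluability rule
#'
#' A participant enters the analysis only if at least three of the five L94
#' subtasks could be evaluated.
#'
#' @param evaluable logical vector, one element per subtask slot (length 5).
#' @export
l94_evaluable <- function(evaluable) {
  stopifnot(length(evaluable) == 5L)
  sum(evaluable, na.rm = TRUE) >= 3L
}

#' Score all L94 subtasks in an item-level table
#'
#' @param items data.frame with columns `patient_id`, `subtask`, `j`, `k`,
#'   `control_recognized`.
#' @return data.frame: one row per patient x administered subtask with
#'   `score`, `evaluable`, `n_conclusive`, `n_inconclusive`.
#' @export
score_l94_table <- function(items) {
  stopifnot(all(c("patient_id", "subtask", "j", "k") %in% names(items)))
  out <- lapply(split(items, list(items$patient_id, items$subtask), drop = TRUE),
                function(d) {
                  s <- subtask_score(d)
                  data.frame(patient_id = d$patient_id[1L], subtask = s$subtask,
                             score = s$score, evaluable = s$evaluable,
                             n_conclusive = s$n_conclusive,
                             n_inconclusive = s$n_inconclusive)
                })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id, out$subtask), , drop = FALSE]
}
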