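#' Developmental age and norm-table entry age
#'
#' To control for cognitive impairment, performance is referenced at the
#' child's developmental age (DA) rather than chronological age (CA). DA at
#' IQ testing is the median age-equivalent of the non-verbal IQ subtests
#' (even counts take the mean of the central pair), and is projected to the
#' dorsal-stream assessment date by assuming a constant developmental rate:
#'
#'   `DA_dorsal = (DA_IQ / CA_IQ) * CA_dorsal`
#'
#' The norm-table entry age is `DA_dorsal`, capped at `CA_dorsal` when the
#' child is developing at or above age level: if PIQ >= 100 or the projected
#' DA exceeds CA, CA is used instead (either trigger suffices; the entry age
#' therefore never exceeds `CA_dorsal`).
#'
#' @param age_equivalents months, one per non-verbal subtest (>= 1 value).
#' @param ca_iq chronological age in months at IQ testing (> 0).
#' @param ca_dorsal chronological age in months at dorsal-stream testing.
#' @param piq optional performance IQ.
#' @return list: `da_iq`, `da_dorsal`, `entry_age` (months, possibly
#'   fractional), `capped_at_ca`.
#' @examples
#' developmental_age(c(36, 48, 60), ca_iq = 72, ca_dorsal = 84)
#' @export
developmental_age <- function(age_equivalents, ca_iq, ca_dorsal, piq = NULL) {
  if (length(age_equivalents) < 1L || any(is.na(age_equivalents)))
    stop("at least one non-missing age-equivalent is required")
  stopifnot(all(age_equivalents > 0), ca_iq > 0, ca_dorsal > 0)
  da_iq <- stats::median(age_equivalents)
  da_dorsal <- (da_iq / ca_iq) * ca_dorsal
  cap <- (!is.null(piq) && !is.na(piq) && piq >= 100) || da_dorsal > ca_dorsal
  list(da_iq = da_iq, da_dorsal = da_dorsal,
       entry_age = if (cap) ca_dorsal else da_dorsal,
       capped_at_ca = cap)
}
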