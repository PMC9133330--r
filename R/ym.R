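#' Year-month age notation
#'
#' Norm tables for paediatric visual tasks are banded in year-month units
#' ("4y3m" = 51 months). These helpers convert between the text notation and
#' integer months, bit-exactly in both directions.
#'
#' @param x character vector like `"4y3m"`; a bare `"5y"` means 60 months.
#' @return `ym_to_months()`: integer months; `months_to_ym()`: character.
#' @examples
#' ym_to_months("4y3m")   # 51
#' months_to_ym(51L)      # "4y3m"
#' @export
ym_to_months <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]+)y(?:([0-9]+)m)?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("cannot parse year-month age: ", paste(x[bad], collapse = ", "))
  vapply(m, function(g) {
    yy <- as.integer(g[2L])
    mm <- if (nzchar(g[3L])) as.integer(g[3L]) else 0L
    if (mm > 11L) stop("month part must be 0-11 in: ", g[1L])
    yy * 12L + mm
  }, integer(1))
}

#' @rdname ym_to_months
#' @param months numeric vector of ages in months; fractional months are
#'   rounded half-up at format time (ages are carried in months internally).
#' @export
months_to_ym <- function(months) {
  months <- floor(months + 0.5)  # round half-up, report-time only
  if (any(months < 0)) stop("negative age")
  sprintf("%dy%dm", months %/% 12L, months %% 12L)
}
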