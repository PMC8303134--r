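## Two-criteria image triage: (1) detectability of all key structures by both
## raters; (2) the iliac-wing check angle within +/-5 degrees for both raters.
## Only images passing both gates are appropriate for Graf angle comparison.

#' 2x2 contingency table of paired OK/Error calls
#'
#' @param a both raters OK; @param b AI OK, human Error; @param c AI Error,
#'   human OK; @param d both Error. All counts >= 0.
#' @return object of class `contingency_2x2` with fields `a`, `b`, `c`, `d`,
#'   `n`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency_2x2: counts must be non-negative integers",
         call. = FALSE)
  }
  structure(as.list(c(counts, n = sum(counts))), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> n = %d\n", x$n))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(AI = c("OK", "Error"),
                              Human = c("OK", "Error")))
  print(m)
  invisible(x)
}

#' Check-angle appropriateness gate
#'
#' An image's check angle passes when its magnitude is within the tolerance
#' (boundary inclusive: "within +/-5 degrees" is read as |check| <= 5).
#'
#' @param check_deg signed check angle(s), degrees.
#' @param tolerance gate half-width in degrees (default 5).
#' @return character vector of `"OK"` / `"Error"`.
#' @export
check_gate <- function(check_deg, tolerance = 5) {
  if (any(!is.finite(check_deg))) {
    stop("check_gate: check_deg must be finite", call. = FALSE)
  }
  ifelse(abs(check_deg) <= tolerance, "OK", "Error")
}

#' Triage one paired reading
#'
#' `fail_detection` when either rater found the image undetectable;
#' otherwise `appropriate` when both raters' check angles pass the gate, and
#' `inappropriate_check_angle` when at least one does not. The three labels
#' partition any cohort.
#'
#' @param pr a [paired_reading()].
#' @param tolerance check-angle gate half-width, degrees.
#' @return one of `"appropriate"`, `"inappropriate_check_angle"`,
#'   `"fail_detection"`.
#' @export
triage <- function(pr, tolerance = 5) {
  stopifnot(inherits(pr, "paired_reading"))
  if (!pr$ai$detectable || !pr$human$detectable) return("fail_detection")
  ok <- check_gate(c(pr$ai$check_deg, pr$human$check_deg), tolerance) == "OK"
  if (all(ok)) "appropriate" else "inappropriate_check_angle"
}

#' Detectability cross-tabulation of a cohort (first triage criterion)
#'
#' @param readings list of [paired_reading()] objects.
#' @return data.frame with rows for each rater's detectable/undetectable
#'   counts, the commonly-detectable count and the fail-detection count, with
#'   percentages of the cohort size to 1 decimal.
#' @export
tabulate_detection <- function(readings) {
  if (length(readings) == 0) {
    stop("tabulate_detection: empty cohort", call. = FALSE)
  }
  ai <- vapply(readings, function(r) r$ai$detectable, TRUE)
  human <- vapply(readings, function(r) r$human$detectable, TRUE)
  n <- length(readings)
  common <- sum(ai & human)
  counts <- c(human_detectable = sum(human),
              human_undetectable = sum(!human),
              ai_detectable = sum(ai),
              ai_undetectable = sum(!ai),
              commonly_detectable = common,
              fail_detection = n - common)
  data.frame(
    subgroup = names(counts),
    n = as.integer(counts),
    pct = round(100 * counts / n, 1),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Check-angle cross-tabulation of commonly detectable readings
#'
#' Applies the check-angle gate to both raters of every reading and
#' cross-tabulates the OK/Error calls (second triage criterion). Column
#' percentages are relative to the human-OK and human-Error totals, to 1
#' decimal.
#'
#' @param readings list of [paired_reading()] objects, all detectable by
#'   both raters.
#' @param tolerance gate half-width, degrees.
#' @return list with `table` (a [contingency_2x2()]) and `column_pct`
#'   (matrix of column percentages).
#' @export
tabulate_check <- function(readings, tolerance = 5) {
  if (length(readings) == 0) {
    stop("tabulate_check: empty cohort", call. = FALSE)
  }
  det <- vapply(readings, function(r) r$ai$detectable && r$human$detectable,
                TRUE)
  if (!all(det)) {
    stop("tabulate_check: all readings must be detectable by both raters",
         call. = FALSE)
  }
  ai_ok <- vapply(readings,
                  function(r) check_gate(r$ai$check_deg, tolerance) == "OK",
                  TRUE)
  h_ok <- vapply(readings,
                 function(r) check_gate(r$human$check_deg, tolerance) == "OK",
                 TRUE)
  tab <- contingency_2x2(sum(ai_ok & h_ok), sum(ai_ok & !h_ok),
                         sum(!ai_ok & h_ok), sum(!ai_ok & !h_ok))
  col_ok <- max(tab$a + tab$c, 1)
  col_err <- max(tab$b + tab$d, 1)
  column_pct <- matrix(
    round(100 * c(tab$a / col_ok, tab$c / col_ok,
                  tab$b / col_err, tab$d / col_err), 1),
    nrow = 2,
    dimnames = list(AI = c("OK", "Error"), Human = c("OK", "Error"))
  )
  list(table = tab, column_pct = column_pct)
}

#' Triage an entire cohort
#'
#' @param readings list of [paired_reading()] objects.
#' @param tolerance check-angle gate half-width, degrees.
#' @return data.frame with `image_id` and `label` per reading.
#' @export
triage_cohort <- function(readings, tolerance = 5) {
  if (length(readings) == 0) stop("triage_cohort: empty cohort", call. = FALSE)
  data.frame(
    image_id = vapply(readings, function(r) r$image_id, ""),
    label = vapply(readings, triage, "", tolerance = tolerance),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
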