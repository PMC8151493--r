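#' Empirical distribution of hyperketonemia onset days
#'
#' The onset of a case cow is the sample day of its first BHB value
#' strictly above `threshold` (no interpolation between visits).  The
#' returned step function \eqn{F(d)} is the fraction of eventual cases
#' whose onset is at or before day \eqn{d}; the denominator is the
#' number of cases, not the herd size.
#'
#' @param table an `observation_table`.
#' @param threshold BHB case threshold (mmol/L), e.g. 0.8 or 1.2.
#' @return An object of class `"onset_ecdf"`: `onsets` (sorted onset
#'   days), `fun` (the step function), `n_cases`, `threshold`.  Empty
#'   (with a warning) when there are no cases.
#' @export
onset_ecdf <- function(table, threshold = 0.8) {
  labels <- label_cows(table, threshold)
  onsets <- sort(labels$onset_day[labels$case])
  if (length(onsets) == 0) {
    warning("no cases at threshold ", threshold, ": empty ECDF")
    fun <- function(d) rep(NA_real_, length(d))
  } else {
    fun <- ecdf(onsets)
  }
  structure(list(onsets = onsets, fun = fun,
                 n_cases = length(onsets), threshold = threshold),
            class = "onset_ecdf")
}

print.onset_ecdf <- function(x, ...) {
  cat("Onset ECDF (BHB > ", x$threshold, " mmol/L): ", x$n_cases,
      " cases\n", sep = "")
  if (x$n_cases > 0) {
    cat("  onset days: ", paste(x$onsets, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Overall incidence proportion
#'
#' Number of case cows divided by the total number of cows tested.
#'
#' @param labels a `case_labels` data frame from [label_cows()].
#' @param n_total total number of cows tested (defaults to the number of
#'   labelled cows).
#' @return A fraction in \[0, 1\].
#' @export
incidence_proportion <- function(labels, n_total = nrow(labels)) {
  stopifnot(inherits(labels, "case_labels"), n_total >= 1)
  sum(labels$case) / n_total
}

#' Maximum ante-partum sampling gap
#'
#' For each cow, the time span in days from its last ante-partum sample
#' (day < 0; day 0 is partum, not ante partum) to partum.  The maximum of
#' these spans over the herd is the smallest time interval a
#' classification scheme can use while guaranteeing at least one
#' measurement per cow within the interval.  Cows without any ante-partum
#' sample are flagged with a warning and skipped.
#'
#' @param table an `observation_table`.
#' @return The maximum gap in days (positive integer).
#' @export
max_prepartum_gap <- function(table) {
  table <- validate_observations(table)
  last_ap <- vapply(split(table$day, table$cow_id), function(d) {
    ap <- d[d < 0]
    if (length(ap) == 0) NA_integer_ else max(ap)
  }, integer(1))
  if (all(is.na(last_ap))) stop("no cow has an ante-partum sample")
  if (anyNA(last_ap)) {
    warning(sum(is.na(last_ap)), " cow(s) without an ante-partum sample ",
            "skipped: ",
            paste(names(last_ap)[is.na(last_ap)], collapse = ", "))
  }
  max(-last_ap, na.rm = TRUE)
}

#' Fraction of eventual cases undetected by a single-day measurement
#'
#' For a single measurement at `day`, the fraction of cows progressing
#' to case status whose onset lies after that day: \eqn{1 - F(day)}.
#'
#' @param ecdf an [onset_ecdf()].
#' @param day measurement day relative to parturition.
#' @return A fraction in \[0, 1\].
#' @export
undetected_fraction <- function(ecdf, day) {
  stopifnot(inherits(ecdf, "onset_ecdf"))
  if (ecdf$n_cases == 0) stop("empty ECDF: no cases")
  1 - ecdf$fun(day)
}
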