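#' Per-interval group tests over the study window
#'
#' Descriptive tests of case-vs-control differences in log biomarker
#' values.  The study window from 15 days ante partum to 62 days post
#' partum is tiled with 6-day intervals (13 intervals for the default
#' bounds), and two extra single-day tests are run at t0 (day of
#' parturition) and t1 (day 10 post partum) using nearest-neighbour
#' linear interpolation of each cow's series.  Within an interval each
#' cow contributes the mean of its log values (one number per cow, so
#' multiple visits in one interval do not pseudo-replicate).  The primary
#' test is Welch's two-sample t-test; a literal one-sample variant (case
#' cows tested against the control mean treated as a fixed constant) is
#' available via `method`.  P-values are not multiplicity-corrected by
#' default; set `p_adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param table an `observation_table`.
#' @param labels a `case_labels` data frame from [label_cows()].
#' @param biomarker one of `"bhb"`, `"nefa"`, `"tbil"`, `"ast"`.
#' @param width interval width in days (default 6).
#' @param range inclusive day range to tile (default `c(-15, 62)`).
#' @param t_days extra single-day tests on interpolated values
#'   (default `c(0, 10)` = t0 and t1).
#' @param method `"welch"` (two-sample, primary) or `"one_sample"`.
#' @param p_adjust apply Benjamini-Hochberg correction (default FALSE).
#' @return Data frame, one row per interval or single-day test, columns
#'   `interval`, `start_day`, `end_day`, `n_case`, `n_control`,
#'   `mean_case`, `mean_control` (log scale), `t`, `p`, `skipped`.
#'   Intervals with fewer than 2 cows in either group are flagged
#'   `skipped` with `NA` statistics.
#' @export
interval_group_tests <- function(table, labels, biomarker = "bhb",
                                 width = 6, range = c(-15, 62),
                                 t_days = c(0, 10),
                                 method = c("welch", "one_sample"),
                                 p_adjust = FALSE) {
  method <- match.arg(method)
  table <- validate_observations(table)
  stopifnot(biomarker %in% BIOMARKERS, width >= 1)
  idx <- match(table$cow_id, labels$cow_id)
  if (anyNA(idx)) stop("labels do not cover all cows in the table")
  is_case <- labels$case[idx]
  if (all(is_case)) stop("no control cows in the table")
  if (!any(is_case)) stop("no case cows in the table")

  span <- range[2] - range[1] + 1
  n_int <- ceiling(span / width)
  starts <- range[1] + width * (seq_len(n_int) - 1)
  ends <- pmin(starts + width - 1, range[2])

  logval <- log(table[[biomarker]])
  run_test <- function(case_means, ctrl_means) {
    if (length(case_means) < 2 || length(ctrl_means) < 2) {
      return(list(t = NA_real_, p = NA_real_, skipped = TRUE))
    }
    tt <- if (method == "welch") {
      t.test(case_means, ctrl_means)
    } else {
      t.test(case_means, mu = mean(ctrl_means))
    }
    list(t = unname(tt$statistic), p = tt$p.value, skipped = FALSE)
  }

  rows <- vector("list", n_int + length(t_days))
  for (j in seq_len(n_int)) {
    sel <- !is.na(logval) & table$day >= starts[j] & table$day <= ends[j]
    cow_means <- tapply(logval[sel], table$cow_id[sel], mean)
    cow_case <- is_case[match(names(cow_means), table$cow_id)]
    res <- run_test(cow_means[cow_case], cow_means[!cow_case])
    rows[[j]] <- data.frame(
      interval = sprintf("[%d,%d]", starts[j], ends[j]),
      start_day = starts[j], end_day = ends[j],
      n_case = sum(cow_case), n_control = sum(!cow_case),
      mean_case = if (any(cow_case)) mean(cow_means[cow_case]) else NA_real_,
      mean_control = if (any(!cow_case)) mean(cow_means[!cow_case]) else NA_real_,
      t = res$t, p = res$p, skipped = res$skipped,
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(t_days)) {
    d <- t_days[k]
    vals <- vapply(split(seq_len(nrow(table)), table$cow_id), function(i) {
      interpolate_at(table$day[i], table[[biomarker]][i], d)
    }, numeric(1))
    ok <- !is.na(vals)
    cow_case <- is_case[match(names(vals), table$cow_id)]
    res <- run_test(log(vals[ok & cow_case]), log(vals[ok & !cow_case]))
    rows[[n_int + k]] <- data.frame(
      interval = sprintf("t(day %d)", d),
      start_day = d, end_day = d,
      n_case = sum(ok & cow_case), n_control = sum(ok & !cow_case),
      mean_case = mean(log(vals[ok & cow_case])),
      mean_control = mean(log(vals[ok & !cow_case])),
      t = res$t, p = res$p, skipped = res$skipped,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (p_adjust) out$p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
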