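BIOMARKERS <- c("bhb", "nefa", "tbil", "ast")

REQUIRED_COLUMNS <- c("cow_id", "parity", "day", BIOMARKERS)

#' Validate a cow-visit observation table
#'
#' Checks the invariants every downstream function relies on: required
#' columns, integer day within \[-60, 120\] relative to parturition (day 0 =
#' partum, negative = ante partum), strictly positive biomarker values (a
#' log transform must be defined wherever a value is present), no duplicate
#' (cow, day) pairs, and rows sorted by cow then day.
#'
#' @param table data frame with columns `cow_id`, `parity`
#'   (`"primiparous"`/`"multiparous"`), `day`, `bhb`, `nefa`, `tbil`, `ast`
#'   and optionally `post_treatment`.
#' @return The table, sorted by cow and day, invisibly classed
#'   `"observation_table"`.
#' @export
validate_observations <- function(table) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(table))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"post_treatment" %in% names(table)) table$post_treatment <- FALSE
  table$cow_id <- as.character(table$cow_id)
  table$day <- as.integer(table$day)
  if (anyNA(table$day)) stop("non-integer or missing 'day' values")
  if (any(table$day < -60 | table$day > 120)) {
    stop("'day' outside [-60, 120]: days are relative to parturition")
  }
  bad_parity <- !table$parity %in% c("primiparous", "multiparous")
  if (any(bad_parity)) {
    stop("invalid parity value(s): ",
         paste(unique(table$parity[bad_parity]), collapse = ", "))
  }
  for (bm in BIOMARKERS) {
    v <- table[[bm]]
    if (!is.numeric(v)) stop("column '", bm, "' is not numeric")
    if (any(v <= 0, na.rm = TRUE)) {
      stop("non-positive ", bm, " value(s); all biomarkers must be > 0")
    }
  }
  key <- paste(table$cow_id, table$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (cow_id, day) pair(s): ",
         paste(gsub("\r", "/day ", dup), collapse = ", "))
  }
  table <- table[order(table$cow_id, table$day), , drop = FALSE]
  rownames(table) <- NULL
  class(table) <- unique(c("observation_table", class(table)))
  table
}

#' Read a cow-visit observation CSV
#'
#' Reads a comma-separated, UTF-8 table with header
#' `cow_id,parity,day,bhb,nefa,tbil,ast,post_treatment` (the
#' `post_treatment` column is optional and defaults to `FALSE`; an empty
#' biomarker field is a missing value).  Rows whose numeric fields cannot
#' be parsed, or whose biomarker values are non-positive, are dropped with
#' a per-row report attached as attribute `"rejected"` (and a warning).
#' Structural problems — a missing required column or a duplicate
#' (cow, day) pair — are fatal.
#'
#' @param path path to the CSV file.
#' @param dialect optional named character vector mapping the standard
#'   column names to the names used in the file, e.g.
#'   `c(cow_id = "animal", day = "dim")`.
#' @return An `observation_table` data frame, sorted by cow and day.
#' @export
read_observations <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (!dialect[[std]] %in% names(raw)) {
        stop("dialect column '", dialect[[std]], "' not found in ", path)
      }
      names(raw)[names(raw) == dialect[[std]]] <- std
    }
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n0 <- nrow(raw)
  suppressWarnings({
    day_num <- as.numeric(raw$day)
    bm_num <- lapply(raw[BIOMARKERS], function(v) as.numeric(v))
  })
  bad_day <- is.na(day_num) | day_num != round(day_num)
  # present in the file but unparseable or non-positive
  bad_bm <- Reduce(`|`, lapply(seq_along(BIOMARKERS), function(i) {
    present <- !is.na(raw[[BIOMARKERS[i]]]) &
      trimws(as.character(raw[[BIOMARKERS[i]]])) != ""
    present & (is.na(bm_num[[i]]) | bm_num[[i]] <= 0)
  }))
  bad <- bad_day | bad_bm
  rejected <- NULL
  if (any(bad)) {
    rejected <- data.frame(row = which(bad),
                           cow_id = as.character(raw$cow_id)[bad],
                           reason = ifelse(bad_day[bad],
                                           "unparseable or non-integer day",
                                           "unparseable or non-positive biomarker"))
    warning(sum(bad), " row(s) rejected; see attr(, 'rejected')")
  }
  keep <- !bad
  tab <- data.frame(cow_id = as.character(raw$cow_id)[keep],
                    parity = as.character(raw$parity)[keep],
                    day = as.integer(day_num[keep]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(BIOMARKERS)) tab[[BIOMARKERS[i]]] <- bm_num[[i]][keep]
  tab$post_treatment <- if ("post_treatment" %in% names(raw)) {
    as.logical(raw$post_treatment)[keep]
  } else FALSE
  out <- validate_observations(tab)
  attr(out, "rejected") <- rejected
  out
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]: comma-separated, UTF-8, standard
#' header, missing biomarker values as empty fields.
#'
#' @param table an `observation_table` (or any data frame passing
#'   [validate_observations()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  table <- validate_observations(table)
  cols <- c(REQUIRED_COLUMNS, "post_treatment")
  utils::write.csv(as.data.frame(table)[cols], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep cows with a minimum number of visits
#'
#' The study cohort rule: only cows with more than ten observations enter
#' the final data set, i.e. at least `min_obs = 11` visits.  Visit rows of
#' retained cows are untouched.
#'
#' @param table an `observation_table`.
#' @param min_obs minimum number of visits a cow must have (default 11,
#'   the "more than 10" cohort rule).
#' @return The filtered `observation_table` (possibly empty).
#' @export
filter_min_observations <- function(table, min_obs = 11) {
  stopifnot(min_obs >= 1)
  table <- validate_observations(table)
  counts <- table(table$cow_id)
  keep <- names(counts)[counts >= min_obs]
  out <- table[table$cow_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Label cows by a BHB case threshold
#'
#' A cow is a case iff any of its serum BHB samples strictly exceeds
#' `threshold` (mmol/L); `onset_day` is the day of the first exceedance.
#' The conventional thresholds are 0.8 mmol/L for hyperketonemia and
#' 1.2 mmol/L for subclinical ketosis, so labelling at 1.2 always yields a
#' subset of the 0.8 case set.
#'
#' @param table an `observation_table`.
#' @param threshold BHB case threshold in mmol/L (strict `>`).
#' @return A data frame, one row per cow: `cow_id`, `case` (logical),
#'   `onset_day` (integer, `NA` for controls), with the threshold stored
#'   as attribute `"threshold"`.  Classed `"case_labels"`.
#' @export
label_cows <- function(table, threshold = 0.8) {
  stopifnot(is.numeric(threshold), threshold > 0)
  table <- validate_observations(table)
  split_idx <- split(seq_len(nrow(table)), table$cow_id)
  res <- lapply(split_idx, function(i) {
    bhb <- table$bhb[i]
    day <- table$day[i]
    ok <- !is.na(bhb)
    if (!any(ok)) return(c(NA_integer_, NA_integer_))  # no usable sample
    hit <- ok & bhb > threshold
    if (any(hit)) c(1L, day[which(hit)[1]]) else c(0L, NA_integer_)
  })
  usable <- !vapply(res, function(x) is.na(x[1]), logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " cow(s) with no usable BHB sample excluded: ",
            paste(names(res)[!usable], collapse = ", "))
  }
  res <- res[usable]
  out <- data.frame(cow_id = names(res),
                    case = vapply(res, `[`, integer(1), 1) == 1L,
                    onset_day = vapply(res, `[`, integer(1), 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("case_labels", class(out))
  out
}

#' Shapiro-Wilk normality assessment on raw and log scale
#'
#' Runs the Shapiro-Wilk test on the raw values and on their natural
#' logarithms and recommends the scale with the larger p-value.  This is
#' the screening step that motivates log-transforming serum biomarker
#' panels before model fitting.
#'
#' @param values numeric vector of strictly positive values (>= 3 finite).
#' @return A list with components `raw` and `log`, each `(W, p)`, and
#'   `recommendation` (`"log"` or `"raw"`).
#' @export
assess_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values")
  if (any(values <= 0)) stop("non-positive value: log scale undefined")
  if (length(unique(values)) == 1) stop("constant vector: normality test degenerate")
  # shapiro.test caps n at 5000
  if (length(values) > 5000) values <- values[seq_len(5000)]
  sw_raw <- stats::shapiro.test(values)
  sw_log <- stats::shapiro.test(log(values))
  list(raw = list(W = unname(sw_raw$statistic), p = sw_raw$p.value),
       log = list(W = unname(sw_log$statistic), p = sw_log$p.value),
       recommendation = if (sw_log$p.value > sw_raw$p.value) "log" else "raw")
}
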