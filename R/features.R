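#' Nearest-neighbour linear interpolation within one cow's series
#'
#' Returns the observed value when `day` was sampled, otherwise the
#' linear interpolation between the nearest flanking observations, and
#' missing (`NA`) when `day` lies outside the observed range — a cow
#' without the needed neighbours has the value missing, never zero.
#'
#' @param days observed days (sorted or not; missing values dropped).
#' @param values observed biomarker values, same length as `days`.
#' @param day the day (or days) at which to interpolate.
#' @return Interpolated value(s), `NA` outside the observed range.
#' @export
interpolate_at <- function(days, values, day) {
  ok <- !is.na(days) & !is.na(values)
  if (sum(ok) == 0) return(rep(NA_real_, length(day)))
  if (sum(ok) == 1) {
    return(ifelse(day == days[ok], values[ok], NA_real_))
  }
  approx(days[ok], values[ok], xout = day, method = "linear",
         rule = 1, ties = mean)$y
}

FEATURE_FAMILY_ORDER <- c("median_ap", "max_ap", "t0", "day", "rise_base",
                          "rise_t0", "parity")

#' Prognostic feature matrix per cow
#'
#' Builds the candidate-classifier features, per biomarker:
#' * (I) `median_ap` — median ante-partum value (baseline);
#' * (II) `max_ap` — maximum ante-partum value;
#' * (III) `t0` — value at partum (day 0, interpolated);
#' * (IV) `d1 ... d10` — interpolated daily values on post-partum days
#'   1 to 10 (the t1 grid);
#' * (V) `rise_base_d*` — increase from baseline to each t1 day;
#' * (VI) `rise_t0_d*` — increase from partum to each t1 day;
#' * (VII) `parity` — parity class (0 = primiparous, 1 = multiparous),
#'   plus optional parity-stratified copies of every feature.
#'
#' Increases are arithmetic differences on the natural scale.  Features
#' whose ingredients are unobservable for a cow (no ante-partum samples,
#' or a day outside the observed range) are missing, not zero.
#'
#' @param table an `observation_table`.
#' @param labels a `case_labels` data frame covering the table's cows.
#' @param biomarkers biomarkers to build features for.
#' @param t1_days post-partum grid days (default 1:10).
#' @param parity_strata also emit per-parity copies of each feature
#'   (value present only for cows of that parity; default TRUE).
#' @return Data frame, one row per labelled cow present in the table:
#'   `cow_id`, `case`, feature columns named `<biomarker>_<feature>`.
#'   Attribute `"feature_info"` maps columns to family and day for
#'   rank tie-breaking.
#' @export
extract_features <- function(table, labels,
                             biomarkers = BIOMARKERS, t1_days = 1:10,
                             parity_strata = TRUE) {
  table <- validate_observations(table)
  stopifnot(inherits(labels, "case_labels"))
  cows <- intersect(labels$cow_id, unique(table$cow_id))
  if (length(cows) == 0) stop("labels cover none of the table's cows")
  split_idx <- split(seq_len(nrow(table)), table$cow_id)[cows]

  out <- data.frame(cow_id = cows,
                    case = labels$case[match(cows, labels$cow_id)],
                    stringsAsFactors = FALSE)
  parity <- vapply(split_idx, function(i) table$parity[i][1], character(1))
  info <- list()
  add_col <- function(df, name, values, family, day = NA_integer_) {
    df[[name]] <- unname(values)
    info[[name]] <<- data.frame(column = name, family = family, day = day,
                                stringsAsFactors = FALSE)
    df
  }
  for (bm in biomarkers) {
    per_cow <- lapply(split_idx, function(i) {
      list(day = table$day[i], val = table[[bm]][i])
    })
    ap_stat <- function(fn) vapply(per_cow, function(s) {
      v <- s$val[s$day < 0 & !is.na(s$val)]
      if (length(v) == 0) NA_real_ else fn(v)
    }, numeric(1))
    at_day <- function(d) vapply(per_cow, function(s) {
      interpolate_at(s$day, s$val, d)
    }, numeric(1))
    base <- ap_stat(median)
    t0 <- at_day(0)
    out <- add_col(out, paste0(bm, "_median_ap"), base, "median_ap")
    out <- add_col(out, paste0(bm, "_max_ap"), ap_stat(max), "max_ap")
    out <- add_col(out, paste0(bm, "_t0"), t0, "t0")
    for (d in t1_days) {
      out <- add_col(out, paste0(bm, "_d", d), at_day(d), "day", d)
    }
    for (d in t1_days) {
      out <- add_col(out, paste0(bm, "_rise_base_d", d),
                     out[[paste0(bm, "_d", d)]] - base, "rise_base", d)
    }
    for (d in t1_days) {
      out <- add_col(out, paste0(bm, "_rise_t0_d", d),
                     out[[paste0(bm, "_d", d)]] - t0, "rise_t0", d)
    }
  }
  out <- add_col(out, "parity", as.numeric(parity == "multiparous"),
                 "parity")
  if (parity_strata) {
    feat_cols <- setdiff(names(out), c("cow_id", "case", "parity"))
    for (p in c("primiparous", "multiparous")) {
      for (cn in feat_cols) {
        v <- out[[cn]]
        v[parity != p] <- NA_real_
        fam <- info[[cn]]$family
        d <- info[[cn]]$day
        out <- add_col(out, paste0(cn, "_", p), v, fam, d)
      }
    }
  }
  attr(out, "feature_info") <- do.call(rbind, info)
  out$parity <- as.numeric(out$parity)
  out
}

#' Rank candidate classifiers by AUC
#'
#' Scores every feature column of an [extract_features()] matrix with
#' [roc_auc()] against the case labels and returns them sorted by
#' decreasing AUC.  Ties are broken by feature family order
#' (median a.p., max a.p., t0, daily t1 values, rises from baseline,
#' rises from partum, parity) and then by day.  Columns unusable for a
#' ROC curve (single class after dropping missing scores, or fewer than
#' one cow per class) are skipped.
#'
#' @param features an [extract_features()] data frame.
#' @param labels optional `case_labels`; defaults to the `case` column
#'   already in `features`.
#' @return Data frame sorted by decreasing AUC: `feature`, `family`,
#'   `day`, `auc`, `n_used`.
#' @export
rank_classifiers <- function(features, labels = NULL) {
  lab <- if (is.null(labels)) {
    features$case
  } else {
    labels$case[match(features$cow_id, labels$cow_id)]
  }
  info <- attr(features, "feature_info")
  feat_cols <- setdiff(names(features), c("cow_id", "case"))
  rows <- lapply(feat_cols, function(cn) {
    roc <- tryCatch(roc_auc(features[[cn]], lab), error = function(e) NULL)
    if (is.null(roc)) return(NULL)
    fam <- if (!is.null(info) && cn %in% info$column) {
      info[info$column == cn, ]
    } else {
      data.frame(family = NA_character_, day = NA_integer_)
    }
    data.frame(feature = cn, family = fam$family, day = fam$day,
               auc = roc$auc, n_used = roc$n_pos + roc$n_neg,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) stop("no usable feature columns")
  fam_rank <- match(rows$family, FEATURE_FAMILY_ORDER)
  ord <- order(-rows$auc, fam_rank, rows$day, rows$feature)
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
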