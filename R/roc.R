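#' ROC curve and AUC for a per-cow score
#'
#' Sweeps the classification rule "score >= threshold => positive" over
#' all distinct observed scores (plus the trivial all-positive and
#' all-negative rules) and integrates the curve by the trapezoidal rule.
#' With this threshold set the trapezoidal area equals the Mann-Whitney
#' estimator, i.e. the probability that a random positive outscores a
#' random negative, with half credit for ties.  Cows with missing scores
#' are dropped and their count reported.
#'
#' @param scores numeric per-cow scores (higher = more case-like).
#' @param labels logical (or 0/1) case indicator, same length.
#' @return An object of class `"roc_curve"`: `thresholds` (decreasing,
#'   starting at `Inf`), `fpr`, `tpr`, per-threshold confusion counts
#'   `tp`, `fp`, `fn`, `tn`, `auc`, `n_pos`, `n_neg`, `n_dropped`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  n_dropped <- sum(!ok)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative with usable scores")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(c) sum(scores >= c & labels), numeric(1))
  fp <- vapply(thr, function(c) sum(scores >= c & !labels), numeric(1))
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr,
                 tp = tp, fp = fp, fn = n_pos - tp, tn = n_neg - fp,
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 n_dropped = n_dropped),
            class = "roc_curve")
}

print.roc_curve <- function(x, ...) {
  cat("ROC curve: ", x$n_pos, " positives / ", x$n_neg, " negatives",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " dropped)"),
      "; AUC = ", round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

clopper_pearson <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Confusion-matrix metrics with exact binomial confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)`, each with a Clopper-Pearson 95% interval.  A metric
#' whose denominator is zero is reported as missing.
#'
#' @param tp,fp,fn,tn non-negative integer counts (not all zero).
#' @param level confidence level (default 0.95).
#' @return Data frame with columns `metric`, `estimate`, `lower`,
#'   `upper`, `x`, `n`; rows `se`, `sp`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn, level = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  defs <- list(se = c(tp, tp + fn), sp = c(tn, tn + fp),
               ppv = c(tp, tp + fp), npv = c(tn, tn + fn))
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    ci <- clopper_pearson(x, n, level)
    data.frame(metric = m,
               estimate = if (n > 0) x / n else NA_real_,
               lower = ci[1], upper = ci[2], x = x, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metric
  out
}

#' Cost-weighted Youden optimal cut-point
#'
#' Selects the threshold maximising the generalised Youden index
#' \deqn{J(c) = Se(c) + r\,Sp(c) - 1, \qquad
#'   r = \frac{(1-p)\,C_{FP}}{p\,C_{FN}},}
#' where \eqn{p} is the prevalence and \eqn{C_{FN}}, \eqn{C_{FP}} the
#' misclassification costs.  The default \eqn{C_{FN} = 4} encodes that a
#' missed ketosis case costs about four times a needless propylene-glycol
#' supplementation; with \eqn{C_{FN} = C_{FP}} and \eqn{p = 0.5} the
#' criterion reduces to the classical Youden index \eqn{Se + Sp - 1}.
#' Candidate cut-offs are the midpoints between adjacent distinct scores
#' plus the two trivial rules; the classification rule is
#' "score >= cutoff => positive", and ties among maximisers are broken
#' toward the lower cutoff (favouring sensitivity, consistent with
#' \eqn{C_{FN} > C_{FP}}).
#'
#' @param roc a `"roc_curve"` from [roc_auc()].
#' @param prevalence disease prevalence `p` in (0, 1); defaults to the
#'   sample prevalence of the ROC input.
#' @param cfn cost of a false negative (default 4).
#' @param cfp cost of a false positive (default 1).
#' @return An object of class `"cutpoint_result"`: `cutoff`, `youden`
#'   (the maximised J), `r`, `prevalence`, `cfn`, `cfp`, confusion
#'   counts `tp`, `fp`, `fn`, `tn`, and `metrics` (the
#'   [confusion_metrics()] table at the selected cutoff).
#' @export
optimal_cutpoint <- function(roc, prevalence = NULL, cfn = 4, cfp = 1) {
  stopifnot(inherits(roc, "roc_curve"), cfn > 0, cfp > 0)
  if (is.null(prevalence)) {
    prevalence <- roc$n_pos / (roc$n_pos + roc$n_neg)
  }
  stopifnot(prevalence > 0, prevalence < 1)
  r <- (1 - prevalence) * cfp / (prevalence * cfn)

  # Candidate cutoffs: midpoints between adjacent distinct scores and the
  # two trivial rules.  roc$thresholds[k] (an observed score, or Inf)
  # classifies exactly like any cutoff in (previous score, this score],
  # so each stored threshold row is one candidate; its representative
  # cutoff value is the midpoint below it (or -Inf for the lowest score,
  # which classifies everything positive).
  scores_desc <- roc$thresholds  # Inf, then distinct scores descending
  k <- length(scores_desc)
  cand_cut <- c(Inf,
                (scores_desc[-c(1, k)] + scores_desc[-(1:2)]) / 2,
                -Inf)
  se <- roc$tpr
  sp <- 1 - roc$fpr
  J <- se + r * sp - 1
  # max J; ties toward the LOWER cutoff = the later index in descending order
  best <- max(which(J == max(J)))
  cm <- confusion_metrics(roc$tp[best], roc$fp[best],
                          roc$fn[best], roc$tn[best])
  structure(list(cutoff = cand_cut[best], youden = J[best], r = r,
                 prevalence = prevalence, cfn = cfn, cfp = cfp,
                 se = se[best], sp = sp[best],
                 ppv = cm["ppv", "estimate"], npv = cm["npv", "estimate"],
                 tp = roc$tp[best], fp = roc$fp[best],
                 fn = roc$fn[best], tn = roc$tn[best],
                 metrics = cm),
            class = "cutpoint_result")
}

print.cutpoint_result <- function(x, ...) {
  cat("Cost-weighted Youden cut-point (CFN = ", x$cfn, ", CFP = ", x$cfp,
      ", p = ", round(x$prevalence, 3), ")\n", sep = "")
  cat("  cutoff: ", format(x$cutoff), " (score >= cutoff => positive)",
      "; J = ", round(x$youden, 4), "\n", sep = "")
  cat("  counts: TP=", x$tp, " FP=", x$fp, " FN=", x$fn, " TN=", x$tn,
      "\n", sep = "")
  m <- x$metrics
  cat("  ", paste(sprintf("%s = %.2f (%.2f-%.2f)", m$metric, m$estimate,
                          m$lower, m$upper), collapse = "; "), "\n", sep = "")
  invisible(x)
}
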