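# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Minimal valid observation table; biomarker values default to plausible
# constants so tests can override just the column they exercise.
toy_table <- function(cow_id, day, bhb = 0.5, nefa = 0.3, tbil = 4,
                      ast = 80, parity = "multiparous") {
  n <- max(length(cow_id), length(day))
  validate_observations(data.frame(
    cow_id = rep_len(cow_id, n), parity = rep_len(parity, n),
    day = rep_len(day, n), bhb = rep_len(bhb, n),
    nefa = rep_len(nefa, n), tbil = rep_len(tbil, n),
    ast = rep_len(ast, n), post_treatment = FALSE,
    stringsAsFactors = FALSE))
}

# case_labels built directly (bypassing BHB thresholding)
manual_labels <- function(cow_id, case, onset_day = NA_integer_) {
  out <- data.frame(cow_id = cow_id, case = case,
                    onset_day = rep_len(onset_day, length(cow_id)),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- NA_real_
  class(out) <- c("case_labels", class(out))
  out
}

# Group curves with the case curve equal to control plus a uniform
# log-scale shift (0 = null herd).
shifted_curves <- function(shift = 0) {
  curves <- default_group_curves()
  for (bm in names(curves)) {
    curves[[bm]]$case <- curves[[bm]]$control
    curves[[bm]]$case[1] <- curves[[bm]]$control[1] + shift
  }
  curves
}

# Brute-force Mann-Whitney AUC: fraction of (positive, negative) pairs
# won, half credit for ties.
mw_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive generalized-Youden search over all midpoint cutoffs plus the
# trivial rules; rule is score >= cutoff => positive, ties toward the
# lower cutoff.
brute_cutpoint <- function(scores, labels, prevalence, cfn = 4, cfp = 1) {
  labels <- as.logical(labels)
  r <- (1 - prevalence) * cfp / (prevalence * cfn)
  s <- sort(unique(scores))
  cands <- c(Inf, rev((s[-1] + s[-length(s)]) / 2), -Inf)
  best_J <- -Inf; best_cut <- NA
  for (c in cands) {  # descending order; later candidate = lower cutoff
    pos <- scores >= c
    se <- sum(pos & labels) / sum(labels)
    sp <- sum(!pos & !labels) / sum(!labels)
    J <- se + r * sp - 1
    if (J >= best_J) { best_J <- J; best_cut <- c }  # >= keeps lower cutoff
  }
  list(cutoff = best_cut, J = best_J)
}

# Gini impurity of a logical label vector
gini <- function(y) {
  p <- mean(y)
  2 * p * (1 - p)
}

# Exhaustive best root split by Gini gain over all (feature, midpoint)
# pairs, honouring a minimum child size.
brute_root_split <- function(X, y, minbucket) {
  best <- list(gain = -Inf)
  g0 <- gini(y)
  n <- length(y)
  for (j in seq_len(ncol(X))) {
    x <- X[[j]]
    s <- sort(unique(x))
    for (cut in (s[-1] + s[-length(s)]) / 2) {
      left <- x < cut
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      gain <- g0 - (sum(left) / n) * gini(y[left]) -
        (sum(!left) / n) * gini(y[!left])
      if (gain > best$gain) {
        best <- list(gain = gain, feature = names(X)[j], cut = cut,
                     left = left)
      }
    }
  }
  best
}

# Gini gain of a given root partition
split_gain <- function(y, left) {
  gini(y) - mean(left) * gini(y[left]) - mean(!left) * gini(y[!left])
}
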