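#' Classification tree over the prognostic features
#'
#' Fits a CART classification tree (Gini impurity) on the feature
#' matrix with the surveillance-study settings: a node must contain at
#' least `min_node` observations for a split to be attempted (so a node
#' with fewer observations is never split), and the tree is
#' cost-complexity pruned using `cv_folds`-fold cross-validation with
#' the 1-SE rule.  The fold assignment is the only source of
#' randomness; the result is deterministic given `seed`.
#'
#' @param features an [extract_features()] data frame (columns other
#'   than `cow_id`/`case` are predictors).
#' @param labels optional `case_labels`; defaults to the `case` column.
#' @param min_node minimum observations a node needs to be split
#'   (default 10); child nodes must have at least `round(min_node / 3)`.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed integer seed for the CV fold assignment.
#' @return A list of class `"cart_fit"`: `tree` (pruned `rpart`),
#'   `full_tree`, `cp_table`, `cp_selected`, `cv_error` (cross-validated
#'   relative error of the pruned tree), `min_node`, `cv_folds`.
#' @export
fit_cart <- function(features, labels = NULL, min_node = 10,
                     cv_folds = 5, seed = 1L) {
  lab <- if (is.null(labels)) {
    features$case
  } else {
    labels$case[match(features$cow_id, labels$cow_id)]
  }
  stopifnot(min_node >= 2, cv_folds >= 2)
  df <- features[, setdiff(names(features), c("cow_id", "case")),
                 drop = FALSE]
  df$.case <- factor(ifelse(lab, "case", "control"),
                     levels = c("control", "case"))
  cc <- sum(stats::complete.cases(df))
  if (cc < min_node) {
    stop("too few complete rows (", cc, ") for min_node = ", min_node)
  }
  set.seed(seed)
  ctrl <- rpart::rpart.control(minsplit = min_node,
                               minbucket = max(1, round(min_node / 3)),
                               xval = cv_folds, cp = 0)
  full <- rpart::rpart(.case ~ ., data = df, method = "class",
                       parms = list(split = "gini"), control = ctrl)
  cp <- full$cptable
  # 1-SE rule: simplest tree whose CV error is within one SE of the best
  if (nrow(cp) > 1 && "xerror" %in% colnames(cp)) {
    best <- which.min(cp[, "xerror"])
    thresh <- cp[best, "xerror"] + cp[best, "xstd"]
    sel <- min(which(cp[, "xerror"] <= thresh))
    cp_sel <- cp[sel, "CP"]
    cv_err <- cp[sel, "xerror"]
  } else {
    cp_sel <- cp[1, "CP"]
    cv_err <- if ("xerror" %in% colnames(cp)) cp[1, "xerror"] else NA_real_
  }
  pruned <- rpart::prune(full, cp = cp_sel)
  structure(list(tree = pruned, full_tree = full, cp_table = cp,
                 cp_selected = cp_sel, cv_error = cv_err,
                 min_node = min_node, cv_folds = cv_folds),
            class = "cart_fit")
}

print.cart_fit <- function(x, ...) {
  cat("CART fit (minsplit = ", x$min_node, ", ", x$cv_folds,
      "-fold CV, 1-SE pruning)\n", sep = "")
  print(x$tree)
  invisible(x)
}
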