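test_that("interpolation is exact at observed days and linear between", {
  expect_equal(interpolate_at(c(7, 14), c(0.4, 1.1), 10),
               0.4 + (3 / 7) * 0.7)
  expect_equal(interpolate_at(10, 0.9, 10), 0.9)
  expect_true(is.na(interpolate_at(c(12, 19), c(0.5, 0.8), 10)))
  expect_true(is.na(interpolate_at(10, 0.9, 9)))
  # unsorted input and NA values are handled
  expect_equal(interpolate_at(c(14, NA, 7), c(1.1, 2, 0.4), 7), 0.4)
})

test_that("feature extraction computes the ante-partum and t1 features", {
  tab <- toy_table("a", day = c(-14, -7, -3, 0, 10),
                   bhb = c(0.3, 0.5, 0.4, 0.5, 0.7))
  lab <- manual_labels("a", TRUE)
  fm <- extract_features(tab, lab, biomarkers = "bhb",
                         parity_strata = FALSE)
  expect_equal(fm$bhb_median_ap, 0.4)
  expect_equal(fm$bhb_max_ap, 0.5)
  expect_equal(fm$bhb_t0, 0.5)
  expect_equal(fm$bhb_d10, 0.7)
  expect_equal(fm$bhb_rise_t0_d10, 0.2)              # increase partum -> t1
  expect_equal(fm$bhb_rise_base_d10, 0.7 - 0.4)      # baseline -> t1
  expect_equal(fm$bhb_d5, 0.5 + 0.5 * 0.2)           # interpolated day 5

  # no ante-partum samples: (I)/(II) missing, not zero
  tab2 <- toy_table("b", day = c(0, 10), bhb = c(0.5, 0.7))
  fm2 <- extract_features(tab2, manual_labels("b", FALSE),
                          biomarkers = "bhb", parity_strata = FALSE)
  expect_true(is.na(fm2$bhb_median_ap))
  expect_true(is.na(fm2$bhb_max_ap))
})

test_that("feature extraction is deterministic and row-per-cow", {
  h <- simulate_herd(sim_config(n_cows = 5, seed = 77))
  lab <- label_cows(h$observations)
  fm1 <- extract_features(h$observations, lab)
  fm2 <- extract_features(h$observations, lab)
  expect_identical(fm1, fm2)
  expect_equal(nrow(fm1), 5)
})

test_that("parity strata carry values only for matching cows", {
  h <- simulate_herd(sim_config(n_cows = 30, seed = 13))
  lab <- label_cows(h$observations)
  fm <- extract_features(h$observations, lab, biomarkers = "bhb")
  primi <- h$truth$parity[match(fm$cow_id, h$truth$cow_id)] == "primiparous"
  expect_true(all(is.na(fm$bhb_t0_primiparous[!primi])))
  expect_equal(fm$bhb_t0_primiparous[primi], fm$bhb_t0[primi])
})

test_that("AUC equals the Mann-Whitney pair-count oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  toy <- list(scores = c(0.2, 0.4, 0.3, 0.8, 0.5),
              labels = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(roc_auc(toy$scores, toy$labels)$auc,
               mw_auc(toy$scores, toy$labels))
  # property: 100 random toy sets with heavy ties
  for (s in 1:100) {
    set.seed(3000 + s)
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, mw_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve satisfies its structural invariants", {
  set.seed(5)
  roc <- roc_auc(rnorm(30), rep(c(TRUE, FALSE), 15))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]),
               c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(roc$auc >= 0 && roc$auc <= 1)
  expect_error(roc_auc(rnorm(5), rep(TRUE, 5)), "positive and one negative")
  # missing scores are dropped and counted
  roc2 <- roc_auc(c(NA, 1, 2, 3), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(roc2$n_dropped, 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cost-weighted cut-point equals exhaustive search", {
  # perfectly separated classes
  roc <- roc_auc(c(1, 2, 3, 11, 12, 13),
                 c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  cp <- optimal_cutpoint(roc, prevalence = 0.5)
  expect_equal(cp$se, 1)
  expect_equal(cp$sp, 1)
  expect_equal(cp$cutoff, 7)  # midpoint between the classes

  # 8-point toy vs brute force at cfn = 4
  scores <- c(0.2, 0.3, 0.4, 0.45, 0.5, 0.6, 0.7, 0.9)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  roc <- roc_auc(scores, labels)
  cp <- optimal_cutpoint(roc, prevalence = 0.5, cfn = 4)
  bf <- brute_cutpoint(scores, labels, prevalence = 0.5, cfn = 4)
  expect_equal(cp$cutoff, bf$cutoff)
  expect_equal(cp$youden, bf$J)

  # classical Youden reduction: cfn = cfp = 1, p = 0.5
  cp1 <- optimal_cutpoint(roc, prevalence = 0.5, cfn = 1, cfp = 1)
  bf1 <- brute_cutpoint(scores, labels, prevalence = 0.5, cfn = 1, cfp = 1)
  expect_equal(cp1$cutoff, bf1$cutoff)
  expect_equal(cp1$youden, cp1$se + cp1$sp - 1)
})

test_that("raising the false-negative cost never raises the cutoff", {
  for (s in 1:40) {
    set.seed(4000 + s)
    n <- sample(8:30, 1)
    scores <- round(stats::runif(n), 2)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- roc_auc(scores, labels)
    cuts <- vapply(c(1, 2, 4, 8),
                   function(cfn) optimal_cutpoint(roc, prevalence = 0.4,
                                                  cfn = cfn)$cutoff,
                   numeric(1))
    # pairwise comparison (diff() is NaN between two infinite cutoffs)
    expect_true(all(cuts[-1] <= cuts[-length(cuts)]))
  }
})

test_that("confusion metrics reproduce hand-checked ratios with CIs", {
  m <- confusion_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(m$estimate, rep(1, 4))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")

  # CI contains the point estimate; width shrinks when counts x10
  m1 <- confusion_metrics(47, 12, 4, 36)
  m10 <- confusion_metrics(470, 120, 40, 360)
  expect_true(all(m1$lower <= m1$estimate & m1$estimate <= m1$upper))
  expect_true(all(m10$upper - m10$lower < m1$upper - m1$lower))
  expect_equal(m1$estimate, m10$estimate)

  # Clopper-Pearson endpoints against binom.test
  bt <- stats::binom.test(47, 51)$conf.int
  expect_equal(unlist(m1["se", c("lower", "upper")], use.names = FALSE),
               as.numeric(bt), tolerance = 1e-12)

  # zero denominator -> missing metric, not an error
  m0 <- confusion_metrics(0, 0, 5, 5)
  expect_true(is.na(m0["ppv", "estimate"]))
})

test_that("classifier ranking orders features by AUC with stable ties", {
  # herd separated only through post-partum BHB
  curves <- shifted_curves(0)
  curves$bhb$case <- curves$bhb$control
  pp_anchor <- c(0.5, 0.5, 0.52, 0.6, 0.9, 0.9, 0.9, 0.85, 0.8)
  curves$bhb$case <- curve_from_points(c(-27, -14, -7, 0, 7, 14, 30, 50, 80),
                                       log(pp_anchor))
  h <- simulate_herd(sim_config(n_cows = 120, group_curves = curves,
                                seed = 61))
  fm <- extract_features(h$observations, labels_from_truth(h),
                         parity_strata = FALSE)
  rk <- rank_classifiers(fm)
  top <- rk$feature[1]
  expect_match(top, "^bhb")
  expect_false(grepl("_ap$|_t0$", top))  # a post-partum BHB feature wins
  expect_true(all(diff(rk$auc) <= 1e-12))

  # single feature
  rk1 <- rank_classifiers(fm[, c("cow_id", "case", "bhb_d10")])
  expect_equal(nrow(rk1), 1)
})

test_that("a label-independent feature has null AUC on average", {
  h <- simulate_herd(sim_config(n_cows = 99, seed = 3))
  lab <- label_cows(h$observations)
  aucs <- vapply(1:200, function(s) {
    set.seed(6000 + s)
    roc_auc(stats::rnorm(nrow(lab)), lab$case)$auc
  }, numeric(1))
  mc_se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 2 * mc_se)
})

test_that("post-partum BHB separation yields AUC above 0.9 at a 0.5 log gap", {
  h <- simulate_herd(sim_config(n_cows = 200,
                                group_curves = shifted_curves(0.5),
                                seed = 11))
  lab <- label_cows(h$observations, 0.8)
  fm <- extract_features(h$observations, lab, biomarkers = "bhb",
                         parity_strata = FALSE)
  expect_gt(roc_auc(fm$bhb_d10, fm$case)$auc, 0.9)
})
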