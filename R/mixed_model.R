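FIT_RANGE <- c(-27, 80)

# Assemble the model frame for one biomarker: log response, case
# indicator, cow factor and the spline design columns, restricted to the
# fitted window.
build_model_frame <- function(table, biomarker, labels, spec,
                              range = FIT_RANGE) {
  table <- validate_observations(table)
  stopifnot(biomarker %in% BIOMARKERS, inherits(labels, "case_labels"))
  idx <- match(table$cow_id, labels$cow_id)
  if (anyNA(idx)) {
    stop("labels do not cover cow(s): ",
         paste(unique(table$cow_id[is.na(idx)]), collapse = ", "))
  }
  keep <- table$day >= range[1] & table$day <= range[2] &
    !is.na(table[[biomarker]])
  df <- data.frame(cow = factor(table$cow_id[keep]),
                   day = table$day[keep],
                   case = as.numeric(labels$case[idx][keep]),
                   y = log(table[[biomarker]][keep]))
  B <- natural_cubic_basis(df$day, spec)
  cbind(df, as.data.frame(B))
}

stage_formula <- function(stage, n_basis) {
  ns_terms <- paste(paste0("ns", seq_len(n_basis)), collapse = " + ")
  fixed <- switch(as.character(stage),
    "1" = sprintf("y ~ %s", ns_terms),
    "2" = ,
    "3" = sprintf("y ~ (%s) * case", ns_terms),
    stop("stage must be 1, 2 or 3"))
  random <- switch(as.character(stage),
    "1" = ,
    "2" = "(1 | cow)",
    "3" = "(1 | cow) + (0 + case | cow)")
  stats::as.formula(paste(fixed, "+", random))
}

#' Fit one stage of the mixed-effects spline profile model
#'
#' The profile model is built in three nested stages, all fitted by
#' maximum likelihood (not REML, so likelihood-ratio tests on the fixed
#' effects are valid) on the natural-log biomarker values restricted to
#' the window 27 days ante partum to 80 days post partum; repeated
#' measurements within a cow are correlated through the random effects.
#'
#' * stage 1: spline fixed effects + per-cow random intercept;
#' * stage 2: adds the case group as a fixed effect on the intercept and
#'   on every spline coefficient (group x spline interaction);
#' * stage 3: additionally a per-cow random case-shift (a scalar random
#'   effect multiplying the case indicator).
#'
#' If the fixed design interpolates the data exactly (a noise-free
#' herd), the marginal likelihood is unbounded as the residual variance
#' tends to zero; this degenerate limit is detected and the exact
#' ordinary-least-squares fixed effects are returned with zero variance
#' components, `loglik = Inf` and `degenerate = TRUE`.
#'
#' @param table an `observation_table`.
#' @param biomarker one of `"bhb"`, `"nefa"`, `"tbil"`, `"ast"`.
#' @param labels a `case_labels` data frame from [label_cows()].
#' @param spec a [spline_spec()].
#' @param stage model stage, 1, 2 or 3.
#' @return An object of class `"profile_fit"`: `stage`, `biomarker`,
#'   `spec`, `beta` (named fixed effects, log scale), `varcomp` (named
#'   variances: `var_intercept`, `var_case_shift` (stage 3), `var_resid`),
#'   `loglik`, `aic`, `n_params`, `n_obs`, `converged`, `degenerate`,
#'   and the underlying `lme4` fit as `fit` (`NULL` when degenerate).
#' @export
fit_stage <- function(table, biomarker, labels, spec = spline_spec(),
                      stage = 2) {
  stage <- as.integer(stage)
  df <- build_model_frame(table, biomarker, labels, spec)
  if (nrow(df) == 0) stop("no observations in the fitted window")
  form <- stage_formula(stage, spec$n_basis)
  fixed_form <- lme4::nobars(form)

  # degenerate (exact-interpolation) limit: residual-free OLS fit
  ols <- stats::lm(fixed_form, data = df)
  if (stats::sd(df$y) > 0 &&
      stats::sd(stats::resid(ols)) < 1e-8 * max(1, stats::sd(df$y))) {
    beta <- stats::coef(ols)
    vc <- c(var_intercept = 0,
            if (stage == 3) c(var_case_shift = 0),
            var_resid = 0)
    out <- list(stage = stage, biomarker = biomarker, spec = spec,
                beta = beta, varcomp = vc, loglik = Inf, aic = -Inf,
                n_params = length(beta) + length(vc), n_obs = nrow(df),
                converged = TRUE, degenerate = TRUE, fit = NULL,
                data = df)
    class(out) <- "profile_fit"
    return(out)
  }

  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore"))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 &&
    (is.null(msgs) || !any(grepl("failed to converge", msgs)))
  ll <- logLik(fit)
  vc_raw <- lme4::VarCorr(fit)
  vc <- c(var_intercept = unname(vc_raw$cow[1, 1]),
          if (stage == 3) c(var_case_shift = unname(vc_raw$cow.1[1, 1])),
          var_resid = sigma(fit)^2)
  n_params <- attr(ll, "df")
  out <- list(stage = stage, biomarker = biomarker, spec = spec,
              beta = lme4::fixef(fit), varcomp = vc,
              loglik = as.numeric(ll),
              aic = -2 * as.numeric(ll) + 2 * n_params,
              n_params = n_params, n_obs = nrow(df),
              converged = converged, degenerate = FALSE, fit = fit,
              data = df)
  class(out) <- "profile_fit"
  out
}

print.profile_fit <- function(x, ...) {
  cat("Mixed-effects spline profile fit (stage ", x$stage, ", ",
      x$biomarker, ", ML)\n", sep = "")
  cat("  n obs: ", x$n_obs, "; logLik: ", format(x$loglik),
      "; AIC: ", format(x$aic), "; params: ", x$n_params, "\n", sep = "")
  cat("  variance components: ",
      paste(names(x$varcomp), signif(x$varcomp, 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  if (x$degenerate) cat("  NOTE: degenerate (noise-free) exact fit\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

lrt_pair <- function(big, small, label) {
  if (big$n_obs != small$n_obs) {
    stop("fits are not on the same observations (", label, ")")
  }
  chi2 <- 2 * (big$loglik - small$loglik)
  df <- big$n_params - small$n_params
  if (df < 1) stop("models are not nested (", label, ")")
  data.frame(comparison = label, chi2 = chi2, df = df,
             p = pchisq(chi2, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio comparison of the three model stages
#'
#' One-way ANOVA-style comparison of the nested maximum-likelihood fits:
#' for each pair, \eqn{\chi^2 = 2(\ell_{big} - \ell_{small})} with
#' degrees of freedom equal to the parameter-count difference, referred
#' to the \eqn{\chi^2} distribution.  The naive \eqn{\chi^2} reference is
#' used for the stage-3 variance component too (anti-conservative at the
#' boundary, as in standard `anova` output).
#'
#' @param fit1,fit2,fit3 `profile_fit` objects for stages 1, 2, 3 on the
#'   same data.
#' @return Data frame with rows `stage2_vs_1`, `stage3_vs_2`,
#'   `stage3_vs_1` and columns `chi2`, `df`, `p`.
#' @export
compare_stages <- function(fit1, fit2, fit3 = NULL) {
  stopifnot(inherits(fit1, "profile_fit"), inherits(fit2, "profile_fit"))
  out <- lrt_pair(fit2, fit1, "stage2_vs_1")
  if (!is.null(fit3)) {
    stopifnot(inherits(fit3, "profile_fit"))
    out <- rbind(out,
                 lrt_pair(fit3, fit2, "stage3_vs_2"),
                 lrt_pair(fit3, fit1, "stage3_vs_1"))
  }
  rownames(out) <- NULL
  out
}

#' Population-level fitted biomarker curve
#'
#' Evaluates the fitted fixed-effect curve on the natural (exponentiated)
#' scale for the requested group.  Stage-1 fits have no group term, so
#' both group arguments give the same curve.  Days outside the fitted
#' window are refused.
#'
#' @param fit a `profile_fit`.
#' @param days days relative to parturition, within \[-27, 80\].
#' @param group `"case"` or `"control"`.
#' @return Numeric vector of fitted biomarker values (natural scale).
#' @export
predict_curve <- function(fit, days, group = c("control", "case")) {
  stopifnot(inherits(fit, "profile_fit"))
  group <- match.arg(group)
  if (any(days < FIT_RANGE[1] | days > FIT_RANGE[2])) {
    stop("days outside the fitted window [", FIT_RANGE[1], ", ",
         FIT_RANGE[2], "]: refusing to extrapolate")
  }
  B <- natural_cubic_basis(days, fit$spec)
  X <- cbind(`(Intercept)` = 1, B)
  if (fit$stage >= 2) {
    case <- as.numeric(group == "case")
    X <- cbind(X, case = case, B * case)
    colnames(X) <- c("(Intercept)", colnames(B), "case",
                     paste0(colnames(B), ":case"))
  }
  beta <- fit$beta[colnames(X)]
  if (anyNA(beta)) stop("fit is missing coefficients for prediction")
  exp(as.vector(X %*% beta))
}
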