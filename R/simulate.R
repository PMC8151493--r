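#' Solve spline-curve coefficients through anchor points
#'
#' Utility for specifying a group mean curve on the log scale: given
#' `n_basis + 1` anchor days and the log-scale values the curve should
#' take there, solves for the intercept-plus-basis coefficients of the
#' unique natural cubic spline through them.
#'
#' @param days anchor days (length `spec$n_basis + 1`, distinct).
#' @param log_values log-scale curve values at the anchor days.
#' @param spec a [spline_spec()].
#' @return Numeric coefficient vector of length `n_basis + 1`
#'   (intercept first).
#' @export
curve_from_points <- function(days, log_values, spec = spline_spec()) {
  stopifnot(length(days) == spec$n_basis + 1,
            length(log_values) == length(days))
  X <- cbind(1, natural_cubic_basis(days, spec))
  as.vector(solve(X, log_values))
}

#' Evaluate a group mean curve (log scale)
#'
#' @param coefs coefficient vector from [curve_from_points()] (intercept
#'   first).
#' @param days days at which to evaluate.
#' @param spec the [spline_spec()] the coefficients refer to.
#' @return Log-scale curve values.
#' @export
eval_curve <- function(coefs, days, spec = spline_spec()) {
  as.vector(cbind(1, natural_cubic_basis(days, spec)) %*% coefs)
}

# Anchor days and log-scale anchor values for the default group mean
# curves.  Shapes mirror the qualitative transition-period profiles:
# BHB peaks at partum and again around day 30 in cases; NEFA a single
# partum peak declining; tBIL and AST a partum peak.  Units: BHB and
# NEFA mmol/L, tBIL umol/L, AST U/L.
CURVE_ANCHOR_DAYS <- c(-27, -14, -7, 0, 7, 14, 30, 50, 80)

DEFAULT_CURVE_VALUES <- list(
  bhb = list(
    control = c(0.50, 0.50, 0.52, 0.60, 0.58, 0.55, 0.52, 0.50, 0.50),
    case    = c(0.55, 0.58, 0.65, 0.95, 0.85, 0.80, 0.95, 0.75, 0.65)),
  nefa = list(
    control = c(0.20, 0.25, 0.30, 0.55, 0.45, 0.35, 0.30, 0.25, 0.20),
    case    = c(0.25, 0.30, 0.45, 0.90, 0.70, 0.55, 0.40, 0.30, 0.25)),
  tbil = list(
    control = c(3.0, 3.0, 3.5, 6.0, 5.0, 4.0, 3.5, 3.0, 3.0),
    case    = c(3.5, 4.0, 5.0, 9.0, 7.0, 5.5, 4.5, 3.5, 3.5)),
  ast = list(
    control = c(70, 70, 75, 95, 90, 80, 75, 80, 85),
    case    = c(75, 80, 90, 130, 120, 100, 90, 95, 100)))

#' Default group mean curves on the standard knot layout
#'
#' For the standard 8-function basis the curves interpolate the default
#' anchor values; for a smaller basis the anchor profile is re-sampled at
#' the spec's knots (boundary + interior) so the same qualitative shapes
#' carry over.
#'
#' @param spec the [spline_spec()] to express the curves on.
#' @return Named list (per biomarker) of lists with `control` and `case`
#'   coefficient vectors (log scale, intercept first).
#' @export
default_group_curves <- function(spec = spline_spec()) {
  anchors <- if (spec$n_basis == length(CURVE_ANCHOR_DAYS) - 1) {
    CURVE_ANCHOR_DAYS
  } else {
    c(spec$boundary_knots[1], spec$interior_knots, spec$boundary_knots[2])
  }
  lapply(DEFAULT_CURVE_VALUES, function(gv) {
    at <- function(v) {
      approx(CURVE_ANCHOR_DAYS, log(v), xout = anchors, rule = 2)$y
    }
    list(control = curve_from_points(anchors, at(gv$control), spec),
         case    = curve_from_points(anchors, at(gv$case), spec))
  })
}

#' Simulation configuration for a synthetic transition-cow herd
#'
#' Encodes the study conditions the generator emulates: weekly visits for
#' 14 consecutive weeks starting two weeks before the expected day of
#' parturition, a two-group herd (hyperketonemic-type vs control-type,
#' case probability ~0.5), group-specific log-scale mean curves on the
#' standard spline layout, a per-cow random intercept, a per-cow random
#' case-shift, and multiplicative log-normal residual noise.  Actual
#' partum day is jittered around the expected day (rounded normal, SD
#' 3 d) so visit days relative to actual partum vary across cows.
#'
#' @param n_cows number of cows.
#' @param p_case probability a cow is of hyperketonemic type.
#' @param visits number of weekly visits per cow.
#' @param first_visit_offset day of the first visit relative to expected
#'   partum (negative = ante partum).
#' @param visit_spacing days between visits.
#' @param partum_jitter_sd SD (days) of the rounded-normal jitter of the
#'   actual partum day around the expected one.
#' @param group_curves per-biomarker `list(control=, case=)` log-scale
#'   coefficient vectors on `spec` (intercept first); defaults to
#'   [default_group_curves()].
#' @param sigma_intercept SD of the per-cow random intercept (log scale).
#' @param sigma_group_slope SD of the per-cow random case-shift
#'   (log scale, case-type cows only).
#' @param sigma_resid residual SD (log scale).
#' @param p_dropout per-visit missingness probability (whole visit row).
#' @param p_primiparous probability a cow is primiparous.
#' @param spec the [spline_spec()] the curves are expressed on.
#' @param seed integer RNG seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cows = 99, p_case = 0.5, visits = 14,
                       first_visit_offset = -14, visit_spacing = 7,
                       partum_jitter_sd = 3, group_curves = NULL,
                       sigma_intercept = 0.25, sigma_group_slope = 0.15,
                       sigma_resid = 0.20, p_dropout = 0,
                       p_primiparous = 0.27, spec = spline_spec(),
                       seed = 1L) {
  defaults <- default_group_curves(spec)
  group_curves <- if (is.null(group_curves)) {
    defaults
  } else {
    utils::modifyList(defaults, group_curves)  # fill missing biomarkers
  }
  cfg <- list(n_cows = as.integer(n_cows), p_case = p_case,
              visits = as.integer(visits),
              first_visit_offset = first_visit_offset,
              visit_spacing = visit_spacing,
              partum_jitter_sd = partum_jitter_sd,
              group_curves = group_curves,
              sigma_intercept = sigma_intercept,
              sigma_group_slope = sigma_group_slope,
              sigma_resid = sigma_resid,
              p_dropout = p_dropout,
              p_primiparous = p_primiparous,
              spec = spec, seed = as.integer(seed))
  with(cfg, stopifnot(
    n_cows >= 1, visits >= 2, p_case > 0, p_case < 1,
    sigma_intercept >= 0, sigma_group_slope >= 0, sigma_resid >= 0,
    partum_jitter_sd >= 0, p_dropout >= 0, p_dropout < 1))
  stopifnot(all(vapply(cfg$group_curves,
                       function(g) all(c("control", "case") %in% names(g)),
                       logical(1))))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a synthetic transition-cow herd
#'
#' Draws a herd under the configured two-group mixed-effects spline
#' structure.  For cow \eqn{i} at day \eqn{t} (relative to its actual,
#' jittered partum day) the log biomarker value is
#' \deqn{\log y_{it} = c_{g(i)}(t) + b_{0i} + u_i\,1[case_i] +
#'   \varepsilon_{it},}
#' with group mean curve \eqn{c_g}, random intercept
#' \eqn{b_{0i} \sim N(0, \sigma_{int}^2)}, random case-shift
#' \eqn{u_i \sim N(0, \sigma_{slope}^2)} and residual
#' \eqn{\varepsilon \sim N(0, \sigma_{res}^2)}, all drawn independently
#' per biomarker.  Values are exported on the natural scale
#' (exponentiated), so they are strictly positive.  Deterministic for a
#' fixed seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `"herd_sim"`: `observations` (an
#'   `observation_table`), `truth` (per cow: `cow_id`, `type`
#'   (`"case"`/`"control"`), `partum_jitter`, and per-biomarker random
#'   effects `b0_<bm>`, `u_<bm>`), `curves` (the generating coefficient
#'   lists) and `config`.
#' @export
simulate_herd <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cows
  ids <- sprintf("cow%03d", seq_len(n))
  type <- ifelse(rbinom(n, 1, config$p_case) == 1, "case", "control")
  parity <- ifelse(rbinom(n, 1, config$p_primiparous) == 1,
                   "primiparous", "multiparous")
  jitter <- round(rnorm(n, 0, config$partum_jitter_sd))
  sched <- config$first_visit_offset +
    config$visit_spacing * (seq_len(config$visits) - 1)
  bms <- names(config$group_curves)
  truth <- data.frame(cow_id = ids, type = type, parity = parity,
                      partum_jitter = jitter, stringsAsFactors = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    days <- as.integer(sched - jitter[i])
    m <- length(days)
    rec <- data.frame(cow_id = ids[i], parity = parity[i], day = days,
                      stringsAsFactors = FALSE)
    for (bm in bms) {
      b0 <- rnorm(1, 0, config$sigma_intercept)
      u <- rnorm(1, 0, config$sigma_group_slope)
      truth[i, paste0("b0_", bm)] <- b0
      truth[i, paste0("u_", bm)] <- u
      coefs <- config$group_curves[[bm]][[type[i]]]
      mu <- eval_curve(coefs, days, config$spec)
      shift <- if (type[i] == "case") u else 0
      rec[[bm]] <- exp(mu + b0 + shift + rnorm(m, 0, config$sigma_resid))
    }
    rec$post_treatment <- FALSE
    if (config$p_dropout > 0) {
      keep <- rbinom(m, 1, 1 - config$p_dropout) == 1
      rec <- rec[keep, , drop = FALSE]
    }
    rows[[i]] <- rec
  }
  obs <- validate_observations(do.call(rbind, rows))
  structure(list(observations = obs, truth = truth,
                 curves = config$group_curves, config = config),
            class = "herd_sim")
}

print.herd_sim <- function(x, ...) {
  cat("Synthetic herd: ", x$config$n_cows, " cows, ",
      nrow(x$observations), " observations, ",
      sum(x$truth$type == "case"), " case-type cows\n", sep = "")
  invisible(x)
}

#' Ground-truth case labels of a simulated herd
#'
#' Builds a `case_labels` object from the simulated cow types rather
#' than from observed BHB exceedances.  Useful for calibration studies
#' where labels must be independent of the observed values (observed
#' labelling via [label_cows()] selects on the noise).
#'
#' @param herd a `"herd_sim"` from [simulate_herd()].
#' @return A `case_labels` data frame (onset days are `NA`: truth types
#'   have no observed onset).
#' @export
labels_from_truth <- function(herd) {
  stopifnot(inherits(herd, "herd_sim"))
  out <- data.frame(cow_id = herd$truth$cow_id,
                    case = herd$truth$type == "case",
                    onset_day = NA_integer_, stringsAsFactors = FALSE)
  attr(out, "threshold") <- NA_real_
  class(out) <- c("case_labels", class(out))
  out
}
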