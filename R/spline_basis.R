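# Knots are dropped in this fixed priority order when a smaller basis is
# requested, keeping the partum knot (day 0) longest.
KNOT_DROP_ORDER <- c(-20, 50, 14, 25, -7, 7)

#' Natural cubic spline specification for transition-period profiles
#'
#' The default layout places interior knots where structural change in the
#' metabolic profile is expected — 20 and 7 days ante partum, parturition,
#' and 7, 14, 25 and 50 days post partum — with boundary knots at the ends
#' of the fitted window (27 days a.p. to 80 days p.p.).  With \eqn{K}
#' interior knots a natural cubic spline (linear beyond the boundary knots)
#' has \eqn{K + 1} basis functions excluding the intercept, so the default
#' has `n_basis = 8`.
#'
#' @param interior_knots strictly increasing interior knot days.
#' @param boundary_knots length-2 boundary knot days, strictly enclosing
#'   the interior knots.
#' @return An object of class `"spline_spec"` with elements
#'   `interior_knots`, `boundary_knots`, `n_basis`.
#' @export
spline_spec <- function(interior_knots = c(-20, -7, 0, 7, 14, 25, 50),
                        boundary_knots = c(-27, 80)) {
  stopifnot(length(boundary_knots) == 2,
            boundary_knots[1] < boundary_knots[2])
  if (is.unsorted(interior_knots, strictly = TRUE)) {
    stop("interior knots must be strictly increasing")
  }
  if (any(interior_knots <= boundary_knots[1] |
          interior_knots >= boundary_knots[2])) {
    stop("interior knots must lie strictly inside the boundary knots")
  }
  structure(list(interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 n_basis = length(interior_knots) + 1L),
            class = "spline_spec")
}

print.spline_spec <- function(x, ...) {
  cat("Natural cubic spline spec: ", x$n_basis, " basis functions\n",
      "  interior knots: ", paste(x$interior_knots, collapse = ", "), "\n",
      "  boundary knots: ", paste(x$boundary_knots, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Reduced knot layout for a smaller basis
#'
#' Sub-family rule used by AIC-based basis-size selection: for
#' `n_basis < 8` the default interior knots are thinned by dropping knots
#' in the fixed priority order (-20, 50, 14, 25, -7, 7), so the partum
#' knot (day 0) is kept longest.
#'
#' @param n_basis requested number of basis functions, between 2 and 8.
#' @param spec the full `spline_spec` to thin (default layout).
#' @return A `spline_spec` with `n_basis` basis functions.
#' @export
thin_spline_spec <- function(n_basis, spec = spline_spec()) {
  stopifnot(n_basis >= 2, n_basis <= spec$n_basis)
  drop_n <- spec$n_basis - n_basis
  if (drop_n == 0) return(spec)
  drop <- KNOT_DROP_ORDER[seq_len(drop_n)]
  keep <- setdiff(spec$interior_knots, drop)
  spline_spec(keep, spec$boundary_knots)
}

#' Evaluate the natural cubic spline design matrix
#'
#' Returns the design matrix (rows = days, columns = `n_basis`) of the
#' natural cubic spline family on the spec's knots: piecewise cubic,
#' twice continuously differentiable at the knots, and linear at and
#' beyond the boundary knots.  The intercept is not included; full column
#' rank requires at least `n_basis` distinct days spanning the knots
#' (a warning is attached otherwise).
#'
#' @param days numeric vector of days relative to parturition.
#' @param spec a [spline_spec()].
#' @return Numeric matrix `length(days) x n_basis` with columns
#'   `ns1 ... ns<n_basis>`.
#' @export
natural_cubic_basis <- function(days, spec = spline_spec()) {
  stopifnot(inherits(spec, "spline_spec"), is.numeric(days))
  B <- splines::ns(days, knots = spec$interior_knots,
                   Boundary.knots = spec$boundary_knots)
  B <- unclass(B)[, , drop = FALSE]
  attributes(B) <- attributes(B)[c("dim")]
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  if (length(unique(days)) < spec$n_basis) {
    attr(B, "rank_warning") <-
      "fewer distinct days than basis functions: design is rank-deficient"
  }
  B
}

#' Choose the basis size by AIC over stage-2 mixed-model fits
#'
#' Fits the stage-2 profile model (spline + group x spline, random cow
#' intercept) for each candidate basis size, using the thinned knot
#' layouts of [thin_spline_spec()], and returns the AIC-minimising size.
#' Ties are broken toward the smaller basis; candidates whose fit fails
#' or does not converge are flagged and excluded from the argmin.
#'
#' @param table an `observation_table`.
#' @param biomarker one of `"bhb"`, `"nefa"`, `"tbil"`, `"ast"`.
#' @param candidates integer vector of basis sizes within \[2, 8\].
#' @param labels a `case_labels` data frame from [label_cows()].
#' @param spec the full spline layout to thin (default layout).
#' @return A list: `n_basis` (chosen size), `aic` (named vector, `NA`
#'   where a fit failed), `fits` (the per-candidate `profile_fit`
#'   objects or `NULL`).
#' @export
select_n_basis <- function(table, biomarker, candidates, labels,
                           spec = spline_spec()) {
  stopifnot(all(candidates >= 2), all(candidates <= spec$n_basis))
  candidates <- sort(unique(as.integer(candidates)))
  aic <- setNames(rep(NA_real_, length(candidates)), candidates)
  fits <- setNames(vector("list", length(candidates)), candidates)
  for (i in seq_along(candidates)) {
    k <- candidates[i]
    fit <- tryCatch(
      fit_stage(table, biomarker, labels, thin_spline_spec(k, spec),
                stage = 2),
      error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) {
      aic[i] <- fit$aic
      fits[[i]] <- fit
    }
  }
  if (all(is.na(aic))) stop("no candidate basis size produced a converged fit")
  best <- candidates[which.min(aic)]  # which.min takes the first (smallest) tie
  list(n_basis = best, aic = aic, fits = fits)
}
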