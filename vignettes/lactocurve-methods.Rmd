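---
title: "Modelling transition-period biomarker profiles and selecting a prognostic ketosis cut-point"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transition-period biomarker profiles and selecting a prognostic ketosis cut-point}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactocurve)
```

## The scientific problem

Around calving, dairy cows mobilise body fat to cover the energy deficit of
early lactation.  When lipolysis outruns hepatic capacity, ketone bodies
accumulate: hyperketonemia (serum beta-hydroxybutyrate, BHB, above
0.8 mmol/L in any weekly sample) and, at BHB above 1.2 mmol/L, subclinical
ketosis (SCK).  `lactocurve` implements a complete longitudinal analysis of
a four-marker serum panel — BHB and non-esterified fatty acids (NEFA) in
mmol/L, total bilirubin (tBIL) in µmol/L, and aspartate aminotransferase
(AST) in U/L — sampled weekly for 14 consecutive weeks starting two weeks
before the expected day of parturition, together with the prognostic
question that motivates such surveillance: can a single early measurement,
at the right day and the right threshold, flag the cows that will become
hyperketonemic?

The pipeline has five stages, each an exported module:

1. **Cohort and labels** — CSV ingestion, the "more than ten visits" cohort
   rule (`filter_min_observations`, default 11), strict-exceedance case
   labelling with onset days (`label_cows`), and a Shapiro–Wilk screen that
   motivates the log scale (`assess_normality`).
2. **Onset incidence** — onset ECDFs over eventual cases (`onset_ecdf`),
   incidence proportions, the maximum ante-partum sampling gap that fixes
   the smallest usable classification interval, and the fraction of cases a
   single-day scheme would miss (`undetected_fraction`).
3. **Profile model** — a three-stage mixed-effects natural cubic spline
   model of the log biomarker course (`fit_stage`, `compare_stages`,
   `predict_curve`).
4. **Interval tests** — descriptive per-interval Welch tests on 6-day
   tiles of the window from 15 days ante partum to 62 days post partum
   (`interval_group_tests`).
5. **Classifiers** — per-cow prognostic features (`extract_features`),
   ROC/AUC ranking (`roc_auc`, `rank_classifiers`), a cost-weighted Youden
   cut-point (`optimal_cutpoint`), confusion metrics with exact binomial
   intervals (`confusion_metrics`), and a CART cross-check (`fit_cart`).

A synthetic-herd generator (`simulate_herd`) reproduces the statistical
structure the model assumes, so the whole pipeline is testable end to end
without animal data.

## The profile model

For one biomarker, let $y_{it}$ be the value for cow $i$ at day $t$
relative to its actual calving day (negative = ante partum).  All
modelling is on $\log y_{it}$: the marker panel is strictly positive and
right-skewed, and the Shapiro–Wilk screen consistently prefers the log
scale.  The mean course is a natural cubic spline $B(t)\beta$ with eight
basis functions: seven interior knots at days $-20, -7, 0, 7, 14, 25, 50$
— placed where structural change is expected (dry-off adaptation, calving,
early-lactation peak) — and boundary knots at the ends of the fitted
window, $-27$ to $80$ days.  A natural spline is linear beyond its
boundary knots, which keeps the curve sane where data are sparse; with $K$
interior knots it contributes $K+1$ regression columns beyond the
intercept, hence $n = 8$.

The model is built in three nested stages, all by maximum likelihood so
that likelihood-ratio tests on fixed effects are valid:

* **Stage 1**: $\log y_{it} = B(t)\beta + b_{0i} + \varepsilon_{it}$, with
  a per-cow random intercept $b_{0i} \sim N(0, \sigma^2_{int})$ capturing
  the repeated-measures correlation.
* **Stage 2** adds the case group (hyperketonemic or SCK, per the chosen
  threshold) as a fixed effect on the intercept and on every spline
  coefficient: the two groups get separate mean curves (9 extra fixed
  parameters).
* **Stage 3** adds a per-cow *random case-shift* $u_i \sim N(0,
  \sigma^2_{shift})$ multiplying the case indicator, allowing case cows to
  sit at individually different heights around their group curve.

Stages are compared pairwise by $\chi^2 = 2\Delta\ell$ with degrees of
freedom from parameter counts.  Fitting is delegated to `lme4` behind the
`fit_stage` surface; the reported log-likelihood is verified in the test
suite against a direct evaluation of the marginal multivariate normal
density with the random effects integrated out analytically.

Three modelling choices were genuinely open and are worth recording:

* *The stage-3 random term.*  "A random group effect on the spline
  coefficients" could mean anything up to an unstructured $8 \times 8$
  covariance, which is hopelessly unidentifiable at herd scale (~50 case
  cows).  We use a scalar random case-shift, the smallest extension that
  preserves strict nesting for the ANOVA; a diagonal per-basis variant
  would be a natural extension but is not needed for any result here.
* *Degenerate likelihoods.*  On a noise-free herd the fixed design
  interpolates the data exactly and the marginal likelihood is unbounded
  as $\sigma^2_{res} \to 0$; generic optimisers stall near, but not at,
  the exact solution.  `fit_stage` detects this limit (OLS residual SD
  below $10^{-8}$ relative to the response scale) and returns the exact
  least-squares coefficients with zero variance components, flagged
  `degenerate`.  This is what makes exact-recovery tests meaningful.
* *Boundary p-values.*  The stage-3-vs-2 comparison tests a variance on
  the boundary of its parameter space; we keep the naive $\chi^2(1)$
  reference (as standard `anova` tables do) and document it as
  anti-conservative.

Basis-size selection (`select_n_basis`) refits stage 2 over candidate
basis sizes and picks the AIC minimum, ties toward the smaller model.
Sub-families thin the interior knots in a fixed priority order
($-20, 50, 14, 25, -7, 7$), keeping the partum knot longest, since partum
is where curvature is never negotiable.

## Interval tests

The protocol this package implements labels these tests "one-sample",
which is internally inconsistent for a two-group contrast.  The primary
implementation is
a Welch two-sample test on per-cow interval means (each cow contributes
one number per 6-day interval, so multiple visits within an interval do
not pseudo-replicate); a literal one-sample variant — case-cow means
tested against the control mean treated as a constant — is available via
`method = "one_sample"` but asserted nowhere.  P-values are deliberately
uncorrected (the tests are descriptive); Benjamini–Hochberg is available
behind a flag.

## Classifiers and the cost-weighted cut-point

Candidate features per cow and biomarker: ante-partum median (baseline)
and maximum, the value at partum ($t_0$), interpolated daily values on
post-partum days 1–10 (the $t_1$ grid, nearest-neighbour linear
interpolation, missing outside the observed range), rises from baseline
and from partum to each grid day, and parity (plus parity-stratified
copies of every feature, our reading of "concentration within different
lactation").  Rises are differences on the natural scale — the classifier
stage never log-transforms.

Each feature is scored by a ROC curve swept over the rule
"score $\ge$ cutoff $\Rightarrow$ positive".  The trapezoidal AUC equals
the Mann–Whitney pair-count estimator with half credit for ties; this
identity is enforced to $10^{-12}$ in the tests.  The operating point is
the generalised Youden index
$$J(c) = Se(c) + r\,Sp(c) - 1, \qquad
  r = \frac{(1-p)\,C_{FP}}{p\,C_{FN}},$$
with prevalence $p$ (defaulting to the sample prevalence) and
misclassification costs $C_{FN} = 4$, $C_{FP} = 1$: a missed ketosis case
(lost milk, follow-on disease) is costed at four needless
propylene-glycol supplementations.  Candidate cutoffs are midpoints
between adjacent distinct scores plus the two trivial rules; ties break
toward the lower cutoff, favouring sensitivity, consistently with
$C_{FN} > C_{FP}$.  With $C_{FN} = C_{FP}$ and $p = 0.5$ the criterion
reduces to the classical Youden index.  Confidence intervals on the
confusion metrics are Clopper–Pearson.

One caveat is mirrored deliberately: the day-10 BHB feature can include
the very sample that labels a cow as a case.  That leakage is part of the
surveillance design being evaluated; a strict prognostic variant would
restrict labels to onsets after day 10.

The CART cross-check uses `rpart` (Gini splits) with the surveillance
settings: a node needs at least 10 observations to be split — a node with
9 is never split — and cost-complexity pruning is selected by 5-fold
cross-validation with the 1-SE rule.  The root split is verified in the
tests against an exhaustive Gini search.

## What the synthetic herd emulates — and what it does not

`simulate_herd` draws, per cow: a type (case/control, default
$p = 0.5$, matching an observed hyperketonemia incidence near one half),
parity (27% primiparous), a calving-day jitter (rounded normal, SD 3 d)
applied to the weekly visit schedule (14 visits from day $-14$), and, per
biomarker, a random intercept, a random case-shift and i.i.d. log-normal
residual noise around group-specific log-scale mean curves:
$$\log y_{it} = c_{g(i)}(t) + b_{0i} + u_i\,1[\text{case}_i]
  + \varepsilon_{it}.$$
The generator is deliberately conjugate to the stage-3 model, so
parameter-recovery and calibration claims are well-posed.  Default
log-scale SDs are $\sigma_{int} = 0.25$, $\sigma_{shift} = 0.15$,
$\sigma_{res} = 0.20$ — between-cow and within-cow coefficients of
variation of roughly 15–25%, typical of serum metabolite panels.  The
default mean curves are anchored at interpretable values (e.g. control
BHB near 0.5–0.6 mmol/L with a mild partum bump; case BHB peaking near
0.95 mmol/L at partum and again around day 30; NEFA with a single partum
peak; tBIL and AST with partum peaks) and reproduce the qualitative
shapes of observed transition profiles; no values were read off published
figures.

The generator does **not** emulate: treatment effects (supplementation
after a positive herd test), parity-specific curves, serial correlation
beyond the shared random effects, assay error structure, or informative
dropout (missingness is uniform per visit and off by default).  Passing
tests therefore demonstrate internal correctness and statistical
calibration under the assumed structure, not agreement with any
particular real herd; quantities like incidence or the selected cut-point
will track the generator's curves, not a published cohort.

## Numerical choices and test design

* Problem sizes: parameter recovery uses 20 replicates of 200-cow herds
  ($\sigma_{int} = 0.3$, $\sigma_{res} = 0.2$) with estimates required to
  be unbiased within two Monte-Carlo standard errors; type-I calibration
  of the stage-2-vs-1 likelihood-ratio test uses 200 null replicates of
  60-cow herds (Kolmogorov–Smirnov uniformity of p-values) and power is
  checked on 20 replicates with a 0.5 log-unit group gap.  Calibration
  herds use ground-truth labels (`labels_from_truth`): labelling by
  observed exceedance selects on the noise and would bias the null.
* Noise-free recovery is exact to $10^{-6}$ via the degenerate-fit path.
* Curve comparisons, never coefficient comparisons: any basis spanning
  the same natural-spline space is equivalent, so tests compare fitted
  curves (to $10^{-6}$–$10^{-8}$) under invertible recombinations of the
  basis.
* Onset is the sample day of first exceedance — no interpolation — and
  the ECDF denominator is the number of eventual cases.
* The ante-partum gap uses strictly negative days; day 0 is partum.
* Ties: AUC uses half credit; cut-point ties resolve to the lower
  threshold; AIC ties resolve to the smaller basis.

## Known limitations

* The stage-3 random case-shift is one of several defensible readings of
  a random group effect "on the spline coefficients".
* The one-sample interval-test variant is a reconstruction; its exact
  original form is unrecoverable.
* Boundary LRTs (stage 3 vs 2) are anti-conservative under the naive
  $\chi^2$ reference.
* Feature (VII) ("concentration within different lactation") is
  interpreted as parity class plus parity-stratified feature copies.
* Published herd-level figures (incidence 52%, AUC 0.915, cut-off
  0.54 mmol/L) depend on an undeposited cohort; this package reproduces
  the *method* exactly and the published confusion-table arithmetic, and
  approaches the herd-level numbers only as closely as a synthetic herd
  can.
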