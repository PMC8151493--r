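# lactocurve

Longitudinal metabolic biomarker profiling and prognostic classification
of hyperketonemia in transition dairy cows.

## What this package is for

During the transition from dry-off into early lactation, dairy cows run a
negative energy balance; excessive fat mobilisation drives ketone bodies
up, and hyperketonemia (serum beta-hydroxybutyrate, BHB, above
0.8 mmol/L) or subclinical ketosis (BHB > 1.2 mmol/L) raises the risk of
displaced abomasum, uterine infection, mastitis and lost milk.
`lactocurve` is for veterinary epidemiologists and herd-health
researchers analysing weekly serum panels (BHB, NEFA in mmol/L, total
bilirubin in µmol/L, AST in U/L) across that window: it models the full
biomarker time course by group, quantifies when cases arise, and selects
a cost-aware early-warning threshold.

The statistical core:

* **Mixed-effects natural cubic spline profiles.** On the log scale,
  $\log y_{it} = B(t)\beta + \text{group terms} + b_{0i} +
  \varepsilon_{it}$, with $B(t)$ a natural cubic spline basis ($n = 8$
  basis functions; interior knots at days $-20, -7, 0, 7, 14, 25, 50$
  relative to calving; boundary knots at $-27$ and $80$), fitted by
  maximum likelihood in three nested stages (random intercept; + fixed
  group×spline effects; + a per-cow random case-shift) and compared by
  likelihood-ratio $\chi^2$ tests.
* **Onset incidence.** Case onset = first sample day with BHB above the
  threshold; the ECDF of onsets over eventual cases gives the fraction a
  single-day measuring scheme would miss.
* **Cost-weighted Youden cut-point.** Every candidate feature (ante-partum
  baseline/maximum, value at partum, interpolated days 1–10 post partum,
  rises, parity) is scored by ROC/AUC; the operating point maximises
  $J(c) = Se(c) + r\,Sp(c) - 1$ with $r = (1-p)C_{FP}/(pC_{FN})$ and
  $C_{FN} = 4$ (a missed ketosis case costs ~4 needless supplementations).
  A CART tree (`rpart`, min node 10, 5-fold CV pruning) cross-checks the
  single-feature ranking.
* **Synthetic herds.** `simulate_herd()` generates cohorts with the
  assumed structure (99 cows, 14 weekly visits from two weeks before
  expected calving, two-group log-scale mean curves, random effects,
  log-normal noise), so every stage is testable without animal data.

## Worked example

```r
library(lactocurve)

herd <- simulate_herd(sim_config(n_cows = 99, seed = 2026))
tab  <- filter_min_observations(herd$observations, min_obs = 11)
lab  <- label_cows(tab, threshold = 0.8)

round(100 * incidence_proportion(lab), 1)
#> 62.6
e <- onset_ecdf(tab, 0.8)
round(100 * undetected_fraction(e, 10), 1)   # % of cases missed by a day-10 test
#> 16.1
max_prepartum_gap(tab)                       # smallest usable test interval, days
#> 7

f1 <- fit_stage(tab, "bhb", lab, stage = 1)
f2 <- fit_stage(tab, "bhb", lab, stage = 2)
f3 <- fit_stage(tab, "bhb", lab, stage = 3)
compare_stages(f1, f2, f3)
#>    comparison      chi2 df            p
#> 1 stage2_vs_1 124.05556  9 1.971878e-22
#> 2 stage3_vs_2   6.90976  1 8.572650e-03
#> 3 stage3_vs_1 130.96532 10 2.968005e-23

fm  <- extract_features(tab, lab)
roc <- roc_auc(fm$bhb_d10, fm$case)
optimal_cutpoint(roc, cfn = 4, cfp = 1)
#> Cost-weighted Youden cut-point (CFN = 4, CFP = 1, p = 0.626)
#>   cutoff: 0.5198747 (score >= cutoff => positive); J = 0.0847
#>   counts: TP=62 FP=16 FN=0 TN=21
#>   se = 1.00 (0.94-1.00); sp = 0.57 (0.39-0.73); ppv = 0.79 (0.69-0.88); npv = 1.00 (0.84-1.00)
```

Reading the output: on this synthetic herd 62.6% of cows exceed
0.8 mmol/L at least once; a single day-10 test would still miss 16.1% of
eventual cases; the group effect on the BHB course is overwhelming
(stage 2 vs 1, $\chi^2(9) = 124$); and the cost-weighted cut-point on
day-10 BHB lands at 0.52 mmol/L — favouring sensitivity (Se = 1.00,
Sp = 0.57), as a 4:1 false-negative cost dictates.  The spline profiles
themselves are available via `predict_curve(f2, -20:80, "case")`.

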