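---
title: "PFS ratios under right censoring: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PFS ratios under right censoring: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfsratio)
```

## The problem

Metastatic neuroendocrine neoplasms (NEN) span indolent small-intestinal NET
that smolder for a decade and neuroendocrine carcinomas that progress in
months. This heterogeneity defeats naive between-patient comparisons of
progression-free survival (PFS): a 12-month PFS is unremarkable under a
somatostatin analog (SSA) in a G1 tumor and exceptional under second-line
chemotherapy in NEC. The PFS ratio — also called the growth modulation
index —

$$ R = \frac{\mathrm{PFS}_2}{\mathrm{PFS}_1} $$

sidesteps this by using each patient as their own control: PFS under the
subsequent therapy divided by PFS under the antecedent one. $R > 1$ means
the later line stabilized disease longer than the earlier one did, the
opposite of the usual expectation that successive lines perform worse. The
classical bar for an "unanticipated improvement" is $R \ge 1.33$; for
scatterplot segmentation we use high ($R > 1.3$) and low ($R < 0.77$)
regions, all thresholds applied as strict inequalities exactly as printed.

`pfsratio` implements this analysis end to end: building consecutive-line
pairs from therapy-course tables, computing ratios with censoring semantics,
estimating median ratios naively and with the Kaplan–Meier method,
comparing ratio distributions between subsequent therapies with the log-rank
test, and quantifying the PFS1–PFS2 association under censoring.

## Censoring semantics of the ratio

PFS1 must be event-terminated: a subsequent line normally starts because the
previous one failed, so the denominator is a completed interval. Courses
where that does not hold (possible in synthetic or messy data) are excluded
by `extract_pairs()` with a logged reason rather than dropped silently —
a censored PFS1 gives a ratio with an unbounded denominator, not a lower
bound.

PFS2 may be censored at last follow-up. Then the recorded ratio is a
*right-censored lower bound*: the true ratio is at least the observed value.
Treating such ratios at face value, with censoring ignored, drags the
median down; the Kaplan–Meier estimator applied on the ratio axis
(`km_median_ratio()`) uses censored ratios as risk-set contributions and
recovers a censoring-aware median. A PFS2 of exactly zero (progression at
treatment start) is kept as ratio 0 with an event and a warning; dropping
those pairs would bias ratios upward.

## Kaplan–Meier estimation and conventions

`fit_km()` is a direct product-limit implementation, agnostic to whether the
axis is months or a dimensionless ratio:

* **Ties**: events precede censorings at identical values (standard
  product-limit convention); a censored observation stays in the risk set at
  its own value.
* **Median**: the smallest event time with $\hat S(t) \le 0.5$. For an even
  uncensored sample this is the lower of the two middle order statistics —
  the step-function convention, not the averaged midpoint. (The naive
  median, `naive_median_ratio()`, defaults to the conventional midpoint,
  with a `"lower"` option; the two conventions and their difference are
  deliberate and tested.)
* **Confidence intervals**: pointwise intervals on the complementary
  log-log scale, $\log(-\log \hat S)$, with Greenwood's variance — the
  common default in survival software; the median CI inverts them: a time
  belongs to the interval while 0.5 lies between the pointwise limits. The
  choice is recorded in every summary (`conf_type = "log-log"`). The test
  suite verifies exact agreement of curves, pointwise intervals and median
  intervals with `survival::survfit(conf.type = "log-log")`.
* **Not estimable**: medians or bounds the curve never reaches are `NA` in
  machine-readable output and printed as `"NE"`.

`logrank_test()` is the standard unweighted k-sample log-rank:
observed-minus-expected events over pooled event times, hypergeometric
covariance, chi-square statistic with $k-1$ degrees of freedom, no
small-sample continuity correction. It is rank-based, hence invariant under
any strictly increasing transform of the axis; the implementation accepts
arbitrary finite reals so transforms such as `log()` can be applied
directly. No multiplicity adjustment is applied anywhere — the analysis is
exploratory by design.

## Correlation of PFS1 and PFS2 under censoring

Two estimators with different scopes:

* `spearman_complete()` — Spearman's rank correlation restricted to pairs
  with progression on the second treatment, with an asymptotic p-value and
  Fisher-transform CI. Simple, but discards censored pairs.
* `censored_copula_rho()` — a Gaussian-copula maximum-likelihood estimator
  for partially censored pairs. Each margin is mapped to normal scores
  through its own Kaplan–Meier estimate (left-continuous at events,
  exceedance probability at censoring values), with survival probabilities
  clipped to $[1/(2n),\,1-1/(2n)]$ to avoid infinite scores. The likelihood
  over the copula correlation $\rho$ uses the copula density for doubly
  observed pairs, the conditional normal tail when one coordinate is
  censored, and the joint normal upper tail (numeric integral, relative
  tolerance $10^{-9}$) when both are. Optimization is a bounded
  one-dimensional search on $(-0.999, 0.999)$ with tolerance $10^{-6}$ —
  deterministic, no seed involved. Censoring in *either* coordinate is
  supported even though the pipeline excludes censored-PFS1 pairs upstream:
  the estimator stands alone.

The default CI is a Fisher z-transform with an effective sample size in
which a censored coordinate contributes half the information of an observed
one ($w_i = (0.5 + 0.5\,e_{1i})(0.5 + 0.5\,e_{2i})$, $n_\mathrm{eff} =
\sum w_i$); a profile-likelihood interval is available via
`ci_method = "profile"`. The estimator reports $\rho$ on the latent-normal
scale together with the implied Spearman coefficient
$\rho_s = \tfrac{6}{\pi}\arcsin(\rho/2)$. With zero censoring it reduces to
the classical normal-scores (van der Waerden) correlation, which the test
suite checks, along with marginal-transform invariance, symmetry in the two
margins, and a grid-search confirmation that the reported maximum is the
maximum of the implemented likelihood.

## The synthetic cohort generator

Patient-level therapy-course data of this kind are rarely deposited, so the
package ships a generator (`synthetic_config()` / `generate_cohort()`)
whose defaults encode a realistic mixed NEN referral cohort. It exists so
that every pipeline stage is testable against known truth — the `truth`
element carries the generating parameters, and `truth_ratios()` returns the
exact generating-model median ratio per sequence.

* **Strata**: histology × primary-site weights for a cohort dominated by
  NET G1/G2 (small-intestinal and pancreatic primaries), with thoracic
  carcinoids, NET G3 and NEC minorities.
* **Sequencing graph**: per histology, therapy paths with probabilities —
  SSA-first courses mostly followed by PRRT (less often everolimus or
  "other") in NET G1/G2 and carcinoids; platinum/etoposide-first courses
  followed by FOLFOX/FOLFIRI, CAPTEM or "other" in NEC; CAPTEM-centric
  NET G3 sequences. A few three-line paths create later-line pairs.
* **Marginals**: lognormal by default (heavy right tail, consistent with the
  L-shaped PFS1–PFS2 scatter seen in such cohorts; months-scale PFS from a
  couple of months to several years), parameterized by the *median* in
  months per therapy (SSA 15.1, PRRT 28.1, everolimus 15.0, CAPTEM 9.8,
  platinum/etoposide 6.0, FOLFOX/FOLFIRI 2.8, Re-PRRT 13.2, other 8.9) with
  sdlog 0.9. Because the ratio of correlated lognormals is lognormal, the
  implied true median ratios are exactly the scale ratios: SSA→PRRT 1.86,
  SSA→everolimus 0.99, SSA→other 0.59, platinum→FOLFOX/FOLFIRI 0.47,
  platinum→CAPTEM 1.63 — the regime of interest for this analysis. Weibull
  and exponential marginals are available for robustness work
  (`truth_ratios()` switches to Monte-Carlo evaluation there).
* **Dependence**: a latent Gaussian vector with exchangeable correlation
  across a patient's lines, the Spearman target (default 0.35) converted to
  the latent scale by $\rho = 2\sin(\pi\rho_s/6)$. Introducing dependence at
  the latent level rather than through a frailty multiplier gives direct
  control of the rank correlation the analysis estimates.
* **Censoring**: administrative and confined to the final line — earlier
  lines are event-terminated by construction, matching the pairing
  assumption. The cutoff is uniform on $(0, W)$ with $W$ calibrated by root
  finding so the expected censored fraction equals `censor_rate` (default
  0.30); censoring is independent of the event times.

Determinism: a fixed config (including its seed) reproduces the cohort
byte for byte, and generation leaves the caller's RNG state untouched.

What the generator does **not** emulate: overall survival, tumor-grade
migration under treatment, toxicity-driven discontinuation, staggered
calendar entry, response-assessment interval discreteness, or
between-therapy selection effects (therapy assignment is independent of the
latent prognosis given the stratum). Passing tests therefore demonstrate
the statistical machinery under a clean data-generating process, not the
clinical validity of any sequence comparison on real data.

## Two calibration caveats the simulations expose

The validation suite runs recovery and calibration simulations at the
cohort scale (500 replicates of 60-pair cohorts for median-ratio recovery,
200 replicates of 177-pair cohorts for correlation recovery, 2,000 null
replicates for log-rank calibration, a 10,000-pair exchangeable-null check —
sizes chosen to pin Monte-Carlo error well below the quantities examined).
Two findings deserve emphasis because they are properties of the *method*,
not implementation defects:

1. **KM-on-ratio under administrative censoring is not exactly unbiased.**
   Administrative censoring happens on the time axis; mapped to the ratio
   axis the censoring value $C/\mathrm{PFS}_1$ shares its denominator with
   the ratio itself, so ratio-axis censoring is not independent of the
   ratio. At the default study conditions (60 pairs, 25% censoring, sdlog
   0.9) the recovery simulation shows the median of KM median-ratio
   estimates about 0.15–0.18 above the generating value 1.86, while a
   control simulation with censoring drawn independently on the ratio axis
   recovers the target — isolating the shift to the mechanism. Any real
   cohort analyzed with KM-on-ratio inherits this: censoring-aware median
   ratios should be read as slightly optimistic under heavy censoring.
2. **The log-rank chi-square reference is anticonservative for very
   unbalanced small groups.** With groups of 60/13/9 the null rejection
   rate at $\alpha = 0.05$ is about 0.07 (identically so for
   `survival::survdiff`, which the suite uses as cross-check); with three
   balanced groups of 50 it is within [0.035, 0.065]. p-values near 0.05
   from comparisons involving a group of fewer than ~15 ratios deserve
   caution; a permutation calibration (as in the test helpers) is the
   remedy when it matters.

## Other numerical and design choices

* Sequence grouping is by therapy-label pair across all lines, with
  `mode = "after_line1_only"` for the first-line-antecedent analysis and
  `mode = "after_specific_therapy"` for a fixed antecedent.
* The per-cell exceedance percentage (`pct_above_1_3`) ignores censoring,
  matching how such percentages are conventionally reported alongside naive
  medians.
* Sequence-summary cells with fewer than `min_n = 4` observations keep
  their sample size but have all statistics suppressed — the minimum-count
  rule used for heatmap reporting; `min_n` is configurable.
* CSV dialect: comma-separated, UTF-8, `.` decimal, missing token `"NA"`;
  durations are months throughout, with no unit auto-detection. Validation
  failures are collected with row numbers and reasons, and validated
  cohorts round-trip through `write_cohort()`/`read_cohort()`.
* The pipeline (`run_pipeline()`) draws no random numbers: identical input
  yields byte-identical output bundles, including the JSON run manifest
  that records every analytic choice (median-CI method, thresholds,
  conventions, suppression rule).

## Limitations

Beyond the two calibration caveats above: the ratio presumes the two
intervals are comparable measurements of the same disease, which grade
migration or radically different assessment schedules can break; excluding
patients without a second line selects for better prognosis; and the
Gaussian copula is an assumption — the estimator is the MLE under that
model, and no equivalence with other censored-correlation estimators is
claimed. The package deliberately stops short of multivariable adjustment
(e.g. Cox models over sequence groups), toxicity, and any clinical
decision-making layer.
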