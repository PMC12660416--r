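# pfsratio

Intra-patient treatment comparisons for neuroendocrine neoplasms (and other
heterogeneous cancers) using **progression-free survival (PFS) ratios**, with
right censoring handled throughout.

## The problem and the statistic

When tumor biology varies as much between patients as it does in
neuroendocrine neoplasms, between-patient PFS comparisons of therapies are
confounded by disease pace. The PFS ratio (growth modulation index) uses each
patient as their own control:

```
R = PFS2 / PFS1
```

where PFS1 is the progression-free interval of the antecedent treatment line
and PFS2 that of the subsequent line. `R > 1` means the later therapy
stabilized disease longer than the earlier one; `R >= 1.33` is the classical
bar for an unanticipated improvement, and `R > 1.3` / `R < 0.77` segment
high- and low-benefit regions.

Censoring makes the naive median of these ratios misleading: a censored PFS2
gives a ratio that is only a *lower bound*. The package therefore estimates
median ratios with the Kaplan–Meier method on the ratio axis, compares ratio
distributions between subsequent therapies with the k-sample log-rank test,
and quantifies the PFS1–PFS2 association with both a complete-case Spearman
coefficient and a Gaussian-copula maximum-likelihood correlation for
partially censored pairs. A configurable synthetic cohort generator
(histology strata, therapy-sequencing graph, correlated lognormal line-wise
PFS, administrative censoring of the final line) makes every stage testable
against known truth.

## Worked example

```r
library(pfsratio)

cfg <- synthetic_config(n_patients = 177, seed = 7)  # study-shaped defaults
cohort <- generate_cohort(cfg)
bundle <- run_pipeline(cohort$records)
print(bundle)
```

```
PFS-ratio report: 177 patients, 376 lines, 199 pairs (0 excluded)
Ratio-distribution comparisons (log-rank):
            therapy1 k  n   statistic df      p_value
1               PRRT 2 30  0.02876176  1 0.8653302860
2                SSA 4 87 13.32828295  3 0.0039778742
3              other 2 19  2.11081776  1 0.1462611400
4 platinum/etoposide 3 33 14.89315277  2 0.0005834357
complete_case_spearman: rho = 0.258 (95% CI 0.090 to 0.412), n = 130
censored_copula: rho = 0.351 (95% CI 0.204 to 0.482), n = 177
```

The log-rank rows say that the ratio distributions of therapies following
first-line SSA differ (p ≈ 0.004): PRRT after SSA achieves disproportionately
long PFS2 while everolimus and "other" do not. The copula estimate says the
two intervals of a patient are only weakly to moderately correlated
(ρ ≈ 0.35), so PFS1 alone is a poor predictor of PFS2.

The censoring contrast for a single sequence:

```r
sp <- bundle$pairs[bundle$pairs$therapy1 == "SSA" & bundle$pairs$therapy2 == "PRRT", ]
naive_median_ratio(sp$ratio)
#> [1] 1.097755
km_median_ratio(sp$ratio, sp$event)
#> median   2 (95% CI 1.1-2.8) [n = 49, events = 31, log-log CI]
```

Treating censored ratios at face value gives a median of 1.10; accounting for
the 18 censored lower bounds roughly doubles it. Per-sequence summaries are
heatmap-ready, with cells of fewer than 4 observations suppressed (sample
size retained), e.g.:

```
  therapy1   therapy2  n naive_median km_median pct_above_1_3 suppressed
      PRRT    Re-PRRT  2           NA        NA            NA       TRUE
       SSA       PRRT 49    1.0977549 2.0102873     42.857143      FALSE
       SSA everolimus 13    0.5099688 1.7106632     30.769231      FALSE
```

Cohorts round-trip through plain CSV (`write_cohort()` / `read_cohort()`
with row-level validation), and `run_pipeline(..., out_dir = ...)` writes the
full bundle (pair table, summaries, group tests, correlation estimates,
per-line KM medians, Sankey-ready transition edge list, JSON manifest)
deterministically.

See the vignette `vignettes/pfs-ratio-methods.Rmd` for the estimators'
definitions, conventions (tie handling, median and CI conventions, "NE"
reporting), the generator's design, and known calibration caveats.

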