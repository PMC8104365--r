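# phenocirc

Circular statistics for long-term plant phenology from herbarium
specimens.

Digitized herbarium records are one of the few data sources that reach
back a century, which makes them attractive for asking whether flowering
and fruiting seasons of (sub)tropical plants have shifted under climate
change. They are also awkward data: collection dates are circular
(December neighbours January), records arrive contaminated with
duplicates, sterile specimens and incomplete labels, and seasonality can
be unimodal, bimodal or absent. `phenocirc` implements the full analysis
chain for this setting:

* **Record cleaning** — duplicate collapse (same collector, date,
  locality), removal of sterile and incompletely labelled specimens, with
  an exactly conserved cleaning report, and assignment to analysis time
  intervals (default: I 1920–1979, II 1980–1999, III 2000–2018).
* **Circular model selection** — maximum-likelihood fits of the ten
  Schnute–Groot von Mises mixture models
  `f(θ) = λ₁VM(θ; q₁, κ₁) + λ₂VM(θ; q₂, κ₂) + (1 − λ₁ − λ₂)/2π`
  (uniform M1; unimodal M2A–M2C; axial bimodal M3A–M4B; non-axial bimodal
  M5A–M5B), ranked by AIC.
* **Seasonality tests** — Rayleigh (statistic r̄, analytic p) for
  uniform/unimodal best fits; Hermans–Rasson (Monte-Carlo p) for bimodal
  best fits, where Rayleigh loses power.
* **Interval comparison** — two-sample Watson U² for grouped (monthly)
  data, `U² = (n₁n₂/N²)[Σtₖdₖ² − (Σtₖdₖ)²/N]`, with permutation p-values
  and a pairwise interval matrix.
* **Climate regression** — per-record photoperiod, precipitation, mean
  temperature and temperature range at lags 0–3 months, Pearson/VIF
  collinearity screen, full OLS model of the collection-month angle and
  AIC backward selection, plus one-way climate ANOVA across intervals.
* **Synthetic data** — seeded generators for record sets (with known
  mixture truth and exact contamination bookkeeping), warming-trend
  climate series, and regression datasets with known active climate terms.

See the methods vignette (`vignettes/phenocirc-methods.Rmd`) for the
models, their assumptions and the design choices.

## Worked example

```r
library(phenocirc)

g <- gen_records(phenology_preset(), seed = 42)   # synthetic specimen set
cleaned <- clean_records(g$records)
cleaned$report
#> Cleaning report:
#>   input records         234
#>   duplicates removed    18
#>   sterile removed       27
#>   missing date removed  9
#>   missing locality rm.  0
#>   retained              180
```

The report is exactly conserved: 234 = 180 + 18 + 27 + 9. Now encode the
flowering months on the circle and select among the ten models:

```r
ang <- month_to_angle(phenophase_subset(cleaned$records, "flowering")$month)
sel <- select_model(ang)
sel$table[1:3, c("rank", "model", "modality", "loglik", "npar", "aic")]
#>   rank model         modality    loglik npar      aic
#> 1    1   M5B bimodal_nonaxial -230.3889    5 470.7777
#> 2    2   M2A         unimodal -251.5437    2 507.0874
#> 3    3   M2C         unimodal -251.3098    3 508.6196
```

Pooled across intervals the sample looks bimodal (this preset drifts the
flowering peak from December to February across intervals), so the
modality-guided test choice is Hermans–Rasson:

```r
choose_uniformity_test(sel$best)
#> [1] "hermans_rasson"
hermans_rasson_test(ang, n_sim = 999, seed = 1)
#> hermans_rasson test: statistic = 115.5312, p = 0.001 (n = 180, monte_carlo)
circ_summary(ang)
#> Circular summary (n = 180 )
#>   mean vector length r = 0.625
#>   mean angle = 6.053 rad; mean date = 18/12 (day/month)
```

Seasonality is significant (p = 0.001) with mean direction in
mid-December. Did it change between intervals?

```r
cmp <- interval_comparison_matrix(months_by_interval(cleaned$records),
                                  n_perm = 999, seed = 1)
cmp$pairs[, c("interval1", "interval2", "u2", "p_value", "significant")]
#>   interval1 interval2        u2 p_value significant
#> 1         I        II 0.3288996   0.005        TRUE
#> 2         I       III 1.0590849   0.001        TRUE
#> 3        II       III 0.5328043   0.001        TRUE
```

All three interval pairs differ at α = 0.05 — the generator did shift the
flowering peak between intervals, and the grouped Watson U² matrix
detects it. Climate regression works the same way from
`build_lagged_design()` through `fit_full_model()` and
`backward_select()`; see the vignette.

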