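---
title: "Circular models and climate regression for herbarium phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular models and climate regression for herbarium phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocirc)
```

## The problem

Digitized herbarium specimens carry a collection date, a locality and
observable phenophases (open flowers, fruits). Pooled over decades, these
records describe when a species reproduces and whether that timing has
shifted between historical periods — provided the analysis respects two
things: collection dates are *circular* (December is next to January), and
specimen sets are contaminated by duplicates, sterile material and
incomplete labels. `phenocirc` implements the full analysis chain:
cleaning, circular model selection, seasonality testing, between-interval
comparison, and climate regression, plus a synthetic-data module that
generates record sets with known ground truth.

## Encoding dates on the circle

Months are mapped to 30-degree arcs: January starts at 0, February at 30
degrees, ..., December at 330 degrees (`month_to_angle()`); all internal
angles are radians in $[0, 2\pi)$. This monthly convention is the default
everywhere because herbarium labels are reliable to the month far more
often than to the day. A `day_of_year` convention is also provided (used
only for reporting mean dates at day resolution); the two differ by at
most half an arc. The inverse mapping (`angle_to_date()`) places the day
linearly within the arc's month; since the original convention discards
days, the reported mean *day* is a convention, not an estimate — different
rounding choices can move it by a few days.

## The ten circular models

Seasonality structure is chosen by maximum likelihood over the ten
Schnute–Groot von Mises mixture models, the standard model-based
alternative to picking a uniformity test by eye. All are special cases of

$$f(\theta) = \lambda_1 \mathrm{VM}(\theta; q_1, \kappa_1)
            + \lambda_2 \mathrm{VM}(\theta; q_2, \kappa_2)
            + \frac{1 - \lambda_1 - \lambda_2}{2\pi},$$

with $\mathrm{VM}(\theta;q,\kappa) = e^{\kappa\cos(\theta-q)} / (2\pi
I_0(\kappa))$. The family runs from the uniform model M1 (no seasonality),
through unimodal models M2A–M2C (one peak, optionally diluted with uniform
"background" collecting), axial bimodal models M3A–M4B (two peaks six
months apart), to non-axial bimodal models M5A–M5B (two peaks anywhere).
Free-parameter counts are 0, 2, 2, 3, 2, 3, 3, 4, 4, 5. Models are ranked
by AIC (`select_model()`); AICc is available behind a flag for small
samples. Ties are broken by fewer free parameters, then by canonical model
order.

Numerical choices that matter:

* **Concentrations** are bounded to $\kappa \in [0, 250]$ and optimized on
  a log scale; monthly binning cannot support sharper peaks, and fitted
  values in the hundreds already describe essentially single-arc spikes.
* **Free component weights** are bounded below by 0.25 so that no fitted
  "bimodal" model degenerates into a unimodal one with a vestigial second
  component; for two-component models the weights sum to one, so
  $\lambda_1 \in [0.25, 0.75]$.
* **Multi-start optimization**: eight deterministic starts (four mean
  directions a quarter-turn apart crossed with two concentration levels)
  plus a method-of-moments start; axial models add an axial-moment start
  (mean direction of doubled angles) and non-axial models add 120-degree
  mode-separation starts. During `select_model()` each model also starts
  from the fitted solutions of the models nested inside it, which is what
  makes the nested-likelihood ordering hold to optimizer tolerance.
* Fits that fail on every start are excluded from ranking with a warning
  rather than silently reported.

A property worth knowing: with all ten models fitted well, AIC selects an
overparameterized alternative on truly uniform data in roughly a quarter
of samples (the classical $P(\chi^2_k > 2k)$ behaviour). The uniform model
is still the modal choice, and the downstream test choice is conservative
about it (see below), but single-dataset model labels should be read with
this in mind.

## Testing seasonality

The Rayleigh test is powerful against unimodal departures from uniformity
but nearly blind to axial bimodal ones (two balanced peaks cancel in the
mean resultant). The package therefore chooses the test from the best-fit
modality (`choose_uniformity_test()`): uniform or unimodal best fits are
tested with Rayleigh (statistic $\bar r$, large-sample analytic p), and
bimodal best fits with the Hermans–Rasson statistic

$$T = \frac{1}{n}\sum_{i,j}\Big[\,\big|\pi - |\theta_i - \theta_j|\big|
  - \tfrac{\pi}{2} - 2.895\big(|\sin(\theta_i - \theta_j)| -
  \tfrac{2}{\pi}\big)\Big],$$

whose null distribution is simulated (`p = (1 + \#\{T_{sim} \ge
T_{obs}\})/(n_{sim}+1)`, default 999 simulations, seedable; a shared null
sample can be passed when many tests of equal $n$ are run). The statistic
is rotation invariant, and its type-I error and power ordering against
Rayleigh are verified by simulation in the test suite rather than against
printed values, since published implementations differ in constants.

## Comparing time intervals

Records are split into analysis intervals (default I 1920–1979, II
1980–1999, III 2000–2018; the long first interval reflects sparse early
collecting). Distribution changes between intervals use the two-sample
Watson $U^2$ for *grouped* data,

$$U^2 = \frac{n_1 n_2}{N^2}\Big[\sum_k t_k d_k^2 -
  \frac{(\sum_k t_k d_k)^2}{N}\Big],$$

with $d_k$ the difference in cumulative relative frequencies at month bin
$k$ and $t_k$ the pooled bin count. The centering term makes the statistic
independent of which month is taken as the origin (verified to $10^{-12}$
in a regression test; January is used for presentation). The p-value comes
from permutation of pooled bin memberships (default 9,999, seeded;
permutations are taken over the smaller group so the result is exactly
symmetric in sample order); the asymptotic tail $2\sum_m (-1)^{m-1}
e^{-2 m^2 \pi^2 u}$ is available as a cheap alternative. No
multiple-testing correction is applied by default across the three
interval pairs, matching common practice in this literature; Holm
adjustment is one flag away.

## Climate covariates and regression

For each record the design (`build_lagged_design()`) contains photoperiod
(hours, astronomical day-length model at the 15th of the month — the
within-month reference day is configurable since labels are monthly),
monthly precipitation (mm), mean temperature and diurnal range (degrees C,
derived as midpoint and difference of the monthly max/min), each at lags
0–3 months before collection, with year wrap-around. Records with any
missing climate month are dropped and counted, not imputed. Collinearity
is screened with pairwise Pearson correlations and VIFs ($1/(1-R_j^2)$;
defaults flag $|r| > 0.8$ and VIF > 10 — lagged photoperiods at a single
site are close to collinear, so a spread of site latitudes is what makes
the lags separable). The full OLS model of the collection-month angle on
all covariates is then reduced by backward stepwise selection under AIC
(`MASS::stepAIC`); AIC rather than p-value thresholds is used because it
is the cited default of the selection machinery this analysis style relies
on, and the two can disagree near $p \approx 0.05$.

Regressing a circular response with ordinary least squares is a deliberate
fidelity choice: it reproduces the field's standard practice, and it works
when the phenophase is concentrated away from the December–January wrap.
It is *wrong* near the wrap (an angle of 0.1 and one of 6.2 rad are close
on the circle but far in OLS); a sine/cosine-response mode exists for
users who need it but is off by default and outside the validated surface.

One-way ANOVA of annual climate means (annual sums for precipitation)
across intervals (`climate_anova()`) completes the reporting set.

## The synthetic-data module

`gen_records()` draws collection months from interval-specific mixture
models (angle to month by arc membership, day fixed at 15), years
uniformly within each interval, and sites by weight, then injects
contamination — exact duplicates, sterile specimens, missing dates — *after*
the clean core is formed, so ground-truth counts are exact. The default
`phenology_preset()` mirrors the scale of a cleaned long-term specimen
dataset: three intervals totalling ~180 records plus ~30% contamination,
sites spanning latitudes $-18$ to $-30$.

`gen_climate()` produces monthly series per site: temperature as baseline
+ linear warming trend (default 0.15 °C/decade over 1920–2016, a
realistic twentieth-century subtropical trend) + seasonal harmonic peaking
in January (austral summer) + Gaussian noise, with the diurnal range in
antiphase; precipitation as a seasonal harmonic scaled by lognormal noise,
so interannual precipitation variation dominates temperature variation.
`tmax >= tmin` holds by construction.

`gen_regression_dataset()` must satisfy a constraint the real data also
satisfies: the response *is* the collection month's angle, so the climate
signal cannot simply be added to it. Candidate records are therefore
screened by Gaussian acceptance on the wrapped difference between their
month angle and their linear predictor. The preset slopes were derived
once, at design time, by regressing the month angle (February–November,
away from the wrap) on photoperiod at lags 0, 1 and 3 across the five
default site latitudes — giving the photoperiod-dominated, mixed-sign,
mixed-lag structure typical of reported phenology–climate models — and the
acceptance noise scale (1.2 rad) was fixed so the realized generating
$R^2$ is about 0.8. The realized $R^2$ is recomputed and stored in the
truth object of every generated dataset.

What the generator does *not* emulate: collector-effort bias in space and
time, taxonomic misidentification, spatially structured climate error, and
day-resolution phenology. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the stated
conditions, not that any real species behaves this way.

## Problem sizes used in the validation suite

The shipped tests run the calibration studies at the scale the methods are
meant for: uniformity-test calibration over 5,000 uniform samples of
$n=50$ (and 2,000 axial-bimodal samples for the power ordering), model
recovery over 100 replicates per generating model at $n=300$ with
$\kappa \ge 2$, interval-shift detection over 100 replicates of 60 records
per interval, and regression recovery over 50 replicates of 150 records.
The acceptance script (`scripts/acceptance.R`) repeats the same analyses
from scratch under a caller-supplied seed.

## Known limitations

* Monthly arcs cap angular resolution at 30 degrees; mean dates are
  reported to the day but carry month-scale uncertainty.
* The OLS-on-angle regression is invalid for phenophases centered on the
  calendar-year wrap (see above).
* AIC model selection overfits uniform data at the usual rates; the
  modality-based test choice, not the model label, is the robust output.
* Climate lookup is exact-key or nearest-site on tables; gridded rasters
  must be flattened to long format upstream.
* The expert step of removing dubiously identified specimens has no
  computable rule; it enters only as a pre-filter before parsing.
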