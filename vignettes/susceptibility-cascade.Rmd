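---
title: "Estimating the air-pollution-susceptible population: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the air-pollution-susceptible population: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airsusc)
```

## The estimation problem

A substantial fraction of any population carries at least one attribute —
young or old age, chronic cardiorespiratory or metabolic disease,
pregnancy, outdoor work, low socio-economic status, poor antioxidant
intake — that raises the risk of harm from a given exposure to ground-level
ozone (O~3~) and fine particulate matter (PM~2.5~). The quantity of
interest is the percent of a population with *at least one* such factor,
nationally and per health region, and how that percent co-varies with
long-term ambient concentrations. The difficulty is double counting: a
70-year-old with diabetes who works outdoors must count once, not three
times, and the data available per factor are heterogeneous — survey
microdata for some factors, national tables for others, annual event
counts for pregnancy.

## The cascade

The population is split into ten age strata with half-open bounds
`[0,10), [10,15), [15,16), [16,20), [20,25), [25,35), [35,45), [45,65),
[65,75), [75,Inf)`. The unequal split of 10–19 exists because pregnancy
estimation includes 15-year-olds while outdoor work starts at 16; any
coarser banding would misalign some factor's scope.

Within a stratum, factors are applied in a fixed order to the fraction not
yet flagged: with effective prevalences $p_1,\dots,p_K$ (zero off-scope),

$$q_0 = 1,\qquad c_k = q_{k-1}p_k,\qquad q_k = q_{k-1}(1-p_k),$$

so factor $k$ claims $c_k$ of the stratum and $\sum_k c_k = 1-\prod_k(1-p_k)$
is the union probability of $K$ independent Bernoulli events. Independence
is the central modelling assumption: no data on the joint distribution of
the factors are assumed to exist, except for the four chronic conditions,
whose union is formed *per respondent* in the microdata before weighting —
within the chronic-disease factor, comorbidity is handled exactly, not by
independence.

Two consequences of the product form are load-bearing and are enforced by
property tests: the total is invariant to factor order (only the
attribution $c_k$ depends on it), and per-stratum mass is conserved
($\sum_k c_k + q_K = 1$). The per-factor population percents are
population-weighted means of $c_k$ across strata and sum exactly to the
total percent, so averaging per-factor percents across regions and summing
gives the mean regional total — the linearity the acceptance checks
exercise with the published per-factor means.

The canonical factor order is frozen as: the two wholesale age factors,
chronic disease, pregnancy, then (inclusive only) outdoor work, education,
vitamin C, and the wholesale "remainder of 10–19 and 65–74" last. Whether
the wholesale age factors precede or follow chronic disease cannot change
any total (order invariance); it only shapes the decomposition, and this
order matches the conventional presentation of the factors. The remainder
factor is implemented as a wholesale factor placed last, so it captures
exactly the population of those strata not already flagged, rather than by
a separate formula.

## Prevalence inputs

* **Survey-weighted factors** (chronic disease, education):
  $\hat p = \sum_i w_i x_i / \sum_i w_i$ over domain respondents with a
  non-missing indicator. Missingness is complete-case *per indicator*; for
  the chronic union a respondent missing any of the four components is
  excluded from the union estimate. Point estimates only — no design-based
  variance. A region × stratum cell with no usable respondents falls back
  to the national estimate for that stratum (tagged in the table's
  provenance column) rather than failing: single-year strata such as age 15
  can be empty in small regional samples, and a national age-specific value
  is the natural fallback for a survey designed to be representative
  regionally. Only a cell empty even nationally is an error.
* **Pregnancy**: annual live births, fetal losses, and induced abortions
  per stratum are each multiplied by an average gestational duration in
  years (defaults 40/52, 11/52, 10/52 respectively — the
  emergency-preparedness worksheet convention; they are arguments, not
  constants) and divided by the female population, giving the expected
  fraction of women concurrently pregnant. The cascade needs stratum-wide
  prevalences, so this is multiplied by each region's female fraction per
  stratum. Pregnancy applies to strata 15 through 45–64; the configured
  rates are near zero in 45–64, which makes the exact upper scope
  numerically minor.
* **Education** applies from stratum 20–24 upward by default (configurable
  via custom criteria): a high-school-completion indicator is meaningless
  for children, and under inclusive criteria the 10–19 remainder factor
  covers them anyway.
* **Outdoor work** is known nationally by age and urbanicity; each region
  receives the convex combination
  $f\,p_\text{urban} + (1-f)\,p_\text{rural}$ with its urban population
  fraction $f$. **Vitamin C** is national by age and broadcast to regions.

## Exposure overlay

Regional concentrations are means over grid cells within each year
(area-weighted if weights are supplied, unweighted otherwise — both are
supported because the aggregation convention of published surfaces is not
always documented), then across years; a missing cell-year is an input
error, never imputed. Quartile thresholds use linearly interpolated order
statistics (`stats::quantile` type 7) with ties assigned to the lower
quartile; on values $1..110$ this yields quartile sizes 28/27/27/28. Labels
are invariant under strictly increasing transforms, so quartiles of ranks
and of raw concentrations agree. If all values are identical the quartiles
are degenerate: everything is labelled 1 with a warning rather than an
arbitrary split. A priority ("double jeopardy") region is one in the top
susceptibility quartile under either criteria set *and* the top
concentration quartile of either pollutant. The stability check compares
regional means over a short and a long averaging window by squared Pearson
correlation.

## Rank correlations

`spearman_rho()` is self-contained: Pearson correlation of midranks, with
a two-sided p-value. For $n \le 8$ the p-value is computed exactly by
enumerating all $n!$ rank permutations, because the $t$ approximation on
$n-2$ degrees of freedom is coarse at those sizes (deviations up to ~0.08
from the exact tail); from $n = 9$ the $t$ approximation is used. Both
behaviours are explicitly selectable. Zero rank variance makes $\rho$
undefined and raises an error; `correlation_report()` catches it per pair
and reports `NA` so one degenerate indicator cannot abort a report.

## The synthetic world

`simulate_world()` exists so the full pipeline — estimation, cascade,
overlay, correlations — can run and be tested end to end with a known
ground truth. Its defaults describe a realistic national setting: 110
regions; lognormal regional populations (median ≈ 160,000); ~1,100
respondents per region; national age shares near a contemporary Canadian
age distribution; chronic-disease, education, outdoor-work, vitamin-C and
fertility parameters chosen so the true national cascade lands near one
third restrictive and two thirds inclusive. Regional structure comes from

* Dirichlet perturbation of the national age shares (concentration 150 by
  default — regional child shares vary by a couple of percentage points,
  as real health regions do); infinite concentration is the degenerate
  no-heterogeneity limit,
* logit-normal perturbation (sd 0.2) of the survey-resolvable prevalences,
* urban fractions uniform on [0.1, 1], and
* a PM~2.5~ urbanicity gradient: regional mean = 5 + 3.5·(urban fraction)
  µg/m³ plus N(0, 1) noise, giving an urbanicity–PM~2.5~ Pearson
  correlation of about 0.67 analytically, in line with the positive
  association real fine-particle surfaces show with urban population.
  O~3~ (baseline 28 ppb, regional sd 4) carries no gradient. Because
  outdoor-work prevalence is higher rural, inclusive susceptibility is
  mechanically higher in rural regions, and a negative PM~2.5~ ×
  susceptibility correlation *emerges* rather than being injected.

Survey weights are inverse inclusion probabilities under age × urbanicity
stratified sampling (default tilt oversamples the elderly 1.5× and rural
respondents 1.3×, so weighted and unweighted estimates genuinely differ),
multiplied by mean-one lognormal noise with configurable coefficient of
variation (default 0.5). Weighted margins therefore match the region's
population margins in expectation, not exactly per realization — the
estimator, not the generator, is under test. With a uniform tilt and zero
dispersion all weights in a region are equal, the degenerate check.

Pollutant surfaces give each region a fixed number of cells (default 4);
cell-year values are regional mean + time-invariant cell offset +
regional inter-annual deviation, truncated at zero. Truncation was chosen
over a log-normal model for transparency: at the configured baselines the
truncation is inactive, and the additive decomposition makes the stability
check's behaviour analytic. One global seed fans out to fixed per-stage
offsets so each stage is individually reproducible; identical seed and
configuration give identical worlds.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: spatial autocorrelation within regions
(cells are exchangeable), household clustering and bootstrap replicate
weights of a real complex survey, inter-factor dependence (draws are
independent, matching the cascade's own assumption, so recovery tests
validate the estimation chain, not the independence assumption itself),
and regional dependence of the nationally-supplied factors beyond the
urbanicity adjustment.

## Numerical conventions and test scale

All internal arithmetic is full double precision; percents are rounded to
one decimal only in printed output, which is why printed rows may not sum
exactly to printed totals. Conservation and order-invariance are asserted
at 10^-12^; agreement with exact Bernoulli enumeration at 10^-9^. A
zero-population stratum keeps well-defined cascade values but contributes
nothing to totals. Prevalences outside [0, 1], missing in-scope
prevalences, empty estimation domains, regions without grid cells, and
inconsistent pregnancy counts (implied prevalence > 1) all raise immediate,
named errors rather than propagating silently.

The test suite runs the estimator-recovery study at 20 regions × 20,000
respondents × 20 seeds (checking regional totals within one percentage
point of truth), the cascade-versus-enumeration study at 1,000 random
instances with a 2,000-draw Monte-Carlo companion, and the generator
calibration at 100–200 regenerations; these sizes make the whole suite run
in about a minute while leaving Monte-Carlo error well inside the asserted
tolerances.

## Limitations

Susceptibility is treated as binary membership in an any-factor union; no
severity weighting is attempted, since the evidence to weight factors
against each other quantitatively is lacking. Independence between factors
overstates the union when factors cluster in the same people (e.g. low SES
and chronic disease), and understates it under negative dependence; the
prevalence-table interface accepts externally supplied joint adjustments,
but none are computed here. No uncertainty intervals accompany the totals
— inputs are point estimates by design. The exposure overlay consumes a
precomputed cell-to-region map; projection handling, regridding, and
raster I/O are out of scope.
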