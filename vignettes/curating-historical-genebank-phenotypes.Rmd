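---
title: "Curating historical genebank phenotypes: models, quality control, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating historical genebank phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histphen)
library(dplyr)
```

## The problem

Genebanks phenotype their accessions as a side product of seed regeneration:
every season a small fraction of the collection is grown in unreplicated
plots and scored for traits such as flowering time (FT, days after
January 1), plant height (PH, cm) and thousand grain weight (TGW, g). Over
decades this accumulates records for thousands of accessions — but the
accession-by-year matrix is extremely sparse (typically more than 93% empty)
and unbalanced: which accessions were grown in which year was decided by
seed viability and acquisition batches, not by an experimental design.

`histphen` turns such records into quality-checked best linear unbiased
estimates (BLUEs) of accession performance. It implements

1. a REML engine for linear mixed models with arbitrary crossed/nested
   random grouping factors and *year-specific residual variances*,
2. a three-step quality control: plausibility rules, a studentized-residual
   outlier test with Bonferroni–Holm correction, and a weather-parameter
   index that corroborates the exclusion of entire anomalous years,
3. a resampling study quantifying how block-wise (rather than random)
   regeneration schedules degrade the precision of variance components and
   BLUEs, and
4. a synthetic-data generator with the statistical structure of historical
   collections, so every stage is testable without access to institutional
   data.

## The historical-data model

A single trait is modelled as

$$y_{ij} = \mu + g_i + a_j + e_{ij},$$

where $g_i$ is the effect of accession $i$, $a_j$ the effect of
regeneration year $j$, and $e_{ij} \sim N(0, \sigma^2_{e^*j})$ a residual
whose variance is specific to year $j$. Heterogeneous residual variances
matter because growing seasons differ in how precisely traits could be
scored; pooling them distorts both the outlier test and the weights behind
the BLUEs.

Two parameterisations of the same model are used for different purposes:

* **BLUE mode** (`estimate_blues()`): accessions fixed, year random. The
  fixed accession estimates are the BLUEs $\mu + g_i$, directly on the trait
  scale, with standard errors from the mixed-model equations. This is also
  the model under which outliers are tested.
* **Component mode** (`estimate_components()`): intercept-only fixed part,
  accession and year random. This yields the second-degree statistics
  $\sigma^2_G$, $\sigma^2_Y$, $\bar\sigma^2_e$ and the entry-mean
  heritability
  $$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \bar\sigma^2_e/\bar n_{yr}},$$
  with $\bar n_{yr}$ the average number of observation years per accession.

Designed validation trials are handled by the same engine with the usual
multi-factor decomposition (environment, accession × environment, trial,
replicate within trial, block within replicate), accessions fixed and
everything else random; nesting is written with `:`
(e.g. `"environment:trial:replicate"`).

## The REML engine

`fit_mixed()` maximises the restricted likelihood on the mixed-model
equations, with sparse design matrices throughout. The schedule is an
expectation–maximisation warm start (10 iterations by default; monotone and
robust far from the optimum) followed by average-information (AI) updates
with step halving, accepting only steps that do not decrease the restricted
log-likelihood. Convergence is declared when the relative change falls below
`tol = 1e-8` (at most 200 iterations; non-convergence is an error that
carries the likelihood trajectory, never a silently returned estimate).

Numerical choices worth knowing about:

* **Boundaries.** Variance components are kept non-negative by flooring.
  Random-term variances may go to (effectively) zero — they are then
  reported with a `boundary` flag. Residual-group variances get a higher
  floor ($10^{-4}$ of the response variance) because near-zero group
  variances make the equations ill-conditioned enough that likelihood
  evaluations turn numerically noisy. Components near the floor that the
  score still pushes downward are pinned there, since EM approaches a
  boundary only geometrically and would otherwise stall. A ceiling of
  $10^3 \times$ the response variance guards against the unbounded
  likelihood spikes of saturated degenerate designs.
* **Small years.** A year-specific residual variance is not estimable from a
  single record; years with fewer than `min_group_size = 2` records are
  pooled into one shared variance group.
* **Studentized residuals.** Each conditional residual is scaled by its
  estimated standard deviation $\sqrt{\sigma^2_{e^*j} - w_i' C^{-1} w_i}$,
  i.e. the year's residual variance minus the record's leverage in the
  mixed-model equations. This leverage-corrected scaling is used instead of
  full case-deletion residuals, whose refits would be prohibitive at
  collection scale; simulation (see the test suite) shows the resulting
  values are calibrated (SD within 10% of 1 under the model) and that a
  single gross contaminant attains the maximum absolute value.
* **Connectivity.** With a fixed accession factor, contrasts between
  accessions in disconnected components of the accession × year incidence
  graph are informed only through the random year distribution; `fit_mixed()`
  reports the number of components rather than silently proceeding.

The engine's accuracy is pinned in the tests against closed-form ANOVA
estimators in the balanced case, against `lme4` for homogeneous fits, and
against `nlme` with `varIdent` for year-heterogeneous fits.

## Three-step quality control

**Step 1 — plausibility.** `plausibility_rules()` is a configurable rule
engine; defaults encode autumn-sown hexaploid winter wheat: allowed taxa,
sowing window (early September to mid-December), and physiological trait
bounds (FT in day-of-year 100–220, PH 20–250 cm, TGW 5–80 g). Institutional
rule sets differ, so the engine takes precedence over any particular
default; each dropped record carries the first violated rule id, and the
pass is idempotent.

**Step 2 — record-level outliers.** Studentized residuals from the BLUE-mode
fit are referred to the standard normal; two-sided p-values are corrected by
the Bonferroni–Holm step-down across all records of the trait, at a
familywise level of $\alpha = 0.05$ by default ($\alpha$ is not dictated by
the method; 0.05 is the conventional choice and configurable). Flagged
records are removed and the model is refit **once** — the single-pass
design reflects that repeated re-testing after removal changes the testing
family; an iterated mode exists behind `iterate = TRUE` but is off by
default. Under a clean null the stage flags anything at all in well under 5%
of datasets (it inherits the conservatism of Holm and of leverage-corrected
scaling).

**Step 3 — year-level screening.** Years can go wrong wholesale (a storm, an
epidemic); record-level tests are blind to this because a year-specific
residual variance simply absorbs the damage. Two statistics are combined:

* the coefficient of variation of the year-specific error,
  $CV_j = \sqrt{\sigma^2_{e^*j}}/YE_j$, where $YE_j$ is the year-level
  expected trait value. The printed formula this implements is ambiguous
  between $\sigma^2/YE$ and $\sqrt{\sigma^2}/YE$; the SD-based form is used
  because a coefficient of variation conventionally relates a standard
  deviation to a level, and the year-flagging test below is invariant to
  the choice (both forms rank the same year first);
* a **weather-parameter index**: forward stepwise regression (smallest AICc,
  admitting a term only when it improves AICc by at least `delta = 2`, at
  most one term per five years and never more than $n_\text{years} - 2$
  terms) of the year effects on standardized monthly weather variables
  (every month × variable pair is a candidate; candidates with missing
  years are excluded rather than imputed). A linear calendar trend is
  removed from the year effects first — a secular trend is not a weather
  signal, and leaving it in lets spurious weather terms absorb it. The
  fitted combination evaluated per year is the index $W_j$.

A year is excluded only by the **conjunction rule**
(`flag_outlier_years()`): its CV exceeds `k_cv = 2` times the mean CV of the
other years *and* its index deviates from the other years' mean by more than
`k_w = 3` of their standard deviations. The conjunction formalises the
judgment that a noisy year is only removed when the weather record
corroborates an anomalous season; either signal alone leaves the year in the
data. The thresholds are configuration, not constants — the documented
historical case they are calibrated against showed a CV inflation of ~2.8×
and an index anomaly of ~4 SD, both clearly beyond these defaults.

`qc_pipeline()` chains the three steps, re-estimates the variance
components after the final removals, and reports per-step counts, fractions
(exact ratios of the reported counts), and heritability before and after.

## The synthetic-data generator

`simulate_historical()` draws from exactly the model the analysis assumes,
plus the contamination the quality control is meant to catch:

* accession effects $g_i \sim N(\delta_{o(i)}, \sigma^2_G)$ with origin mean
  shifts $\delta$; the default eight origins mirror the composition of the
  balanced 160-accession subset used in the resampling study
  (51:42:27:15:7:6:6:6), with shifts spanning about ±6 days on the FT scale
  — the order of magnitude of latitude-driven phenology differences between,
  say, Greek and Swedish material. The paper trail behind the method gives
  no numeric origin effects, so this is a package calibration choice, made
  once.
* year effects composed of a linear trend (default −0.27 days/year), a
  weather-driven component, and independent noise, scaled so the *total*
  year-effect variance equals `sigma2_Y`. The default weather model spreads
  its variance over four standardized monthly drivers (February maximum
  temperature, April/June rainfall, April humidity) and explains ~38% of the
  year-effect variance — a realistic share for a stepwise weather index, and
  one that leaves the index stage a recoverable signal of known strength.
* per-year residual variances drawn log-normally around `sigma2_e_mean`
  (dispersion 0.4 on the log scale by default).
* default second-degree calibration $\mu = 160$, $\sigma^2_Y = 72$,
  $\sigma^2_G = 15.6$, $\bar\sigma^2_e = 6.5$ — the flowering-time values of
  a large winter-wheat collection — over 70 regeneration years, with 3–6
  observed years per accession (~94% of cells empty).
* an optional **disaster year** (`bad_year`): residual variance inflated
  8-fold, a 4-SD anomaly on *all* weather drivers aligned in the damaging
  direction, and an additional year-effect shift of −2 SD beyond the linear
  weather path. The multi-driver anomaly plus extra damage emulates an
  epidemic-style event (extreme weather triggering disease that devastates
  the trait) — the situation the conjunction rule exists for. A disaster
  clearly inside the detectable region is simulated deliberately: the
  acceptance checks verify that the machinery fires when both signals are
  present, not the rule's marginal receiver characteristics.
* optional gross outliers: a configurable fraction of records shifted by
  ±`magnitude` residual SDs, with truth flags returned.

What the generator does **not** emulate: genetic architecture (no markers,
no QTL), genotype × year interaction (the historical model has none), spatial
field structure, non-random (NMAR) regeneration decisions such as
germination-triggered regrowing, and serially correlated weather. Tests
passing on this generator therefore demonstrate that the pipeline recovers
the truth *under its own assumptions* and detects the modelled contamination
— not that real historical data satisfy those assumptions.

## The missing-pattern study

`run_scenario()` starts from a complete accession × year reference dataset,
repeatedly applies one of three observation schedules — blocks of accessions
sharing their observed years defined by origin (A) or drawn at random with
the same sizes, re-randomized each replicate (B), or fully independent
per-accession year subsets (C, MCAR) — refits the model, and summarises bias
and the replicate SD of each estimate against the full-data reference fit
(the reference is the full-data fit, not generator truth, so the study
isolates the effect of the missingness pattern; generator truth is available
separately when the input is synthetic). Replicates that fail to converge
are recorded and skipped; the run errors if more than 5% fail. Year subsets
per block are sampled without coverage constraints, with a warning when the
block count cannot cover all years.

Under origin mean shifts, scenario A confounds origins with year subsets and
inflates the replicate SD of $\hat\sigma^2_G$ well beyond C, with B in
between (B's inflation stems purely from block-shared year subsets and is
the smallest of the three gaps). Zeroing the origin shifts collapses A to B
— the causal-mechanism check. On bias, all three scenarios are nearly
unbiased for the reference fit, which is the expected behaviour of REML
under MCAR/MAR-type schedules.

## Post-estimation summaries

* `correlate_blues()` — Pearson/Spearman agreement of two BLUE tables over
  their common accessions (e.g. historical vs validation estimates).
* `normalized_rank_product()` — the rank-based comparator: within-year ranks
  scaled to (0, 1], aggregated across an accession's years by geometric mean
  (arithmetic on request). The construction is reassembled from its name —
  the originating study does not print the formula — so it is deliberately
  configurable; it exists to demonstrate the contrast with BLUEs (rank
  aggregation discards scale information and saturates at the extremes).
* `temporal_trend()` — OLS slope of year effects on calendar year (negative
  = earlier flowering over time).
* `panel_variance_ratio()` — genetic-variance and BLUE-range ratios between
  a panel and a reference collection, as percentages.

## Problem sizes used in tests and the acceptance script

Simulation-based checks run at sizes chosen to give each check sharp
resolution while keeping a full run comfortably interactive: parameter
recovery at 1,000 accessions × 70 years (≈5,000 records) over 10–20 seeds;
the null familywise-error study on 300–1,000 small datasets of 300 records;
the resampling study at the 160 × 6 design with 100 replicates per scenario;
disaster-year detection at 200 accessions × 63 years; the full-pipeline
heritability check over 20–50 seeds. The collection-scale defaults of the
generator (6,000 accessions) are used where only data structure matters,
not model fitting. The engine's dense mixed-model-equation solve is
comfortable up to a few thousand fixed-plus-random levels; collections far
beyond that would need the absorbed/sparse-inverse route that dedicated
mixed-model software uses, which is out of scope here.

## Known limitations

* The engine targets the model family above; general covariance structures
  (AR1 years, factor-analytic G×E) are out of scope.
* Studentized residuals are leverage-corrected conditional residuals, not
  exact case-deletion residuals; their null calibration is verified by
  simulation, not proved.
* The weather index is an in-sample descriptive regression; with few years
  and many candidate month × variable pairs it must be read as
  corroborating evidence (which is how the conjunction rule uses it), not
  as a predictive model.
* CV-based year screening requires the trait level $YE_j$ to be positive —
  true for FT/PH/TGW scales; traits centred near zero would need a
  different denominator.
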