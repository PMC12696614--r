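---
title: "Detecting and attributing water-related vegetation browning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and attributing water-related vegetation browning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegdry)
library(dplyr)
```

# The scientific problem

Widespread greening of the land surface has been observed since the 1980s,
but in some regions the greening has stalled or reversed. One candidate
explanation is water: declining water availability (soil moisture,
precipitation) and rising atmospheric water demand (vapor pressure
deficit) can constrain leaf area even while CO2 and temperature keep
rising. Because "drying" can be expressed through several partly
disagreeing variables, a robust analysis has to ask where *multiple*
water-related variables agree on drying, whether that agreement coincides
spatially with browning, and whether an independent statistical
attribution of inter-annual LAI variability points at the same water
variables.

`vegdry` implements that chain as composable tibble-based stages:

1. per-cell trend detection (`mann_kendall()`, `theil_sen()`,
   `grid_trends()`) and period-mean change testing
   (`bootstrap_change_significance()`, `grid_change()`);
2. derived water-demand variables (`compute_vpd()`,
   `compute_dryness_index()`) and the 2-of-4 drying agreement
   (`classify_drying()`);
3. greenness categorization under a decadal LAI study mask
   (`classify_greenness()`), coincidence mapping (`coincidence_map()`),
   cosine-weighted area statistics (`area_fraction()`,
   `browning_drying_summary()`) and Cramér's V correspondence
   (`cramers_v()`);
4. per-cell driver attribution (`attribute_cell()`, `attribute_grid()`)
   via all-subsets regression, AIC model ensembles, LMG variance
   partitioning and Akaike weighting;
5. ensemble voting across model-like members (`modal_trend_category()`,
   `drying_model_fraction()`, `modal_dominant_driver()`,
   `multimodel_mean_summary()`);
6. pipeline orchestration with serializable, hashed configurations
   (`run_config()`, `run_observational_pipeline()`,
   `run_ensemble_pipeline()`, `run_demo()`).

The pipeline runners, stage functions and this vignette are the package's
interface; maps are tidy tibbles persisted as CSV, so any stage can be
inspected, filtered or re-entered with ordinary dplyr verbs.

# Models and procedures

## Trend machinery

The Mann–Kendall statistic is $S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$
with tie-corrected variance
$\mathrm{var}(S) = \big[n(n-1)(2n+5) - \sum_k t_k(t_k-1)(2t_k+5)\big]/18$,
continuity-corrected deviate ($z = (S-1)/\sqrt{\mathrm{var}(S)}$ for
$S>0$, $(S+1)/\sqrt{\mathrm{var}(S)}$ for $S<0$) and a two-sided normal
p-value. Significance uses $\alpha = 0.1$ by default: annual series of
20–39 values with large natural variability rarely clear stricter
thresholds, and the downstream drying definition already demands
multi-variable agreement. The Theil–Sen slope (median of pairwise slopes)
is reported as the robust trend magnitude; the test itself never uses it.

Aridity-like long-term change is tested differently: the mean of the
second half minus the mean of the first half, compared against a null of
300 random re-partitions of the pooled values into pseudo-halves of the
original sizes (drawing without replacement; a flag switches to
with-replacement resampling). The observed difference is significant
outside the 10th–90th percentile band, so the null calibration is 20%
by construction. We chose the permutation (without-replacement) form as
the default because it tests exchangeability of years directly; for mean
differences the within-half ordering is irrelevant.

## Drying classification

Four water variables define drying: root-zone soil moisture and
precipitation flag drying on significant *decreasing* trends, VPD and the
dryness index on significant *increasing* trends. A cell dries when at
least 2 of 4 agree; a sensitivity variant ignores significance. VPD uses
the Magnus form $e_s(T) = 0.6108\exp(17.27T/(T+237.3))$ with the actual
vapor pressure evaluated at the dew point. With the 0.6108 coefficient
both pressures are in kPa; an optional flag rescales to Pa. Trend signs
and significance are invariant to that unit choice. The dryness index is
net radiation over energy-equivalent precipitation,
$R_n / (\lambda P)$ with $\lambda = 2.45\,\mathrm{MJ\,kg^{-1}}$ and
annual precipitation (mm yr$^{-1}$ = kg m$^{-2}$ yr$^{-1}$) converted to
W m$^{-2}$ over a Julian year; the conversion constant only scales the
index, never its trend direction.

Cells are excluded from the study area when the decadal mean LAI drops
below 0.5 in any decade window (default: calendar decades covering the
data years) — sparse vegetation makes LAI trends uninterpretable.
Unmasked cells are classed by Theil–Sen slope sign crossed with
Mann–Kendall significance; an exactly zero slope ties to nonsignificant
greening so the map keeps four categories. Area fractions weight cells by
the cosine of their center latitude, the exact relative area of
equal-angle grid cells.

## Driver attribution

Per cell, annual LAI is modeled as
$y = \beta_0 + \beta_1 x_1 + \dots + \beta_n x_n + \epsilon$ over ten
predictors: annual means of soil moisture, precipitation, VPD,
temperature, net radiation, shortwave radiation, tree cover and crop
fraction, plus the annual minimum of monthly soil moisture and the annual
maximum of daily temperature as drought/heat-wave proxies. Predictors are
normalized by their column maxima, which makes importances invariant to
positive rescaling of any raw predictor and is the reason temperatures
must arrive in Kelvin — for nonnegative data the map lands in (0, 1],
while a nonpositive maximum would make it meaningless, so such columns
are rejected with a unit-conversion hint.

All $2^{10}$ predictor subsets are fitted by OLS and ranked by
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ ($k$ counts intercept, slopes
and residual variance; this equals `stats::AIC` up to an additive
constant that cancels in all comparisons). Collinearity is handled by the
ranking itself: overlapping predictors buy little likelihood for their
extra parameters. The model ensemble keeps subsets with
$\Delta\mathrm{AIC} < 2$ (strict) *and* adjusted $R^2 > 0.36$ (strict), a
floor chosen between the 0.26 and 0.4 benchmarks common in ecological
regression. AIC is the default despite $n \le 39$; AICc is available as
`ic = "aicc"` since the small-sample correction can reorder models at
these lengths — we expose rather than silently impose it.

Within each selected model the $R^2$ is partitioned by the
Lindeman–Merenda–Gold metric: the average over all orderings of a
predictor's sequential $R^2$ gain, computed exactly via the
subset-size-weighted sum over subsets. Because every subset's $R^2$ is
already available from the all-subsets pass, LMG shares cost only the
combinatorial summation. Importances are then averaged over the ensemble
with Akaike weights; a predictor absent from a model contributes zero
there (a flag renormalizes over containing models instead, for
sensitivity). The single-model single-predictor special case — that
predictor is dominant with importance equal to its $R^2$ — falls out of
the weighted average automatically. Ties for dominance are declared
within an absolute tolerance of $10^{-9}$, tight enough that only exact
symmetry (e.g. duplicated information) triggers it. The water-variable
rank map uses {soil moisture, precipitation, VPD} as the water set by
default; the annual soil-moisture minimum can be added via
`water_vars` if one prefers to count drought extremes as water.

## Ensemble voting

Member maps are summarized per cell by counting: the modal greenness
category over members with data (a member's own LAI mask applies first),
requiring data from at least 5 members; the fraction of members
simulating 2-of-4 drying, relative to members with data rather than the
full ensemble so masked members do not dilute the signal; and the modal
dominant driver, flagged low-agreement below 3 agreeing members, with
exact count ties a distinct status. Voting happens per member *before*
aggregation — categories from a multi-model-mean field would answer a
different question.

# The synthetic-data generator

Every field is baseline + linear trend + stationary AR(1) noise,
initialized from the stationary distribution
($\sigma/\sqrt{1-\phi^2}$) so there is no burn-in; rectangular lat/lon
boxes can override trends (last listed wins). Defaults
(`default_driver_specs()`) describe a humid tropical-to-temperate cell:
soil moisture 0.30 (sd 0.02, $\phi$ 0.3), precipitation 800 mm yr⁻¹ (sd
50), VPD 0.8 kPa (sd 0.05), temperature 288 K (sd 0.3), net/shortwave
radiation 120/200 W m⁻², tree/crop cover 0.5/0.2 (sd 0.01, $\phi$ 0.5
for land-cover persistence). Sub-annual series are not simulated: the
annual extremes enter the analysis only as annual aggregates, so they are
generated directly as the parent mean minus/plus a strictly nonnegative
offset field, which guarantees min ≤ mean ≤ max by construction and
yields the realistic strong correlation between a mean and its extreme.
Each variable draws from its own sub-seed, so regenerating or editing one
never perturbs another. LAI is a known linear response to the
divide-by-max-normalized drivers plus iid noise, clipped at zero with a
count of clipped cell-years.

The generator emulates the *structure* of satellite/reanalysis products —
annual resolution, per-cell trends, serially correlated interannual
noise, driver-coupled LAI — but not their failure modes: no orbital-drift
artifacts, no cloud/quality-flag gaps, no spatially correlated noise, no
nonlinear or lagged vegetation responses, and the AR(1)+trend noise model
is a stand-in whose parameters are user-set, not calibrated to any real
product. Passing tests therefore demonstrate correctness and calibration
of the *method* under known ground truth, not performance on real
observations.

# Study conditions and problem sizes

The demonstration study (`default_grid()`, `simulate_study()`,
`run_demo()`) uses a 20 × 30 cell grid over 1982–2020 (39 years, split
1982–2001 / 2002–2020) with 7 ensemble members — a desk-scale mirror of a
multi-decadal global analysis. The forced truth box (lat 0–15, lon 0–30,
50 cells) imposes soil-moisture (−0.004 yr⁻¹), precipitation
(−10 mm yr⁻¹) and VPD (+0.01 kPa yr⁻¹) trends, roughly 4 noise standard
deviations per 20-year half so per-variable detection is near-certain
while leaving the out-of-box false-positive machinery of a 10% test
intact; the dryness index dries through the precipitation decline. LAI
couples to normalized soil moisture ($\beta = 2$, noise sd 0.05), so the
box browns and the attribution truth is soil moisture. A southern strip
has its LAI intercept set to 0.2 to exercise the decadal study mask.
Calibration experiments use 10,000 replicates (Mann–Kendall type-I error,
bootstrap null rate), oracle comparisons 200–1,000 random cases, and
recovery experiments 24-cell grids per predictor with LAI noise at 20% of
the signal standard deviation. The split-year default follows the figure
convention 1982–2001 / 2002–2020; it is configurable.

# Numerical choices, degenerate inputs, limitations

- Fully tied series get $\mathrm{var}(S) = 0$ and are reported as
  $z = 0$, $p = 1$, never as a division by zero.
- Cells with fewer than 10 valid years (or 4 for a bare test) are
  reported missing rather than tested; attribution requires 12
  observations.
- Rank-deficient predictor subsets are skipped (not pseudo-inverted) so
  AIC stays comparable across subsets; zero-variance columns are dropped
  before the search; the intercept-only model is a candidate that anchors
  $\Delta\mathrm{AIC}$ but can never pass the adjusted-$R^2$ floor.
- Exact-fit subsets (RSS numerically zero) are floored at machine level
  inside the log-likelihood, so a perfect fit ranks best instead of
  producing `-Inf` arithmetic.
- Zero-precipitation cells make the dryness index undefined and are
  counted, as are clipped super-saturated VPD inputs and clipped negative
  synthetic LAI values.
- Cramér's V on a degenerate table (one observed category on either
  side) is `NA` with a warning, not 0.
- Known limitations: no prewhitening variants of the trend test and no
  field-significance/multiple-testing control (per-cell $\alpha$ only);
  no drought indices beyond the dryness index; no CO2, nutrient, snow or
  lagged predictors in the attribution; equal-angle cosine weighting
  assumes regular grids.

# A compact end-to-end run

```{r demo, eval = FALSE}
g    <- grid_spec(seq(0, 12, by = 3), seq(0, 15, by = 3), 1982:2020)
scen <- simulate_study(seed = 1, grid = g, n_members = 5,
                       box = list(lat = c(6, 12), lon = c(0, 9)))
cfg  <- run_config(seed = 1, min_models = 4, min_agree = 3)

obs <- run_observational_pipeline(scen$drivers, scen$lai, cfg)
ens <- run_ensemble_pipeline(scen$members, cfg)

autoplot(obs$coincidence_second)
co <- dplyr::left_join(scen$truth_cells, obs$coincidence_second,
                       by = c("lat", "lon"))
jaccard_index(co$in_box, co$category == "browning_and_drying")
```

`run_demo(seed, out_dir)` performs the full-size version of this run
(both pipelines on the 20 × 30 grid with 7 members), writes all artifacts
and a `report.json` with the recovery metrics, and is bit-reproducible
for a fixed seed.
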