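---
title: "Degree-day cohort demography for insect mass rearing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day cohort demography for insect mass rearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortDD)
```

## The problem

Inundative biological control needs mass rearing: many healthy,
reproductive individuals of a natural enemy, produced predictably and
cheaply. The assassin bug *Zelus renardii* (the Leafhopper Assassin Bug) is
a candidate predator of *Xylella fastidiosa* vectors, and rearing trials
compare live prey (*Drosophila melanogaster*, labelled `Dm`) against
artificial diet formulations (`D0`–`D4`, spanning oligidic, meridic and
holidic recipes). Two questions drive the analysis this package implements:

1. **Demography** — does a cohort reared on a given diet survive, reproduce
   and grow? This is answered with stage-structured cohort life tables and
   a brood-to-brood population trend.
2. **Phenology** — how much physiological time does development cost on
   each diet? Because insects are ectotherms, calendar durations depend on
   the temperature trace; accumulated degree-days (ADD) put all cohorts on
   a common physiological clock and let one project generations per year at
   any rearing temperature.

The package is organised as an analysis workflow (`analysis/01…05`) over a
set of tested building blocks: rearing-log and temperature I/O, the
degree-day engine, life-table construction, the diet-comparison statistics,
and a seeded synthetic-cohort generator.

## The degree-day clock

Each calendar day contributes

$$\mathrm{ADD} = \sum_{\text{days}} \max\!\left(0,\;
  \frac{T_{\max} + T_{\min}}{2} - T_{\mathrm{base}}\right)$$

with $T_{\mathrm{base}} = 15\,^\circ$C, the species' lower developmental
threshold. This is the simple-average ("Method 1") degree-day estimator
with negative contributions clipped to zero. Under the modelled laboratory
regime (18–25 °C) the daily mean never drops below the threshold, so
clipping is observationally neutral there — but it is fixed as a contract
(`dd_params(clip = TRUE)`) so the engine behaves sensibly on colder traces.
No upper developmental threshold is applied and no sine-wave or hourly
interpolation is attempted; events are recorded daily, so sub-daily
resolution would be spurious precision.

**Interval convention.** Accumulation is over half-open date intervals
$[\text{entry}, \text{exit})$: the molt day's heat belongs to the stage
being entered. The original analysis does not state its convention; the
half-open choice is applied uniformly, which makes per-stage ledger entries
add exactly to the biofix-to-death total (a property the tests assert).

**Biofix.** Accumulation starts at oviposition (`date_EG`). Because
"cumulative ADD up to the adult" can be read with or without the egg
stage, `cumulative_add()` exposes both (`from = "EG"` is the default,
`from = "N1"` the alternative reading).

## Cohort life tables

For a cohort of $N_{EG}$ eggs followed through stages
$EG, N1, \dots, N5, AD$, with $N(x)$ individuals entering stage $x$:

* $l_x = N(x)/N_{EG}$ — fraction surviving from cohort start;
* $p_x = N(x{+}1)/N(x)$ — period survival ($p_{AD} = 0$: the adult stage
  is terminal in a single-cohort table);
* $q_x = 1 - p_x$ — period mortality;
* $d_x = l_x - l_{x+1}$ — fraction of the original cohort dying in the
  stage ($d_{AD} = l_{AD}$), so $\sum_x d_x = 1$;
* $e_x$ — expectation of life in degree-days: the mean ADD accumulated
  between entry into stage $x$ and death, over the individuals that
  entered $x$. The published one-line definition ("average ADD value per
  survived individual") is ambiguous; this definition is fixed by the
  structure of the published tables — $e_x$ decreases stage by stage, and
  $e_{EG} - e_{N1}$ is a constant 128 degree-days in all ten published
  cohorts, consistent with a fixed egg-stage heat requirement.

All ratios are computed from raw integer counts; rounding (half-up, two
decimals — the convention that reproduces printed values such as
$29/33 \to 0.88$ and $26/33 \to 0.79$) happens only in
`render_life_table()`.

**Population trend.** $T$ = eggs in the subsequent brood / eggs in the
previous one ($T > 1$ growing, $= 1$ equilibrium, $< 1$ declining). $T$ is
computed from actually counted next-brood egg totals, not from mean
fecundity times female count — the published ratios ($338/33 = 10.24$,
etc.) confirm that reading. The per-diet mean trend averages the
*2-decimal-rounded* per-generation trends (`mean_trend(rounded = TRUE)`):
for four of five diets the raw and rounded conventions agree after
rounding, but the live-prey diet discriminates (raw averaging gives 11.42
where the published table prints 11.43), so the published-table convention
is the rounded one and the pipeline follows it.

**Errata.** Reconstructing every published survival cell from the count
columns alone succeeds for 275 of 280 cells. The five exceptions
contradict their own table's count column and are carried as flagged
errata in `zelus_reference_cells()`: one $d_x$ cell printed as 0 where
$l_x$ drops by 0.03; one egg row printed as $p_x/q_x/d_x = 1/0/0$ although
the same table shows one egg failing; and one egg row printed with
$p_x = 0$ (alongside $q_x = 0$, so $p_x + q_x \ne 1$) although all 33 eggs
hatch. The tests assert both the agreement of the other 275 cells and the
internal consistency of the recomputed values for these five.

## The comparison battery

Run per generation unless noted; all delegating to standard
implementations behind the module surface, except Games–Howell which is
coded from its closed form:

* **Sex ratio** — Pearson $\chi^2$ (no continuity correction) on the
  diet × sex table of adults; undetermined individuals excluded. The post
  hoc inspects standardized Pearson residuals, two-sided normal p-values,
  Bonferroni-adjusted over all cells. With five diets the homogeneity df
  is 4, matching the published analysis.
* **Mortality** — death before adult entry, out of the initial 33.
  Fisher's exact test on the full $r \times 2$ table, then all pairwise
  2×2 exact tests with Bonferroni adjustment.
* **Cumulative ADD** — Welch's ANOVA (heteroscedasticity is the rule for
  these data) and the Games–Howell post hoc:
  $q_{ij} = |\bar x_i - \bar x_j| / \sqrt{(s_i^2/n_i + s_j^2/n_j)/2}$
  referred to the studentized range with Welch–Satterthwaite df.
* **Per-instar ADD** — Kruskal–Wallis with tie correction, independently
  per instar.
* **Fecundity and hatch** — two-way ANOVA (diet, generation) with type-II
  sums of squares (robust to the unbalanced design left by a diet that
  fails in one generation), with Lilliefors residual normality and Levene
  homogeneity reported alongside.

Exact tests have discrete null distributions and are mildly conservative
at small counts; at the cohort sizes modelled here (33 per diet) the
realized size at $\alpha = 0.05$ stays within binomial sampling bounds of
the nominal level, which the calibration tests verify over 2000 simulated
null datasets per test.

## The synthetic-cohort generator

The trial's raw logs and temperature trace were never deposited, so the
generator is the package's data source. It emulates the study conditions:
33 individuals per diet per generation, two generations ~180 days apart,
a seasonal laboratory oscillating between 18 and 25 °C (sinusoidal annual
cycle, Gaussian daily jitter of 0.5 °C, truncated to stay above the
threshold and keep $T_{\min} \le T_{\max}$), per-stage mortality of 0–12%,
roughly balanced sexes except one female-skewed diet, ~26–29 eggs per
female and hatch above 96%.

Per-diet calibration anchors, taken from the published summaries and kept
in `zelus_cumulative_add_summaries()` / `default_diet_profiles()`:

* egg-to-adult ADD means per diet (1924–2332 degree-days; generation-1
  values where printed, the generation-2 value for `D0`, the only one
  printed);
* adult ADD budgets set to the published adult expectation-of-life column
  (489–1266 degree-days);
* per-stage mortalities equal to the first-generation life-table
  mortalities;
* fecundity means 25.45–26.92 (SD ≈ 3.6–6.5) eggs/female, +1.67 in the
  second generation (the published between-generation shift); hatch
  probabilities 0.96–0.98.

Structural choices:

* **Per-stage requirements are lognormal** with CV 0.30 — positive
  support and right skew matching the strong late-instar dispersion in the
  published data; summed over stages this yields cumulative SDs within the
  span of the printed ±SD values (176–467).
* **The egg stage needs 128 degree-days** for every diet — the constant
  $e_{EG} - e_{N1}$ gap noted above; an inference from the published
  tables, not a stated value. The nymphal shares of the remainder rise
  from 10% (N1) to 35% (N5), mirroring the reported instar ranking.
* **Mortality is a single Bernoulli draw at stage entry**, the minimal
  model consistent with life-table granularity; death falls uniformly
  within the stage.
* **Day quantization is unbiased**: development events are logged on
  whichever adjacent day's accumulated heat is nearest the drawn
  requirement. Always logging the first day that *exceeds* the requirement
  would overstate every realized stage duration by about half a day's
  heat (~1% of the egg-to-adult total over six stages), a systematic bias
  the parameter-recovery tests would inherit.
* **Seeds are explicit everywhere** (`with_seed()` scopes
  Mersenne-Twister state and restores the caller's), so identical
  config + seed reproduces a dataset bit-for-bit, and generated logs
  always pass `validate_rearing_log()`.

What the generator does **not** emulate: overwintering effects on later
egg batches (a known bias source in multi-brood rearing that has no
formal model here — the analysis restricts itself to first-batch
juveniles), genetic structure or inbreeding, prey dynamics, and
any diet × instar interaction beyond the per-stage means. Passing
recovery tests therefore show the pipeline is consistent with its own
generative assumptions, not that real rearing data satisfy them.

## The reference fixture

`zelus_fixture()` is a deterministic (non-random) rearing log whose stage
counts, next-brood egg totals, sex skews and the `D2` collapse equal the
published values; it is the acceptance surface for the life-table and
trend computations. Its calendar dates follow a fixed per-stage schedule
under a constant 18–25 °C series and are synthetic, so degree-day-derived
columns computed from it (notably $e_x$) are *not* reference values — the
published $e_x$ columns, cumulative-ADD means, fecundity summaries and
test statistics cannot be recomputed without the unpublished raw data and
serve only as calibration anchors and sanity envelopes. `D2`'s per-stage
death allocation is likewise synthetic (flagged in `zelus_counts()`):
only its start count and total collapse were published.

## Numerical choices and degenerate inputs

* Rounding: half-up at render time only, with a $10^{-8}$ absolute guard
  absorbing binary representation error on intended exact halves.
* Degenerate statistics: all-constant groups raise a degenerate-input
  error (Welch, fecundity ANOVA); a single constant group is allowed;
  instars observed in fewer than two diets are skipped with a warning;
  all-zero diet rows are dropped from contingency tables with a warning.
* Empty cohorts and increasing stage counts are rejected outright;
  a stage nobody reached has $e_x$ absent (`NA`), not zero.
* Trend with an empty previous brood is an error; an empty next brood
  gives $T = 0$ (declining), as for the failed diet.

## Problem sizes

The test suite simulates cohorts of 33 (the study design) for pipeline and
oracle checks, 200 random cohorts for life-table replay equivalence, 2000
null datasets per test for size calibration, and 500 individuals per diet
for parameter recovery; the whole suite runs in about a minute on one
core. These sizes are the package's chosen trade-off between Monte-Carlo
resolution and a fast feedback loop.

## Limitations

* The degree-day engine is deliberately minimal: no upper threshold, no
  sine-wave interpolation, no microclimate correction.
* $T$ is the only population-growth summary; intrinsic rate of increase,
  $R_0$ and Leslie-matrix projections are natural extensions left out of
  scope.
* The $e_x$ definition, the 128 degree-day egg requirement, and the
  molt-day convention are inferences fixed by published structure, not
  stated protocol; anyone with the raw logs could refute them.
* Published test statistics (e.g. the sex-ratio $\chi^2$ or the Welch F on
  the real data) are not reproduction targets: they depend on the
  unpublished individual-level data.
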