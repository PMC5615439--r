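---
title: "Day-to-day variability of energy balance components: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Day-to-day variability of energy balance components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebvar)
```

## The problem

Free-living energy expenditure, physical activity and energy intake all
fluctuate from day to day. For wheelchair users with spinal cord injury this
variability is compounded by practical constraints on monitoring: multi-sensor
devices are burdensome, weighed food diaries fatigue their keepers, and
cohorts are small. Two questions follow for anyone designing a monitoring
study in this population:

1. **How many days must an outcome be measured** before the average is a
   reliable characterisation of the person rather than of the week?
2. **Which nuisance factors** — device wear time, day of the week, the sheer
   accumulation of diary-keeping burden — **distort the measurements**, and by
   how much?

`ebvar` implements the full analysis chain for both questions on daily
subject-day records, plus a synthetic cohort generator with exactly the
statistical structure the analysis assumes, so every stage can be validated
by parameter recovery without access to any real cohort.

## Data model

The pipeline consumes two tables. The *subject table* carries per-person
covariates: age (years), sex, the vertebral level of the spinal lesion
(coded ordinally, C1 = 1 through S5 = 29, so a larger code means a lower,
more caudal lesion and typically more preserved function), and measured
resting metabolic rate (RMR, kcal/day). The *daily table* has one row per
subject-day: monitor wear minutes, day of week, the 1-based "day of entry"
order index, and the outcome columns — total energy expenditure (TEE),
physical activity energy expenditure (PAEE), physical activity level
(PAL = TEE/RMR), minutes of sedentary (<1.5 METs), light (1.5–2.9 METs) and
moderate-to-vigorous (≥3 METs) activity, total energy intake, and the
macronutrient percentage composition of intake. A minute-level MET epoch
stream can be collapsed into the wear and intensity-band columns with
`aggregate_epochs()`; non-worn minutes are treated as missing data, never as
sedentary time, so band minutes always partition wear minutes exactly.

### Valid days

A day counts as valid only when the monitor was worn *strictly more* than
80% of it — more than 0.80 × 1440 = 1152 minutes — so a day at exactly 1152
minutes is excluded. Both the fraction and the day length are arguments of
`filter_valid_days()`; the strict inequality is deliberate and tested.
Partially worn, non-valid days are dropped entirely rather than imputed.

### Energy components

`derive_components()` partitions TEE as RMR + DIT + PAEE, with diet-induced
thermogenesis fixed at 10% of TEE (the `dit_fraction` argument, should a
different convention be wanted) and PAEE as the remainder. The identity
RMR + DIT + PAEE = TEE holds by construction, and PAL = TEE/RMR. On a low
day, measured RMR can exceed 90% of TEE, making the derived PAEE negative;
such rows are flagged (`paee_negative`) but retained, because discarding
them would bias low-activity days out of the variance estimates.

## The reliability model

Every outcome is analysed on the natural-log scale, which makes the daily
noise approximately multiplicative and lets effects back-transform to
percents via $100(e^b - 1)$. `fit_variance_model()` fits, by REML through
`lme4`,

$$\log(y_{ij} + c) = \beta_0 + x_{ij}'\beta + u_i + e_{ij}, \qquad
  u_i \sim N(0, \sigma_b^2),\; e_{ij} \sim N(0, \sigma_w^2),$$

with a random intercept per subject and fixed adjustments for age,
injury-level code, daily wear fraction, sex, day of week, and the linear
order index. The single-day intraclass correlation is the between-subject
share of total variance,

$$ICC_s = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2},$$

and the number of days whose average reaches a target reliability $ICC_t$
follows from the Spearman–Brown prophecy formula,

$$N = \frac{ICC_t}{1 - ICC_t}\cdot\frac{1 - ICC_s}{ICC_s},$$

reported both as the real value and as its ceiling (days are whole; the
default target is the conventional 0.80 acceptable-reliability cut-off).
Plugging the real-valued $N$ back into the step-up formula
$N\,ICC_s/(1 + (N-1)ICC_s)$ recovers the target to machine precision, and
the test suite asserts exactly that.

Complementing the ICC, `intra_individual_cv()` reports day-to-day
variability on the raw scale: per-subject CV = 100 × sample SD across the
subject's valid days / subject mean, summarised across subjects by the mean
with a 95% t-interval. For a lognormal outcome with within-subject log SD
$\sigma_w$ the population CV is $100\sqrt{e^{\sigma_w^2} - 1}$, which is the
closed form the generator tests recover.

### Choices worth knowing about

* **Offsets for zero days.** MVPA minutes and alcohol percentage are zero on
  real days, and the log needs $y + c > 0$. The default policy
  (`default_offsets()`) adds $c = 1$ unit for those two outcomes and 0
  elsewhere; it is configurable because no single convention is canonical.
* **Adjusted-model ICC.** The ICC is taken from the covariate-adjusted
  model's variance components — the same models the covariate effects come
  from — so the "reliability" being extrapolated is that of the outcome net
  of the known fixed effects. Passing `covariates = character(0)` gives the
  unadjusted decomposition, which on balanced data reproduces the one-way
  ANOVA estimators $\hat\sigma_w^2 = MS_w$,
  $\hat\sigma_b^2 = (MS_b - MS_w)/k$ to within the REML convergence
  tolerance; the tests verify this equivalence at 1e-6.
* **Degrees of freedom.** Inference on fixed effects uses a conservative
  between–within approximation, $df = n_{obs} - p - n_{subjects}$, applied
  consistently in the contrasts, intervals and the MBI engine below.
* **Degenerate fits.** A REML between-variance of zero makes the prophecy
  formula diverge; such outcomes are flagged `unreliable` (no finite number
  of days achieves the target) rather than erroring the whole table. A
  prophecy value beyond the longest observed monitoring run is flagged
  `beyond_observed`, since extrapolation past the measured window loses
  precision.

## Magnitude-based inference

Statistical significance says little about whether an effect matters. The
MBI layer classifies each effect against a *smallest worthwhile effect*
(SWE) of 0.20 between-subject standard deviations on the log scale. With
effect estimate $b$, standard error $se$ and the residual $df$ above, the
probabilities that the true effect is substantially positive, trivial, or
substantially negative are central-t tail areas beyond $\pm SWE$. An effect
is **unclear** when the probabilities of crossing *both* thresholds exceed
5%; otherwise it is labelled with its most probable category and a
probabilistic qualifier (<0.5% most unlikely, 0.5–5% very unlikely, 5–25%
unlikely, 25–75% possible, 75–95% likely, 95–99.5% very likely, >99.5% most
likely). Boundary probabilities fall into the higher bin, and direction ties
break toward "trivial" — both conservative conventions, documented because
the published scale is ambiguous at its edges. The t distribution (rather
than the normal) is used deliberately: with ~30 subjects the extra tail mass
is honest.

Three contrast families are built on this engine:

* `covariate_effect()` — for numeric covariates, the change from a
  "typically low" (mean − 1 SD) to a "typically high" (mean + 1 SD) value,
  i.e. $2\,SD_x\,\beta$, which makes magnitudes comparable across covariates
  and invariant to units (tested); for sex, the male−female level difference.
* `order_effect()` — the linear day-of-entry drift accumulated across the
  week, $(n_{days}-1)\beta_{order}$, back-transformed to the percent change
  from day 1 to day 7. This is the diary-fatigue signal: intake reporting
  drifting downward as the week wears on.
* `day_of_week_effects()` — adjusted means per weekday (model predictions
  at covariate means, back-transformed), all 21 pairwise contrasts with
  unadjusted p-values (a Holm option exists but is off by default, mirroring
  how such tables are conventionally presented), and the
  highest-versus-lowest fitted day as a classified percent effect. The
  contrasts are computed directly from the coefficient vector and its
  covariance so the df policy stays consistent; the adjusted means agree
  with `emmeans` on the same model in the test suite.

## The synthetic cohort generator

`generate_cohort()` draws data from exactly the model the analysis fits:

$$\log y_{ij} = \mu + x_i'\gamma + d_{dow(j)} + \delta\,(j-1) + u_i + e_{ij}$$

with configured $\sigma_b$, $\sigma_w$ per outcome, optional log-scale
covariate effects, seven day-of-week offsets, and an order drift
$\delta = \log(1 + \text{drift}\%/100)/(n_{days}-1)$ that accumulates to the
stated weekly percent change. Covariates are drawn independently of the
random effects (tested), numeric covariates enter centred so $\mu$ stays the
grand log mean, and a single `set.seed(seed)` at entry governs every stream
in a fixed draw order, so one integer reproduces the cohort exactly.

`preset_paperlike()` ships the study conditions the package is validated
under: 33 subjects × 7 consecutive days; 18% female; age ~ N(44, 9²)
truncated to 22–61; lesion levels uniform over T1–L4; measured RMR
~ N(1481, 180²) kcal/day; ~96% wear on normal days with a 12% chance of a
low-wear day (40–80% wear, failing the validity cutoff) and 2% missing days,
which lands valid days in the observed 4–7 per-subject range. Within-subject
SDs are calibrated from published intra-individual CV magnitudes through the
exact lognormal identity (TEE 7%, PAEE 34%, sedentary 9%, light 46%, MVPA
97%, intake 26%, macronutrients 20–26%, alcohol 160%); between-subject SDs
are set so the implied single-day ICCs reproduce the observed reliability
ordering (TEE most reliable among expenditure outcomes, sedentary time
least; dietary fat least reliable overall). Energy intake carries a −15%
weekly order drift; alcohol is elevated on Friday/Saturday; sex and
injury-level effects on the expenditure outcomes are sized to the published
2-SD magnitudes (e.g. +12% TEE per 2 SD of lesion level). Because the
published record contains means, CVs and effect sizes but no per-outcome
between-subject SDs, the preset is an approximate calibration, not a
reconstruction.

Two structural compromises are deliberate. The three intensity-band
outcomes are drawn as independent lognormals and then rescaled
proportionally on days where their sum would exceed wear minutes, keeping
the partition invariant; the preset's sedentary mean (1150 min/day) sits
slightly below the published adjusted mean (1255) so the bands typically fit
inside a ~96% wear day. Macronutrient percentages are renormalised to sum
to 100, which slightly damps their configured CVs; moment-recovery tests
therefore use the unconstrained outcomes. The generator also draws PAL and
PAEE as outcomes in their own right rather than deriving them from the
generated TEE and a subject RMR, because each outcome's reliability is
analysed marginally; consistency of the derivation arithmetic is tested
separately through `derive_components()`.

What passing parameter-recovery tests on this generator shows is that the
*estimation machinery* is correct under the assumed model. It does not show
that real accelerometer or diary data satisfy the model — real MVPA has a
point mass at zero rather than a lognormal tail, real wear gaps are not
missing at random, and real macronutrient shares are compositional from the
start.

## Validation scale and numerics

Parameter-recovery checks run at 500 subjects × 7 days (ICC recovery within
±0.03 at nominal 0.2/0.5/0.8; order-drift recovery within ±2 percentage
points), the lognormal CV closed form at 500 × 25 days — the longer window
keeps the small-sample bias of the per-subject SD (the $c_4$ factor,
≈ −4% at 7 days) from contaminating a 5% check of the distributional
identity — and the REML/ANOVA equivalence on a balanced 5 × 4 grid at 1e-6.
REML estimation inherits `lme4`'s convergence machinery; variance components
are non-negative by parameterisation, and the ICC truncates a (moment-based)
negative between-variance at zero before forming the ratio. The prophecy
ceiling applies a relative 1e-9 guard so a floating-point hair above an
integer does not inflate the reported days.

## Limitations

* The random-intercept model admits no random slopes; if subjects truly
  differ in their weekday patterns or order drifts, $\sigma_w^2$ absorbs it.
* Spearman–Brown extrapolation far beyond the observed window (flagged
  `beyond_observed`) assumes day-to-day errors stay exchangeable over weeks.
* MBI as a framework has known critiques; the implementation here is the
  classification machinery, not a defence of it, and no Bayesian or
  equivalence-testing variant is provided.
* The generator's realism targets are calibrated from published summary
  statistics only and are labelled approximate throughout.
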