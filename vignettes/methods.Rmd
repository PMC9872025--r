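---
title: "Methods: maturation-referenced specialization and fitness development models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maturation-referenced specialization and fitness development models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hoopdev)
```

`hoopdev` asks whether early (pre-pubertal) specialization in basketball is
associated with better physical fitness or faster fitness development in
adolescence. This vignette documents the statistical machinery, the constants
it relies on, the synthetic cohorts used to validate it, and the numerical
choices behind the implementation.

## 1. Maturation and specialization referencing

Somatic maturity is estimated from stature and decimal age through the
sex-specific linear maturity-offset equations in the age-by-stature product:

* female: offset = −7.709133 + 0.0042232 · (age · stature)
* male: offset = −7.999994 + 0.0036124 · (age · stature)

with age in years, stature in cm, and the offset in years (negative =
pre-PHV). Age at peak height velocity is `aPHV = age − offset`. These
coefficients live in `maturation_config()` rather than in code so they are
auditable and replaceable; three published group-mean evaluations are kept as
regression tests.

Maturity status compares estimated aPHV against the meta-analytic reference
(11.9 y female, 13.9 y male): more than six months early → *early*, within
±0.5 y (boundary inclusive, the symmetric reading of "within plus/minus six
months") → *average*, more than six months late → *late*. Because the offset
equations lose validity away from PHV, only female U13 and male U13/U15
players are classified; everyone else is `not_classified`. The assessment
uses each player's **pre-season anthropometry of their first observed
season**, making maturity a player-level constant in the models; which
occasion the original protocol used is not documented, and pre-season is the
natural choice because descriptive reference values are pre-season values.
Classification uses point estimates; an optional CI-aware mode (demoting to
*average* whenever the difference interval implied by the reference CI
overlaps the tolerance band) exists but is off by default, since the
reference CIs describe uncertainty in the population milestone, not in the
player.

Specialization onset (self-reported age of exclusive, year-round,
coach-supervised basketball) is placed against the same milestones: before
the growth-spurt onset reference (9.4 y F / 11.1 y M) → *pre-puberty*;
between onset and aPHV references, **both boundaries inclusive** →
*mid-puberty*; after aPHV → *late-puberty*; missing → *unknown*. Ties at the
references are resolved into the closed mid interval — the sources say
"before/between/after" without fixing ties, and the closed-mid reading is the
symmetric one. Both boundaries are tested explicitly. The classifier applies
no rounding: it is a pure function of the stored onset value.

## 2. Fitness scoring

Each outcome (CMJ cm, line-drill s, yo-yo IR1 m) is z-scored against the
pooled mean and n−1 SD over *all* non-missing observations — all sexes, age
groups and occasions. The line-drill z is negated (lower time is better) and
the composite is the sum of the three. The pooling reference population is
not documented in the original protocol; pooling across the whole sample is
the only convention consistent with strongly negative composites for
younger/female cells and increasing composites with male age, and it is
flagged here as an assumption. Scoring new data against a fitted pipeline
reuses the stored means/SDs (no re-standardization). A missing component
makes the composite missing; no imputation occurs anywhere.

For modelling, outcomes and body mass are standardized by **two** SDs
(`standardize_2sd()`), so coefficients of binary indicators (sex, phase) are
directly comparable with those of continuous covariates; the scaling record
(center, 2·SD) is stored with every fit for exact back-transformation.

## 3. Model structures

**Within-season model** (per outcome): Gaussian likelihood on the 2-SD
standardized outcome with population terms intercept, `phasemid`, `phaseend`
(treatment indicators against the pre-season baseline — two indicators rather
than a linear trend, because seasonal change need not be monotone), `sexmale`
and sex-by-phase interactions. Group-level blocks enter additively
(cross-classified, not nested), each coefficient with its own SD: player
(intercept + both phase slopes), season year (intercept),
specialization×sex, age-group×sex, and maturity×sex (each intercept + phase
slopes). `unknown` and `not_classified` are retained as ordinary levels and
are partially pooled. For yo-yo IR1 and the composite, 2-SD standardized
body mass is a population covariate (body size drives long-duration
intermittent performance); the short-term maximal outputs carry no body-size
term. Each outcome's design uses every row with that outcome observed — no
listwise deletion across outcomes.

**Growth model** (per outcome): population intercept, centered age, age²,
sex, and sex×age; intercept/age/age² varying by player (level 2) and by
specialization-onset category (level 3). Age is centered at 14.0 y — the
midrange of the 11–17 y observation span — to decorrelate the linear and
quadratic terms; the constant is recorded in the spec. Sex enters as a
population term (the original description is sex-faceted but silent on the
term; including it is flagged as an assumption here).

**Priors**: independent normal(0, 5) margins per population coefficient
(reading "multivariate normal (0,5)" as independent margins — no off-diagonal
structure is documented), exponential(rate 1) on every group SD, half
Student-t(3, 0, 2.5) on the residual SD. Group-level coefficients are
modelled as independent within a block (diagonal covariance). A correlation
prior over jointly varying intercept/slope blocks would be the conventional
companion, but the chosen backend has no native prior over correlation
matrices, and the scaled-Wishart workaround would silently replace the
exponential SD priors; keeping the documented priors exact was judged more
important than modelling a correlation the data (8–16 levels per contrast
block) could barely inform.

## 4. Sampling, parameterization and diagnostics

Models are fitted with JAGS (Gibbs/slice sampling) via `rjags`; the backend
identity is recorded in every fit. Defaults: 4 chains × 10,000 iterations
with 1,000 warm-up (adaptation + burn-in), so 9,000 kept draws per chain.
This is longer than a gradient-based sampler would need: Gibbs moves one
conditional at a time and mixes more slowly per sweep, and the default
length is what meets the package's convergence contract (below) on
cohort-sized fits. Chains are seeded deterministically from the settings
seed; identical seed + settings + data give bit-identical draws.

Each group coefficient is parameterized either **centered**
(`u ~ N(0, sd)`) or **non-centered** (`u = sd·z`, `z ~ N(0,1)`). The
non-centered form is essential for weakly identified coefficients (phase
slopes, small contrast blocks, SDs near zero), where the centered form
funnels; the centered form is essential where the data strongly inform the
level effects (age-group and maturity cell intercepts, the growth model's
player intercepts), where the non-centered form couples `sd` and `z` and
random-walks. The per-coefficient defaults in `season_model_spec()` and
`growth_model_spec()` encode exactly this rule.

`diagnostics()` computes rank-normalized split-chain Rhat and bulk effective
sample size (Geyer-truncated multi-chain autocorrelation) from the stored
draws only, and passes a fit when every parameter has Rhat < 1.01 and
ESS > 400 (both configurable). Divergent transitions do not exist for Gibbs
samplers, so the report's divergence count is `NA` with a note. On occasion a
single small-block SD in the composite-outcome model hovers near Rhat ≈ 1.01
at the default length; running longer chains resolves it.
`posterior_predictive_check()` simulates replicate data sets from the full
fitted linear predictor plus residual noise and reports tail probabilities
for the observed mean, SD and per-group means.

Numerical edge cases: an exactly degenerate likelihood (zero residual
variance) is outside the backend's support — the log density of a point mass
cannot be evaluated — and a near-degenerate posterior (residual SDs below
about 10⁻³ of the outcome scale) makes the Gibbs chain crawl. Noise-free
validation scenarios therefore use a numerically negligible residual of
10⁻², roughly 0.03% of the outcome's scale and far inside the 1% recovery
tolerance they are checked against. Zero-variance outcome
columns, missing mandatory columns and non-finite outcomes are rejected with
named errors before sampling.

## 5. Posterior surfaces

`predict_expected()` evaluates the posterior of the *expected* outcome (the
linear predictor) over the factor grid — sex × specialization × phase, or
sex × specialization × age — with other group levels held at the population
line and standardized body mass at 0 (the pooled mean). Ribbons are central
68% intervals (16th–84th percentiles, comparable to ±1 SD). These are
epistemic ribbons for group means, not posterior-predictive ribbons for new
observations: the displayed uncertainty is the uncertainty of the expected
group trajectory. `contrast_specialization()` differences the expectation
draws pair-wise per draw, preserving posterior correlation, and reports 68%
and 90% intervals and the posterior probability of a positive difference on
the standardized and natural scales (differences back-transform through the
scale factor alone). All summaries are pure functions of stored draws.

## 6. The synthetic cohort generator

`simulate_cohort()` generates cohorts with the structure the models assume,
with every generating parameter exposed in `sim_config()` and echoed in a
ground-truth record named like the fitted parameters. Defaults describe a
cohort of 181 players (40 female / 141 male) enrolled across the 2015–2019
seasons, one or two consecutive seasons each, with phase-completion
probabilities (0.65/0.90/0.55) that reproduce the imbalanced ~500-observation
design with mid-season best attended.

* **Stature** follows a monotone logistic curve parameterized by adult
  stature, aPHV and a tempo parameter — the simplest monotone family with an
  identifiable PHV; per-player aPHV is drawn around the reference milestones
  (11.9/13.9 ± 0.5 y). Adult stature, spurt span and tempo (169/22/1.2
  female, 188/28/1.1 male) were chosen once so that pre-season cell means
  sit within one published SD of the descriptive reference cells.
* **Body mass** scales allometrically with stature
  (20.2 · (stature/100)^2.2 · lognormal noise). Anthropometric technical
  errors (0.25 cm, 0.42 kg) are added as measurement noise.
* **Fitness outcomes** are a deterministic mean function — sex-specific
  intercept at age 14 and linear age slope, sex-specific phase effects
  (females improve modestly across the season, males maintain), plus
  specialization and maturity effects in pooled-SD units (defaults zero, the
  null) — plus player intercept and phase random effects, a season-year
  effect and residual noise, calibrated once to the published pre-season
  cells. The mean function uses the player's *season-baseline* age, not the
  occasion age, so that the configured phase effects are exactly the
  estimands of the season model's phase terms; chronological age itself
  advances normally in the records. Outcomes are recorded with realistic
  granularity: CMJ to 1 cm, line drill to 0.01 s, yo-yo to the 40 m shuttle.
* **Specialization onset** is drawn from a mixture over the four categories
  (≈46/33/7/14%), given a value inside the implied age window, rounded to
  0.5 y as self-reports are, then re-categorized with the same
  classification rule the analysis uses — so injected effects always target
  the analysed label, and rounding can shift boundary draws between
  categories (which slightly reshapes realized frequencies, as real
  self-reports would).
* `inject_specialization_effect()` shifts one category's mean function by
  `effect_size × pooled_sd_ref` on every outcome. The per-outcome
  `pooled_sd_ref` constants (6.0 cm, 2.7 s, 368 m) equal the generator's own
  null-cohort pooled SDs measured at large n, which is what makes
  "effect_size in pooled-SD units" literally true by construction.

What the generator does **not** emulate: within-player correlation between
outcomes beyond shared player effects, informative (non-random) dropout,
maturity-dependent fitness physiology (maturity categories exist but default
to zero effect), multi-sport participation histories, and real measurement
artifacts such as learning effects. Passing recovery tests therefore shows
the estimator recovers effects under the assumed structure with realistic
sizes and imbalance — not that the structure is true of real data. No
within-player correlation estimates were available to calibrate variance
components; the defaults (e.g. player intercept SD 3 cm vs residual 2 cm for
CMJ) are chosen for testability and documented as non-estimates.

## 7. Validation strategy and problem sizes

The test suite validates the loop simulate → classify → score → fit →
contrast end to end, at sizes chosen to keep the default run practical on a
single CPU: dense-grid oracle equivalence for both classifiers (10⁴ points
including exact boundary ties); composite-score identities on 100 random
tables; 20 null cohorts at study size fitted at 4 × 1,000 iterations with
all pre/mid/late contrast 90% intervals checked for zero coverage (≥ 80% of
replicates must cover — the computational analogue of "no substantial
variation by onset of specialization"); a 300-player cohort with a +0.5
pooled-SD pre-puberty effect recovered by the male pre-vs-mid contrast
within ±0.15 (the late-puberty cell at its natural 7% share is too small at
n = 300 for that pairwise contrast to be a meaningful check — its own
sampling noise exceeds the band); quadratic growth-curve recovery
(noise-free within 1%, noisy within 3 Monte-Carlo SEs); convergence of
default fits; and bit-identical reproduction under identical seeds.

## 8. Known limitations

* The offset equations are biased at the extremes of the age range; no
  numeric correction is published, and none is applied — the applicability
  rule (not-classified outside the near-PHV groups) is the mitigation.
* Two variance components of the season model are structurally
  unidentifiable at the study's dimensions regardless of sampler: the player
  phase-slope SDs (one observation per player-phase, slope variance ≪
  residual variance) and the season SD (five season levels). Their
  posteriors are prior-influenced; they are retained in the model for
  partial pooling, not for estimation, and recovery is not asserted for
  them.
* Group-level intercepts and slopes are independent within blocks; any true
  intercept-slope correlation is absorbed into the residual structure.
* The composite's pooled-z construction makes its scale sample-dependent;
  composite values are not comparable across data sets scored with
  different scalings (hence the stored scaling records).
* Only the two observed sex categories are supported, mirroring the data
  the method was built for.
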