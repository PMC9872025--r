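# hoopdev

Does specializing in basketball before puberty give young players a physical
fitness advantage? `hoopdev` provides the full analysis toolchain for that
question in longitudinal youth-basketball testing data: maturation-referenced
classification of specialization onset and somatic maturity status, composite
fitness scoring, Bayesian hierarchical models of within-season and
developmental fitness change, and a synthetic-cohort generator with known
ground truth for validating the whole loop by parameter recovery.

It is aimed at sport scientists and biostatisticians working with repeated
fitness testing of adolescent athletes (countermovement jump, line drill,
yo-yo intermittent recovery level 1), where growth and maturation confound
naive comparisons.

## The science in brief

**Maturation.** Somatic maturity is estimated from the sex-specific
age-by-stature maturity-offset equations,

```
offset = a_sex + b_sex * (age * stature),     aPHV = age - offset
```

with a negative offset meaning the player has not yet reached peak height
velocity (PHV). Estimated aPHV is compared with meta-analytic reference ages
(11.9 y for females, 13.9 y for males): players more than six months ahead of
the reference are *early* maturers, within six months *average*, beyond
*late*. The offset equations are only trusted near PHV, so only female U13
and male U13/U15 players are classified.

**Specialization onset.** The self-reported age of exclusive, year-round
basketball participation is placed against the pubertal milestones (onset of
the growth spurt: 9.4 y female / 11.1 y male; aPHV: 11.9 / 13.9 y):
before the onset reference = *pre-puberty* (early) specialization, between
onset and aPHV = *mid-puberty*, after aPHV = *late-puberty*; missing =
*unknown*.

**Fitness score.** Each outcome is standardized against the pooled mean and
SD of all observations; line-drill z-scores are reversed (lower time is
better); the composite is `z_cmj + z_linedrill_reversed + z_yoyo`.

**Models.** Outcomes (2-SD standardized) are modelled with cross-classified
hierarchical Gaussian regressions: a within-season model with phase
indicators (mid/end vs pre-season), sex and sex-by-phase terms, and varying
intercepts/phase-slopes by player, season year, specialization-by-sex,
age-group-by-sex and maturity-by-sex; and a three-level quadratic growth
model in chronological age with trajectories varying by player and by
specialization-onset group. Priors are weakly informative: normal(0, 5) for
population coefficients, exponential(1) for group SDs, half Student-t(3, 0,
2.5) for the residual. Sampling uses JAGS (4 chains); expectations are
summarized with central 68% credible ribbons and specialization contrasts
are computed draw-by-draw within sex.

## Worked example

```r
library(hoopdev)

round(age_at_phv("female", 12.5, 163.3), 1)   # 11.6
classify_specialization("male", 8.0)$category # pre_puberty

co  <- simulate_cohort(sim_config(seed = 1))  # 181 players, 471 observations
d   <- prepare_model_data(co$table)           # score + classify
fit <- fit_model(season_model_spec("cmj"), d, sampler_settings(seed = 1))

predict_expected(fit)   # posterior group means with 68% ribbons (natural scale)
#>      sex specialization phase  est   lo   hi
#> 1 female    pre_puberty   pre 24.0 21.9 26.1
#> 2 female    pre_puberty   mid 24.4 22.0 26.8
#> 3 female    pre_puberty   end 25.5 23.0 27.9
#> ...

contrast_specialization(fit, "male", "pre_puberty", "late_puberty")
#>   phase mean_nat lo90_nat hi90_nat p_gt0
#> 1   pre    -0.45     -1.9    0.534 0.288
#> 2   mid    -1.72     -3.6   -0.023 0.047
#> 3   end    -0.15     -1.8    1.431 0.446

diagnostics(fit)
#> <hd_diagnostics: 634 parameters; PASS>
#>   max rhat 1.0031 (threshold 1.010); min bulk ESS 945 (threshold 400)
```

The prediction rows are expected CMJ (cm) for pre-puberty-specialized female
players across the season with 68% credible bounds. The contrast rows say
that on this null-generated cohort the male pre-vs-late specialization
difference in CMJ is small at every phase and its 90% interval essentially
covers zero — the pattern expected when early specialization confers no
advantage. `diagnostics()` confirms the chains mixed (split-chain Rhat,
bulk ESS).

`run_pipeline(run_config(...))` executes the whole chain (simulate/load →
classify → score → fit → predictions/contrasts/diagnostics/posterior
predictive checks) and writes CSV/JSON artifacts plus a manifest;
`inst/scripts/run_pipeline.R` is a command-line wrapper around it.

## Vignette

`vignettes/methods.Rmd` documents the model structure and assumptions, every
tunable constant with units and defaults, what the synthetic cohorts do and
do not emulate, numerical choices (parameterization of the Gibbs sampler,
tolerances, degenerate inputs) and known limitations.
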