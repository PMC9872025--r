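# Small in-code fixtures shared across tests.

tiny_table <- function() {
  tibble::tibble(
    player_id = c("A", "A", "A", "B", "B", "C"),
    sex = factor(c("female", "female", "female", "male", "male", "male"),
                 levels = c("female", "male")),
    birth_date = as.Date(c(rep("2006-05-10", 3), rep("2005-03-02", 2), "2002-11-20")),
    assessment_date = as.Date(c("2019-03-01", "2019-07-15", "2019-11-20",
                                "2019-03-01", "2019-07-15", "2019-03-01")),
    chronological_age = c(12.8, 13.2, 13.5, 14.0, 14.4, 16.3),
    season_year = 2019L,
    phase = factor(c("pre", "mid", "end", "pre", "mid", "pre"),
                   levels = c("pre", "mid", "end"), ordered = TRUE),
    age_group = factor(c("U13", "U13", "U13", "U15", "U15", "U17"),
                       levels = c("U13", "U15", "U17")),
    stature = c(160.2, 161.0, 161.5, 170.3, 171.0, 185.2),
    body_mass = c(52.1, 52.8, 53.0, 60.4, 61.0, 78.9),
    specialization_onset_age = c(8.5, 8.5, 8.5, 12.0, 12.0, NA),
    cmj = c(24, 25, 25, 33, 34, 40),
    line_drill = c(37.5, 37.2, 37.0, 34.1, 33.9, 31.5),
    yoyo_ir1 = c(360, 400, 400, 760, 800, 1240)
  )
}

# random scored-style table for brute-force composite checks
random_outcome_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    player_id = sprintf("P%02d", seq_len(n)),
    sex = factor(sample(c("female", "male"), n, TRUE), levels = c("female", "male")),
    cmj = rnorm(n, 30, 6),
    line_drill = rnorm(n, 34, 3),
    yoyo_ir1 = abs(rnorm(n, 700, 300))
  )
}

# settings small enough for unit tests (not for diagnostics-quality inference)
quick_settings <- function(seed = 1, chains = 2, iterations = 500, warmup = 250) {
  sampler_settings(chains = chains, iterations = iterations,
                   warmup = warmup, seed = seed)
}

# noiseless simulation config: every variance component, measurement error and
# rounding switched off
noiseless_config <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  cfg$measurement_error[] <- 0
  cfg$mass$sd_log <- 0
  for (o in names(cfg$outcomes)) {
    cfg$outcomes[[o]]$player_sd[] <- 0
    cfg$outcomes[[o]]$season_sd <- 0
    cfg$outcomes[[o]]$residual_sd <- 0
    cfg$outcomes[[o]]$round <- 0
  }
  for (s in c("female", "male")) {
    cfg$growth[[s]]$adult_sd <- 0
    cfg$growth[[s]]$aphv_sd <- 0
  }
  cfg
}

# independent mean-function oracle for the generator (separate code path)
mean_function_oracle <- function(cfg, sex, phase, baseline_age, outcome,
                                 spec_category = "unknown",
                                 maturity_timing = "average") {
  oc <- cfg$outcomes[[outcome]]
  ph <- if (phase == "pre") 0 else oc$phase[[sex]][[if (phase == "mid") "mid" else "end"]]
  sp <- if (spec_category %in% names(cfg$effects$specialization)) {
    cfg$effects$specialization[[spec_category]] * oc$pooled_sd_ref
  } else 0
  mt <- cfg$effects$maturity[[maturity_timing]] * oc$pooled_sd_ref
  oc$intercept[[sex]] + oc$age_slope[[sex]] * (baseline_age - 14) + ph + sp + mt
}
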