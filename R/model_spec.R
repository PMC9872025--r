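#' Weakly informative prior set
#'
#' The priors used for every model in the package: independent normal(0, 5)
#' margins for population-level coefficients, exponential(rate 1) for
#' group-level standard deviations, and a half Student-t(3, 0, 2.5) for the
#' residual scale. With outcomes standardized by two standard deviations these
#' are weakly informative and regularize the imbalanced repeated-measures
#' fits.
#'
#' @param b_scale Normal prior SD for population-level coefficients.
#' @param sd_rate Exponential rate for group-level SDs.
#' @param sigma_df,sigma_scale Degrees of freedom and scale of the half
#'   Student-t residual prior.
#' @return List of class `hd_prior_set`.
#' @export
prior_set <- function(b_scale = 5, sd_rate = 1, sigma_df = 3, sigma_scale = 2.5) {
  stopifnot(b_scale > 0, sd_rate > 0, sigma_df > 0, sigma_scale > 0)
  structure(list(b_scale = b_scale, sd_rate = sd_rate,
                 sigma_df = sigma_df, sigma_scale = sigma_scale),
            class = "hd_prior_set")
}

#' Sampler settings
#'
#' Four chains are run for `iterations` sweeps each, the first `warmup` of
#' which (adaptation plus burn-in) are discarded, so the stored draw count is
#' `chains * (iterations - warmup)`. The defaults keep 9,000 draws per chain:
#' the Gibbs backend mixes more slowly per sweep than gradient-based samplers,
#' and this length meets the package's convergence contract (split-chain
#' Rhat < 1.01, bulk ESS > 400) on cohort-sized fits.
#'
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param iterations Sweeps per chain, including warm-up.
#' @param warmup Discarded sweeps per chain.
#' @param seed Integer seed governing all chains.
#' @return List of class `hd_sampler_settings`.
#' @export
sampler_settings <- function(chains = 4, iterations = 10000, warmup = 1000, seed = 1) {
  if (chains < 2) abort("at least 2 chains are required for diagnostics")
  if (warmup >= iterations) abort("warmup must be smaller than iterations")
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 backend = "rjags"),
            class = "hd_sampler_settings")
}

model_outcomes <- c("cmj", "line_drill", "yoyo_ir1", "fitness_score")

check_outcome <- function(outcome) {
  if (!outcome %in% model_outcomes) {
    abort(sprintf("unknown outcome '%s' (expected one of %s)", outcome,
                  paste(model_outcomes, collapse = ", ")))
  }
  outcome
}

new_model_spec <- function(outcome, family, population, blocks,
                           priors, standardize, age_center = NULL) {
  structure(list(outcome = outcome, family = family, population = population,
                 blocks = blocks, priors = priors, standardize = standardize,
                 age_center = age_center),
            class = "hd_model_spec")
}

#' Within-season varying-intercept, varying-slope model specification
#'
#' Declares the cross-classified model of change across a competitive season.
#' Population-level terms: intercept, the two phase indicators (mid, end;
#' pre-season is the baseline), sex, and sex-by-phase interactions so the
#' seasonal response can differ between female and male players. For the
#' yo-yo IR1 and composite fitness outcomes a 2-SD-standardized body-mass
#' term partitions the influence of body size on long-duration performance;
#' short-term maximal outputs (CMJ, line drill) carry no body-size term.
#' Group-level blocks, each with its own exponential-prior SDs and entered
#' additively (cross-classified, not nested): player (intercept + both phase
#' slopes), season year (intercept), specialization-onset-by-sex,
#' age-group-by-sex and maturity-status-by-sex (each intercept + phase
#' slopes). `unknown` and `not_classified` are ordinary factor levels, so
#' sparse cells are partially pooled rather than dropped.
#'
#' @param outcome One of `"cmj"`, `"line_drill"`, `"yoyo_ir1"`,
#'   `"fitness_score"`.
#' @param body_mass `"auto"` (include for yo-yo and composite), `"include"`,
#'   or `"exclude"`.
#' @param priors A [prior_set()].
#' @param standardize Standardize the outcome by 2 SD before fitting
#'   (default `TRUE`).
#' @return A model spec of class `hd_model_spec`.
#' @export
season_model_spec <- function(outcome, body_mass = c("auto", "include", "exclude"),
                              priors = prior_set(), standardize = TRUE) {
  check_outcome(outcome)
  body_mass <- match.arg(body_mass)
  with_mass <- switch(body_mass,
                      auto = outcome %in% c("yoyo_ir1", "fitness_score"),
                      include = TRUE, exclude = FALSE)
  population <- c("Intercept", "phasemid", "phaseend", "sexmale",
                  "sexmale:phasemid", "sexmale:phaseend",
                  if (with_mass) "body_mass_std")
  phase_coefs <- c("Intercept", "phasemid", "phaseend")
  nc3 <- rep("noncentered", 3)
  # intercepts of the cell-difference blocks carry large, data-informed
  # effects and sample centered; weakly identified coefficients sample
  # non-centered (see fit.R)
  cen1 <- c("centered", "noncentered", "noncentered")
  blocks <- list(
    player = list(group = "player_id", coefs = phase_coefs, param = nc3),
    season = list(group = "season_year", coefs = "Intercept",
                  param = "noncentered"),
    spec_sex = list(group = "spec_sex", coefs = phase_coefs, param = nc3),
    agegrp_sex = list(group = "agegrp_sex", coefs = phase_coefs, param = cen1),
    maturity_sex = list(group = "maturity_sex", coefs = phase_coefs, param = cen1)
  )
  new_model_spec(outcome, "season", population, blocks, priors, standardize)
}

#' Three-level quadratic growth model specification
#'
#' Declares the developmental model of fitness against chronological age.
#' Population-level terms: intercept, centered age and age squared
#' (decorrelated by centering at `age_center`, default 14.0 y, the midrange of
#' the 11-17 y span), sex, and a sex-by-age interaction for the sex-contrast
#' surfaces. Trajectories (intercept, age, age-squared coefficients) vary
#' between players (level 2) and between specialization-onset groups
#' (level 3), with the `unknown` onset category retained as an ordinary
#' level; the residual is level 1.
#'
#' @inheritParams season_model_spec
#' @param age_center Centering constant for chronological age, in years;
#'   recorded in the spec.
#' @return A model spec of class `hd_model_spec`.
#' @export
growth_model_spec <- function(outcome, age_center = 14.0,
                              priors = prior_set(), standardize = TRUE) {
  check_outcome(outcome)
  age_coefs <- c("Intercept", "age_c", "age_c2")
  blocks <- list(
    player = list(group = "player_id", coefs = age_coefs,
                  param = c("centered", "noncentered", "noncentered")),
    spec_group = list(group = "spec_category", coefs = age_coefs,
                      param = rep("noncentered", 3))
  )
  new_model_spec(outcome, "growth",
                 c("Intercept", "age_c", "age_c2", "sexmale", "sexmale:age_c"),
                 blocks, priors, standardize, age_center = age_center)
}

#' Intercept-only model specification
#'
#' A minimal specification (population intercept plus residual, no group
#' levels), mainly useful for calibration checks: under the weak normal(0, 5)
#' prior its posterior mean is essentially the sample mean.
#'
#' @inheritParams season_model_spec
#' @return A model spec of class `hd_model_spec`.
#' @export
intercept_model_spec <- function(outcome, priors = prior_set(), standardize = FALSE) {
  check_outcome(outcome)
  new_model_spec(outcome, "intercept_only", "Intercept", list(), priors, standardize)
}

#' @export
print.hd_model_spec <- function(x, ...) {
  cat(sprintf("<hd_model_spec: %s model for %s>\n", x$family, x$outcome))
  cat("population terms:", paste(x$population, collapse = ", "), "\n")
  for (nm in names(x$blocks)) {
    cat(sprintf("group block %s (by %s): %s\n", nm, x$blocks[[nm]]$group,
                paste(x$blocks[[nm]]$coefs, collapse = ", ")))
  }
  if (!is.null(x$age_center)) cat("age centered at", x$age_center, "y\n")
  cat(sprintf("priors: b ~ normal(0, %g); sd ~ exponential(%g); sigma ~ student_t(%g, 0, %g)\n",
              x$priors$b_scale, x$priors$sd_rate, x$priors$sigma_df, x$priors$sigma_scale))
  invisible(x)
}

#' Serialize a model spec or configuration to YAML
#'
#' @param x A model spec, prior set, sampler settings, or any plain list.
#' @param path Optional output path.
#' @return The YAML string, invisibly when written to `path`.
#' @export
spec_to_yaml <- function(x, path = NULL) {
  y <- yaml::as.yaml(unclass_recursive(x))
  if (!is.null(path)) { writeLines(y, path); return(invisible(y)) }
  y
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Attach classification and scoring columns needed by the models
#'
#' Convenience wrapper running the scoring and classification steps:
#' pooled z-scores and the composite via [score_fitness()], player-level
#' maturity status via [assess_maturity()] and specialization category via
#' [assess_specialization()], joined back onto the occasion-level table as
#' `maturity_status` and `spec_category`.
#'
#' @param table Observation table.
#' @param config A [maturation_config()].
#' @param scaling Optional scoring scaling records to reuse (see
#'   [score_fitness()]).
#' @return The scored table with classification columns.
#' @export
prepare_model_data <- function(table, config = maturation_config(), scaling = NULL) {
  scored <- score_fitness(table, scaling = scaling)
  mat <- assess_maturity(table, config)
  spc <- assess_specialization(table, config)
  out <- scored |>
    dplyr::left_join(dplyr::select(mat, "player_id", maturity_status = "status"),
                     by = "player_id") |>
    dplyr::left_join(dplyr::select(spc, "player_id", spec_category = "category"),
                     by = "player_id")
  attr(out, "scaling") <- attr(scored, "scaling")
  attr(out, "provenance") <- attr(table, "provenance")
  out
}
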