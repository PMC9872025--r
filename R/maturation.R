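#' Maturation constants: offset coefficients and reference milestones
#'
#' Bundles the sex-specific coefficients of the age-by-stature maturity-offset
#' prediction equations with meta-analytic reference ages for the pubertal
#' milestones, and the classification tolerance. The offset equation is
#' `offset = intercept + slope * (age * stature)`, with a negative offset
#' meaning the player has not yet reached peak height velocity (PHV).
#'
#' Reference milestones (years, with 95% CI): initiation of the pubertal
#' growth spurt 9.4 (9.0-9.8) for females and 11.1 (10.8-11.5) for males;
#' age at PHV 11.9 (11.8-12.0) for females and 13.9 (13.8-14.0) for males.
#' All constants live in this config block so they are auditable and
#' swappable.
#'
#' @param coefficients Per-sex `intercept` (years) and `slope`
#'   (years per year\eqn{\cdot}cm) of the offset equation.
#' @param reference Per-sex reference ages: `onset` (initiation of the growth
#'   spurt) and `aphv`, each with a 95% CI.
#' @param tolerance_years Half-width of the "average maturer" band around the
#'   reference age at PHV; six months = 0.5 decimal years, boundary-inclusive.
#' @return A list of class `hd_maturation_config`.
#' @export
maturation_config <- function(
    coefficients = list(
      female = list(intercept = -7.709133, slope = 0.0042232),
      male   = list(intercept = -7.999994, slope = 0.0036124)
    ),
    reference = list(
      female = list(onset = 9.4, onset_ci = c(9.0, 9.8),
                    aphv = 11.9, aphv_ci = c(11.8, 12.0)),
      male   = list(onset = 11.1, onset_ci = c(10.8, 11.5),
                    aphv = 13.9, aphv_ci = c(13.8, 14.0))
    ),
    tolerance_years = 0.5) {
  for (s in sex_levels) {
    if (coefficients[[s]]$slope <= 0) {
      abort(sprintf("offset slope must be positive (%s)", s))
    }
    if (reference[[s]]$onset >= reference[[s]]$aphv) {
      abort(sprintf("reference onset must precede reference aPHV (%s)", s))
    }
  }
  if (reference$female$aphv >= reference$male$aphv) {
    abort("female reference aPHV must precede male reference aPHV")
  }
  structure(list(coefficients = coefficients, reference = reference,
                 tolerance_years = tolerance_years),
            class = "hd_maturation_config")
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- setdiff(unique(sex[!is.na(sex)]), sex_levels)
  if (length(bad)) {
    abort(sprintf("unknown sex label(s): %s", paste(bad, collapse = ", ")))
  }
  sex
}

#' Maturity offset from age and stature
#'
#' Predicted distance in years from the measurement occasion to peak height
#' velocity, from the sex-specific linear model in the age-by-stature product:
#' `offset = intercept + slope * (age * stature)`. Negative values mean the
#' player is pre-PHV.
#'
#' @param sex `"female"` or `"male"` (vectorized).
#' @param chronological_age Decimal age in years.
#' @param stature Stature in cm.
#' @param config A [maturation_config()].
#' @return Offset in years.
#' @export
#' @examples
#' maturity_offset("female", 12.5, 163.3)  # ~ +0.91 y (post-PHV)
#' maturity_offset("male", 12.6, 165.4)    # ~ -0.47 y (pre-PHV)
maturity_offset <- function(sex, chronological_age, stature,
                            config = maturation_config()) {
  sex <- check_sex(sex)
  n <- max(length(sex), length(chronological_age), length(stature))
  sex <- rep_len(sex, n)
  chronological_age <- rep_len(chronological_age, n)
  stature <- rep_len(stature, n)
  ic <- vapply(config$coefficients, `[[`, 0, "intercept")[sex]
  sl <- vapply(config$coefficients, `[[`, 0, "slope")[sex]
  unname(ic + sl * (chronological_age * stature))
}

#' Estimated age at peak height velocity
#'
#' Subtracts the maturity offset from chronological age:
#' `aPHV = age - offset`. Returned at full precision; round to 0.1 years for
#' reporting.
#'
#' @inheritParams maturity_offset
#' @return Estimated age at PHV in years.
#' @export
#' @examples
#' round(age_at_phv("female", 12.5, 163.3), 1)  # 11.6
age_at_phv <- function(sex, chronological_age, stature,
                       config = maturation_config()) {
  chronological_age - maturity_offset(sex, chronological_age, stature, config)
}

#' Classify maturity status against the reference age at PHV
#'
#' Compares a player's estimated age at PHV with the sex-specific reference:
#' early maturers are more than six months ahead of the reference (estimated
#' aPHV lower by more than `tolerance_years`), late maturers more than six
#' months behind, and average maturers within the band (boundary-inclusive).
#' The offset equations lose validity away from the ages around PHV, so only
#' female under-13 and male under-13/under-15 players are classified; all
#' other groups are `not_classified`.
#'
#' With `ci_aware = TRUE` a player whose difference interval (estimated aPHV
#' minus the reference 95% CI bounds) overlaps the tolerance band is demoted
#' to `average`; the default classifies on point estimates, as the reference
#' CIs are descriptive.
#'
#' @param sex,age_group Player sex and competition age group (vectorized).
#' @param estimated_aphv Estimated age at PHV in years (may be `NA`).
#' @param config A [maturation_config()].
#' @param ci_aware Use the reference CI when classifying (default `FALSE`).
#' @return A tibble with `status` (`early`/`average`/`late`/`not_classified`),
#'   `delta` (estimated minus reference aPHV; `NA` when not applicable) and
#'   `rule_note`.
#' @export
classify_maturity <- function(sex, age_group, estimated_aphv,
                              config = maturation_config(), ci_aware = FALSE) {
  sex <- check_sex(sex)
  age_group <- as.character(age_group)
  n <- max(length(sex), length(age_group), length(estimated_aphv))
  sex <- rep_len(sex, n)
  age_group <- rep_len(age_group, n)
  estimated_aphv <- rep_len(estimated_aphv, n)

  tol <- config$tolerance_years
  ref <- vapply(config$reference, `[[`, 0, "aphv")[sex]
  applicable <- (sex == "female" & age_group == "U13") |
    (sex == "male" & age_group %in% c("U13", "U15"))

  delta <- ifelse(applicable, estimated_aphv - ref, NA_real_)
  status <- rep("not_classified", n)
  note <- ifelse(applicable, "", "offset equation not valid for this sex/age group")

  cls <- applicable & !is.na(estimated_aphv)
  status[cls & delta < -tol] <- "early"
  status[cls & abs(delta) <= tol] <- "average"
  status[cls & delta > tol] <- "late"
  if (ci_aware) {
    lo <- estimated_aphv - vapply(config$reference, function(r) r$aphv_ci[2], 0)[sex]
    hi <- estimated_aphv - vapply(config$reference, function(r) r$aphv_ci[1], 0)[sex]
    amb <- cls & status %in% c("early", "late") & lo <= tol & hi >= -tol
    status[amb] <- "average"
    note[amb] <- "reference CI overlaps tolerance band"
  }
  miss <- applicable & is.na(estimated_aphv)
  status[miss] <- "not_classified"
  note[miss] <- "missing estimate"
  note[cls & note == ""] <- sprintf("delta = %+.2f y vs reference %.1f y",
                                    delta[cls & note == ""], ref[cls & note == ""])

  tibble::tibble(status = factor(status, levels = maturity_levels),
                 delta = delta, rule_note = note)
}

maturity_levels <- c("early", "average", "late", "not_classified")

#' Per-player maturity assessment from an observation table
#'
#' Computes the maturity offset and estimated age at PHV at each player's
#' pre-season occasion of their first observed season (earliest phase with
#' non-missing age and stature) and classifies maturity status with
#' [classify_maturity()]. The pre-season estimate defines the player's status
#' for the whole analysis, so status is a player-level constant in the models.
#'
#' @param table Observation table.
#' @param config A [maturation_config()].
#' @inheritParams classify_maturity
#' @return Tibble with one row per player: `player_id`, `sex`, `age_group`,
#'   `estimated_offset`, `estimated_aphv`, `status`, `rule_note`.
#' @export
assess_maturity <- function(table, config = maturation_config(), ci_aware = FALSE) {
  base <- table |>
    dplyr::filter(!is.na(.data$chronological_age)) |>
    dplyr::arrange(.data$season_year, .data$phase) |>
    dplyr::group_by(.data$player_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  off <- ifelse(is.na(base$stature), NA_real_,
                maturity_offset(base$sex, base$chronological_age, base$stature, config))
  aphv <- base$chronological_age - off
  cls <- classify_maturity(base$sex, base$age_group, aphv, config, ci_aware)
  tibble::tibble(player_id = base$player_id, sex = base$sex,
                 age_group = base$age_group,
                 estimated_offset = off, estimated_aphv = aphv,
                 status = cls$status, rule_note = cls$rule_note)
}
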