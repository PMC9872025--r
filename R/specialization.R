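#' Classify specialization onset against the pubertal-growth milestones
#'
#' The self-reported age at which a player began exclusive, year-round,
#' coach-supervised basketball participation is placed relative to the
#' sex-specific reference milestones: before the reference age of initiation
#' of the pubertal growth spurt is `pre_puberty` (early specialization);
#' between the onset reference and the reference age at PHV, inclusive on both
#' sides, is `mid_puberty`; after the reference age at PHV is `late_puberty`.
#' A missing onset age yields `unknown`. No rounding is applied: the category
#' is a pure function of the stored value.
#'
#' @param sex `"female"` or `"male"` (vectorized).
#' @param onset_age Self-reported specialization-onset age in years, or `NA`.
#' @param config A [maturation_config()] supplying the reference milestones.
#' @return A tibble with `category`
#'   (`pre_puberty`/`mid_puberty`/`late_puberty`/`unknown`) and `rule_note`.
#' @export
#' @examples
#' classify_specialization("male", 8.0)$category     # pre_puberty (8.0 < 11.1)
#' classify_specialization("female", 10.0)$category  # mid_puberty (9.4 <= 10 <= 11.9)
classify_specialization <- function(sex, onset_age, config = maturation_config()) {
  sex <- check_sex(sex)
  n <- max(length(sex), length(onset_age))
  sex <- rep_len(sex, n)
  onset_age <- rep_len(onset_age, n)

  bad <- !is.na(onset_age) & (onset_age < 3 | onset_age > 18)
  if (any(bad)) {
    abort(sprintf("implausible specialization onset age(s) outside [3, 18] y: %s",
                  paste(unique(onset_age[bad]), collapse = ", ")))
  }
  onset_ref <- vapply(config$reference, `[[`, 0, "onset")[sex]
  aphv_ref <- vapply(config$reference, `[[`, 0, "aphv")[sex]

  category <- dplyr::case_when(
    is.na(onset_age) ~ "unknown",
    onset_age < onset_ref ~ "pre_puberty",
    onset_age <= aphv_ref ~ "mid_puberty",
    TRUE ~ "late_puberty"
  )
  note <- dplyr::case_when(
    is.na(onset_age) ~ "onset age not reported",
    TRUE ~ sprintf("onset %.1f y vs references %.1f / %.1f y", onset_age,
                   onset_ref, aphv_ref)
  )
  tibble::tibble(category = factor(category, levels = specialization_levels),
                 rule_note = note)
}

specialization_levels <- c("pre_puberty", "mid_puberty", "late_puberty", "unknown")

#' Per-player specialization assessment from an observation table
#'
#' Takes each player's first non-missing reported onset age (the value is a
#' player-level constant) and classifies it with [classify_specialization()].
#'
#' @param table Observation table.
#' @param config A [maturation_config()].
#' @return Tibble with one row per player: `player_id`, `sex`, `onset_age`,
#'   `category`, `rule_note`.
#' @export
assess_specialization <- function(table, config = maturation_config()) {
  base <- table |>
    dplyr::group_by(.data$player_id) |>
    dplyr::summarise(
      sex = .data$sex[1],
      onset_age = .data$specialization_onset_age[
        which(!is.na(.data$specialization_onset_age))[1]],
      .groups = "drop")
  cls <- classify_specialization(base$sex, base$onset_age, config)
  tibble::tibble(player_id = base$player_id, sex = base$sex,
                 onset_age = base$onset_age,
                 category = cls$category, rule_note = cls$rule_note)
}
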