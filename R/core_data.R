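#' Observation-table schema
#'
#' The longitudinal testing record is a tidy table with one row per player x
#' assessment occasion. `observation_schema()` returns a machine-readable
#' description of the expected columns (name, type, unit, whether mandatory),
#' suitable for JSON export with [schema_json()].
#'
#' @return A tibble with columns `field`, `type`, `unit`, `required`.
#' @export
observation_schema <- function() {
  tibble::tribble(
    ~field,                     ~type,      ~unit,           ~required,
    "player_id",                "character", NA,             TRUE,
    "sex",                      "factor",    "female/male",  TRUE,
    "birth_date",               "date",      NA,             FALSE,
    "assessment_date",          "date",      NA,             FALSE,
    "chronological_age",        "numeric",   "years",        FALSE,
    "season_year",              "integer",   "calendar year", TRUE,
    "phase",                    "factor",    "pre/mid/end",  TRUE,
    "age_group",                "factor",    "U13/U15/U17",  FALSE,
    "stature",                  "numeric",   "cm",           FALSE,
    "body_mass",                "numeric",   "kg",           FALSE,
    "specialization_onset_age", "numeric",   "years",        FALSE,
    "cmj",                      "numeric",   "cm",           FALSE,
    "line_drill",               "numeric",   "s",            FALSE,
    "yoyo_ir1",                 "numeric",   "m",            FALSE
  )
}

#' @rdname observation_schema
#' @param path Optional file path; when given the JSON is written there.
#' @export
schema_json <- function(path = NULL) {
  js <- jsonlite::toJSON(observation_schema(), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Default column mapping for delimited input files
#'
#' Maps internal field names onto file headers. Deposited data sets use
#' unspecified headers, so the mapping is user-configurable: pass a named
#' character vector `c(internal_name = "file header", ...)` to
#' [load_observations()].
#'
#' @return Named character vector.
#' @export
default_column_mapping <- function() {
  fields <- observation_schema()$field
  setNames(fields, fields)
}

phase_levels <- c("pre", "mid", "end")
age_group_levels <- c("U13", "U15", "U17")
sex_levels <- c("female", "male")

na_markers <- c("", "NA", "N/A")

parse_numeric_col <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warn(sprintf("%d unparseable value(s) in column '%s' set to missing", sum(bad), name))
  }
  out
}

#' Load longitudinal observations from a delimited file
#'
#' Reads a UTF-8 delimited text file with a header row into an observation
#' table. Cells equal to `""`, `"NA"` or `"N/A"` become missing; unparseable
#' numeric cells become missing with a warning (never silent zeros). When both
#' birth and assessment dates are present, decimal age is recomputed from the
#' dates (to the nearest 0.1 years) and takes precedence over a supplied
#' `chronological_age` column, with a warning when the two disagree by more
#' than 0.1 years. Missing `age_group` is derived from birth year and season
#' year with [derive_age_group()].
#'
#' @param path Path to the input file.
#' @param mapping Named character vector mapping internal field names to file
#'   headers; see [default_column_mapping()].
#' @param delim Field delimiter (default comma).
#' @return A tibble with the columns of [observation_schema()] and a
#'   `provenance` attribute of `"file"`.
#' @export
load_observations <- function(path, mapping = default_column_mapping(), delim = ",") {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, na = na_markers,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)

  present <- mapping[mapping %in% names(raw)]
  mandatory <- c("player_id", "sex", "phase")
  missing_cols <- setdiff(mandatory, names(present))
  has_age <- "chronological_age" %in% names(present) ||
    all(c("birth_date", "assessment_date") %in% names(present))
  if (!has_age) missing_cols <- c(missing_cols, "chronological_age (or birth_date + assessment_date)")
  if (length(missing_cols)) {
    abort(sprintf("mandatory column(s) missing from %s: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }

  tab <- tibble::tibble(.rows = nrow(raw))
  for (f in names(present)) tab[[f]] <- raw[[present[[f]]]]
  for (f in setdiff(observation_schema()$field, names(tab))) tab[[f]] <- NA_character_

  tab$player_id <- as.character(tab$player_id)
  sex <- tolower(trimws(tab$sex))
  unknown_sex <- setdiff(unique(sex[!is.na(sex)]), sex_levels)
  if (length(unknown_sex)) {
    abort(sprintf("unknown sex label(s): %s (expected female/male)",
                  paste(unknown_sex, collapse = ", ")))
  }
  tab$sex <- factor(sex, levels = sex_levels)
  ph <- tolower(trimws(tab$phase))
  unknown_ph <- setdiff(unique(ph[!is.na(ph)]), phase_levels)
  if (length(unknown_ph)) {
    abort(sprintf("unknown phase label(s): %s (expected pre/mid/end)",
                  paste(unknown_ph, collapse = ", ")))
  }
  tab$phase <- factor(ph, levels = phase_levels, ordered = TRUE)

  tab$birth_date <- readr::parse_date(as.character(tab$birth_date), na = na_markers)
  tab$assessment_date <- readr::parse_date(as.character(tab$assessment_date), na = na_markers)
  for (f in c("chronological_age", "stature", "body_mass",
              "specialization_onset_age", "cmj", "line_drill", "yoyo_ir1")) {
    tab[[f]] <- parse_numeric_col(tab[[f]], f)
  }
  tab$season_year <- as.integer(parse_numeric_col(tab$season_year, "season_year"))

  # dates take precedence over a stated decimal age
  have_dates <- !is.na(tab$birth_date) & !is.na(tab$assessment_date)
  if (any(have_dates)) {
    age_dates <- round(as.numeric(tab$assessment_date - tab$birth_date) / 365.25, 1)
    disagree <- have_dates & !is.na(tab$chronological_age) &
      abs(tab$chronological_age - age_dates) > 0.1
    if (any(disagree)) {
      warn(sprintf("%d row(s): stated chronological_age differs from date-derived age by > 0.1 y; dates used",
                   sum(disagree)))
    }
    tab$chronological_age[have_dates] <- age_dates[have_dates]
  }

  no_season <- is.na(tab$season_year) & !is.na(tab$assessment_date)
  tab$season_year[no_season] <- as.integer(format(tab$assessment_date[no_season], "%Y"))

  ag <- toupper(trimws(as.character(tab$age_group)))
  need_ag <- (is.na(ag) | !ag %in% age_group_levels) &
    !is.na(tab$birth_date) & !is.na(tab$season_year)
  if (any(need_ag)) {
    by <- as.integer(format(tab$birth_date[need_ag], "%Y"))
    ag[need_ag] <- as.character(derive_age_group(by, tab$season_year[need_ag]))
  }
  tab$age_group <- factor(ag, levels = age_group_levels)

  tab <- tab[, observation_schema()$field]
  attr(tab, "provenance") <- "file"
  tab
}

#' Write an observation table to CSV
#'
#' Inverse of [load_observations()] under the default mapping; numeric fields
#' are written at full precision so that a write/read round trip reproduces
#' the table.
#'
#' @param table Observation table.
#' @param path Output path.
#' @export
write_observations <- function(table, path) {
  readr::write_csv(table, path, na = "NA")
  invisible(path)
}

#' Validate an observation table
#'
#' Checks the structural invariants of the observation table and returns a
#' report; validation never throws. Error-severity rules: plausible ranges
#' (age 8-20 y, stature 120-220 cm, body mass 25-130 kg), strictly positive
#' line-drill times, non-negative yo-yo distances, specialization onset in
#' 3-18 y, at most one record per (player, season, phase), and a single sex
#' per player. Warning-severity: yo-yo distance not a multiple of the 40 m
#' out-and-back shuttle (recording granularity is not guaranteed).
#'
#' @param table Observation table.
#' @return A tibble with one row per rule: `rule`, `severity`, `n_fail` and a
#'   `rows` list-column of offending row indices. The table passes when no
#'   error-severity rule fails; see [table_valid()].
#' @export
validate_table <- function(table) {
  idx <- seq_len(nrow(table))
  fail <- function(lgl) idx[which(lgl %in% TRUE)]

  dup <- duplicated(table[, c("player_id", "season_year", "phase")]) &
    !is.na(table$phase)
  sex_tab <- dplyr::distinct(table, .data$player_id, .data$sex)
  bad_players <- sex_tab$player_id[duplicated(sex_tab$player_id)]

  yoyo_frac <- table$yoyo_ir1 / 40
  rules <- list(
    list("chronological_age within 8-20 y", "error",
         fail(!is.na(table$chronological_age) &
                (table$chronological_age < 8 | table$chronological_age > 20))),
    list("stature within 120-220 cm", "error",
         fail(!is.na(table$stature) & (table$stature < 120 | table$stature > 220))),
    list("body_mass within 25-130 kg", "error",
         fail(!is.na(table$body_mass) & (table$body_mass < 25 | table$body_mass > 130))),
    list("line_drill strictly positive", "error",
         fail(!is.na(table$line_drill) & table$line_drill <= 0)),
    list("yoyo_ir1 non-negative", "error",
         fail(!is.na(table$yoyo_ir1) & table$yoyo_ir1 < 0)),
    list("yoyo_ir1 multiple of 40 m shuttle", "warning",
         fail(!is.na(table$yoyo_ir1) & table$yoyo_ir1 >= 0 &
                abs(yoyo_frac - round(yoyo_frac)) > 1e-6)),
    list("specialization onset within 3-18 y", "error",
         fail(!is.na(table$specialization_onset_age) &
                (table$specialization_onset_age < 3 | table$specialization_onset_age > 18))),
    list("one record per (player, season, phase)", "error", fail(dup)),
    list("single sex per player", "error",
         fail(table$player_id %in% bad_players))
  )
  tibble::tibble(
    rule = vapply(rules, `[[`, "", 1),
    severity = vapply(rules, `[[`, "", 2),
    n_fail = vapply(rules, function(r) length(r[[3]]), 0L),
    rows = lapply(rules, `[[`, 3)
  )
}

#' @rdname validate_table
#' @param report A validation report from [validate_table()].
#' @return `table_valid()`: `TRUE` when no error-severity rule fails.
#' @export
table_valid <- function(report) {
  all(report$n_fail[report$severity == "error"] == 0L)
}

#' Derive the competition age group from birth and season year
#'
#' A player is grouped by the age attained during the season's calendar year:
#' a player completing 13 years (or fewer) is under-13, one completing 14 or
#' 15 years is under-15, and one completing 16 or 17 years is under-17.
#'
#' @param birth_year Integer birth year(s).
#' @param season_year Integer season calendar year(s); recycled.
#' @return Factor with levels `U13`, `U15`, `U17`.
#' @export
#' @examples
#' derive_age_group(2006, 2019)  # attains 13 -> U13
#' derive_age_group(2005, 2019)  # attains 14 -> U15
derive_age_group <- function(birth_year, season_year) {
  n <- max(length(birth_year), length(season_year))
  birth_year <- rep_len(as.integer(birth_year), n)
  season_year <- rep_len(as.integer(season_year), n)
  a <- season_year - birth_year
  if (any(a < 9, na.rm = TRUE)) {
    abort(sprintf("implausible input: attained age below 9 (birth %s, season %s)",
                  birth_year[which(a < 9)[1]], season_year[which(a < 9)[1]]))
  }
  if (any(a > 17, na.rm = TRUE)) {
    abort(sprintf("attained age %d is outside the supported age groups (max under-17)",
                  max(a, na.rm = TRUE)))
  }
  factor(dplyr::case_when(a <= 13 ~ "U13", a <= 15 ~ "U15", TRUE ~ "U17"),
         levels = age_group_levels)
}
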