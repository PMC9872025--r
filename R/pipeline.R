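#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: an input file (or a
#' simulation config when `input` is `NULL`), the maturation constants, the
#' outcomes and model families to fit, sampler settings, an output directory
#' and a master seed from which all per-stage seeds are derived
#' deterministically.
#'
#' @param input Path to a delimited observation file, or `NULL` to simulate.
#' @param mapping Column mapping for [load_observations()].
#' @param sim An [sim_config()] used when `input` is `NULL`; its seed is
#'   overridden by the run seed.
#' @param maturation A [maturation_config()].
#' @param outcomes Outcomes to model.
#' @param models Model families to fit: `"season"`, `"growth"` or both.
#' @param settings A [sampler_settings()]; its seed is derived per fit.
#' @param outdir Output directory (created if needed).
#' @param seed Master seed.
#' @return List of class `hd_run_config`.
#' @export
run_config <- function(input = NULL, mapping = default_column_mapping(),
                       sim = sim_config(), maturation = maturation_config(),
                       outcomes = model_outcomes,
                       models = c("season", "growth"),
                       settings = sampler_settings(),
                       outdir = "hoopdev-run", seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(input = input, mapping = mapping, sim = sim,
                 maturation = maturation, outcomes = outcomes, models = models,
                 settings = settings, outdir = outdir, seed = as.integer(seed)),
            class = "hd_run_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[hoopdev] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes load/simulate, maturity and specialization classification,
#' composite scoring, model fitting per outcome and family, predictions,
#' specialization contrasts, diagnostics and posterior predictive checks,
#' writing each stage's output before the next begins: `observations.csv`,
#' `maturity.csv`, `specialization.csv`, `scored.csv`, `validation.csv`,
#' per-fit `draws_<family>_<outcome>.csv` (population-level, SD and residual
#' parameters in tidy chain/draw/parameter/value form), `predictions.csv`,
#' `contrasts.csv`, `diagnostics.csv`, `ppc.csv` and a `manifest.json` with
#' the config hash, seeds, backend and stage timings. Inputs are never
#' mutated; re-running with the same config reproduces the outputs.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "hd_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  tick <- function(nm, t0) timings[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)

  t0 <- Sys.time()
  if (is.null(config$input)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    table <- cohort$table
    truth <- cohort$truth
    stage_log(verbose, "simulated cohort: %d players, %d observations",
              dplyr::n_distinct(table$player_id), nrow(table))
  } else {
    table <- load_observations(config$input, config$mapping)
    truth <- NULL
    stage_log(verbose, "loaded %s: %d observations", config$input, nrow(table))
  }
  write_observations(table, file.path(config$outdir, "observations.csv"))
  report <- validate_table(table)
  readr::write_csv(dplyr::select(report, -"rows"),
                   file.path(config$outdir, "validation.csv"))
  if (!table_valid(report)) {
    bad <- report[report$severity == "error" & report$n_fail > 0, ]
    abort(sprintf("stage 'validate': %s (rows %s)", bad$rule[1],
                  paste(head(bad$rows[[1]], 5), collapse = ", ")))
  }
  tick("load", t0)

  t0 <- Sys.time()
  maturity <- assess_maturity(table, config$maturation)
  specialization <- assess_specialization(table, config$maturation)
  readr::write_csv(maturity, file.path(config$outdir, "maturity.csv"))
  readr::write_csv(specialization, file.path(config$outdir, "specialization.csv"))
  stage_log(verbose, "classified %d players (maturity, specialization)", nrow(maturity))
  tick("classify", t0)

  t0 <- Sys.time()
  data <- prepare_model_data(table, config$maturation)
  readr::write_csv(data, file.path(config$outdir, "scored.csv"))
  tick("score", t0)

  fits <- list(); diags <- list(); preds <- list(); ppcs <- list(); ctrs <- list()
  fit_i <- 0L
  for (family in config$models) {
    for (outcome in config$outcomes) {
      fit_i <- fit_i + 1L
      t0 <- Sys.time()
      spec <- switch(family, season = season_model_spec(outcome),
                     growth = growth_model_spec(outcome))
      st <- config$settings
      st$seed <- config$seed + 1000L * fit_i
      key <- paste(family, outcome, sep = "_")
      fit <- fit_model(spec, data, st)
      fits[[key]] <- fit
      readr::write_csv(
        tidy_draws(fit, "^(b_|sd_|sigma$)", regex = TRUE),
        file.path(config$outdir, sprintf("draws_%s.csv", key)))
      dg <- diagnostics(fit)
      diags[[key]] <- dplyr::mutate(dg$parameters, fit = key, .before = 1)
      preds[[key]] <- dplyr::mutate(predict_expected(fit), fit = key, .before = 1)
      pairs <- utils::combn(setdiff(specialization_levels, "unknown"), 2)
      ctrs[[key]] <- dplyr::bind_rows(lapply(sex_levels, function(s)
        dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j)
          dplyr::select(contrast_specialization(fit, s, pairs[1, j], pairs[2, j]),
                        -"draws_std"))))) |>
        dplyr::mutate(fit = key, .before = 1)
      ppcs[[key]] <- dplyr::mutate(posterior_predictive_check(fit),
                                   fit = key, .before = 1)
      tick(paste0("fit_", key), t0)
      stage_log(verbose, "fitted %s (%d rows, %.1f s; diagnostics %s)",
                key, fit$n_obs, fit$runtime_s, if (dg$pass) "pass" else "FAIL")
    }
  }
  readr::write_csv(dplyr::bind_rows(diags), file.path(config$outdir, "diagnostics.csv"))
  readr::write_csv(dplyr::bind_rows(preds), file.path(config$outdir, "predictions.csv"))
  readr::write_csv(dplyr::bind_rows(ctrs), file.path(config$outdir, "contrasts.csv"))
  readr::write_csv(dplyr::bind_rows(ppcs), file.path(config$outdir, "ppc.csv"))

  manifest <- list(
    package = as.character(utils::packageVersion("hoopdev")),
    seed = config$seed,
    config_hash = rlang::hash(unclass_recursive(
      config[setdiff(names(config), "outdir")])),
    backend = if (length(fits)) fits[[1]]$backend else NA,
    n_observations = nrow(table),
    n_players = dplyr::n_distinct(table$player_id),
    provenance = attr(table, "provenance") %||% "unknown",
    timings_s = timings,
    created = format(t_start, "%Y-%m-%d %H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log(verbose, "wrote artifacts to %s", config$outdir)
  invisible(list(table = table, truth = truth, maturity = maturity,
                 specialization = specialization, data = data, fits = fits,
                 diagnostics = dplyr::bind_rows(diags),
                 predictions = dplyr::bind_rows(preds),
                 contrasts = dplyr::bind_rows(ctrs),
                 ppc = dplyr::bind_rows(ppcs), manifest = manifest))
}
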