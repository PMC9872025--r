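## Design construction and JAGS fitting.
##
## Each group-level coefficient is sampled either centered
## (u ~ N(0, sd), best when the data strongly inform the level effects, e.g.
## age-group cell differences) or non-centered (u = sd * z, z ~ N(0,1), best
## for weakly identified effects near zero, e.g. phase slopes and small
## contrast blocks). With a Gibbs backend the wrong choice mixes poorly in
## either direction; the per-coefficient defaults in the model specs were
## chosen to meet the package's convergence contract.

block_levels <- function(name, data) {
  switch(name,
    player_id = sort(unique(as.character(data$player_id))),
    season_year = sort(unique(as.character(data$season_year))),
    spec_sex = as.vector(outer(specialization_levels, sex_levels, paste, sep = ":")),
    agegrp_sex = as.vector(outer(age_group_levels, sex_levels, paste, sep = ":")),
    maturity_sex = as.vector(outer(maturity_levels, sex_levels, paste, sep = ":")),
    spec_category = specialization_levels,
    abort(sprintf("unknown grouping factor '%s'", name))
  )
}

block_values <- function(name, data) {
  switch(name,
    player_id = as.character(data$player_id),
    season_year = as.character(data$season_year),
    spec_sex = paste(data$spec_category, data$sex, sep = ":"),
    agegrp_sex = paste(data$age_group, data$sex, sep = ":"),
    maturity_sex = paste(data$maturity_status, data$sex, sep = ":"),
    spec_category = as.character(data$spec_category)
  )
}

design_columns <- function(terms, data, spec) {
  cols <- lapply(terms, function(tm) {
    switch(tm,
      "Intercept" = rep(1, nrow(data)),
      "phasemid" = as.numeric(data$phase == "mid"),
      "phaseend" = as.numeric(data$phase == "end"),
      "sexmale" = as.numeric(data$sex == "male"),
      "sexmale:phasemid" = as.numeric(data$sex == "male" & data$phase == "mid"),
      "sexmale:phaseend" = as.numeric(data$sex == "male" & data$phase == "end"),
      "body_mass_std" = data$body_mass_std,
      "age_c" = data$chronological_age - spec$age_center,
      "age_c2" = (data$chronological_age - spec$age_center)^2,
      "sexmale:age_c" = as.numeric(data$sex == "male") *
        (data$chronological_age - spec$age_center),
      abort(sprintf("unknown model term '%s'", tm))
    )
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

required_model_columns <- function(spec) {
  switch(spec$family,
    season = c(spec$outcome, "player_id", "sex", "phase", "season_year",
               "age_group", "spec_category", "maturity_status",
               if ("body_mass_std" %in% spec$population) "body_mass"),
    growth = c(spec$outcome, "player_id", "sex", "chronological_age",
               "spec_category"),
    intercept_only = spec$outcome
  )
}

build_design <- function(spec, data) {
  need <- required_model_columns(spec)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("model data lacks column(s): %s (run prepare_model_data() first?)",
                  paste(missing_cols, collapse = ", ")))
  }
  y_raw <- data[[spec$outcome]]
  if (any(is.infinite(y_raw))) abort("non-finite outcome values in model data")

  keep <- !is.na(y_raw)
  for (cl in setdiff(need, spec$outcome)) keep <- keep & !is.na(data[[cl]])
  df <- data[keep, , drop = FALSE]

  scaling <- list()
  if (spec$standardize) {
    ysc <- standardize_2sd(df[[spec$outcome]], name = spec$outcome)
    y <- ysc$values
    scaling$y <- ysc[c("center", "scale", "name")]
  } else {
    y <- df[[spec$outcome]]
    scaling$y <- list(center = 0, scale = 1, name = spec$outcome)
  }
  if ("body_mass_std" %in% spec$population) {
    msc <- standardize_2sd(df$body_mass, name = "body_mass")
    df$body_mass_std <- msc$values
    scaling$body_mass <- msc[c("center", "scale", "name")]
  }

  X <- design_columns(spec$population, df, spec)
  blocks <- lapply(names(spec$blocks), function(nm) {
    bk <- spec$blocks[[nm]]
    lv <- block_levels(bk$group, df)
    val <- block_values(bk$group, df)
    bad <- setdiff(unique(val), lv)
    if (length(bad)) abort(sprintf("unexpected level(s) in %s: %s", bk$group,
                                   paste(bad, collapse = ", ")))
    param <- bk$param %||% rep("noncentered", length(bk$coefs))
    list(name = nm, group = bk$group, coefs = bk$coefs, param = param,
         levels = lv, index = match(val, lv),
         Z = design_columns(bk$coefs, df, spec))
  })
  names(blocks) <- names(spec$blocks)
  list(y = y, X = X, blocks = blocks, data = df, rows_kept = which(keep),
       scaling = scaling)
}

jags_model_code <- function(spec, design, sample_prior = FALSE) {
  pr <- spec$priors
  lines <- c("model {")
  if (!sample_prior) {
    terms <- "inprod(X[n,], b)"
    for (bk in design$blocks) {
      for (c in seq_along(bk$coefs)) {
        terms <- c(terms, sprintf("u_%s[g_%s[n],%d] * Zm_%s[n,%d]",
                                  bk$name, bk$name, c, bk$name, c))
      }
    }
    lines <- c(lines,
               "  for (n in 1:N) {",
               paste0("    mu[n] <- ", paste(terms, collapse = " +\n      ")),
               "    y[n] ~ dnorm(mu[n], tau)",
               "  }")
  }
  lines <- c(lines, sprintf("  for (k in 1:%d) { b[k] ~ dnorm(0, %.10g) }",
                            ncol(design$X), 1 / pr$b_scale^2))
  for (bk in design$blocks) {
    nc <- length(bk$coefs)
    L <- length(bk$levels)
    for (c in seq_len(nc)) {
      if (bk$param[c] == "centered") {
        lines <- c(lines, sprintf(
          "  for (j in 1:%d) { u_%s[j,%d] ~ dnorm(0, pow(sd_%s[%d], -2)) }",
          L, bk$name, c, bk$name, c))
      } else {
        lines <- c(lines, sprintf(
          "  for (j in 1:%d) { z_%s[j,%d] ~ dnorm(0, 1); u_%s[j,%d] <- sd_%s[%d] * z_%s[j,%d] }",
          L, bk$name, c, bk$name, c, bk$name, c, bk$name, c))
      }
    }
    lines <- c(lines,
      sprintf("  for (c in 1:%d) { sd_%s[c] ~ dexp(%.10g) }", nc, bk$name, pr$sd_rate))
  }
  lines <- c(lines,
             sprintf("  sigma ~ dt(0, %.10g, %d) T(0,)", 1 / pr$sigma_scale^2,
                     as.integer(pr$sigma_df)),
             "  tau <- pow(sigma, -2)",
             "}")
  paste(lines, collapse = "\n")
}

## mcmc.list -> array [iteration, chain, parameter] with readable names
relabel_draws <- function(samples, spec, design) {
  mat <- lapply(samples, as.matrix)
  raw <- colnames(mat[[1]])
  new <- raw
  new[raw == "sigma"] <- "sigma"
  bmask <- grepl("^b\\[", raw)
  new[bmask] <- paste0("b_", spec$population[as.integer(sub("^b\\[(\\d+)\\]$", "\\1", raw[bmask]))])
  new[raw == "b"] <- paste0("b_", spec$population[1])
  for (bk in design$blocks) {
    sdm <- grepl(sprintf("^sd_%s\\[", bk$name), raw)
    new[sdm] <- paste0("sd_", bk$name, "__",
                       bk$coefs[as.integer(sub(".*\\[(\\d+)\\]$", "\\1", raw[sdm]))])
    # JAGS reports length-1 vectors without the bracket
    new[raw == paste0("sd_", bk$name)] <- paste0("sd_", bk$name, "__", bk$coefs[1])
    um <- grepl(sprintf("^u_%s\\[", bk$name), raw)
    if (any(um)) {
      ij <- do.call(rbind, regmatches(raw[um], regexec("\\[(\\d+),(\\d+)\\]$", raw[um])))
      new[um] <- sprintf("r_%s[%s,%s]", bk$name,
                         bk$levels[as.integer(ij[, 2])],
                         bk$coefs[as.integer(ij[, 3])])
    }
  }
  arr <- array(NA_real_, dim = c(nrow(mat[[1]]), length(mat), length(raw)),
               dimnames = list(NULL, NULL, new))
  for (ch in seq_along(mat)) arr[, ch, ] <- mat[[ch]]
  arr
}

ensure_glm_module <- function() {
  if (!"glm" %in% rjags::list.modules()) rjags::load.module("glm", quiet = TRUE)
}

#' Fit a declared model with the JAGS backend
#'
#' Translates the model spec into JAGS code (non-centered group effects),
#' builds the design from the non-missing rows of the outcome and covariates
#' (no listwise deletion across outcomes), standardizes the outcome by 2 SD
#' when the spec says so, and samples with `settings$chains` chains seeded
#' deterministically from `settings$seed` — identical seed, settings and data
#' give bit-identical draws. The stored draw count is
#' `chains * (iterations - warmup)`.
#'
#' @param spec A model spec from [season_model_spec()], [growth_model_spec()]
#'   or [intercept_model_spec()].
#' @param data Scored, classified observation table (see
#'   [prepare_model_data()]).
#' @param settings A [sampler_settings()].
#' @param sample_prior `"no"` (default) or `"only"` for prior-only sampling
#'   (no likelihood; useful to check the implied prior scales).
#' @param min_rows Floor on the number of usable rows (default 30).
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `hd_fit` holding the labelled draws array
#'   (`iteration x chain x parameter`), the spec, priors, scaling records,
#'   design bookkeeping, settings, JAGS model code and runtime.
#' @export
fit_model <- function(spec, data, settings = sampler_settings(),
                      sample_prior = c("no", "only"), min_rows = 30,
                      quiet = TRUE) {
  stopifnot(inherits(spec, "hd_model_spec"))
  sample_prior <- match.arg(sample_prior)
  prior_only <- sample_prior == "only"
  design <- build_design(spec, data)
  if (!prior_only && length(design$y) < min_rows) {
    abort(sprintf("only %d usable rows for outcome %s (floor %d)",
                  length(design$y), spec$outcome, min_rows))
  }

  code <- jags_model_code(spec, design, sample_prior = prior_only)
  jdata <- list()
  if (!prior_only) {
    jdata <- list(N = length(design$y), y = design$y, X = design$X)
    for (bk in design$blocks) {
      jdata[[paste0("g_", bk$name)]] <- bk$index
      jdata[[paste0("Zm_", bk$name)]] <- bk$Z
    }
  }

  base_seed <- as.integer(abs(settings$seed) %% 2147480000L)
  inits <- lapply(seq_len(settings$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = base_seed + ch)
  })
  monitors <- c("b", "sigma",
                unlist(lapply(design$blocks, function(bk)
                  c(paste0("sd_", bk$name), paste0("u_", bk$name)))))

  ensure_glm_module()
  adapt <- min(500L, max(1L, settings$warmup %/% 2L))
  burn <- settings$warmup - adapt
  kept <- settings$iterations - settings$warmup

  t0 <- Sys.time()
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = jdata, inits = inits,
                            n.chains = settings$chains, n.adapt = adapt,
                            quiet = TRUE)
    if (burn > 0) update(jm, burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = kept, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  runtime <- as.numeric(Sys.time() - t0, units = "secs")

  draws <- relabel_draws(samples, spec, design)
  structure(list(
    draws = draws, spec = spec, priors = spec$priors,
    scaling = design$scaling,
    design = design[c("X", "blocks", "rows_kept")],
    data = design$data, y = design$y,
    settings = settings, sample_prior = prior_only,
    jags_code = code,
    backend = paste0("rjags/JAGS ", paste(rjags::jags.version(), collapse = ".")),
    n_obs = if (prior_only) 0L else length(design$y),
    runtime_s = runtime
  ), class = "hd_fit")
}

#' @export
print.hd_fit <- function(x, ...) {
  cat(sprintf("<hd_fit: %s model for %s, backend %s>\n",
              x$spec$family, x$spec$outcome, x$backend))
  cat(sprintf("  %d observations; %d chains x %d kept draws; seed %d; %.1f s\n",
              x$n_obs, dim(x$draws)[2], dim(x$draws)[1],
              x$settings$seed, x$runtime_s))
  cat(sprintf("  priors: b ~ normal(0, %g); sd ~ exp(%g); sigma ~ student_t(%g, 0, %g)\n",
              x$priors$b_scale, x$priors$sd_rate, x$priors$sigma_df,
              x$priors$sigma_scale))
  cat(sprintf("  outcome scaling: center %.4g, scale %.4g\n",
              x$scaling$y$center, x$scaling$y$scale))
  invisible(x)
}

#' Flatten the draws of a fit
#'
#' `draws_matrix()` stacks chains into a `(chains x kept) x parameter`
#' matrix; `tidy_draws()` returns the long tidy form (one row per chain,
#' iteration and parameter) for export.
#'
#' @param fit An `hd_fit`.
#' @param parameters Optional character vector or regular expression
#'   (`regex = TRUE`) selecting parameters.
#' @param regex Treat `parameters` as a regular expression.
#' @return A matrix, or a tibble for `tidy_draws()`.
#' @export
draws_matrix <- function(fit, parameters = NULL, regex = FALSE) {
  arr <- fit$draws
  pn <- dimnames(arr)[[3]]
  sel <- select_parameters(pn, parameters, regex)
  out <- do.call(rbind, lapply(seq_len(dim(arr)[2]), function(ch) {
    m <- arr[, ch, sel, drop = FALSE]
    dim(m) <- c(dim(arr)[1], length(sel))
    m
  }))
  colnames(out) <- pn[sel]
  out
}

#' @rdname draws_matrix
#' @export
tidy_draws <- function(fit, parameters = NULL, regex = FALSE) {
  arr <- fit$draws
  pn <- dimnames(arr)[[3]]
  sel <- select_parameters(pn, parameters, regex)
  tidyr::expand_grid(chain = seq_len(dim(arr)[2]), draw = seq_len(dim(arr)[1]),
                     parameter = pn[sel]) |>
    dplyr::mutate(value = as.vector(aperm(arr[, , sel, drop = FALSE], c(3, 1, 2))))
}

select_parameters <- function(pn, parameters, regex) {
  if (is.null(parameters)) return(seq_along(pn))
  if (regex) return(grep(parameters, pn))
  miss <- setdiff(parameters, pn)
  if (length(miss)) abort(sprintf("unknown parameter(s): %s", paste(miss, collapse = ", ")))
  match(parameters, pn)
}
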