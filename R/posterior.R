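## Posterior surfaces: expectation grids, specialization contrasts,
## posterior predictive checks. All summaries are pure functions of the
## stored draws.

spec_block_name <- function(fit) {
  switch(fit$spec$family,
         season = "spec_sex", growth = "spec_group",
         abort(sprintf("no specialization grouping in a %s model", fit$spec$family)))
}

default_grid <- function(fit, age_seq = seq(11, 17, by = 0.5)) {
  switch(fit$spec$family,
    season = tidyr::expand_grid(sex = sex_levels,
                                specialization = specialization_levels,
                                phase = phase_levels),
    growth = tidyr::expand_grid(sex = sex_levels,
                                specialization = specialization_levels,
                                age = age_seq),
    abort(sprintf("no default prediction grid for a %s model", fit$spec$family)))
}

## expectation draws (standardized scale) for each grid row: ndraws x ngrid
expectation_draws <- function(fit, grid) {
  spec <- fit$spec
  dm <- draws_matrix(fit)
  gdat <- tibble::tibble(
    sex = grid$sex,
    phase = if ("phase" %in% names(grid)) grid$phase else NA,
    chronological_age = if ("age" %in% names(grid)) grid$age else NA,
    body_mass_std = 0   # covariate reference: pooled mean
  )
  Xg <- design_columns(spec$population, gdat, spec)
  mu <- dm[, paste0("b_", spec$population), drop = FALSE] %*% t(Xg)

  bname <- spec_block_name(fit)
  bk <- fit$design$blocks[[bname]]
  lev <- switch(spec$family,
                season = paste(grid$specialization, grid$sex, sep = ":"),
                growth = as.character(grid$specialization))
  bad <- setdiff(unique(lev), bk$levels)
  if (length(bad)) abort(sprintf("factor level(s) not in the fitted model: %s",
                                 paste(bad, collapse = ", ")))
  Zg <- design_columns(bk$coefs, gdat, spec)
  for (c in seq_along(bk$coefs)) {
    r_c <- dm[, sprintf("r_%s[%s,%s]", bname, lev, bk$coefs[c]), drop = FALSE]
    mu <- mu + r_c * rep(Zg[, c], each = nrow(dm))
  }
  mu
}

#' Posterior expectations over a factor grid with 68% ribbons
#'
#' Evaluates the posterior distribution of the expected outcome (the linear
#' predictor, i.e. the epistemic uncertainty of the group mean, not the
#' posterior predictive spread) at each grid point: sex by specialization by
#' season phase for the within-season model, or sex by specialization by
#' chronological age for the growth model. Other group levels are held at the
#' population line and standardized body mass at 0 (the pooled mean). The
#' central 68% interval (16th/84th percentiles) is comparable to plus/minus
#' one standard deviation.
#'
#' @param fit An `hd_fit` of a season or growth model.
#' @param grid Optional prediction grid; defaults to the full factor grid of
#'   the retained levels, including `unknown`/`not_classified`.
#' @param prob Central interval probability (default 0.68).
#' @param scale `"natural"` (back-transformed via the stored scaling record)
#'   or `"standardized"`.
#' @param keep_draws Attach the per-grid-point expectation draws as a
#'   list-column.
#' @return Tibble: grid variables plus `est` (posterior median), `lo`, `hi`.
#' @export
predict_expected <- function(fit, grid = NULL, prob = 0.68,
                             scale = c("natural", "standardized"),
                             keep_draws = FALSE) {
  scale <- match.arg(scale)
  grid <- grid %||% default_grid(fit)
  mu <- expectation_draws(fit, grid)
  if (scale == "natural") mu <- unstandardize(mu, fit$scaling$y)
  a <- (1 - prob) / 2
  out <- grid
  out$est <- unname(apply(mu, 2, median))
  out$lo <- unname(apply(mu, 2, quantile, probs = a))
  out$hi <- unname(apply(mu, 2, quantile, probs = 1 - a))
  if (keep_draws) out$draws <- lapply(seq_len(ncol(mu)), function(j) mu[, j])
  out
}

#' Specialization contrasts within sex
#'
#' Posterior difference between two specialization-onset categories within a
#' sex, computed draw-by-draw (preserving posterior correlation), at each
#' season phase (season model) or at a set of ages (growth model). Both the
#' standardized and natural scales are reported; differences back-transform
#' through the scale factor alone.
#'
#' @param fit An `hd_fit` of a season or growth model.
#' @param sex `"female"` or `"male"`.
#' @param level_a,level_b Specialization categories to contrast (a minus b).
#' @param age_seq Ages at which growth-model contrasts are evaluated.
#' @return A tibble with one row per phase/age: posterior `mean`, `median`,
#'   central 68% and 90% intervals (standardized scale), the same on the
#'   natural scale (`*_nat`), the posterior probability the difference
#'   exceeds zero, and the difference draws as a list-column `draws_std`.
#' @export
contrast_specialization <- function(fit, sex, level_a, level_b,
                                    age_seq = seq(11, 17, by = 1)) {
  sex <- match.arg(sex, sex_levels)
  for (lv in c(level_a, level_b)) {
    if (!lv %in% specialization_levels) {
      abort(sprintf("unknown specialization level '%s'", lv))
    }
  }
  units <- switch(fit$spec$family,
                  season = tibble::tibble(phase = factor(phase_levels,
                                                         levels = phase_levels)),
                  growth = tibble::tibble(age = age_seq))
  ga <- dplyr::mutate(units, sex = sex, specialization = level_a)
  gb <- dplyr::mutate(units, sex = sex, specialization = level_b)
  diff <- expectation_draws(fit, ga) - expectation_draws(fit, gb)
  dimnames(diff) <- NULL
  sc <- fit$scaling$y$scale

  out <- units
  out$sex <- sex
  out$level_a <- level_a
  out$level_b <- level_b
  out$mean <- colMeans(diff)
  out$median <- apply(diff, 2, median)
  out$lo68 <- unname(apply(diff, 2, quantile, probs = 0.16))
  out$hi68 <- unname(apply(diff, 2, quantile, probs = 0.84))
  out$lo90 <- unname(apply(diff, 2, quantile, probs = 0.05))
  out$hi90 <- unname(apply(diff, 2, quantile, probs = 0.95))
  out$mean_nat <- out$mean * sc
  out$lo90_nat <- out$lo90 * sc
  out$hi90_nat <- out$hi90 * sc
  out$p_gt0 <- apply(diff, 2, function(d) mean(d > 0))
  out$draws_std <- lapply(seq_len(ncol(diff)), function(j) diff[, j])
  out
}

#' Posterior predictive check
#'
#' Simulates replicate data sets from the fitted posterior (full linear
#' predictor including all group effects, plus residual noise) and compares
#' observed summary statistics — overall mean and SD, and per-group means —
#' against their replicate distributions. The tail probability is the
#' fraction of replicates at or above the observed value; values near 0 or 1
#' flag misfit.
#'
#' @param fit An `hd_fit`.
#' @param n_rep Number of replicate data sets (default 200).
#' @param seed Seed for the replicate noise (defaults to the fit seed).
#' @return Tibble with one row per statistic: `observed`, `rep_mean`,
#'   `rep_q05`, `rep_q95`, `p_tail`; the replicate count is recorded in the
#'   `n_rep` attribute.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = NULL) {
  if (fit$sample_prior) abort("posterior predictive checks need a likelihood fit")
  dm <- draws_matrix(fit)
  idx <- round(seq(1, nrow(dm), length.out = n_rep))
  dm <- dm[idx, , drop = FALSE]
  spec <- fit$spec

  mu <- dm[, paste0("b_", spec$population), drop = FALSE] %*% t(fit$design$X)
  for (bk in fit$design$blocks) {
    for (c in seq_along(bk$coefs)) {
      r_c <- dm[, sprintf("r_%s[%s,%s]", bk$name, bk$levels[bk$index], bk$coefs[c]),
                drop = FALSE]
      mu <- mu + r_c * rep(bk$Z[, c], each = nrow(dm))
    }
  }
  set.seed(seed %||% fit$settings$seed)
  yrep <- mu + matrix(rnorm(length(mu), sd = rep(dm[, "sigma"], ncol(mu))),
                      nrow(mu), ncol(mu))

  df <- fit$data
  groups <- switch(spec$family,
                   season = paste(df$sex, df$phase, sep = ":"),
                   growth = as.character(df$sex),
                   rep("all", nrow(df)))
  stat_fns <- c(list(mean = function(v) mean(v), sd = function(v) sd(v)),
                lapply(setNames(unique(groups), paste0("mean[", unique(groups), "]")),
                       function(g) { force(g); function(v) mean(v[groups == g]) }))
  obs <- vapply(stat_fns, function(f) f(fit$y), 0)
  rep_stats <- vapply(stat_fns, function(f) apply(yrep, 1, f), numeric(nrow(yrep)))

  out <- tibble::tibble(
    statistic = names(stat_fns),
    observed = unname(obs),
    rep_mean = colMeans(rep_stats),
    rep_q05 = apply(rep_stats, 2, quantile, probs = 0.05),
    rep_q95 = apply(rep_stats, 2, quantile, probs = 0.95),
    p_tail = vapply(seq_along(stat_fns), function(j) mean(rep_stats[, j] >= obs[j]), 0)
  )
  attr(out, "n_rep") <- n_rep
  out
}

#' Plot prediction ribbons by specialization within sex
#'
#' Sex-faceted display of [predict_expected()] output: season phases on the
#' x-axis with point ranges, or chronological age with shaded 68% ribbons,
#' colored by specialization-onset category.
#'
#' @param predictions Output of [predict_expected()].
#' @param outcome_label Y-axis label.
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions, outcome_label = "outcome") {
  if ("phase" %in% names(predictions)) {
    p <- ggplot2::ggplot(predictions,
        ggplot2::aes(x = .data$phase, y = .data$est,
                     colour = .data$specialization,
                     group = .data$specialization)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                               position = ggplot2::position_dodge(0.35)) +
      ggplot2::geom_line(position = ggplot2::position_dodge(0.35))
  } else {
    p <- ggplot2::ggplot(predictions,
        ggplot2::aes(x = .data$age, y = .data$est,
                     colour = .data$specialization,
                     fill = .data$specialization)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           alpha = 0.25, colour = NA) +
      ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~sex) +
    ggplot2::labs(y = outcome_label, caption = "shaded/whiskered: central 68% credible interval") +
    ggplot2::theme_minimal()
}
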