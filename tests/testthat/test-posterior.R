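# One moderate fit shared across the posterior-surface tests.
shared_fit <- local({
  co <- simulate_cohort(sim_config(seed = 14))
  d <- prepare_model_data(co$table)
  fit_model(season_model_spec("cmj"), d,
            quick_settings(seed = 6, chains = 2, iterations = 1800, warmup = 300))
})

test_that("interval endpoints equal the empirical quantiles of the same draws", {
  pred <- predict_expected(shared_fit, keep_draws = TRUE)
  for (j in c(1, 7, 20)) {
    dr <- pred$draws[[j]]
    expect_equal(pred$lo[j], unname(quantile(dr, 0.16)))
    expect_equal(pred$hi[j], unname(quantile(dr, 0.84)))
    expect_equal(pred$est[j], median(dr))
  }
  # grid covers every retained level
  expect_equal(nrow(pred), 2 * 4 * 3)
  expect_error(predict_expected(shared_fit,
    grid = tibble::tibble(sex = "male", specialization = "semi_pro", phase = "pre")),
    "semi_pro")
})

test_that("back-transform of a prediction at the standardization mean is exact", {
  std <- predict_expected(shared_fit, scale = "standardized", keep_draws = TRUE)
  nat <- predict_expected(shared_fit, scale = "natural", keep_draws = TRUE)
  rec <- shared_fit$scaling$y
  expect_equal(nat$est, unstandardize(std$est, rec))
  # a zero standardized prediction maps to the pooled raw mean
  expect_equal(unstandardize(0, rec), mean(shared_fit$data$cmj))
})

test_that("self-contrast is identically zero and contrasts are antisymmetric", {
  ct_self <- contrast_specialization(shared_fit, "male", "pre_puberty", "pre_puberty")
  expect_true(all(vapply(ct_self$draws_std, function(d) all(d == 0), TRUE)))
  expect_true(all(ct_self$lo90 == 0 & ct_self$hi90 == 0))

  ab <- contrast_specialization(shared_fit, "female", "pre_puberty", "late_puberty")
  ba <- contrast_specialization(shared_fit, "female", "late_puberty", "pre_puberty")
  for (j in seq_len(nrow(ab))) {
    expect_equal(ab$draws_std[[j]], -ba$draws_std[[j]])
  }
  expect_equal(ab$mean, -ba$mean)
  expect_error(contrast_specialization(shared_fit, "male", "pre_puberty", "none"),
               "unknown specialization level")
})

test_that("68% interval width tracks twice the posterior SD for normal-ish marginals", {
  # checked on the identified expectation at each grid cell (the population
  # intercept alone shares a redundant direction with the cell intercepts and
  # is not approximately normal)
  pred <- predict_expected(shared_fit, keep_draws = TRUE)
  ratio <- vapply(pred$draws, function(d)
    unname(quantile(d, 0.84) - quantile(d, 0.16)) / (2 * sd(d)), 0)
  expect_lt(max(abs(ratio - 1)), 0.15)
})

test_that("rhat and ess behave correctly on constructed chains", {
  set.seed(33)
  # i.i.d. chains from one distribution
  iid <- array(rnorm(1500 * 4), dim = c(1500, 4, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  dg <- diagnostics(iid, ess_min = 400)
  expect_true(dg$pass)
  expect_true(all(dg$parameters$rhat > 0.99 & dg$parameters$rhat < 1.01))
  # ESS of i.i.d. draws is close to the total draw count
  expect_true(all(abs(dg$parameters$ess_bulk / 6000 - 1) < 0.2))

  # one chain shifted by 10 SDs: flagged
  shifted <- iid
  shifted[, 4, 1] <- shifted[, 4, 1] + 10
  dg2 <- diagnostics(shifted)
  expect_gt(dg2$parameters$rhat[1], 1.1)
  expect_false(dg2$pass)

  # strongly autocorrelated chains: ESS far below the draw count
  ar <- array(0, dim = c(1500, 4, 1), dimnames = list(NULL, NULL, "a"))
  for (ch in 1:4) {
    x <- numeric(1500); for (t in 2:1500) x[t] <- 0.95 * x[t - 1] + rnorm(1)
    ar[, ch, 1] <- x
  }
  expect_lt(diagnostics(ar)$parameters$ess_bulk, 1500)

  expect_error(diagnostics(array(rnorm(100), dim = c(100, 1, 1))), "2 chains")
})

test_that("own convergence statistics agree with coda on well-behaved chains", {
  set.seed(44)
  arr <- array(rnorm(1000 * 4, mean = 2), dim = c(1000, 4, 1),
               dimnames = list(NULL, NULL, "a"))
  ml <- coda::mcmc.list(lapply(1:4, function(ch) coda::mcmc(arr[, ch, 1])))
  expect_equal(rhat(arr[, , 1]),
               unname(coda::gelman.diag(ml)$psrf[1, 1]), tolerance = 0.01)
  expect_equal(ess_bulk(arr[, , 1]),
               unname(coda::effectiveSize(ml)[1]), tolerance = 0.15)
})

test_that("posterior predictive checks are calibrated for a well-specified fit", {
  ppc <- posterior_predictive_check(shared_fit, n_rep = 150)
  expect_equal(attr(ppc, "n_rep"), 150)
  # data generated from the model family itself: tails should be unremarkable
  expect_true(all(ppc$p_tail > 0.01 & ppc$p_tail < 0.99))
  inside <- ppc$observed >= ppc$rep_q05 & ppc$observed <= ppc$rep_q95
  expect_gte(mean(inside), 0.9)
  expect_true("mean" %in% ppc$statistic)
  # pure function of stored draws: repeated summaries identical
  expect_equal(posterior_predictive_check(shared_fit, n_rep = 150), ppc)
})

test_that("prediction plots build for both model families", {
  pred <- predict_expected(shared_fit)
  p <- plot_predictions(pred, "countermovement jump (cm)")
  expect_s3_class(p, "ggplot")
})
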