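test_that("season specs carry the body-mass term only for size-dependent outcomes", {
  expect_true("body_mass_std" %in% season_model_spec("yoyo_ir1")$population)
  expect_true("body_mass_std" %in% season_model_spec("fitness_score")$population)
  expect_false("body_mass_std" %in% season_model_spec("cmj")$population)
  expect_false("body_mass_std" %in% season_model_spec("line_drill")$population)
  expect_error(season_model_spec("bench_press"), "unknown outcome")
})

test_that("growth specs declare the quadratic structure and record the centering", {
  spec <- growth_model_spec("line_drill")
  expect_true(all(c("age_c", "age_c2") %in% spec$population))
  expect_equal(spec$age_center, 14.0)
  expect_true("spec_group" %in% names(spec$blocks))
  expect_setequal(spec$blocks$spec_group$coefs, c("Intercept", "age_c", "age_c2"))
  # the unknown onset category is an ordinary retained level
  expect_true("unknown" %in% hoopdev:::block_levels("spec_category", NULL))
})

test_that("the design keeps one row per non-missing observation", {
  co <- simulate_cohort(sim_config(seed = 8))
  d <- prepare_model_data(co$table)
  d$cmj[c(3, 10)] <- NA
  d$yoyo_ir1[5] <- NA
  des_cmj <- hoopdev:::build_design(season_model_spec("cmj"), d)
  expect_equal(length(des_cmj$y), nrow(d) - 2)   # yoyo missingness irrelevant
  des_yy <- hoopdev:::build_design(season_model_spec("yoyo_ir1"), d)
  expect_equal(length(des_yy$y), nrow(d) - 1)
  # standardized outcome has SD exactly 0.5
  expect_equal(sd(des_cmj$y), 0.5)
})

test_that("an intercept-only fit recovers the sample mean under the weak prior", {
  set.seed(99)
  d <- tibble::tibble(player_id = "x", cmj = rnorm(500, mean = 2.0, sd = 1.0))
  f <- fit_model(intercept_model_spec("cmj"), d, quick_settings(seed = 4))
  post_mean <- mean(draws_matrix(f, "b_Intercept"))
  expect_gt(post_mean, 1.9)
  expect_lt(post_mean, 2.1)
  expect_equal(post_mean, mean(d$cmj), tolerance = 0.05)
  # residual scale is recovered too
  expect_equal(mean(draws_matrix(f, "sigma")), sd(d$cmj), tolerance = 0.1)
})

test_that("identical seeds give bit-identical draws; different seeds differ", {
  co <- simulate_cohort(sim_config(seed = 8))
  d <- prepare_model_data(co$table)
  st <- quick_settings(seed = 11, iterations = 300, warmup = 150)
  f1 <- fit_model(season_model_spec("cmj"), d, st)
  f2 <- fit_model(season_model_spec("cmj"), d, st)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_model(season_model_spec("cmj"), d, quick_settings(seed = 12,
                  iterations = 300, warmup = 150))
  expect_false(identical(f1$draws, f3$draws))
  # draw count contract
  expect_equal(dim(f1$draws)[1:2], c(150L, 2L))
})

test_that("prior-only sampling reproduces the declared prior scales", {
  d <- tibble::tibble(player_id = "x", cmj = rnorm(50))
  f <- fit_model(intercept_model_spec("cmj"), d,
                 sampler_settings(chains = 2, iterations = 3000, warmup = 500,
                                  seed = 21),
                 sample_prior = "only")
  b <- draws_matrix(f, "b_Intercept")
  expect_equal(sd(b), 5, tolerance = 0.25)  # normal(0, 5) margin
  expect_equal(mean(b), 0, tolerance = 0.3)
})

test_that("settings and spec invariants are enforced", {
  expect_error(sampler_settings(chains = 1), "at least 2 chains")
  expect_error(sampler_settings(iterations = 500, warmup = 500), "smaller")
  d <- tibble::tibble(player_id = "x", cmj = rnorm(10))
  expect_error(fit_model(intercept_model_spec("cmj"), d, quick_settings()),
               "floor")
  d2 <- tibble::tibble(player_id = "x", cmj = c(rnorm(49), Inf))
  expect_error(fit_model(intercept_model_spec("cmj"), d2, quick_settings(),
                         min_rows = 10), "non-finite")
})

test_that("specs and priors serialize to readable YAML", {
  y <- spec_to_yaml(season_model_spec("yoyo_ir1"))
  parsed <- yaml::yaml.load(y)
  expect_equal(parsed$outcome, "yoyo_ir1")
  expect_equal(parsed$priors$b_scale, 5)
  expect_true("body_mass_std" %in% parsed$population)
})

test_that("pooling collapses group predictions when the group SDs are pinned near zero", {
  # exponential(1e6) prior puts each group SD in a point mass near zero:
  # group-level predictions must collapse onto the population line
  co <- simulate_cohort(sim_config(seed = 8))
  d <- prepare_model_data(co$table)
  spec <- season_model_spec("cmj", priors = prior_set(sd_rate = 1e6))
  f <- fit_model(spec, d, quick_settings(seed = 5, iterations = 400, warmup = 200))
  pred <- predict_expected(f, scale = "standardized")
  spread <- pred |>
    dplyr::group_by(sex, phase) |>
    dplyr::summarise(spread = diff(range(est)), .groups = "drop")
  expect_lt(max(spread$spread), 1e-3)
})
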