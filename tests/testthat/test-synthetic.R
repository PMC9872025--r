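test_that("the same seed reproduces the cohort bit-identically", {
  a <- simulate_cohort(sim_config(seed = 77))
  b <- simulate_cohort(sim_config(seed = 77))
  expect_identical(a$table, b$table)
  expect_identical(a$truth$outcomes, b$truth$outcomes)
  c <- simulate_cohort(sim_config(seed = 78))
  expect_false(identical(a$table, c$table))
})

test_that("default cohorts satisfy every observation-table invariant", {
  co <- simulate_cohort(sim_config(seed = 5))
  rep <- validate_table(co$table)
  expect_equal(sum(rep$n_fail[rep$severity == "error"]), 0L)
  expect_true(table_valid(rep))
  expect_equal(attr(co$table, "provenance"), "synthetic")
  # cohort shape: ~180 players at the configured sex ratio
  players <- dplyr::distinct(co$table, player_id, sex)
  expect_equal(nrow(players), 181L)
  expect_equal(sum(players$sex == "female"), 40L)
})

test_that("the noise-free limit equals the deterministic mean function exactly", {
  cfg <- noiseless_config(seed = 3)
  co <- simulate_cohort(cfg)
  tab <- co$table
  truthp <- co$truth$players
  for (i in sample(nrow(tab), 40)) {
    row <- tab[i, ]
    pl <- truthp[truthp$player_id == row$player_id, ]
    for (o in c("cmj", "line_drill", "yoyo_ir1")) {
      expected <- mean_function_oracle(cfg, as.character(row$sex),
                                       as.character(row$phase),
                                       attr(tab, "baseline_age")[i], o,
                                       pl$spec_category, pl$maturity_timing)
      expect_equal(row[[o]], expected, tolerance = 1e-9,
                   info = paste(o, row$player_id, row$phase))
    }
  }
})

test_that("stature growth is monotone within player in the noise-free limit", {
  co <- simulate_cohort(noiseless_config(seed = 9))
  mono <- co$table |>
    dplyr::arrange(player_id, season_year, phase) |>
    dplyr::group_by(player_id) |>
    dplyr::summarise(ok = all(diff(stature) >= -1e-9), .groups = "drop")
  expect_true(all(mono$ok))
})

test_that("female aPHV precedes male aPHV under the defaults", {
  co <- simulate_cohort(sim_config(seed = 21))
  pl <- co$truth$players
  expect_lt(mean(pl$aphv[pl$sex == "female"]), mean(pl$aphv[pl$sex == "male"]))
  expect_equal(mean(pl$aphv[pl$sex == "female"]), 11.9, tolerance = 0.3)
  expect_equal(mean(pl$aphv[pl$sex == "male"]), 13.9, tolerance = 0.2)
})

test_that("default pre-season cells sit within one SD of the published descriptives", {
  co <- simulate_cohort(sim_config(seed = 1))
  pre <- co$table[co$table$phase == "pre", ]
  cell <- function(g, s, f) mean(pre[[f]][pre$age_group == g & pre$sex == s])
  # U17 male stature 186.5 (7.5); U13 female CMJ 24.3 (3.9)
  expect_gt(cell("U17", "male", "stature"), 179)
  expect_lt(cell("U17", "male", "stature"), 194)
  expect_gt(cell("U13", "female", "cmj"), 20.4)
  expect_lt(cell("U13", "female", "cmj"), 28.2)
  # a few more published cells at the same +/- 1 SD tolerance
  expect_equal(cell("U13", "male", "stature"), 165.4, tolerance = 11.0)
  expect_equal(cell("U15", "male", "line_drill"), 33.57, tolerance = 3.7)
  expect_equal(cell("U17", "male", "yoyo_ir1"), 1203.3, tolerance = 348)
  expect_equal(cell("U13", "female", "line_drill"), 37.36, tolerance = 1.88)
})

test_that("cell means converge to the mean function at large n", {
  cfg <- sim_config(n_female = 1000, n_male = 1000, seed = 55)
  co <- simulate_cohort(cfg)
  d <- co$table
  ba <- attr(d, "baseline_age")
  for (s in c("female", "male")) {
    for (ph in c("pre", "mid", "end")) {
      sel <- d$sex == s & d$phase == ph
      n <- sum(sel)
      oracle <- mean(vapply(which(sel), function(i)
        mean_function_oracle(cfg, s, ph, ba[i], "cmj"), 0))
      oc <- cfg$outcomes$cmj
      se <- sqrt(sum(oc$player_sd^2) + oc$season_sd^2 + oc$residual_sd^2) / sqrt(n)
      expect_lt(abs(mean(d$cmj[sel]) - oracle), 3 * se + 0.5)  # 0.5: rounding to 1 cm
    }
  }
})

test_that("onset mixture produces category frequencies near the configured shares", {
  co <- simulate_cohort(sim_config(n_female = 800, n_male = 2800, seed = 13))
  pl <- co$truth$players
  freq <- table(pl$spec_category) / nrow(pl)
  expect_lt(abs(freq[["pre_puberty"]] - 0.46), 0.05)
  expect_lt(abs(freq[["mid_puberty"]] - 0.33), 0.05)
  expect_lt(abs(freq[["unknown"]] - 0.14), 0.04)
})

test_that("effect injection is exact, symmetric and inert at zero", {
  cfg <- sim_config(seed = 2)
  expect_identical(inject_specialization_effect(cfg, "pre_puberty", 0), cfg)
  up <- inject_specialization_effect(cfg, "mid_puberty", 0.4)
  dn <- inject_specialization_effect(cfg, "mid_puberty", -0.4)
  expect_equal(up$effects$specialization[["mid_puberty"]], 0.4)
  expect_equal(dn$effects$specialization[["mid_puberty"]], -0.4)
  expect_error(inject_specialization_effect(cfg, "semi_pro", 1), "unknown")

  # by construction the injected gap appears at large n; compare category
  # means of the residual from the no-effect oracle so age/sex composition
  # differences between categories cannot confound the check
  big <- inject_specialization_effect(
    sim_config(n_female = 600, n_male = 2100, seed = 17), "pre_puberty", 0.5)
  co <- simulate_cohort(big)
  d <- co$table
  ba <- attr(d, "baseline_age")
  pl <- co$truth$players
  cat_of <- setNames(pl$spec_category, pl$player_id)
  base <- vapply(seq_len(nrow(d)), function(i)
    mean_function_oracle(big, as.character(d$sex[i]), as.character(d$phase[i]),
                         ba[i], "cmj", spec_category = "unknown"), 0)
  resid <- d$cmj - base
  gap <- mean(resid[cat_of[d$player_id] == "pre_puberty"]) -
    mean(resid[cat_of[d$player_id] == "mid_puberty"])
  expect_lt(abs(gap / big$outcomes$cmj$pooled_sd_ref - 0.5), 0.06)
})

test_that("configs round-trip through serialization unchanged", {
  cfg <- inject_specialization_effect(sim_config(seed = 101), "late_puberty", -0.2)
  path <- withr::local_tempfile(fileext = ".json")
  sim_config_to_json(cfg, path)
  expect_identical(sim_config_from_json(path), cfg)
})

test_that("invalid configs are rejected with a collective message", {
  expect_error(sim_config(phase_completion = c(pre = 1.2, mid = 0.5, end = 0.5)),
               "probabilities")
  cfg_err <- tryCatch(
    sim_config(phase_completion = c(pre = -0.1, mid = 0.5, end = 0.5),
               measurement_error = c(stature = -1, body_mass = 0.42)),
    error = conditionMessage)
  expect_match(cfg_err, "probabilities")
  expect_match(cfg_err, "standard deviations")
})
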