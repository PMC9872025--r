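# Frozen expectations for the offset equation, hand-evaluated from the
# configured coefficients:
#   female: -7.709133 + 0.0042232 * (12.5 * 163.3) = 0.911474
#   male:   -7.999994 + 0.0036124 * (12.6 * 165.4) = -0.471608
test_that("maturity offset reproduces hand-evaluated values", {
  expect_equal(maturity_offset("female", 12.5, 163.3), 0.911474, tolerance = 1e-6)
  expect_equal(maturity_offset("male", 12.6, 165.4), -0.471608, tolerance = 1e-6)
  # degenerate product term: stature 0 returns the sex intercept
  cfg <- maturation_config()
  expect_equal(maturity_offset("female", 12, 0), cfg$coefficients$female$intercept)
  expect_error(maturity_offset("other", 12, 160), "unknown sex")
})

test_that("estimated age at PHV matches the published group-mean values", {
  expect_equal(round(age_at_phv("female", 12.5, 163.3), 1), 11.6)
  expect_equal(round(age_at_phv("male", 12.6, 165.4), 1), 13.1)
  expect_equal(round(age_at_phv("male", 14.2, 176.6), 1), 13.1)
})

test_that("offset and age at PHV are exact complements of chronological age", {
  set.seed(42)
  sex <- sample(c("female", "male"), 50, TRUE)
  age <- runif(50, 9, 18)
  st <- runif(50, 130, 200)
  expect_equal(age_at_phv(sex, age, st) + maturity_offset(sex, age, st), age)
})

test_that("maturity classification matches a brute-force oracle on a dense grid", {
  cfg <- maturation_config()
  grid <- expand.grid(sex = c("female", "male"),
                      age_group = c("U13", "U15", "U17"),
                      aphv = seq(9, 17, length.out = 850),
                      stringsAsFactors = FALSE)
  got <- classify_maturity(grid$sex, grid$age_group, grid$aphv, cfg)

  oracle <- mapply(function(s, g, a) {
    if (!((s == "female" && g == "U13") || (s == "male" && g %in% c("U13", "U15")))) {
      return("not_classified")
    }
    d <- a - cfg$reference[[s]]$aphv
    if (d < -0.5) "early" else if (d > 0.5) "late" else "average"
  }, grid$sex, grid$age_group, grid$aphv)
  expect_equal(as.character(got$status), unname(oracle))

  # exactly one label each, monotone in aPHV within applicable groups
  expect_false(any(is.na(got$status)))
  for (s in c("female", "male")) {
    sub <- got$status[grid$sex == s & grid$age_group == "U13"]
    ranks <- match(as.character(sub), c("early", "average", "late"))
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("the six-month band is boundary-inclusive and applicability is honored", {
  cfg <- maturation_config()
  ref_f <- cfg$reference$female$aphv
  at <- classify_maturity(c("female", "female"), "U13", c(ref_f - 0.5, ref_f + 0.5), cfg)
  expect_equal(as.character(at$status), c("average", "average"))

  expect_equal(as.character(classify_maturity("female", "U13", 11.6)$status), "average")
  expect_equal(as.character(classify_maturity("male", "U13", 13.1)$status), "early")
  expect_equal(as.character(classify_maturity("female", "U15", 11.2)$status), "not_classified")
  expect_equal(as.character(classify_maturity("female", "U17", 11.2)$status), "not_classified")
  expect_equal(as.character(classify_maturity("male", "U17", 13.0)$status), "not_classified")

  miss <- classify_maturity("male", "U13", NA_real_)
  expect_equal(as.character(miss$status), "not_classified")
  expect_match(miss$rule_note, "missing estimate")
})

test_that("the optional CI-aware mode only ever demotes to average", {
  cfg <- maturation_config()
  aphv <- seq(10.5, 13.5, by = 0.05)
  point <- classify_maturity("female", "U13", aphv, cfg)
  ci <- classify_maturity("female", "U13", aphv, cfg, ci_aware = TRUE)
  changed <- as.character(point$status) != as.character(ci$status)
  expect_true(all(as.character(ci$status)[changed] == "average"))
})

test_that("player-level assessment uses the first pre-season anthropometry", {
  tab <- tiny_table()
  res <- assess_maturity(tab)
  expect_equal(nrow(res), 3L)
  a <- res[res$player_id == "A", ]
  expect_equal(a$estimated_offset,
               maturity_offset("female", 12.8, 160.2), tolerance = 1e-10)
  expect_equal(as.character(res$status[res$player_id == "C"]), "not_classified")
})

test_that("config invariants are enforced", {
  expect_error(maturation_config(tolerance_years = 0.5,
    reference = list(
      female = list(onset = 12.5, onset_ci = c(12, 13), aphv = 11.9,
                    aphv_ci = c(11.8, 12.0)),
      male = list(onset = 11.1, onset_ci = c(10.8, 11.5), aphv = 13.9,
                  aphv_ci = c(13.8, 14.0)))),
    "onset must precede")
})
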