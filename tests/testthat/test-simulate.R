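test_that("the default normative cohort has 404 speakers, ages 20-93", {
  cohort <- simulate_normative_cohort(simulation_config(seed = 4))
  expect_equal(nrow(cohort), 404)
  expect_true(all(cohort$age >= 20 & cohort$age <= 93))
  expect_true(all(cohort$sex %in% c("F", "M")))
  expect_equal(validate_tables(cohort), character(0))
  # every sex-by-decade stratum is large enough for centile estimation
  bands <- default_age_bands()
  band <- cut(cohort$age, bands, right = FALSE)
  expect_true(all(table(cohort$sex, band) >= 20))
})

test_that("the cohort generator is seed-deterministic and guards allocation", {
  a <- simulate_normative_cohort(simulation_config(seed = 99))
  b <- simulate_normative_cohort(simulation_config(seed = 99))
  expect_identical(a, b)
  c <- simulate_normative_cohort(simulation_config(seed = 100))
  expect_false(identical(a, c))
  expect_error(
    simulate_normative_cohort(simulation_config(n_normative = 100)),
    "guarantee")
})

test_that("default templates encode the six qualitative group signatures", {
  tpl <- default_group_templates()
  expect_length(tpl, 6)
  expect_setequal(names(tpl), c("AoS", "ALS", "Kennedy", "PD", "SCA",
                                "Wilson"))
  for (t in tpl) {
    expect_true(all(vapply(t$dims, length, integer(1)) == 5))
    expect_equal(unname(vapply(t$dims, sum, numeric(1))), rep(1, 7))
  }
  # Kennedy: severe articulation, normal DDK
  expect_equal(sum(tpl$Kennedy$dims$articulation[4:5]), 1)
  expect_gte(tpl$Kennedy$dims$ddk[1], 0.8)
  # ALS and SCA: slow DDK (mass on levels >= 2)
  expect_gte(sum(tpl$ALS$dims$ddk[3:5]), 0.8)
  expect_gte(sum(tpl$SCA$dims$ddk[3:5]), 0.8)
  # SCA: articulation preserved
  expect_gte(tpl$SCA$dims$articulation[1], 0.8)
  # PD: voice deviance dominates, DDK near normal
  expect_gte(sum(tpl$PD$dims$voice[2:5]), 0.8)
  expect_gte(tpl$PD$dims$ddk[1], 0.8)
})

test_that("patients generated for target levels re-score to those levels", {
  rs <- small_refset()
  for (tpl in default_group_templates()[c("Kennedy", "ALS", "PD")]) {
    pats <- simulate_patient_group(tpl, rs, n = 8, seed = 21)
    specs <- rs$specs
    for (i in seq_len(nrow(pats))) {
      p <- score_profile(pats[i, ], rs)
      for (m in specs$name) {
        expect_identical(
          unname(p$component_scores[m]),
          pats[[paste0("target_", m)]][i],
          info = sprintf("%s speaker %d measure %s", tpl$group, i, m))
      }
    }
  }
})

test_that("an all-normal template yields all-zero profiles", {
  rs <- small_refset()
  tpl <- default_group_templates()$AoS
  tpl$dims <- lapply(tpl$dims, function(p) c(1, 0, 0, 0, 0))
  pats <- simulate_patient_group(tpl, rs, n = 5, seed = 3)
  devs <- score_table(pats, rs)
  expect_true(all(devs$total_devs == 0))
})

test_that("patient generation is seed-deterministic", {
  rs <- small_refset()
  tpl <- default_group_templates()$SCA
  expect_identical(simulate_patient_group(tpl, rs, n = 5, seed = 13),
                   simulate_patient_group(tpl, rs, n = 5, seed = 13))
})

test_that("band placement inverts the ladder for every attainable level", {
  set.seed(303)
  for (i in 1:200) {
    c50 <- rnorm(1, 50, 20)
    icd <- rexp(1, 1 / 8) + 0.05
    c5 <- c50 - icd
    c1 <- c5 - rexp(1, 1 / 5)
    ref <- data.frame(c1 = c1, c5 = c5, c50 = c50, icd = icd)
    lev <- sample(0:4, 1)
    pl <- devscreen:::.place_in_band(lev, ref)
    expect_identical(score_measure(pl$value, ref), as.integer(pl$level))
    expect_gte(pl$level, min(lev, 4))  # only ever adjusted toward severity
    # level-4 placements stay within the finite cap
    if (pl$level == 4) expect_gte(pl$value, c50 - 3 * icd)
  }
})

test_that("the direct deviance simulator is sized, seeded and calibrated", {
  devs <- simulate_devs_cohort(n_per_group = 10, seed = 5)
  expect_equal(nrow(devs), 60)
  expect_equal(as.integer(table(devs$group)), rep(10L, 6))
  expect_identical(devs, simulate_devs_cohort(n_per_group = 10, seed = 5))
  feats <- devs_feature_columns()
  expect_equal(devs$total_devs, rowSums(devs[, feats]))

  # marginal frequencies of a single-measure dimension match the template
  tpl <- default_group_templates()["Kennedy"]
  big <- simulate_devs_cohort(tpl, n_per_group = 2000, seed = 6)
  p_hat <- mean(big$SpeechRate == 0)
  p <- tpl$Kennedy$dims$speech_rate[1]
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 2000))
})
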