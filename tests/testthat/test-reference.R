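test_that("centile estimation interpolates between order statistics", {
  expect_equal(estimate_centiles(1:99, 0.50), 50)
  expect_equal(estimate_centiles(rep(7, 12), 0.3), 7)
  expect_equal(estimate_centiles(1:99, 0.05), 5.9)
  expect_error(estimate_centiles(numeric(0), 0.5), "no observations")
  expect_error(estimate_centiles(1:10, 0), "inside")
})

test_that("centile estimation matches a sort-and-interpolate oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:30, 1)
    v <- round(rnorm(n, 50, 20), 3)
    probs <- runif(4, 0.01, 0.99)
    expect_equal(estimate_centiles(v, probs), oracle_quantile(v, probs),
                 tolerance = 1e-12)
  }
  # monotone in p
  v <- rlnorm(25)
  q <- estimate_centiles(v, seq(0.05, 0.95, by = 0.05))
  expect_true(!is.unsorted(q))
})

test_that("built references are ordered, non-negative and fully stratified", {
  rs <- small_refset()
  refs <- rs$references
  expect_true(all(refs$c1 <= refs$c5 + 1e-12))
  expect_true(all(refs$c5 <= refs$c50 + 1e-12))
  expect_true(all(refs$icd >= 0))
  expect_equal(refs$icd, refs$c50 - refs$c5)
  # age-stratified measures: one row per sex x band; pooled: one per sex
  k <- length(rs$bands) - 1
  for (m in rs$specs$name) {
    sub <- refs[refs$measure == m, ]
    expected <- if (rs$specs$stratify_age[rs$specs$name == m]) 2 * k else 2
    expect_equal(nrow(sub), expected)
  }
})

test_that("orientation involution: high tail on V equals low tail on -V", {
  set.seed(17)
  cohort <- simulate_normative_cohort(
    simulation_config(n_normative = 60, seed = 17, bands = c(20, 94),
                      min_stratum_n = 10))
  specs_hi <- measure_registry()["jitter_ppq5", ]
  specs_lo <- specs_hi
  specs_lo$pathological_tail <- "low"
  neg <- cohort
  neg$jitter_ppq5 <- -neg$jitter_ppq5
  r_hi <- build_reference(cohort, specs_hi, bands = c(20, 94),
                          min_stratum_n = 10)$references
  r_lo <- build_reference(neg, specs_lo, bands = c(20, 94),
                          min_stratum_n = 10)$references
  expect_equal(r_hi[c("c1", "c5", "c50", "icd")],
               r_lo[c("c1", "c5", "c50", "icd")])
  # and the oriented median of a high-tail measure is minus the raw median
  f <- cohort$sex == "F"
  expect_equal(r_hi$c50[r_hi$sex == "F"],
               unname(-quantile(cohort$jitter_ppq5[f], 0.5, type = 7)))
})

test_that("undersized strata are refused by name", {
  cohort <- simulate_normative_cohort(
    simulation_config(n_normative = 60, seed = 3, bands = c(20, 94),
                      min_stratum_n = 10))
  expect_error(build_reference(cohort, bands = c(20, 94), min_stratum_n = 50),
               "min_stratum_n")
})

test_that("lookup pools MPT across age, matches bands, clamps out-of-range", {
  rs <- small_refset()
  mpt <- lookup_reference(rs, "mpt_seconds", 45, "F")
  expect_true(mpt$pooled_age)
  sr1 <- lookup_reference(rs, "speech_rate_phon_per_s", 45, "M")
  expect_equal(c(sr1$band_lo, sr1$band_hi), c(20, 55))
  sr2 <- lookup_reference(rs, "speech_rate_phon_per_s", 60, "M")
  expect_equal(c(sr2$band_lo, sr2$band_hi), c(55, 94))
  expect_warning(sr3 <- lookup_reference(rs, "speech_rate_phon_per_s", 19, "M"),
                 "clamped")
  expect_equal(sr3$band_lo, 20)
  expect_warning(sr4 <- lookup_reference(rs, "speech_rate_phon_per_s", 97, "M"),
                 "clamped")
  expect_equal(sr4$band_hi, 94)
  expect_error(lookup_reference(rs, "nope", 40, "F"), "unknown measure")
})

test_that("reference sets round-trip through the JSON document", {
  rs <- small_refset()
  path <- tempfile(fileext = ".json")
  write_reference_json(rs, path)
  rs2 <- read_reference_json(path)
  expect_equal(rs2$references, rs$references, tolerance = 1e-12)
  expect_equal(rs2$bands, rs$bands)
  expect_equal(rs2$specs$name, rs$specs$name)
  # a lookup through the re-read set is identical
  a <- lookup_reference(rs, "cpps_vowel", 33, "F")
  b <- lookup_reference(rs2, "cpps_vowel", 33, "F")
  expect_equal(b$c50, a$c50)
})
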