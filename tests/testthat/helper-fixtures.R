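# Shared fixtures built in code.

# A toy oriented reference with icd = 20 used across ladder tests.
toy_ref <- function() data.frame(c1 = 72, c5 = 80, c50 = 100, icd = 20)

# Small but valid normative setup (fewer speakers, two age bands) for tests
# that need a real reference set quickly.
small_refset <- function(seed = 11, n = 120, bands = c(20, 55, 94),
                         min_stratum_n = 15) {
  cfg <- simulation_config(n_normative = n, seed = seed, bands = bands,
                           min_stratum_n = min_stratum_n)
  cohort <- simulate_normative_cohort(cfg)
  build_reference(cohort, bands = bands, min_stratum_n = min_stratum_n)
}

# Full-size reference set, cached per test run.
full_refset <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      cohort <- simulate_normative_cohort(simulation_config(seed = seed))
      cache <<- build_reference(cohort)
    }
    cache
  }
})

# Rename a template's group label (for same-template null experiments).
relabel_template <- function(tpl, label) {
  tpl$group <- label
  tpl
}

# Map an oriented value back to the raw scale for a given pathological tail.
.orient_raw <- function(x_oriented, tail) {
  if (tail == "high") -x_oriented else x_oriented
}

# Random two-class dataset for classifier tests.
random_pair_data <- function(n, p = 7, seed) {
  set.seed(seed)
  list(x = matrix(sample(0:6, n * p, replace = TRUE), n, p),
       y = sample(c("a", "b"), n, replace = TRUE))
}
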