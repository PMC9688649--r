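#' Default sampling parameters for the raw speech measures
#'
#' One row per raw input column: distribution family (\code{"normal"} or
#' \code{"lognormal"} — strictly positive quantities such as perturbation
#' measures and repetition rates are log-normal), location (mean, or median
#' for the log-normal family), scale (SD, or SD of log), a linear age slope
#' (per year, centred at age 55; on the log scale for log-normal) and an
#' additive shift for male speakers (same scale convention).  Values are
#' plausible for adult speakers but are simulation knobs, not normative
#' claims.
#'
#' @return Data frame of per-measure sampling parameters.
#' @export
default_measure_params <- function() {
  p <- function(name, family, location, scale, age_slope = 0, sex_shift = 0,
                lo = -Inf, hi = Inf) {
    data.frame(name = name, family = family, location = location,
               scale = scale, age_slope = age_slope, sex_shift = sex_shift,
               lo = lo, hi = hi, stringsAsFactors = FALSE)
  }
  rbind(
    p("intelligibility_correct", "normal", 13.8, 0.8, lo = 0, hi = 15),
    p("articulation_errors", "lognormal", 3, 0.6, lo = 0, hi = 151),
    p("mpt_seconds", "normal", 21, 6, sex_shift = 3, lo = 3),
    p("jitter_ppq5", "lognormal", 0.30, 0.35, age_slope = 0.004),
    p("shimmer_apq11", "lognormal", 6.0, 0.30, age_slope = 0.003),
    p("f0sd_vowel", "lognormal", 2.0, 0.40),
    p("cpps_vowel", "normal", 14, 2.0, age_slope = -0.02),
    p("f0sd_sentence", "normal", 25, 6, sex_shift = -8, lo = 1),
    p("cpps_sentence", "normal", 10, 1.8, age_slope = -0.015),
    p("prosody_f0range_st", "normal", 6, 1.8, lo = 0.2),
    p("speech_rate_phon_per_s", "normal", 13.5, 1.5, age_slope = -0.02,
      lo = 2),
    p("amr_ba", "lognormal", 26, 0.12, age_slope = -0.002),
    p("amr_de", "lognormal", 26, 0.12, age_slope = -0.002),
    p("amr_go", "lognormal", 25, 0.12, age_slope = -0.002),
    p("amr_kla", "lognormal", 22, 0.13, age_slope = -0.002),
    p("amr_tra", "lognormal", 22, 0.13, age_slope = -0.002),
    p("smr_badego", "lognormal", 25, 0.12, age_slope = -0.002)
  )
}

#' Simulation configuration
#'
#' @param n_normative Normative cohort size (default 404).
#' @param n_per_group Patients per clinical group (default 10).
#' @param age_range Inclusive integer age range (default 20 to 93).
#' @param seed Integer seed; fully determines all generator output.
#' @param measure_params Per-measure sampling parameters, see
#'   [default_measure_params()].
#' @param bands Age-band edges used for the stratum-size guarantee.
#' @param min_stratum_n Guaranteed minimum speakers per sex-by-band stratum.
#' @return List of class \code{sim_config}.
#' @export
simulation_config <- function(n_normative = 404, n_per_group = 10,
                              age_range = c(20, 93), seed = 1,
                              measure_params = default_measure_params(),
                              bands = default_age_bands(),
                              min_stratum_n = 20) {
  structure(list(n_normative = n_normative, n_per_group = n_per_group,
                 age_range = age_range, seed = as.integer(seed),
                 measure_params = measure_params, bands = bands,
                 min_stratum_n = min_stratum_n),
            class = "sim_config")
}

# draw one raw value for measure row `pr` given age and sex
.draw_measure <- function(pr, age, sex) {
  shift <- pr$age_slope * (age - 55) + if (sex == "M") pr$sex_shift else 0
  x <- if (pr$family == "lognormal") {
    stats::rlnorm(1, meanlog = log(pr$location) + shift, sdlog = pr$scale)
  } else {
    stats::rnorm(1, mean = pr$location + shift, sd = pr$scale)
  }
  min(max(x, pr$lo), pr$hi)
}

#' Simulate a neurotypical normative cohort
#'
#' Generates \code{n_normative} speakers with sex and integer age, allocated
#' so that every sex-by-age-band stratum receives at least
#' \code{min_stratum_n} speakers (the remainder is spread evenly), and one
#' draw per raw measure from the configured per-measure distributions with
#' linear age and sex effects.  Output is deterministic given the seed.
#'
#' @param config A \code{sim_config}, see [simulation_config()].
#' @return Data frame in the cohort layout: \code{speaker_id}, \code{sex},
#'   \code{age}, one column per raw measure (including the six DDK items).
#' @export
simulate_normative_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bands <- config$bands
  k <- length(bands) - 1L
  strata <- expand.grid(sex = c("F", "M"), band = seq_len(k),
                        stringsAsFactors = FALSE)
  ns <- nrow(strata)
  n <- config$n_normative
  if (n < ns * config$min_stratum_n) {
    stop(sprintf("n_normative = %d cannot guarantee %d speakers in each of %d strata",
                 n, config$min_stratum_n, ns))
  }
  alloc <- rep(n %/% ns, ns)
  extra <- n - sum(alloc)
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L

  lo_age <- config$age_range[1]; hi_age <- config$age_range[2]
  rows <- list()
  id <- 0L
  mp <- config$measure_params
  for (s in seq_len(ns)) {
    blo <- max(bands[strata$band[s]], lo_age)
    bhi <- min(bands[strata$band[s] + 1L] - 1L, hi_age)
    ages <- sample(seq(blo, bhi), alloc[s], replace = TRUE)
    for (a in ages) {
      id <- id + 1L
      vals <- setNames(numeric(nrow(mp)), mp$name)
      for (i in seq_len(nrow(mp))) {
        vals[i] <- .draw_measure(mp[i, ], a, strata$sex[s])
      }
      rows[[id]] <- data.frame(speaker_id = sprintf("N%03d", id),
                               sex = strata$sex[s], age = a,
                               as.list(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default deviance-profile templates for the six clinical groups
#'
#' Each template gives, per speech dimension, a probability vector over
#' target deviance levels 0..4 (applied independently to every component
#' measure for the voice and DDK composites).  The templates encode the
#' qualitative group signatures of the six motor-speech-disorder subtypes:
#' \itemize{
#'   \item AoS (post-stroke apraxia of speech): severe articulation,
#'     moderate DDK and speech-rate slowing, heterogeneous voice.
#'   \item PD (hypokinetic dysarthria, Parkinson): deviant voice with mild
#'     articulation, essentially normal DDK.
#'   \item ALS (mixed dysarthria): slow DDK with voice and moderate
#'     articulation deviance, normal speech rate.
#'   \item Kennedy (flaccid dysarthria): severe articulation (levels 3-4),
#'     normal DDK.
#'   \item SCA (ataxic dysarthria, spinocerebellar ataxia): slow DDK with
#'     preserved articulation.
#'   \item Wilson (mixed dysarthria): severe articulation with reduced
#'     intelligibility, normal DDK and speech rate.
#' }
#'
#' @return Named list of six templates; each a list with \code{group} and
#'   \code{dims}, a named list of length-5 probability vectors.
#' @export
default_group_templates <- function() {
  t <- function(group, intelligibility = c(1, 0, 0, 0, 0),
                articulation = c(1, 0, 0, 0, 0), mpt = c(0.9, 0.1, 0, 0, 0),
                voice = c(1, 0, 0, 0, 0), prosody = c(1, 0, 0, 0, 0),
                speech_rate = c(1, 0, 0, 0, 0), ddk = c(1, 0, 0, 0, 0)) {
    dims <- list(intelligibility = intelligibility,
                 articulation = articulation, mpt = mpt, voice = voice,
                 prosody = prosody, speech_rate = speech_rate, ddk = ddk)
    stopifnot(all(abs(vapply(dims, sum, numeric(1)) - 1) < 1e-9))
    list(group = group, dims = dims)
  }
  list(
    AoS = t("AoS",
            intelligibility = c(0.5, 0.3, 0.2, 0, 0),
            articulation = c(0, 0, 0.2, 0.4, 0.4),
            voice = c(0.4, 0.3, 0.2, 0.1, 0),
            prosody = c(0.6, 0.3, 0.1, 0, 0),
            speech_rate = c(0.2, 0.2, 0.3, 0.2, 0.1),
            ddk = c(0.1, 0.3, 0.4, 0.2, 0)),
    ALS = t("ALS",
            intelligibility = c(0.6, 0.3, 0.1, 0, 0),
            articulation = c(0.2, 0.4, 0.3, 0.1, 0),
            mpt = c(0.85, 0.1, 0.05, 0, 0),
            voice = c(0.3, 0.3, 0.2, 0.2, 0),
            prosody = c(0.7, 0.2, 0.1, 0, 0),
            ddk = c(0, 0.1, 0.3, 0.4, 0.2)),
    Kennedy = t("Kennedy",
                intelligibility = c(0.7, 0.3, 0, 0, 0),
                articulation = c(0, 0, 0, 0.5, 0.5),
                voice = c(0.6, 0.3, 0.1, 0, 0),
                prosody = c(0.8, 0.1, 0.1, 0, 0),
                speech_rate = c(0.8, 0.1, 0.1, 0, 0),
                ddk = c(0.85, 0.15, 0, 0, 0)),
    PD = t("PD",
           intelligibility = c(0.8, 0.2, 0, 0, 0),
           articulation = c(0.4, 0.5, 0.1, 0, 0),
           voice = c(0.1, 0.3, 0.3, 0.2, 0.1),
           prosody = c(0.7, 0.2, 0.1, 0, 0),
           speech_rate = c(0.8, 0.2, 0, 0, 0),
           ddk = c(0.9, 0.1, 0, 0, 0)),
    SCA = t("SCA",
            intelligibility = c(0.8, 0.2, 0, 0, 0),
            articulation = c(0.85, 0.15, 0, 0, 0),
            mpt = c(0.95, 0.05, 0, 0, 0),
            voice = c(0.5, 0.3, 0.2, 0, 0),
            prosody = c(0.5, 0.3, 0.2, 0, 0),
            speech_rate = c(0.3, 0.3, 0.3, 0.1, 0),
            ddk = c(0, 0.1, 0.3, 0.4, 0.2)),
    Wilson = t("Wilson",
               intelligibility = c(0.2, 0.4, 0.3, 0.1, 0),
               articulation = c(0, 0.1, 0.3, 0.4, 0.2),
               voice = c(0.4, 0.3, 0.2, 0.1, 0),
               prosody = c(0.6, 0.3, 0.1, 0, 0),
               speech_rate = c(0.85, 0.15, 0, 0, 0),
               ddk = c(0.85, 0.15, 0, 0, 0))
  )
}

# Oriented interval of raw-scale band for deviance level `lev` given a
# reference row; NULL if the band is empty (possible for level 2 in
# heavy-tailed strata and for levels 1-3 under a degenerate reference).
.band_interval <- function(lev, ref) {
  c1 <- ref$c1; c5 <- ref$c5; c50 <- ref$c50; icd <- ref$icd
  if (icd == 0) {
    w <- max(c5 - c1, 1)
    iv <- switch(as.character(lev),
                 "0" = c(c5, c5 + w),
                 "1" = c(c1, c5),
                 "4" = c(c1 - 2 * w, c1),
                 NULL)
  } else {
    iv <- switch(as.character(lev),
                 "0" = c(c5, c50),
                 "1" = c(max(c1, c50 - 1.5 * icd), c5),
                 "2" = c(c50 - 1.5 * icd, c1),
                 "3" = c(c50 - 2 * icd, c50 - 1.5 * icd),
                 "4" = c(c50 - 3 * icd, c50 - 2 * icd))
  }
  if (is.null(iv) || iv[2] <= iv[1]) NULL else iv
}

# Place an oriented value achieving deviance level `lev` (or the nearest
# attainable level when the requested band is empty); returns
# list(value, level).
.place_in_band <- function(lev, ref) {
  order_try <- switch(as.character(lev),
                      "0" = c(0),
                      "1" = c(1, 2, 3, 4),
                      "2" = c(2, 3, 4),
                      "3" = c(3, 4),
                      "4" = c(4))
  for (l in order_try) {
    iv <- .band_interval(l, ref)
    if (!is.null(iv)) {
      return(list(value = stats::runif(1, iv[1], iv[2]),
                  level = as.integer(l)))
    }
  }
  stop("no attainable band for level ", lev)  # unreachable for valid refs
}

#' Simulate one patient group with a prescribed deviance profile
#'
#' For each speaker and measure, a target deviance level is drawn from the
#' group template, then the raw value is placed by inverse scoring —
#' uniformly inside the oriented centile band for that level (the unbounded
#' level-4 band is capped at an oriented deficit of three inter-centile
#' distances to keep values finite) — so that [score_measure()] recovers the
#' level exactly.  When a drawn band is empty (level 2 in heavy-tailed
#' strata where the 1st centile lies above \code{c50 - 1.5 icd}, or under a
#' degenerate reference), the target is moved to the nearest attainable more
#' severe level.  The DDK alternating and sequential rates are placed from
#' the template and the SMR-AMR difference follows from them by definition;
#' its level is obtained by scoring.  All achieved levels are recorded in
#' \code{target_*} columns, so re-scoring the table reproduces them exactly.
#'
#' @param template One template from [default_group_templates()].
#' @param refset A \code{devs_refset} built from a normative cohort.
#' @param n Number of speakers.
#' @param seed Integer seed.
#' @param age_range Inclusive integer age range for patients.
#' @return Data frame in the patient layout: \code{speaker_id},
#'   \code{group}, \code{sex}, \code{age}, the raw measure columns
#'   (including the six DDK items), and one \code{target_<measure>} column
#'   per registry measure.
#' @export
simulate_patient_group <- function(template, refset, n = 10, seed = 1,
                                   age_range = c(20, 93)) {
  stopifnot(inherits(refset, "devs_refset"), n >= 1)
  set.seed(seed)
  specs <- refset$specs
  rows <- list()
  for (i in seq_len(n)) {
    sex <- sample(c("F", "M"), 1)
    age <- sample(seq(age_range[1], age_range[2]), 1)
    vals <- list(); targets <- list()
    # place every non-derived registry measure plus the two controllable
    # derived DDK rates; the SMR-AMR difference follows
    for (j in seq_len(nrow(specs))) {
      m <- specs$name[j]
      if (m == "ddk_smr_minus_amr") next
      dim <- specs$dimension[j]
      lev <- sample(0:4, 1, prob = template$dims[[dim]])
      ref <- lookup_reference(refset, m, age, sex)
      pl <- .place_in_band(lev, ref)
      vals[[m]] <- .orient(pl$value, specs$pathological_tail[j])
      targets[[m]] <- pl$level
    }
    # expand derived DDK rates into the six item columns (items equal within
    # their group so the derived means reproduce the placed values exactly)
    vals$amr_ba <- vals$amr_de <- vals$amr_go <- vals$ddk_amr_cv
    vals$amr_kla <- vals$amr_tra <- vals$ddk_amr_ccv
    vals$smr_badego <- vals$ddk_smr_cv
    vals$ddk_smr_minus_amr <- vals$ddk_smr_cv - vals$ddk_amr_cv
    ref_d <- lookup_reference(refset, "ddk_smr_minus_amr", age, sex)
    targets$ddk_smr_minus_amr <-
      score_measure(vals$ddk_smr_minus_amr, ref_d, "low")
    names(targets) <- paste0("target_", names(targets))
    rows[[i]] <- data.frame(
      speaker_id = sprintf("%s%02d", template$group, i),
      group = template$group, sex = sex, age = age,
      vals[raw_measure_columns()], targets, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a deviance-score table directly from group templates
#'
#' Bypasses raw measures: dimension-level deviance scores are drawn straight
#' from the templates (per component for the voice and DDK composites, then
#' combined with [composite_score()]).  Fast path for exercising the
#' classifier.
#'
#' @param templates List of group templates (default all six).
#' @param n_per_group Speakers per group (default 10).
#' @param seed Integer seed.
#' @return Deviance table: \code{speaker_id}, \code{group}, seven dimension
#'   columns (display labels), \code{total_devs}.
#' @export
simulate_devs_cohort <- function(templates = default_group_templates(),
                                 n_per_group = 10, seed = 1) {
  set.seed(seed)
  labs <- dimension_labels()
  n_comp <- c(voice = 6, ddk = 4)
  rows <- list()
  for (tpl in templates) {
    for (i in seq_len(n_per_group)) {
      dims <- setNames(numeric(7), dimension_names())
      for (d in dimension_names()) {
        pr <- tpl$dims[[d]]
        if (d %in% names(n_comp)) {
          comp <- sample(0:4, n_comp[d], replace = TRUE, prob = pr)
          dims[d] <- composite_score(comp, n_comp[d])
        } else {
          dims[d] <- sample(0:4, 1, prob = pr)
        }
      }
      row <- as.list(setNames(unname(dims), unname(labs[names(dims)])))
      rows[[length(rows) + 1L]] <- data.frame(
        speaker_id = sprintf("%s%02d", tpl$group, i), group = tpl$group,
        row, total_devs = sum(dims), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
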