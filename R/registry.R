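#' Registry of the speech measures in the screening battery
#'
#' The battery quantifies seven speech dimensions. Five dimensions
#' (intelligibility, articulation, maximum phonation time, prosody, speech
#' rate) rest on a single measure each; the voice dimension combines six
#' acoustic measures and the diadochokinetic (DDK) dimension four derived
#' rates, for fifteen measures in total.  Each registry entry records the
#' dimension the measure feeds, which tail of its raw distribution is
#' pathological (\code{"low"}: smaller values are deviant, e.g. fewer words
#' understood; \code{"high"}: larger values are deviant, e.g. more
#' articulation errors or more jitter), whether the normative reference is
#' stratified by age band in addition to sex, and the measurement units.
#'
#' Maximum phonation time is referenced by sex only (\code{stratify_age =
#' FALSE}): sustained-vowel duration shows no usable age effect in normative
#' cohorts, so all ages are pooled into one reference per sex.
#'
#' The four DDK measures are not observed directly but derived from the six
#' per-item repetition rates via [derive_ddk_measures()].
#'
#' @return A data frame with one row per measure and columns \code{name},
#'   \code{dimension}, \code{pathological_tail}, \code{stratify_age},
#'   \code{derived}, \code{units}.
#' @examples
#' reg <- measure_registry()
#' table(reg$dimension)
#' @export
measure_registry <- function() {
  reg <- data.frame(
    name = c(
      "intelligibility_correct", "articulation_errors", "mpt_seconds",
      "jitter_ppq5", "shimmer_apq11", "f0sd_vowel", "cpps_vowel",
      "f0sd_sentence", "cpps_sentence",
      "prosody_f0range_st", "speech_rate_phon_per_s",
      "ddk_amr_cv", "ddk_amr_ccv", "ddk_smr_cv", "ddk_smr_minus_amr"
    ),
    dimension = c(
      "intelligibility", "articulation", "mpt",
      "voice", "voice", "voice", "voice", "voice", "voice",
      "prosody", "speech_rate",
      "ddk", "ddk", "ddk", "ddk"
    ),
    pathological_tail = c(
      "low", "high", "low",
      "high", "high", "high", "low", "low", "low",
      "low", "low",
      "low", "low", "low", "low"
    ),
    stratify_age = c(
      TRUE, TRUE, FALSE,
      TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
      TRUE, TRUE,
      TRUE, TRUE, TRUE, TRUE
    ),
    derived = c(rep(FALSE, 11), rep(TRUE, 4)),
    units = c(
      "words correct (0-15)", "errors (0-151)", "s",
      "%", "%", "Hz", "dB", "Hz", "dB",
      "semitones", "phonemes/s",
      rep("phonemes/4s", 3), "phonemes/4s (difference)"
    ),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- reg$name
  reg
}

#' Canonical order of the seven speech dimensions
#'
#' Fixed feature order used throughout: deviance profiles, classifier feature
#' vectors and importance vectors all follow it.
#'
#' @return Character vector of length 7.
#' @export
dimension_names <- function() {
  c("intelligibility", "articulation", "mpt", "voice",
    "prosody", "speech_rate", "ddk")
}

#' Display labels for the seven dimensions
#'
#' Short labels used as column headers in exported deviance tables.
#' @return Named character vector mapping dimension name to label.
#' @export
dimension_labels <- function() {
  c(intelligibility = "Intellig", articulation = "Articul", mpt = "MPT",
    voice = "Voice", prosody = "Prosody", speech_rate = "SpeechRate",
    ddk = "DDK")
}

#' Names of the six per-item DDK rate columns
#' @return Character vector of the raw DDK input columns.
#' @export
ddk_item_names <- function() {
  c("amr_ba", "amr_de", "amr_go", "amr_kla", "amr_tra", "smr_badego")
}

#' Raw (non-derived) measure columns expected in input tables
#' @return Character vector of column names: the eleven directly observed
#'   measures plus the six DDK item rates.
#' @export
raw_measure_columns <- function() {
  reg <- measure_registry()
  c(reg$name[!reg$derived & reg$dimension != "ddk"], ddk_item_names())
}

#' Derive the four DDK summary rates from the six per-item rates
#'
#' Alternating motion rate (AMR) items repeat a single syllable; the three CV
#' items (/ba/, /de/, /go/) are averaged into \code{ddk_amr_cv} and the two
#' CCV items (/kla/, /tra/) into \code{ddk_amr_ccv}.  The sequential motion
#' rate \code{ddk_smr_cv} is the /badego/ rate.  The AMR/SMR contrast
#' \code{ddk_smr_minus_amr = ddk_smr_cv - ddk_amr_cv} captures speakers who
#' repeat a single syllable adequately but break down on syllable sequencing;
#' it may be negative.  All rates are phoneme counts over a fixed 4-second
#' window.
#'
#' @param rates Named numeric vector or single-row list/data frame holding the
#'   six items named as in [ddk_item_names()], all non-negative.
#' @return Named numeric vector with elements \code{ddk_amr_cv},
#'   \code{ddk_amr_ccv}, \code{ddk_smr_cv}, \code{ddk_smr_minus_amr}.
#' @examples
#' derive_ddk_measures(c(amr_ba = 13, amr_de = 13, amr_go = 13,
#'                       amr_kla = 10, amr_tra = 12, smr_badego = 12))
#' @export
derive_ddk_measures <- function(rates) {
  rates <- unlist(rates)
  items <- ddk_item_names()
  missing <- setdiff(items, names(rates))
  if (length(missing)) {
    stop("missing DDK item(s): ", paste(missing, collapse = ", "))
  }
  rates <- rates[items]
  if (anyNA(rates) || any(!is.finite(rates))) {
    stop("DDK item rates must be finite")
  }
  if (any(rates < 0)) stop("DDK item rates must be >= 0")
  amr_cv <- mean(rates[c("amr_ba", "amr_de", "amr_go")])
  amr_ccv <- mean(rates[c("amr_kla", "amr_tra")])
  smr_cv <- unname(rates["smr_badego"])
  c(ddk_amr_cv = amr_cv,
    ddk_amr_ccv = amr_ccv,
    ddk_smr_cv = smr_cv,
    ddk_smr_minus_amr = smr_cv - amr_cv)
}

#' Append derived DDK columns to a measurement table
#'
#' @param tab Data frame containing the six DDK item columns.
#' @return \code{tab} with the four derived DDK columns appended.
#' @export
add_ddk_measures <- function(tab) {
  items <- ddk_item_names()
  missing <- setdiff(items, names(tab))
  if (length(missing)) {
    stop("missing DDK item column(s): ", paste(missing, collapse = ", "))
  }
  tab$ddk_amr_cv <- rowMeans(tab[c("amr_ba", "amr_de", "amr_go")])
  tab$ddk_amr_ccv <- rowMeans(tab[c("amr_kla", "amr_tra")])
  tab$ddk_smr_cv <- tab$smr_badego
  tab$ddk_smr_minus_amr <- tab$ddk_smr_cv - tab$ddk_amr_cv
  tab
}
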