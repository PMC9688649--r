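#' Empirical centiles by linear interpolation between order statistics
#'
#' Uses the h = (n - 1) p + 1 convention (the common default of statistical
#' software, \code{stats::quantile} type 7): the p-th centile is read off the
#' sorted sample at fractional rank h, interpolating linearly between
#' neighbouring order statistics.
#'
#' @param values Numeric vector of observations (finite, non-empty).
#' @param probs Probabilities strictly inside (0, 1).
#' @return Numeric vector of centile values, one per probability.
#' @examples
#' estimate_centiles(1:99, c(0.05, 0.5))   # 5.9, 50
#' @export
estimate_centiles <- function(values, probs) {
  if (length(values) == 0) stop("no observations")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("observations must be finite")
  }
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("probs must lie strictly inside (0, 1)")
  }
  unname(stats::quantile(values, probs = probs, type = 7))
}

#' Default decade age bands covering ages 20 to 93
#'
#' Half-open decade bands [20,30), ..., [70,80) with a final wider band
#' [80,94) so the oldest normative speakers are not isolated in a thin
#' stratum.
#'
#' @return Numeric vector of band edges (length 8).
#' @export
default_age_bands <- function() {
  c(20, 30, 40, 50, 60, 70, 80, 94)
}

# Index of the band containing `age`; clamps below the first / above the last
# edge. Returns list(idx, clamped).
.band_index <- function(age, bands) {
  k <- length(bands) - 1L
  if (age < bands[1]) return(list(idx = 1L, clamped = TRUE))
  if (age >= bands[length(bands)]) return(list(idx = k, clamped = TRUE))
  list(idx = findInterval(age, bands, rightmost.closed = FALSE),
       clamped = FALSE)
}

# Orient raw values so that lower always means more deviant.
.orient <- function(x, tail) if (tail == "high") -x else x

#' Build age/sex-stratified centile references from a normative cohort
#'
#' For every measure and every stratum (sex crossed with age band, or sex
#' alone for measures with \code{stratify_age = FALSE}), the cohort values are
#' first oriented so that the pathological tail maps to the low side
#' (\code{x} for tail \code{"low"}, \code{-x} for tail \code{"high"}), then
#' the 1st, 5th and 50th centiles are estimated with [estimate_centiles()].
#' The inter-centile distance \code{icd = c50 - c5} (non-negative by
#' construction on the oriented scale) is the severity unit of the deviance
#' ladder in [score_measure()].
#'
#' @param cohort Data frame with columns \code{speaker_id}, \code{sex}
#'   (\code{"F"}/\code{"M"}), \code{age} (years) and one column per raw
#'   measure (the six DDK items may be given in place of the derived DDK
#'   measures; they are derived automatically).
#' @param specs Measure registry, as returned by [measure_registry()].
#' @param bands Age-band edges (half-open bands), default
#'   [default_age_bands()].
#' @param min_stratum_n Minimum cohort size per stratum (default 20); smaller
#'   strata make the 5th centile an unstable extreme order statistic and are
#'   refused.
#' @return An object of class \code{devs_refset}: the stratified centile
#'   table plus the registry and band definition used to build it.
#' @seealso [lookup_reference()], [score_profile()], [write_reference_json()]
#' @export
build_reference <- function(cohort, specs = measure_registry(),
                            bands = default_age_bands(),
                            min_stratum_n = 20) {
  stopifnot(is.data.frame(cohort), length(bands) >= 2, !is.unsorted(bands))
  need <- c("speaker_id", "sex", "age")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(cohort$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(specs$derived) && !all(specs$name[specs$derived] %in% names(cohort))) {
    cohort <- add_ddk_measures(cohort)
  }
  missing <- setdiff(specs$name, names(cohort))
  if (length(missing)) {
    stop("cohort lacks measure column(s): ", paste(missing, collapse = ", "))
  }

  k <- length(bands) - 1L
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    m <- specs$name[i]
    tail <- specs$pathological_tail[i]
    if (specs$stratify_age[i]) {
      strata <- expand.grid(sex = c("F", "M"), band = seq_len(k),
                            stringsAsFactors = FALSE)
    } else {
      strata <- data.frame(sex = c("F", "M"), band = NA_integer_)
    }
    for (j in seq_len(nrow(strata))) {
      sx <- strata$sex[j]
      b <- strata$band[j]
      sel <- cohort$sex == sx
      if (!is.na(b)) {
        sel <- sel & cohort$age >= bands[b] & cohort$age < bands[b + 1L]
      }
      v <- .orient(cohort[[m]][sel], tail)
      if (length(v) < min_stratum_n) {
        stop(sprintf(
          "stratum (%s, %s) for measure '%s' has n = %d < min_stratum_n = %d",
          sx, if (is.na(b)) "POOLED" else
            sprintf("[%g,%g)", bands[b], bands[b + 1L]),
          m, length(v), min_stratum_n))
      }
      q <- estimate_centiles(v, c(0.01, 0.05, 0.50))
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, sex = sx,
        band_lo = if (is.na(b)) NA_real_ else bands[b],
        band_hi = if (is.na(b)) NA_real_ else bands[b + 1L],
        pooled_age = is.na(b),
        c1 = q[1], c5 = q[2], c50 = q[3], icd = q[3] - q[2],
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  refs <- do.call(rbind, rows)
  rownames(refs) <- NULL
  structure(list(references = refs, specs = specs, bands = bands,
                 min_stratum_n = min_stratum_n),
            class = "devs_refset")
}

#' Look up the reference distribution for one measure and speaker
#'
#' Returns the centile reference of the stratum matching the speaker's sex
#' and the age band containing their age (the sex-pooled-age stratum for
#' measures referenced without age stratification, such as maximum phonation
#' time).  Ages outside the band range are clamped to the nearest band with a
#' warning; clinical tables legitimately contain such ages.
#'
#' @param refset A \code{devs_refset} from [build_reference()].
#' @param measure Measure name.
#' @param age Age in years.
#' @param sex \code{"F"} or \code{"M"}.
#' @return One-row data frame with \code{c1}, \code{c5}, \code{c50},
#'   \code{icd}, \code{n} and the stratum description.
#' @export
lookup_reference <- function(refset, measure, age, sex) {
  stopifnot(inherits(refset, "devs_refset"), age >= 0)
  if (!measure %in% refset$specs$name) stop("unknown measure: ", measure)
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  refs <- refset$references
  spec <- refset$specs[refset$specs$name == measure, ]
  if (!spec$stratify_age) {
    out <- refs[refs$measure == measure & refs$sex == sex, ]
  } else {
    bi <- .band_index(age, refset$bands)
    if (bi$clamped) {
      warning(sprintf(
        "age %g outside reference range [%g, %g); clamped to nearest band",
        age, refset$bands[1], refset$bands[length(refset$bands)]))
    }
    lo <- refset$bands[bi$idx]
    out <- refs[refs$measure == measure & refs$sex == sex &
                  !refs$pooled_age & refs$band_lo == lo, ]
  }
  if (nrow(out) != 1L) stop("no reference stratum found for ", measure)
  out
}

#' @export
print.devs_refset <- function(x, ...) {
  cat("Normative centile reference set\n")
  cat(sprintf("  measures: %d  strata rows: %d\n",
              nrow(x$specs), nrow(x$references)))
  cat(sprintf("  age bands: %s (half-open)\n",
              paste(x$bands, collapse = " ")))
  cat(sprintf("  min stratum n: %d, stratum n range: %d-%d\n",
              x$min_stratum_n, min(x$references$n), max(x$references$n)))
  invisible(x)
}

#' @export
summary.devs_refset <- function(object, ...) {
  refs <- object$references
  agg <- aggregate(cbind(icd, n) ~ measure, data = refs,
                   FUN = function(v) round(mean(v), 3))
  cat("Per-measure mean inter-centile distance and stratum size\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' Serialize a reference set to a versioned JSON document
#'
#' @param refset A \code{devs_refset}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_reference_json <- function(refset, path) {
  stopifnot(inherits(refset, "devs_refset"))
  doc <- list(
    schema = "devscreen-reference", version = 1L,
    bands = refset$bands, min_stratum_n = refset$min_stratum_n,
    specs = refset$specs, references = refset$references)
  jsonlite::write_json(doc, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read a reference set written by [write_reference_json()]
#'
#' @param path JSON file path.
#' @return A \code{devs_refset}.
#' @export
read_reference_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "devscreen-reference")) {
    stop("not a devscreen reference document")
  }
  refs <- as.data.frame(doc$references, stringsAsFactors = FALSE)
  refs$band_lo <- as.numeric(refs$band_lo)
  refs$band_hi <- as.numeric(refs$band_hi)
  structure(list(references = refs,
                 specs = as.data.frame(doc$specs, stringsAsFactors = FALSE),
                 bands = as.numeric(doc$bands),
                 min_stratum_n = as.integer(doc$min_stratum_n)),
            class = "devs_refset")
}
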