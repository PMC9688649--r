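#' Deviance score of one raw measurement against its centile reference
#'
#' Implements the centile ladder on the oriented scale (lower = more
#' deviant).  With oriented value \code{x'}, oriented deficit
#' \code{D = c50 - x'} and inter-centile distance \code{icd = c50 - c5}, the
#' bands are evaluated severe-first:
#' \itemize{
#'   \item DevS 4 if \code{D > 2 * icd}
#'   \item DevS 3 if \code{D > 1.5 * icd}
#'   \item DevS 2 if \code{x' < c1}
#'   \item DevS 1 if \code{x' < c5}
#'   \item DevS 0 otherwise (normal range, \code{x' >= c5} inclusive)
#' }
#' Severe-first precedence resolves the overlap that arises in heavy-tailed
#' strata where the 1st centile lies above \code{c50 - 1.5 * icd}.
#'
#' A degenerate reference (\code{icd == 0}, e.g. a ceiling-effect
#' intelligibility stratum where \code{c50 == c5}) has no severity unit; the
#' ladder falls back to two thresholds — \code{x' >= c5} gives 0,
#' \code{c1 <= x' < c5} gives 1, \code{x' < c1} gives 4 — and a warning is
#' emitted.
#'
#' @param x Raw measurement value.
#' @param ref Reference row (from [lookup_reference()]) with oriented
#'   \code{c1}, \code{c5}, \code{c50}, \code{icd}.
#' @param pathological_tail \code{"low"} or \code{"high"}: which raw tail is
#'   deviant; \code{x} is oriented accordingly before banding.
#' @return Integer deviance score in 0..4.
#' @examples
#' ref <- data.frame(c1 = 72, c5 = 80, c50 = 100, icd = 20)
#' score_measure(85, ref)  # 0: inside the normal range
#' score_measure(59, ref)  # 4: deficit exceeds twice the inter-centile distance
#' @export
score_measure <- function(x, ref, pathological_tail = "low") {
  stopifnot(length(x) == 1L, is.finite(x))
  xo <- .orient(x, pathological_tail)
  c1 <- ref$c1; c5 <- ref$c5; c50 <- ref$c50; icd <- ref$icd
  if (icd < 0) stop("negative inter-centile distance")
  if (icd == 0) {
    warning("degenerate reference (icd = 0); using two-threshold ladder")
    if (xo >= c5) return(0L)
    if (xo >= c1) return(1L)
    return(4L)
  }
  d <- c50 - xo
  if (d > 2 * icd) return(4L)
  if (d > 1.5 * icd) return(3L)
  if (xo < c1) return(2L)
  if (xo < c5) return(1L)
  0L
}

#' Composite deviance score for a multi-measure dimension
#'
#' The voice dimension has six component measures and the DDK dimension four.
#' Component deviance scores (each 0..4) are combined by linear rescaling of
#' their sum to the range 0..6, \code{6 * sum / (4 * k)}, so that a fully
#' deviant profile reaches exactly 6 and the two composite dimensions carry
#' comparable weight to the five single-measure dimensions in the total.
#' The composite is left unrounded.
#'
#' @param component_devs Integer vector of component scores in 0..4.
#' @param k Expected component count (6 for voice, 4 for DDK); defaults to
#'   \code{length(component_devs)}.
#' @return Composite score in [0, 6].
#' @examples
#' composite_score(c(4, 4, 4, 4, 4, 4))  # 6
#' composite_score(c(4, 4, 4, 0, 0, 0))  # 3
#' @export
composite_score <- function(component_devs, k = length(component_devs)) {
  if (length(component_devs) != k) {
    stop("expected ", k, " components, got ", length(component_devs))
  }
  if (any(component_devs < 0 | component_devs > 4)) {
    stop("component deviance scores must lie in 0..4")
  }
  6 * sum(component_devs) / (4 * k)
}

#' Seven-dimension deviance profile for one speaker
#'
#' Derives the DDK summary rates if needed, scores every registry measure
#' against the reference stratum matching the speaker's sex and age,
#' combines the voice and DDK component scores into composites and sums the
#' seven dimension scores into the total deviance score (range 0..32:
#' five dimensions capped at 4 plus two composites capped at 6).
#'
#' @param record Single-row data frame or named list with \code{sex},
#'   \code{age} and the raw measure values (DDK items or derived DDK
#'   measures).
#' @param refset A \code{devs_refset} from [build_reference()].
#' @param specs Measure registry (defaults to the refset's own).
#' @return A list of class \code{devs_profile}: \code{dimensions} (named
#'   numeric vector in canonical order), \code{component_scores} (per-measure
#'   DevS), \code{total_devs}.
#' @export
score_profile <- function(record, refset, specs = refset$specs) {
  record <- as.list(record)
  if (is.null(record$sex) || is.null(record$age)) {
    stop("record must carry sex and age")
  }
  have_ddk_items <- all(ddk_item_names() %in% names(record))
  if (have_ddk_items) {
    record <- c(record, as.list(derive_ddk_measures(record[ddk_item_names()])))
  }
  missing <- setdiff(specs$name, names(record))
  if (length(missing)) {
    stop("missing measure(s): ", paste(missing, collapse = ", "))
  }
  comp <- setNames(integer(nrow(specs)), specs$name)
  for (i in seq_len(nrow(specs))) {
    m <- specs$name[i]
    ref <- lookup_reference(refset, m, record$age, record$sex)
    comp[m] <- score_measure(record[[m]], ref, specs$pathological_tail[i])
  }
  dims <- setNames(numeric(7), dimension_names())
  for (d in dimension_names()) {
    members <- specs$name[specs$dimension == d]
    dims[d] <- if (length(members) == 1L) comp[members]
               else composite_score(comp[members], length(members))
  }
  structure(list(dimensions = dims, component_scores = comp,
                 total_devs = sum(dims)),
            class = "devs_profile")
}

#' @export
print.devs_profile <- function(x, ...) {
  cat("Deviance profile (0-4 per dimension; voice/DDK composites 0-6)\n")
  print(round(x$dimensions, 2))
  cat(sprintf("total deviance score: %g (max 32)\n", x$total_devs))
  invisible(x)
}

#' Score a whole patient (or cohort) table into a deviance table
#'
#' @param patients Data frame in the cohort layout (\code{speaker_id},
#'   \code{sex}, \code{age}, raw measures) with an optional \code{group}
#'   column.
#' @param refset A \code{devs_refset}.
#' @return Data frame with \code{speaker_id}, \code{group} (if present), the
#'   seven dimension scores under their display labels (Intellig, Articul,
#'   MPT, Voice, Prosody, SpeechRate, DDK) and \code{total_devs}.
#' @export
score_table <- function(patients, refset) {
  stopifnot(is.data.frame(patients), nrow(patients) >= 1)
  labs <- dimension_labels()[dimension_names()]
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- score_profile(patients[i, , drop = FALSE], refset)
    row <- as.list(setNames(unname(p$dimensions), unname(labs)))
    row$total_devs <- p$total_devs
    out[[i]] <- as.data.frame(row)
  }
  res <- do.call(rbind, out)
  front <- data.frame(speaker_id = patients$speaker_id,
                      stringsAsFactors = FALSE)
  if ("group" %in% names(patients)) front$group <- patients$group
  cbind(front, res)
}

#' Export per-group radar-profile data as JSON
#'
#' Writes one JSON document per clinical group listing every speaker's seven
#' dimension scores — the data behind per-group radar plots of deviance
#' profiles.
#'
#' @param devs_table Deviance table from [score_table()] including a
#'   \code{group} column.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_radar_json <- function(devs_table, dir) {
  if (!"group" %in% names(devs_table)) stop("devs_table lacks a group column")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labs <- unname(dimension_labels()[dimension_names()])
  paths <- character(0)
  for (g in unique(devs_table$group)) {
    sub <- devs_table[devs_table$group == g, , drop = FALSE]
    doc <- list(group = g, dimensions = labs,
                speakers = lapply(seq_len(nrow(sub)), function(i) {
                  list(speaker_id = sub$speaker_id[i],
                       scores = as.numeric(sub[i, labs]))
                }))
    p <- file.path(dir, paste0("radar_", gsub("[^A-Za-z0-9]", "_", g), ".json"))
    jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
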