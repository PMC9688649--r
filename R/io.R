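#' Read a measurement table (normative cohort or patient layout)
#'
#' Comma-separated, header row, UTF-8, "." decimal separator.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_measure_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("speaker_id", "sex", "age")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' Write a table as comma-separated text
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_measure_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a measurement table against the battery's range invariants
#'
#' Checks, row by row: sex is \code{"F"} or \code{"M"}; age is non-negative;
#' intelligibility is within 0..15 words; articulation errors within 0..151
#' scored targets; all DDK item rates and the speech rate are non-negative;
#' required raw measure columns are present.
#'
#' @param tab Parsed measurement table.
#' @param require_measures Require all raw measure columns (default TRUE).
#' @return Character vector of violations (empty when the table is valid),
#'   each addressed by row.
#' @export
validate_tables <- function(tab, require_measures = TRUE) {
  errs <- character(0)
  add <- function(rows, msg) {
    if (length(rows)) {
      errs <<- c(errs, sprintf("row %d: %s", rows, msg))
    }
  }
  if (require_measures) {
    missing <- setdiff(raw_measure_columns(), names(tab))
    if (length(missing)) {
      errs <- c(errs, paste("missing measure column(s):",
                            paste(missing, collapse = ", ")))
      return(errs)
    }
  }
  if ("sex" %in% names(tab)) {
    add(which(!tab$sex %in% c("F", "M")), "sex must be 'F' or 'M'")
  }
  if ("age" %in% names(tab)) {
    add(which(!is.finite(tab$age) | tab$age < 0), "age must be >= 0")
  }
  chk_range <- function(col, lo, hi, what) {
    if (col %in% names(tab)) {
      v <- tab[[col]]
      add(which(!is.finite(v) | v < lo | v > hi),
          sprintf("%s must lie in [%g, %g]", what, lo, hi))
    }
  }
  chk_range("intelligibility_correct", 0, 15, "intelligibility words correct")
  chk_range("articulation_errors", 0, 151, "articulation error count")
  for (col in c(ddk_item_names(), "speech_rate_phon_per_s")) {
    if (col %in% names(tab)) {
      v <- tab[[col]]
      add(which(!is.finite(v) | v < 0), paste(col, "must be >= 0"))
    }
  }
  errs
}
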