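#' Run the full screening analysis end to end on synthetic data
#'
#' Chains the stages: simulate a normative cohort, build the stratified
#' centile reference, simulate the six patient groups from their templates,
#' score every patient into a seven-dimension deviance table, run the 15
#' pairwise leave-one-speaker-out classifications, and write all artifacts
#' (tables as CSV, reference and radar data as JSON) to \code{out_dir}.
#'
#' @param out_dir Output directory (created if absent).
#' @param config Simulation configuration, see [simulation_config()].
#' @param templates Group templates (default [default_group_templates()]).
#' @return Invisibly, a list with the in-memory \code{cohort},
#'   \code{refset}, \code{patients}, \code{devs_table} and \code{pairwise}
#'   results.
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         templates = default_group_templates()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort <- simulate_normative_cohort(config)
  write_measure_table(cohort, file.path(out_dir, "normative_cohort.csv"))
  refset <- build_reference(cohort, bands = config$bands,
                            min_stratum_n = config$min_stratum_n)
  write_reference_json(refset, file.path(out_dir, "reference.json"))

  patients <- do.call(rbind, lapply(seq_along(templates), function(i) {
    simulate_patient_group(templates[[i]], refset, n = config$n_per_group,
                           seed = config$seed + i)
  }))
  write_measure_table(patients, file.path(out_dir, "patients.csv"))

  devs <- score_table(patients, refset)
  write_measure_table(devs, file.path(out_dir, "devs_table.csv"))
  write_radar_json(devs, file.path(out_dir, "radar"))

  pw <- pairwise_matrix(devs)
  write_pairwise_report(pw, out_dir)
  invisible(list(cohort = cohort, refset = refset, patients = patients,
                 devs_table = devs, pairwise = pw))
}

#' Write the pairwise classification report files
#'
#' Emits the symmetric accuracy matrix (cells \code{"overall (accC1/accC2)"}
#' with a \code{Mean ± SD} summary row), the pairs-by-features importance
#' matrix from the full-data trees, fold-averaged importances as a
#' diagnostics file, and the per-speaker prediction log.
#'
#' @param pw A \code{pairwise_matrix} object.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_pairwise_report <- function(pw, out_dir) {
  stopifnot(inherits(pw, "pairwise_matrix"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p1 <- file.path(out_dir, "accuracy_matrix.csv")
  utils::write.csv(as.data.frame(pw$accuracy_matrix), p1,
                   fileEncoding = "UTF-8")
  p2 <- file.path(out_dir, "importance_matrix.csv")
  utils::write.csv(pw$importance, p2, row.names = FALSE,
                   fileEncoding = "UTF-8")
  fold <- t(vapply(pw$results, function(r) r$importance_foldavg,
                   numeric(length(devs_feature_columns()))))
  p3 <- file.path(out_dir, "importance_foldavg.csv")
  utils::write.csv(data.frame(pair = names(pw$results), fold,
                              check.names = FALSE),
                   p3, row.names = FALSE, fileEncoding = "UTF-8")
  p4 <- file.path(out_dir, "predictions.csv")
  utils::write.csv(pw$predictions, p4, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(p1, p2, p3, p4))
}

# minimal --key value argument parser for the CLI
.parse_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    if (i == length(args)) stop("missing value for ", key)
    out[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommand dispatcher backing the \code{inst/cli/devscreen.R} script.
#' Subcommands: \code{simulate-norms}, \code{simulate-patients},
#' \code{build-reference}, \code{score}, \code{classify-pairs},
#' \code{report}, \code{run-all}.  Options are \code{--key value} pairs:
#' \code{--out} (directory or file), \code{--cohort}, \code{--patients},
#' \code{--reference}, \code{--devs}, \code{--seed}, \code{--n},
#' \code{--min-stratum-n}, \code{--max-depth}, \code{--min-leaf},
#' \code{--group}.  All randomness derives from \code{--seed}.
#'
#' @param args Character vector of command-line arguments (first element the
#'   subcommand).
#' @return Exit status, 0 on success (invisibly); validation failures raise
#'   errors that the wrapper script converts to a non-zero exit.
#' @export
devscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop("usage: devscreen <simulate-norms|simulate-patients|build-reference|",
         "score|classify-pairs|report|run-all> [--key value ...]")
  }
  cmd <- args[1]
  opts <- .parse_args(args[-1])
  seed <- as.integer(.cli_num(opts, "seed", 1))
  cfg <- simulation_config(
    seed = seed,
    n_per_group = .cli_num(opts, "n", 10),
    min_stratum_n = .cli_num(opts, "min-stratum-n", 20))

  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing required option --", key)
    opts[[key]]
  }
  load_validated <- function(path) {
    tab <- read_measure_table(path)
    errs <- validate_tables(tab)
    if (length(errs)) stop(paste(errs, collapse = "\n"))
    tab
  }

  switch(cmd,
    "simulate-norms" = {
      write_measure_table(simulate_normative_cohort(cfg), need("out"))
    },
    "simulate-patients" = {
      refset <- read_reference_json(need("reference"))
      tpls <- default_group_templates()
      if (!is.null(opts$group)) tpls <- tpls[opts$group]
      pats <- do.call(rbind, lapply(seq_along(tpls), function(i) {
        simulate_patient_group(tpls[[i]], refset, n = cfg$n_per_group,
                               seed = seed + i)
      }))
      write_measure_table(pats, need("out"))
    },
    "build-reference" = {
      cohort <- load_validated(need("cohort"))
      refset <- build_reference(cohort, min_stratum_n = cfg$min_stratum_n)
      write_reference_json(refset, need("out"))
    },
    "score" = {
      pats <- load_validated(need("patients"))
      refset <- read_reference_json(need("reference"))
      write_measure_table(score_table(pats, refset), need("out"))
    },
    "classify-pairs" = ,
    "report" = {
      devs <- utils::read.csv(need("devs"), stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
      pw <- pairwise_matrix(devs,
                            max_depth = .cli_num(opts, "max-depth", 3),
                            min_leaf = .cli_num(opts, "min-leaf", 1))
      write_pairwise_report(pw, need("out"))
    },
    "run-all" = {
      run_pipeline(need("out"), config = cfg)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
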