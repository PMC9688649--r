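# round half away from zero to `digits` decimals (display convention for
# accuracy summaries; base round() would round half to even)
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Feature columns of a deviance table, in canonical order
#' @return Character vector of the seven dimension display labels.
#' @export
devs_feature_columns <- function() {
  unname(dimension_labels()[dimension_names()])
}

#' Leave-one-speaker-out evaluation of one group pair
#'
#' For a pair of clinical groups with one seven-dimension deviance profile
#' per speaker, fits one tree per fold (every speaker held out once, the
#' tree refit on the rest with identical hyperparameters) and scores the
#' held-out speaker.  Accuracies are reported as percentages, overall and
#' per class; with balanced classes the overall accuracy equals the mean of
#' the per-class accuracies.  The feature-importance vector comes from a
#' final tree fit on all pair data (per-fold importances are also retained,
#' averaged, for diagnostics).
#'
#' @param pairset Data frame with \code{speaker_id}, \code{group} (exactly
#'   two distinct labels, at least two speakers each) and the seven feature
#'   columns of [devs_feature_columns()].
#' @param max_depth,min_leaf Tree hyperparameters, see [gini_tree()].
#' @param features Feature column names (default the canonical seven).
#' @return Object of class \code{pairwise_result}: pair labels, overall and
#'   per-class accuracy (percent), importance vector (sums to 1 when the
#'   full-data tree splits), fold-averaged importance, and the per-speaker
#'   prediction log.
#' @export
loso_evaluate <- function(pairset, max_depth = 3, min_leaf = 1,
                          features = devs_feature_columns()) {
  stopifnot(is.data.frame(pairset))
  missing <- setdiff(c("speaker_id", "group", features), names(pairset))
  if (length(missing)) {
    stop("pairset lacks column(s): ", paste(missing, collapse = ", "))
  }
  groups <- sort(unique(as.character(pairset$group)))
  if (length(groups) != 2) stop("pairset must contain exactly two groups")
  tab <- table(pairset$group)
  if (any(tab < 2)) {
    stop("each class needs at least 2 speakers; ",
         names(tab)[which.min(tab)], " has ", min(tab))
  }
  x <- as.matrix(pairset[, features, drop = FALSE])
  y <- as.character(pairset$group)
  n <- nrow(x)
  pred <- character(n)
  imp_folds <- matrix(0, n, length(features),
                      dimnames = list(NULL, features))
  for (i in seq_len(n)) {
    fit <- gini_tree(x[-i, , drop = FALSE], y[-i],
                     max_depth = max_depth, min_leaf = min_leaf)
    pred[i] <- predict(fit, x[i, , drop = FALSE])
    imp_folds[i, ] <- feature_importance(fit)
  }
  correct <- pred == y
  acc_class <- vapply(groups, function(g) 100 * mean(correct[y == g]),
                      numeric(1))
  full <- gini_tree(x, y, max_depth = max_depth, min_leaf = min_leaf)
  structure(list(
    groups = groups,
    overall = 100 * mean(correct),
    per_class = acc_class,
    importance = feature_importance(full),
    importance_foldavg = colMeans(imp_folds),
    tree = full,
    predictions = data.frame(speaker_id = pairset$speaker_id,
                             group = y, predicted = pred,
                             correct = correct,
                             stringsAsFactors = FALSE)),
    class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %g%% (%g/%g)\n", x$groups[1], x$groups[2],
              x$overall, x$per_class[1], x$per_class[2]))
  top <- sort(x$importance, decreasing = TRUE)[1:3]
  cat("top features:", paste(sprintf("%s %.2f", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Mean and population standard deviation of a set of accuracies
#'
#' Aggregation used for the summary row of the pairwise accuracy matrix:
#' arithmetic mean and population standard deviation (divisor \code{n}, not
#' \code{n - 1}), both rounded half away from zero to 1 decimal for display.
#'
#' @param accuracies Non-empty numeric vector of percentages.
#' @return List with \code{mean}, \code{sd} (rounded to 1 decimal) and a
#'   \code{formatted} string \code{"mean ± sd"}.
#' @examples
#' row_summary(c(75, 80, 70, 75, 95))  # 79.0 +/- 8.6
#' @export
row_summary <- function(accuracies) {
  if (length(accuracies) == 0) stop("no accuracies to summarize")
  m <- mean(accuracies)
  s <- sqrt(mean((accuracies - m)^2))
  m <- round_half_up(m, 1)
  s <- round_half_up(s, 1)
  list(mean = m, sd = s,
       formatted = sprintf("%.1f ± %.1f", m, s))
}

#' Pairwise classification of every pair of clinical groups
#'
#' Runs [loso_evaluate()] on each unordered pair of groups (15 pairs for six
#' groups) and assembles the symmetric accuracy matrix — cell (A, B) reads
#' \code{"overall (accA/accB)"} and cell (B, A) the same overall with the
#' per-class entries swapped — with a final \code{"Mean ± SD"} row
#' summarizing each column via [row_summary()], plus the pairs-by-features
#' importance matrix.
#'
#' @param devs_table Deviance table (from [score_table()] or
#'   [simulate_devs_cohort()]) with \code{speaker_id}, \code{group} and the
#'   seven feature columns.
#' @param max_depth,min_leaf Tree hyperparameters.
#' @return Object of class \code{pairwise_matrix}: \code{results} (named
#'   list of \code{pairwise_result}), \code{groups},
#'   \code{accuracy_matrix} (character, with summary row),
#'   \code{importance} (pairs x 7 data frame) and \code{predictions}
#'   (stacked per-speaker log).
#' @export
pairwise_matrix <- function(devs_table, max_depth = 3, min_leaf = 1) {
  groups <- sort(unique(as.character(devs_table$group)))
  if (length(groups) < 2) stop("need at least two groups")
  if (anyDuplicated(groups)) stop("duplicate group labels")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  results <- list()
  for (pr in pairs) {
    sub <- devs_table[devs_table$group %in% pr, , drop = FALSE]
    results[[paste(pr, collapse = "_vs_")]] <-
      loso_evaluate(sub, max_depth = max_depth, min_leaf = min_leaf)
  }

  k <- length(groups)
  acc <- matrix("-", k, k, dimnames = list(groups, groups))
  overall_by_col <- setNames(vector("list", k), groups)
  for (res in results) {
    a <- res$groups[1]; b <- res$groups[2]
    cell <- function(first, second) {
      sprintf("%g (%g/%g)", res$overall, res$per_class[first],
              res$per_class[second])
    }
    # column = the group the column header names (class 1 of that column)
    acc[b, a] <- cell(a, b)
    acc[a, b] <- cell(b, a)
    overall_by_col[[a]] <- c(overall_by_col[[a]], res$overall)
    overall_by_col[[b]] <- c(overall_by_col[[b]], res$overall)
  }
  summary_row <- vapply(groups, function(g)
    row_summary(overall_by_col[[g]])$formatted, character(1))
  acc <- rbind(acc, `Mean ± SD` = summary_row)

  imp <- t(vapply(results, function(r) r$importance,
                  numeric(length(devs_feature_columns()))))
  imp <- data.frame(pair = names(results), imp, row.names = NULL,
                    check.names = FALSE)
  preds <- do.call(rbind, lapply(names(results), function(nm) {
    cbind(pair = nm, results[[nm]]$predictions)
  }))
  structure(list(results = results, groups = groups,
                 accuracy_matrix = acc, importance = imp,
                 predictions = preds),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("Pairwise LOSO classification: %d groups, %d pairs\n",
              length(x$groups), length(x$results)))
  print(x$accuracy_matrix, quote = FALSE)
  invisible(x)
}
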