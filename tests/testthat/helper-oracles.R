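# Independent oracles used to cross-check the implementation.

# Quantile by explicit sort-and-interpolate at fractional rank h = (n-1)p + 1.
oracle_quantile <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }, numeric(1))
}

# Deviance ladder by enumerating all band predicates on the oriented value
# and taking the maximum applicable severity.
oracle_score <- function(x_oriented, c1, c5, c50, icd) {
  d <- c50 - x_oriented
  sev <- c(
    `4` = d > 2 * icd,
    `3` = d > 1.5 * icd,
    `2` = x_oriented < c1,
    `1` = x_oriented < c5
  )
  if (any(sev)) max(as.integer(names(sev)[sev])) else 0L
}

oracle_gini <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

# Exhaustive enumeration of all (feature, midpoint) splits; ties resolved by
# lowest feature index then lowest threshold; NULL when nothing improves.
oracle_best_split <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  cnt <- function(yy) vapply(classes, function(cl) sum(yy == cl), integer(1))
  n <- nrow(x)
  gp <- oracle_gini(cnt(y))
  best <- NULL
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    for (thr in (u[-length(u)] + u[-1]) / 2) {
      left <- x[, j] <= thr
      dec <- gp - (sum(left) / n) * oracle_gini(cnt(y[left])) -
        (sum(!left) / n) * oracle_gini(cnt(y[!left]))
      if (dec > 1e-12 &&
          (is.null(best) || dec > best$decrease + 1e-12)) {
        best <- list(feature = j, threshold = thr, decrease = dec)
      }
    }
  }
  best
}

# Walk a fitted tree together with its training data, applying `fun` to every
# internal node with the subset of data that reached it.
walk_tree_nodes <- function(node, x, y, fun) {
  if (isTRUE(node$leaf)) return(invisible())
  fun(node, x, y)
  left <- x[, node$feature] <= node$threshold
  walk_tree_nodes(node$left, x[left, , drop = FALSE], y[left], fun)
  walk_tree_nodes(node$right, x[!left, , drop = FALSE], y[!left], fun)
}

tree_depth <- function(node) {
  if (isTRUE(node$leaf)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}
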