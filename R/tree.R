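#' Gini impurity of a two-class node
#'
#' \code{1 - p1^2 - p2^2} for class proportions \code{p}; 0 for a pure node,
#' 0.5 for a balanced two-class node.
#'
#' @param class_counts Non-negative counts, not all zero.
#' @return Impurity in [0, 0.5] for two classes.
#' @examples
#' gini_impurity(c(10, 10))  # 0.5
#' gini_impurity(c(9, 1))    # 0.18
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be non-negative")
  n <- sum(class_counts)
  if (n == 0) stop("all-zero class counts")
  1 - sum((class_counts / n)^2)
}

# counts of y (character) over the canonical class vector
.class_counts <- function(y, classes) {
  vapply(classes, function(cl) sum(y == cl), integer(1))
}

#' Best axis-aligned split of a node by Gini impurity decrease
#'
#' Exhaustive search over every feature and every midpoint between
#' consecutive distinct sorted feature values, maximizing the weighted
#' impurity decrease
#' \code{G - (nL/n) GL - (nR/n) GR}.  Samples with feature value \code{<=}
#' threshold go left.  Ties are broken deterministically: lowest feature
#' index first, then lowest threshold.
#'
#' @param x Numeric matrix or data frame of features (rows = samples).
#' @param y Character/factor labels.
#' @param classes Canonical class vector (defaults to sorted unique labels).
#' @param min_leaf Minimum samples per child (candidate splits violating it
#'   are skipped).
#' @return \code{NULL} if no split decreases impurity, else a list with
#'   \code{feature} (column index), \code{threshold}, \code{decrease}.
#' @export
best_split <- function(x, y, classes = sort(unique(as.character(y))),
                       min_leaf = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (n < 2) return(NULL)
  g_parent <- gini_impurity(.class_counts(y, classes))
  best <- NULL
  best_dec <- 0
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]
    uniq <- unique(vs)
    if (length(uniq) < 2) next
    thresholds <- (uniq[-length(uniq)] + uniq[-1]) / 2
    for (thr in thresholds) {
      left <- v <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      gl <- gini_impurity(.class_counts(y[left], classes))
      gr <- gini_impurity(.class_counts(y[!left], classes))
      dec <- g_parent - (nl / n) * gl - ((n - nl) / n) * gr
      if (dec > best_dec + 1e-12) {
        best_dec <- dec
        best <- list(feature = j, threshold = thr, decrease = dec)
      }
    }
  }
  best
}

.majority_label <- function(counts, classes) {
  # tie broken by canonical (alphabetical) class order: which.max takes the
  # first maximum and `classes` is sorted
  classes[which.max(counts)]
}

.grow_node <- function(x, y, classes, depth, max_depth, min_leaf) {
  counts <- .class_counts(y, classes)
  g <- gini_impurity(counts)
  node <- list(n = length(y), counts = counts, gini = g,
               label = .majority_label(counts, classes))
  if (g == 0 || depth >= max_depth || length(y) < 2 * min_leaf) {
    node$leaf <- TRUE
    return(node)
  }
  sp <- best_split(x, y, classes, min_leaf)
  if (is.null(sp)) {
    node$leaf <- TRUE
    return(node)
  }
  left <- x[, sp$feature] <= sp$threshold
  node$leaf <- FALSE
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$decrease <- sp$decrease
  node$left <- .grow_node(x[left, , drop = FALSE], y[left], classes,
                          depth + 1L, max_depth, min_leaf)
  node$right <- .grow_node(x[!left, , drop = FALSE], y[!left], classes,
                           depth + 1L, max_depth, min_leaf)
  node
}

#' Fit a depth-limited binary classification tree by Gini impurity
#'
#' Greedy recursive partitioning with exhaustive split search
#' ([best_split()]), no pruning and no randomness: identical inputs always
#' yield the identical tree.  Growth stops at a pure node, at the depth
#' limit, or when no split decreases impurity; leaves predict their majority
#' label with ties broken by canonical (alphabetical) label order.  The
#' depth limit defaults to 3 edges root-to-leaf, a deliberately shallow
#' setting that guards against overfitting the small per-group samples this
#' classifier is designed for.
#'
#' @param x Feature matrix or data frame (numeric).
#' @param y Class labels (two classes; a single-class input yields a
#'   depth-0 leaf).
#' @param max_depth Maximum edges on any root-to-leaf path (default 3).
#' @param min_leaf Minimum samples per leaf (default 1, "vanilla" tree).
#' @return Object of class \code{gini_tree} with the node structure, the
#'   canonical class order, and the feature names.
#' @seealso [predict.gini_tree()], [feature_importance()], [loso_evaluate()]
#' @examples
#' x <- data.frame(a = c(0, 0, 1, 1), b = c(5, 6, 5, 6))
#' fit <- gini_tree(x, c("u", "u", "v", "v"))
#' predict(fit, x)
#' @export
gini_tree <- function(x, y, max_depth = 3, min_leaf = 1) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1)
  classes <- sort(unique(y))
  if (length(classes) > 2) stop("gini_tree is a two-class classifier")
  root <- .grow_node(x, y, classes, 0L, max_depth, min_leaf)
  structure(list(root = root, classes = classes,
                 features = colnames(x), p = ncol(x),
                 max_depth = max_depth, min_leaf = min_leaf,
                 n = length(y)),
            class = "gini_tree")
}

.tree_depth <- function(node) {
  if (isTRUE(node$leaf)) return(0L)
  1L + max(.tree_depth(node$left), .tree_depth(node$right))
}

.predict_one <- function(node, xi) {
  while (!isTRUE(node$leaf)) {
    node <- if (xi[node$feature] <= node$threshold) node$left else node$right
  }
  node$label
}

#' Predict class labels from a fitted tree
#'
#' Deterministic descent; at each internal node a feature value less than or
#' equal to the node threshold goes left.
#'
#' @param object A \code{gini_tree}.
#' @param newdata Matrix or data frame whose columns match the training
#'   features (same count and order).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.gini_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$p) {
    stop("expected ", object$p, " features, got ", ncol(x))
  }
  if (!is.numeric(x) || anyNA(x)) stop("feature values must be numeric and non-missing")
  vapply(seq_len(nrow(x)), function(i) .predict_one(object$root, x[i, ]),
         character(1))
}

#' Normalized Gini feature importance of a fitted tree
#'
#' Each internal node contributes its weighted impurity decrease
#' \code{(n_node/n_total) * [G - (nL/n_node) GL - (nR/n_node) GR]} to its
#' split feature; the accumulated totals are normalized to sum to 1.  A tree
#' with no split returns an all-zero vector (nothing to normalize).
#'
#' @param tree A \code{gini_tree}.
#' @return Named numeric vector over the training features, non-negative,
#'   summing to 1 (or all zero for a split-free tree).
#' @export
feature_importance <- function(tree) {
  stopifnot(inherits(tree, "gini_tree"))
  imp <- numeric(tree$p)
  n_total <- tree$root$n
  walk <- function(node) {
    if (isTRUE(node$leaf)) return(invisible())
    wl <- node$left$n / node$n
    wr <- node$right$n / node$n
    dec <- node$gini - wl * node$left$gini - wr * node$right$gini
    imp[node$feature] <<- imp[node$feature] + (node$n / n_total) * dec
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  names(imp) <- if (!is.null(tree$features)) tree$features
                else paste0("x", seq_len(tree$p))
  imp
}

.print_node <- function(node, features, indent = "") {
  if (isTRUE(node$leaf)) {
    cat(sprintf("%sleaf: %s (counts %s, gini %.3f)\n", indent, node$label,
                paste(node$counts, collapse = "/"), node$gini))
  } else {
    f <- if (!is.null(features)) features[node$feature]
         else paste0("x", node$feature)
    cat(sprintf("%s%s <= %g (n %d, gini %.3f, decrease %.4f)\n", indent, f,
                node$threshold, node$n, node$gini, node$decrease))
    .print_node(node$left, features, paste0(indent, "  "))
    .print_node(node$right, features, paste0(indent, "  "))
  }
}

#' @export
print.gini_tree <- function(x, ...) {
  cat(sprintf("Gini classification tree (depth %d/%d, n = %d, classes: %s)\n",
              .tree_depth(x$root), x$max_depth, x$n,
              paste(x$classes, collapse = " vs ")))
  .print_node(x$root, x$features)
  invisible(x)
}

#' @export
summary.gini_tree <- function(object, ...) {
  imp <- feature_importance(object)
  cat(sprintf("Tree depth %d (limit %d), %d training samples\n",
              .tree_depth(object$root), object$max_depth, object$n))
  cat("Feature importance (normalized Gini decrease):\n")
  print(round(imp, 4))
  invisible(list(depth = .tree_depth(object$root), importance = imp))
}
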