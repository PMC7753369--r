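#' Per-trial feature table
#'
#' @param X Trials x features numeric matrix, all values finite.
#' @param y Class labels, one per row; at least 2 classes.
#' @param feature_names Optional column names.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(X, y, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values")
  if (nrow(X) != length(y))
    stop("row count (", nrow(X), ") must match label count (", length(y), ")")
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  if (is.null(feature_names))
    feature_names <- colnames(X)
  if (is.null(feature_names))
    feature_names <- sprintf("f%03d", seq_len(ncol(X)))
  if (length(feature_names) != ncol(X))
    stop("feature_names length must equal the feature count")
  colnames(X) <- feature_names
  structure(list(X = X, y = as.character(y),
                 feature_names = as.character(feature_names)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trial(s) x %d feature(s); classes: %s\n",
              nrow(x$X), ncol(x$X),
              paste(names(table(x$y)), table(x$y), sep = ":", collapse = " ")))
  invisible(x)
}

# Sorted unique class labels of a label vector (the canonical class order
# used for score columns and tie-breaking by "smaller class index").
.class_levels_of <- function(y) sort(unique(as.character(y)))

#' k-nearest-neighbour classification
#'
#' Euclidean distances, majority vote over the `k` nearest training points.
#' Scores are the neighbour vote fractions per class. Deterministic tie
#' rules: equal distances are broken by lower training-row index, and vote
#' ties by smaller class index (position in the sorted class labels).
#'
#' @param train A [feature_table()].
#' @param test_points Numeric matrix of query rows (same feature count).
#' @param k Number of neighbours, `1 <= k <= nrow(train$X)`.
#' @return A list with `labels` (predicted class per query) and `scores`
#'   (queries x classes vote-fraction matrix, columns in sorted class order).
#' @export
knn_classify <- function(train, test_points, k = 5) {
  stopifnot(inherits(train, "feature_table"))
  test_points <- matrix(as.numeric(test_points), ncol = ncol(train$X))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(train$X))
    stop("k (", k, ") exceeds the number of training rows (", nrow(train$X), ")")
  classes <- .class_levels_of(train$y)
  nq <- nrow(test_points)
  scores <- matrix(0, nq, length(classes), dimnames = list(NULL, classes))
  labels <- character(nq)
  for (i in seq_len(nq)) {
    d2 <- colSums((t(train$X) - test_points[i, ])^2)
    nn <- order(d2, seq_along(d2))[seq_len(k)]  # distance ties: lower index
    votes <- table(factor(train$y[nn], levels = classes))
    scores[i, ] <- as.numeric(votes) / k
    labels[i] <- classes[which.max(votes)]      # vote ties: smaller class index
  }
  list(labels = labels, scores = scores)
}

# ---- Gini decision tree ----------------------------------------------------

.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

# Best axis-aligned split of a node: for each feature, sort once and sweep
# all thresholds with prefix class counts (vectorized weighted Gini).
# Tie rules: first feature, lowest threshold.
.best_split <- function(X, y, classes, min_leaf) {
  n <- length(y)
  Y <- outer(y, classes, "==") + 0  # n x C indicator
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    valid <- which(xs[-n] < xs[-1])  # left part = sorted positions 1..i
    valid <- valid[valid >= min_leaf & (n - valid) >= min_leaf]
    if (!length(valid)) next
    cum <- apply(Y[ord, , drop = FALSE], 2, cumsum)
    nl <- valid; nr <- n - valid
    cl <- cum[valid, , drop = FALSE]
    cr <- rep(1, length(valid)) %o% cum[n, ] - cl
    g <- (nl * (1 - rowSums((cl / nl)^2)) +
          nr * (1 - rowSums((cr / nr)^2))) / n
    i <- which.min(g)  # which.min takes the first = lowest threshold
    if (is.null(best) || g[i] < best$impurity - 1e-12)
      best <- list(feature = j,
                   threshold = (xs[valid[i]] + xs[valid[i] + 1]) / 2,
                   impurity = g[i])
  }
  best
}

# Recursive binary tree grown by greedy Gini minimization. A zero-gain split
# is still taken on an impure node when one exists (required to resolve
# XOR-type interactions that no single split improves); recursion terminates
# because every split strictly shrinks both children.
.grow_tree <- function(X, y, classes, depth, max_depth, min_leaf) {
  counts <- as.numeric(table(factor(y, levels = classes)))
  leaf <- list(leaf = TRUE, counts = counts)
  if (length(unique(y)) == 1 || depth >= max_depth || length(y) < 2 * min_leaf)
    return(leaf)
  best <- .best_split(X, y, classes, min_leaf)
  if (is.null(best)) return(leaf)
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       counts = counts,
       left = .grow_tree(X[left, , drop = FALSE], y[left], classes,
                         depth + 1, max_depth, min_leaf),
       right = .grow_tree(X[!left, , drop = FALSE], y[!left], classes,
                          depth + 1, max_depth, min_leaf))
}

.predict_tree_row <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$counts
}

#' Decision-tree classification
#'
#' Binary axis-aligned CART-style tree grown by greedy Gini-impurity
#' minimization (zero-gain splits are taken on impure nodes so interaction
#' patterns remain separable). Leaf scores are the training class frequencies
#' at the leaf; prediction ties go to the smaller class index.
#'
#' @param train A [feature_table()].
#' @param test_points Numeric matrix of query rows.
#' @param max_depth Maximum tree depth (`Inf` = unlimited).
#' @param min_leaf Minimum training rows per leaf.
#' @return A list with `labels`, `scores` (queries x classes leaf-frequency
#'   matrix) and the fitted `tree`.
#' @export
tree_classify <- function(train, test_points, max_depth = Inf, min_leaf = 1) {
  stopifnot(inherits(train, "feature_table"))
  if (nrow(train$X) == 0) stop("empty training set")
  test_points <- matrix(as.numeric(test_points), ncol = ncol(train$X))
  classes <- .class_levels_of(train$y)
  tree <- .grow_tree(train$X, train$y, classes, 0, max_depth, min_leaf)
  nq <- nrow(test_points)
  scores <- matrix(0, nq, length(classes), dimnames = list(NULL, classes))
  labels <- character(nq)
  for (i in seq_len(nq)) {
    counts <- .predict_tree_row(tree, test_points[i, ])
    scores[i, ] <- counts / sum(counts)
    labels[i] <- classes[which.max(counts)]
  }
  list(labels = labels, scores = scores, tree = tree)
}

# ---- metrics ---------------------------------------------------------------

# One-vs-rest rank-sum AUC of a score column.
.auc_binary <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics: accuracy, macro specificity, macro AUC
#'
#' Accuracy is the fraction of correct predictions. Specificity is the
#' macro-averaged one-vs-rest true-negative rate `TN / (TN + FP)`. AUC is the
#' macro-averaged one-vs-rest area under the ROC curve of each class's score
#' column (rank-sum formulation, ties counted half). All metrics are
#' expressed in percent; classes absent from `y_true` are skipped for AUC
#' with a warning.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param scores Rows x classes score matrix (columns in sorted class order,
#'   rows summing to 1); required for AUC, otherwise `NA`.
#' @param classes Class label universe (default: sorted unique labels seen).
#' @return A list with `accuracy`, `specificity`, `auc` (percent) and the
#'   `confusion` matrix (true x predicted).
#' @examples
#' compute_metrics(c("P","P","N","N","N","N"), c("P","P","P","N","N","N"))
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(classes)) classes <- .class_levels_of(c(y_true, y_pred))
  n <- length(y_true)
  confusion <- table(factor(y_true, levels = classes),
                     factor(y_pred, levels = classes))
  accuracy <- 100 * sum(diag(confusion)) / n
  spec <- vapply(classes, function(cl) {
    tn <- sum(y_true != cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }, 1)
  specificity <- 100 * mean(spec, na.rm = TRUE)
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (is.null(colnames(scores))) colnames(scores) <- classes
    aucs <- vapply(classes, function(cl) {
      pos <- y_true == cl
      if (!any(pos) || all(pos)) {
        warning("class '", cl, "' absent from one side; skipped for AUC")
        return(NA_real_)
      }
      .auc_binary(scores[pos, cl], scores[!pos, cl])
    }, 1)
    auc <- 100 * mean(aucs, na.rm = TRUE)
  }
  list(accuracy = accuracy, specificity = specificity, auc = auc,
       confusion = confusion)
}

# Min-max scaling fit on training rows only (per feature), applied to both
# sets; constant training features map to 0 (same convention as
# minmax_normalize). Prevents test-fold leakage of normalization statistics.
.fit_minmax <- function(train_X) {
  lo <- apply(train_X, 2, min); hi <- apply(train_X, 2, max)
  span <- hi - lo
  span[span == 0] <- Inf  # constant feature -> all zeros
  list(lo = lo, span = span)
}
.apply_minmax <- function(scaler, X)
  sweep(sweep(X, 2, scaler$lo), 2, scaler$span, "/")

#' Stratified k-fold cross-validation
#'
#' Shuffles each class's trials with the given seed, deals them round-robin
#' into `folds` stratified folds, fits the classifier on the training folds
#' (with per-feature min-max scaling fit on training data only) and evaluates
#' [compute_metrics()] on each held-out fold. Aggregate metrics are the means
#' over folds; the confusion matrix is summed over folds.
#'
#' @param table A [feature_table()]; every class needs at least `folds`
#'   members.
#' @param classifier A list: `model = "knn"` with `k`, or `model = "tree"`
#'   with optional `max_depth`, `min_leaf`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param scale Apply min-max feature scaling fit on training folds?
#' @return An object of class `"metrics_report"`: per-fold and mean
#'   accuracy/specificity/auc (percent), summed confusion matrix, and a
#'   configuration fingerprint.
#' @export
cross_validate <- function(table, classifier = list(model = "knn", k = 5),
                           folds = 10, seed = 1, scale = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  classes <- .class_levels_of(table$y)
  counts <- table(table$y)
  small <- names(counts)[counts < folds]
  if (length(small))
    stop("class '", small[[1]], "' has ", counts[small[[1]]],
         " trial(s); need >= ", folds, " for stratified ", folds, "-fold CV")
  fold_id <- integer(nrow(table$X))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  for (cl in classes) {
    idx <- sample(which(table$y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  per_fold <- vector("list", folds)
  confusion <- NULL
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- table$X[tr, , drop = FALSE]; Xte <- table$X[!tr, , drop = FALSE]
    if (scale) {
      sc <- .fit_minmax(Xtr)
      Xtr <- .apply_minmax(sc, Xtr); Xte <- .apply_minmax(sc, Xte)
    }
    tt <- feature_table(Xtr, table$y[tr], table$feature_names)
    pred <- if (identical(classifier$model, "tree"))
      tree_classify(tt, Xte,
                    max_depth = classifier$max_depth %||% Inf,
                    min_leaf = classifier$min_leaf %||% 1)
    else
      knn_classify(tt, Xte, k = classifier$k %||% 5)
    m <- compute_metrics(table$y[!tr], pred$labels, pred$scores, classes)
    per_fold[[f]] <- m
    confusion <- if (is.null(confusion)) m$confusion else confusion + m$confusion
  }
  grab <- function(name) vapply(per_fold, `[[`, 1, name)
  structure(list(
    fold_accuracy = grab("accuracy"),
    fold_specificity = grab("specificity"),
    fold_auc = grab("auc"),
    accuracy = mean(grab("accuracy")),
    specificity = mean(grab("specificity")),
    auc = mean(grab("auc")),
    confusion = confusion,
    config = list(classifier = classifier, folds = folds, seed = seed,
                  scale = scale, n = nrow(table$X),
                  n_features = ncol(table$X))
  ), class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cl <- x$config$classifier
  cat(sprintf("<metrics_report> %s, %d-fold CV (n = %d, %d features)\n",
              paste(cl$model, if (identical(cl$model, "knn")) paste0("k=", cl$k %||% 5)),
              x$config$folds, x$config$n, x$config$n_features))
  cat(sprintf("  accuracy    %6.2f %%\n", x$accuracy))
  cat(sprintf("  specificity %6.2f %%\n", x$specificity))
  cat(sprintf("  AUC         %6.2f %%\n", x$auc))
  invisible(x)
}
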