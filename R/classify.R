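#' K-nearest-neighbour tissue classification with cross-validation
#'
#' Classifies samples from their 39 arm-level features with a K-nearest-
#' neighbour vote on Euclidean distances (default K = 5) and evaluates the
#' held-out accuracy by leave-one-out or stratified k-fold cross-validation.
#' Features are used on their raw scale by default, matching the arm-level
#' RPKM (or beta) features the rest of the package produces; `zscore = TRUE`
#' standardizes each feature first.
#'
#' Determinism: candidate neighbours are ordered by (distance, sample id);
#' vote ties are broken in favour of the class of the nearest neighbour among
#' the tied classes. Results are therefore invariant to the row order of
#' `features`.
#'
#' @param features Numeric matrix, samples x features, rownames = sample ids.
#' @param labels Class labels: named vector (sample id -> class) or a vector
#'   aligned with the rows of `features`.
#' @param k Number of neighbours (default 5; K = 3, 5, 7 are the usual
#'   choices); must be < number of training samples.
#' @param mode `"loocv"` or `"kfold"`.
#' @param n_folds Fold count for `mode = "kfold"` (stratified by class).
#' @param seed Seed for fold assignment.
#' @param zscore Standardize features before computing distances.
#' @return Object of class `classification_report`: list with `accuracy`,
#'   `per_class` (data frame class, n, accuracy), `k`, `mode`, `n_folds`,
#'   `seed`, and the held-out `predictions`.
#' @export
knn_cv <- function(features, labels, k = 5L, mode = c("loocv", "kfold"),
                   n_folds = 5L, seed = 1L, zscore = FALSE) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(rownames(features))) rownames(features) <- paste0("s", seq_len(n))
  if (!is.null(names(labels))) {
    labels <- labels[rownames(features)]
  }
  labels <- as.character(labels)
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must cover every sample")
  }
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (n < k + 1) stop("need at least k + 1 samples")
  if (zscore) features <- scale(features)

  D <- as.matrix(stats::dist(features))
  pred <- character(n)
  if (mode == "loocv") {
    for (i in seq_len(n)) {
      pred[i] <- knn_vote(D[i, -i], labels[-i], rownames(features)[-i], k)
    }
  } else {
    folds <- stratified_folds(labels, n_folds, seed)
    for (f in seq_len(n_folds)) {
      test <- which(folds == f)
      train <- which(folds != f)
      for (i in test) {
        pred[i] <- knn_vote(D[i, train], labels[train],
                            rownames(features)[train], k)
      }
    }
  }
  correct <- pred == labels
  classes <- sort(unique(labels))
  per_class <- data.frame(
    class = classes,
    n = as.vector(table(factor(labels, classes))),
    accuracy = vapply(classes, function(cl) mean(correct[labels == cl]), 0),
    stringsAsFactors = FALSE
  )
  structure(list(accuracy = mean(correct),
                 per_class = per_class,
                 k = as.integer(k),
                 mode = mode,
                 n_folds = if (mode == "kfold") as.integer(n_folds) else NA_integer_,
                 seed = if (mode == "kfold") as.integer(seed) else NA_integer_,
                 predictions = stats::setNames(pred, rownames(features))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("knn (k=%d, %s) accuracy: %.3f over %d samples, %d classes\n",
              x$k, x$mode, x$accuracy, length(x$predictions),
              nrow(x$per_class)))
  invisible(x)
}

# majority vote among the k nearest training samples; neighbours ordered by
# (distance, sample id), vote ties broken by the nearest tied-class neighbour
knn_vote <- function(dists, train_labels, train_ids, k) {
  ord <- order(dists, train_ids)
  nn <- ord[seq_len(k)]
  votes <- table(train_labels[nn])
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1) return(winners)
  for (j in nn) {
    if (train_labels[j] %in% winners) return(train_labels[j])
  }
  winners[1]
}

# per-class round-robin fold assignment after a seeded shuffle
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# mean expression per group of genes; assignment is a vector aligned with
# the rows of values; returns samples x groups
aggregate_gene_groups <- function(values, assignment, group_levels) {
  f <- factor(assignment, levels = group_levels)
  counts <- table(f)
  if (any(counts == 0)) {
    stop("group(s) with zero genes: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  sums <- rowsum(values, f)
  t(sums / as.vector(counts))
}

#' Gene-to-arm aggregation permutation test for classification
#'
#' Asks whether the 39 arm-level mean-expression features are more
#' informative for tissue-of-origin classification than arbitrary
#' aggregations of the same genes into 39 groups of identical sizes. The
#' observed statistic P is the LOOCV KNN accuracy using the true gene-to-arm
#' assignment; each of `n_perm` iterations permutes the assignment vector
#' across genes (preserving the exact group sizes), recomputes the 39
#' features and the accuracy N_i. The empirical p value is the fraction of
#' iterations with N_i strictly greater than P.
#'
#' @param expr An [expression_matrix].
#' @param map Named vector gene -> arm (`"unassigned"` ignored).
#' @param labels Sample labels (named vector or aligned with samples).
#' @param k Neighbours for the KNN vote.
#' @param n_perm Number of shuffles (>= 1).
#' @param seed Seed for the shuffle stream.
#' @return A `permutation_result` with the accuracies as statistics
#'   (`observed`, `null`, `p`).
#' @export
gene_group_shuffle_test <- function(expr, map, labels, k = 5L,
                                    n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  keep_arms <- included_arms()
  map <- map[names(map) %in% rownames(expr$values)]
  map <- map[map %in% keep_arms]
  if (!length(map)) stop("no genes map to included arms")
  vals <- expr$values[names(map), , drop = FALSE]
  assignment <- unname(map)
  if (is.null(names(labels))) {
    labels <- stats::setNames(as.character(labels), colnames(expr$values))
  }
  feat <- aggregate_gene_groups(vals, assignment, keep_arms)
  observed <- knn_cv(feat, labels, k = k, mode = "loocv")$accuracy
  set.seed(seed)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    shuffled <- assignment[sample.int(length(assignment))]
    feat_i <- aggregate_gene_groups(vals, shuffled, keep_arms)
    null[i] <- knn_cv(feat_i, labels, k = k, mode = "loocv")$accuracy
  }
  structure(list(observed = observed, null = null, n_perm = as.integer(n_perm),
                 p = mean(null > observed), axis = "gene_groups",
                 seed = as.integer(seed), add_one = FALSE),
            class = "permutation_result")
}
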