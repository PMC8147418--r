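#' Hierarchical clustering of tissues on arm-level features
#'
#' Agglomerative clustering (via [stats::hclust()]) of group rows described
#' by their 39 arm-level features; complete linkage on Euclidean distances by
#' default. Undefined feature entries (e.g. driver-imbalance scores of arms
#' without drivers) are imputed with the column mean before clustering and
#' the affected columns are flagged in the result. Rows are ordered
#' lexicographically by id before clustering so the result is independent of
#' input row order, with merge-height ties resolved towards the smallest
#' leaf-id pair.
#'
#' @param features Numeric matrix, groups x features, with rownames; or a
#'   precomputed [stats::dist] object (in which case `metric` is ignored).
#' @param linkage Linkage method passed to `hclust` (default `"complete"`).
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return Object of class `arm_dendrogram`: list with the underlying
#'   `hclust` object, `linkage`, `metric`, `leaf_ids`, and
#'   `imputed_columns`.
#' @export
hierarchical_cluster <- function(features, linkage = "complete",
                                 metric = "euclidean") {
  if (inherits(features, "dist")) {
    if (attr(features, "Size") < 2) stop("need at least 2 groups to cluster")
    h <- stats::hclust(features, method = linkage)
    return(structure(list(hclust = h, linkage = linkage,
                          metric = "precomputed", leaf_ids = h$labels,
                          imputed_columns = character(0)),
                     class = "arm_dendrogram"))
  }
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 groups to cluster")
  if (is.null(rownames(features))) {
    stop("features must carry group ids as rownames")
  }
  features <- features[order(rownames(features)), , drop = FALSE]
  imputed <- character(0)
  if (anyNA(features)) {
    for (j in seq_len(ncol(features))) {
      miss <- is.na(features[, j])
      if (any(miss)) {
        col_mean <- mean(features[!miss, j])
        if (is.nan(col_mean)) col_mean <- 0
        features[miss, j] <- col_mean
        imputed <- c(imputed, colnames(features)[j] %||% as.character(j))
      }
    }
  }
  h <- stats::hclust(stats::dist(features, method = metric), method = linkage)
  structure(list(hclust = h, linkage = linkage, metric = metric,
                 leaf_ids = h$labels, imputed_columns = imputed),
            class = "arm_dendrogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.arm_dendrogram <- function(x, ...) {
  cat(sprintf("arm_dendrogram: %d leaves, %s linkage, %s metric\n",
              length(x$leaf_ids), x$linkage, x$metric))
  invisible(x)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height at which leaves i and j are first joined.
#' The resulting matrix is ultrametric: d(i, k) <= max(d(i, j), d(j, k)) for
#' every triple.
#'
#' @param d An `arm_dendrogram` from [hierarchical_cluster()].
#' @return Symmetric numeric matrix with a zero diagonal and leaf ids as
#'   dimnames.
#' @export
cophenetic_matrix <- function(d) {
  stopifnot(inherits(d, "arm_dendrogram"))
  m <- as.matrix(stats::cophenetic(d$hclust))
  m[d$leaf_ids, d$leaf_ids]
}

#' Spearman similarity of two cophenetic matrices
#'
#' Quantifies how similar two hierarchical clusterings of the same groups
#' are: the Spearman correlation between their cophenetic distances over the
#' strictly-lower-triangle pairs, with leaves aligned by id (the intersection
#' is used, with a warning when leaves are dropped). The reported p value is
#' the usual t approximation, which treats the leaf pairs as independent —
#' an approximation, since pairs sharing a leaf are not.
#'
#' @param c1,c2 Cophenetic matrices with leaf ids as dimnames.
#' @return List with `rho`, `p`, and `n_pairs`.
#' @export
cophenetic_similarity <- function(c1, c2) {
  shared <- intersect(rownames(c1), rownames(c2))
  if (length(shared) < 3) stop("need at least 3 shared leaves")
  if (length(shared) < nrow(c1) || length(shared) < nrow(c2)) {
    warning(sprintf("dropping %d unmatched leaf/leaves",
                    (nrow(c1) - length(shared)) + (nrow(c2) - length(shared))))
  }
  m1 <- c1[shared, shared]
  m2 <- c2[shared, shared]
  lt <- lower.tri(m1)
  r <- spearman_rho(m1[lt], m2[lt])
  list(rho = r$rho, p = r$p, n_pairs = r$n)
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' @param d An `arm_dendrogram`.
#' @param n_clusters Number of clusters (1 <= n_clusters <= leaves); the tree
#'   is cut at the height yielding exactly this many connected components
#'   (via [stats::cutree()]; with tied merge heights the earlier merge in the
#'   agglomeration order, i.e. the smallest-leaf-id pair, is kept together
#'   first).
#' @return Named integer vector group id -> cluster label.
#' @export
cut_clusters <- function(d, n_clusters = 4L) {
  stopifnot(inherits(d, "arm_dendrogram"))
  n <- length(d$leaf_ids)
  if (n_clusters < 1 || n_clusters > n) {
    stop("n_clusters must lie between 1 and the number of leaves")
  }
  stats::cutree(d$hclust, k = n_clusters)
}
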