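#' Spearman rank correlation with t-approximation p value
#'
#' Computes rho as the Pearson correlation of average-ranked data over
#' pairwise-complete observations, with a two-sided p value from the
#' t approximation with n - 2 degrees of freedom. Returns `NA` for rho and p
#' when fewer than 3 complete pairs remain or either vector is constant.
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` in either are
#'   dropped.
#' @return List with `rho`, `p`, and `n` (complete pairs used).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

align_profiles <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  shared_rows <- intersect(rownames(A), rownames(B))
  shared_cols <- intersect(colnames(A), colnames(B))
  if (length(shared_rows) == 0) stop("no shared groups between the matrices")
  if (length(shared_cols) == 0) stop("no shared arms between the matrices")
  dropped <- (nrow(A) - length(shared_rows)) + (nrow(B) - length(shared_rows)) +
    (ncol(A) - length(shared_cols)) + (ncol(B) - length(shared_cols))
  if (dropped > 0) {
    warning(sprintf("dropping %d unmatched row(s)/column(s)", dropped))
  }
  list(A = A[shared_rows, shared_cols, drop = FALSE],
       B = B[shared_rows, shared_cols, drop = FALSE])
}

#' Arm-wise and group-wise correlation profiles
#'
#' Given two aligned group x arm matrices (e.g. per-tissue mean arm
#' expression and per-tissue arm imbalance scores), computes one Spearman
#' correlation per arm (across groups) and one per group (across arms).
#' Undefined entries (missing values, constant vectors, fewer than 3 pairs)
#' propagate as `NA`.
#'
#' @param A,B Numeric matrices with matching group rownames and arm colnames;
#'   unmatched rows/columns are dropped with a warning.
#' @return List with data frames `by_arm` (id, rho, p, n) and `by_group`.
#' @export
correlation_profiles <- function(A, B) {
  al <- align_profiles(A, B)
  by_arm <- lapply(colnames(al$A), function(j) {
    r <- spearman_rho(al$A[, j], al$B[, j])
    data.frame(id = j, rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
  })
  by_group <- lapply(rownames(al$A), function(i) {
    r <- spearman_rho(al$A[i, ], al$B[i, ])
    data.frame(id = i, rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
  })
  list(by_arm = do.call(rbind, by_arm),
       by_group = do.call(rbind, by_group))
}

# rank and standardize each column; columns with zero variance become NA
standardize_ranks_cols <- function(M) {
  if (nrow(M) < 3) {
    # fewer than 3 pairs: every correlation is undefined
    return(matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M)))
  }
  R <- apply(M, 2, rank, ties.method = "average")
  R <- scale(R)
  R[, attr(R, "scaled:scale") == 0] <- NA_real_
  R / sqrt(nrow(M) - 1)
}

#' Positive-correlation-count permutation test
#'
#' Tests whether the number of positive correlations between two aligned
#' group x arm matrices exceeds what random pairings produce. The observed
#' statistic P is the number of strictly positive defined correlations along
#' the chosen axis (`by_arm`: one rho per arm across groups; `by_group`: one
#' rho per group across arms). Each of `n_perm` iterations shuffles B's arm
#' labels (`by_arm`) or B's group labels (`by_group`) uniformly at random and
#' recomputes the count N_i. The empirical p value is the fraction of
#' iterations with N_i strictly greater than P; `add_one = TRUE` instead uses
#' the (sum(N_i >= P) + 1) / (n_perm + 1) variant. Undefined correlations
#' count as non-positive in both P and every N_i.
#'
#' @param A,B Aligned numeric matrices (groups x arms).
#' @param axis `"by_arm"` or `"by_group"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param add_one Use the add-one empirical p variant.
#' @return Object of class `permutation_result`: list with `observed`,
#'   `null` (integer vector length `n_perm`), `n_perm`, `p`, `axis`, `seed`.
#' @export
permutation_positive_count_test <- function(A, B, axis = c("by_arm", "by_group"),
                                            n_perm = 1000L, seed = 1L,
                                            add_one = FALSE) {
  axis <- match.arg(axis)
  if (n_perm < 1) stop("n_perm must be >= 1")
  al <- align_profiles(A, B)
  A <- al$A
  B <- al$B
  set.seed(seed)
  if (!anyNA(A) && !anyNA(B)) {
    # fast path: rho sign equals the sign of the cross-product of
    # column-standardized (or row-standardized) ranks
    if (axis == "by_group") {
      A <- t(A)
      B <- t(B)
    }
    Ar <- standardize_ranks_cols(A)
    Br <- standardize_ranks_cols(B)
    observed <- sum(colSums(Ar * Br) > 0, na.rm = TRUE)
    k <- ncol(B)
    null <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(k)
      null[i] <- sum(colSums(Ar * Br[, idx, drop = FALSE]) > 0, na.rm = TRUE)
    }
  } else {
    count_fn <- function(Bm) {
      pr <- correlation_profiles_quiet(A, Bm)
      rho <- if (axis == "by_arm") pr$by_arm$rho else pr$by_group$rho
      sum(rho > 0, na.rm = TRUE)
    }
    observed <- count_fn(B)
    null <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      if (axis == "by_arm") {
        Bp <- B[, sample.int(ncol(B)), drop = FALSE]
        colnames(Bp) <- colnames(B)
      } else {
        Bp <- B[sample.int(nrow(B)), , drop = FALSE]
        rownames(Bp) <- rownames(B)
      }
      null[i] <- count_fn(Bp)
    }
  }
  p <- if (add_one) (sum(null >= observed) + 1) / (n_perm + 1) else mean(null > observed)
  structure(list(observed = observed, null = null, n_perm = as.integer(n_perm),
                 p = p, axis = axis, seed = as.integer(seed),
                 add_one = add_one),
            class = "permutation_result")
}

correlation_profiles_quiet <- function(A, B) {
  suppressWarnings(correlation_profiles(A, B))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%s): observed P = %s, n_perm = %d, p = %.4g\n",
              x$axis, format(x$observed), x$n_perm, x$p))
  invisible(x)
}

#' Restrict an arm call matrix to early-stage tumors
#'
#' Keeps samples whose AJCC stage normalizes to 0 or I. Stage strings such as
#' "Stage 0", "Stage I", "Stage IA", "Stage IB" are retained; sub-stage
#' letters are ignored; "Stage II" and beyond are dropped. Samples with a
#' missing stage cannot be verified and are dropped (their count is
#' reported).
#'
#' @param calls An [arm_calls] object whose metadata has a `stage` column.
#' @return The filtered [arm_calls] object.
#' @export
filter_early_stage <- function(calls) {
  stopifnot(inherits(calls, "arm_calls"))
  if (!"stage" %in% names(calls$metadata)) {
    stop("metadata has no 'stage' column")
  }
  stage <- normalize_stage(calls$metadata$stage)
  n_missing <- sum(is.na(stage))
  if (n_missing > 0) {
    message(sprintf("dropping %d sample(s) with missing stage", n_missing))
  }
  keep <- !is.na(stage) & stage %in% c("0", "I")
  arm_calls(calls$calls[keep, , drop = FALSE],
            calls$metadata[keep, , drop = FALSE])
}

# "Stage IA" -> "I", "Stage 0" -> "0", "Stage IIB" -> "II"; NA for blank/unknown
normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s[s %in% c("", "NA", "UNKNOWN", "NOT AVAILABLE")] <- NA_character_
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("(?<=[IV0])[ABC]$", "", s, perl = TRUE)
  s
}
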