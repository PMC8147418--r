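#' Chromosome arm imbalance scores
#'
#' For each group of samples (a tissue of origin, or a single cancer type)
#' and each of the 39 arms, the imbalance score is the difference between the
#' frequency of gains and the frequency of losses:
#' score(a, g) = (number of +1 calls - number of -1 calls) / n_g.
#' Scores lie in [-1, 1]; an arm with no events scores 0. Samples whose call
#' was missing upstream were already re-set to 0 (non-aneuploid) at load time.
#'
#' @param calls An [arm_calls] object.
#' @param grouping Either the name of a metadata column (`"tissue"` or
#'   `"cancer_type"`) or a named character vector sample_id -> group.
#' @return An object of class `imbalance_profile`: list with matrices
#'   `score`, `gain_freq`, `loss_freq` (groups x 39 arms) and `n_samples`
#'   (named vector of group sizes).
#' @examples
#' m <- matrix(0L, 4, 39, dimnames = list(paste0("s", 1:4), included_arms()))
#' m[, "1p"] <- c(1L, 1L, -1L, 0L)
#' ac <- arm_calls(m, data.frame(sample_id = paste0("s", 1:4), tissue = "t"))
#' arm_imbalance_score(ac, "tissue")$score[, "1p"] # 0.25
#' @export
arm_imbalance_score <- function(calls, grouping = "tissue") {
  stopifnot(inherits(calls, "arm_calls"))
  g <- resolve_grouping(calls$metadata, grouping, rownames(calls$calls))
  groups <- sort(unique(g))
  n_g <- table(g)
  if (any(n_g == 0)) {
    stop("empty group: ", names(n_g)[which(n_g == 0)[1]])
  }
  gains <- rowsum((calls$calls == 1L) + 0, g)[groups, , drop = FALSE]
  losses <- rowsum((calls$calls == -1L) + 0, g)[groups, , drop = FALSE]
  n <- as.vector(n_g[groups])
  gain_freq <- gains / n
  loss_freq <- losses / n
  structure(list(score = (gains - losses) / n,
                 gain_freq = gain_freq,
                 loss_freq = loss_freq,
                 n_samples = stats::setNames(n, groups)),
            class = "imbalance_profile")
}

#' @export
print.imbalance_profile <- function(x, ...) {
  cat(sprintf("imbalance_profile: %d group(s) x %d arms\n",
              nrow(x$score), ncol(x$score)))
  invisible(x)
}

resolve_grouping <- function(metadata, grouping, sample_ids) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(metadata)) {
    g <- stats::setNames(as.character(metadata[[grouping]]), metadata$sample_id)
  } else if (!is.null(names(grouping))) {
    g <- stats::setNames(as.character(grouping), names(grouping))
  } else {
    stop("grouping must be a metadata column name or a named vector")
  }
  out <- g[sample_ids]
  if (any(is.na(out)) || any(out == "")) {
    stop("every sample must be mapped to exactly one group")
  }
  stats::setNames(unname(out), sample_ids)
}

#' Mean arm-wide gene expression features
#'
#' Aggregates a genes x samples expression matrix into 39 arm-level features:
#' the unweighted arithmetic mean RPKM of the genes assigned to each arm.
#' At `level = "sample"` one feature vector per sample is returned (the
#' feature set used for tissue-of-origin classification); at
#' `level = "group"` the grand mean over all genes and all samples of the
#' group is returned (the per-tissue summary correlated with imbalance
#' scores). With genes fixed per arm across samples the grand mean equals the
#' mean of per-sample features.
#'
#' @param expr An [expression_matrix].
#' @param map Named vector gene_id -> arm id (`"unassigned"` entries and
#'   genes absent from `expr` are ignored).
#' @param level `"sample"` or `"group"`.
#' @param grouping Needed for `level = "group"`: metadata column name or
#'   named vector sample -> group.
#' @param log2p1 If `TRUE`, aggregate log2(RPKM + 1) instead of raw RPKM.
#'   Off by default: features are kept on the raw scale.
#' @param arms Arm definition table.
#' @return Numeric matrix, rows = samples or groups, 39 arm columns.
#' @export
mean_arm_expression <- function(expr, map, level = c("sample", "group"),
                                grouping = "tissue", log2p1 = FALSE,
                                arms = arm_definition()) {
  stopifnot(inherits(expr, "expression_matrix"))
  level <- match.arg(level)
  keep_arms <- included_arms(arms)
  map <- map[names(map) %in% rownames(expr$values)]
  map <- map[map %in% keep_arms]
  if (!length(map)) stop("no genes map to included arms")
  counts <- table(factor(map, levels = keep_arms))
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    stop("arm(s) with zero assigned genes: ", paste(empty, collapse = ", "))
  }
  vals <- expr$values[names(map), , drop = FALSE]
  if (log2p1) vals <- log2(vals + 1)
  sums <- rowsum(vals, group = factor(map, levels = keep_arms))
  feat <- t(sums / as.vector(counts)) # samples x arms
  feat <- feat[, keep_arms, drop = FALSE]
  if (level == "sample") return(feat)
  g <- resolve_grouping(expr$metadata, grouping, colnames(expr$values))
  grp <- rowsum(feat, g)
  grp / as.vector(table(g)[rownames(grp)])
}

#' Oncogene / tumor-suppressor imbalance per arm
#'
#' For a tissue (or all tissues), computes for each arm the difference
#' between the fraction of resident driver genes annotated as oncogenes and
#' the fraction annotated as tumor suppressors:
#' frac_onco - frac_ts, in [-1, 1]. Arms carrying no driver for the tissue
#' are undefined (`NA`) rather than 0, and are excluded from downstream
#' correlations.
#'
#' @param drivers A [driver_table()] with an `arm_id` column.
#' @param tissues Character vector of tissues to score; default all tissues
#'   present in the table.
#' @param arms Arm definition table.
#' @return List of class `driver_imbalance` with matrices `score`,
#'   `frac_onco`, `frac_ts`, `n_drivers` (tissues x 39 arms).
#' @export
onco_ts_imbalance <- function(drivers, tissues = NULL, arms = arm_definition()) {
  stopifnot(inherits(drivers, "driver_table") || is.data.frame(drivers))
  keep_arms <- included_arms(arms)
  if (is.null(tissues)) tissues <- sort(unique(drivers$tissue))
  if (nrow(drivers) == 0 || length(tissues) == 0) {
    warning("empty driver table: all scores undefined")
    if (length(tissues) == 0) tissues <- "none"
  }
  d <- drivers[drivers$arm_id %in% keep_arms & drivers$tissue %in% tissues, ,
               drop = FALSE]
  zero <- matrix(0, length(tissues), length(keep_arms),
                 dimnames = list(tissues, keep_arms))
  n_onco <- zero
  n_ts <- zero
  if (nrow(d)) {
    tab <- table(factor(d$tissue, levels = tissues),
                 factor(d$arm_id, levels = keep_arms),
                 factor(d$role, levels = c("oncogene", "tumor_suppressor")))
    n_onco <- zero + tab[, , "oncogene"]
    n_ts <- zero + tab[, , "tumor_suppressor"]
  }
  n_tot <- n_onco + n_ts
  frac_onco <- n_onco / n_tot # NaN where no drivers
  frac_ts <- n_ts / n_tot
  score <- frac_onco - frac_ts
  score[n_tot == 0] <- NA_real_
  frac_onco[n_tot == 0] <- NA_real_
  frac_ts[n_tot == 0] <- NA_real_
  structure(list(score = score, frac_onco = frac_onco, frac_ts = frac_ts,
                 n_drivers = n_tot),
            class = "driver_imbalance")
}

#' Quantile-normalize values onto a reference distribution
#'
#' Maps each value to the empirical quantile of the reference distribution at
#' its own rank, so that the output has (interpolated) reference-distribution
#' quantiles as its values while preserving the input's rank order. Used to
#' put arm-level mean expression (or methylation) on the same scale as arm
#' imbalance scores for side-by-side comparison. Quantiles use plotting
#' positions (i - 0.5)/n with linear interpolation between reference order
#' statistics; tied inputs receive the quantile of their average rank; `NA`
#' values pass through.
#'
#' @param values Numeric vector to rescale (may contain `NA`).
#' @param reference Numeric vector (length >= 2) defining the target
#'   distribution.
#' @return Numeric vector of the same length and order as `values`.
#' @examples
#' quantile_normalize_to_reference(c(10, 20, 30), c(-1, 0, 1)) # -1 0 1
#' @export
quantile_normalize_to_reference <- function(values, reference) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 2) stop("reference must contain at least 2 values")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0) return(out)
  r <- rank(values[ok], ties.method = "average")
  probs <- (r - 0.5) / n
  m <- length(reference)
  ref_sorted <- sort(reference)
  ref_probs <- (seq_len(m) - 0.5) / m
  out[ok] <- stats::approx(ref_probs, ref_sorted, xout = probs, rule = 2)$y
  out
}
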