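#' Remove SNP-proximal methylation probes
#'
#' Drops probes lying within `max_distance` base pairs (inclusive) of a known
#' SNP, whose beta values are unreliable. Probes with an unknown SNP distance
#' are retained and their count reported.
#'
#' @param annotation A `probe_annotation` table with a `snp_distance` column.
#' @param max_distance Inclusive distance threshold in bp (default 15).
#' @return The filtered `probe_annotation`.
#' @export
filter_snp_proximal_probes <- function(annotation, max_distance = 15) {
  stopifnot(is.data.frame(annotation))
  d <- annotation$snp_distance
  if (any(d < 0, na.rm = TRUE)) stop("negative snp_distance")
  n_unknown <- sum(is.na(d))
  if (n_unknown > 0) {
    message(sprintf("%d probe(s) with unknown SNP distance retained", n_unknown))
  }
  keep <- is.na(d) | d > max_distance
  out <- annotation[keep, , drop = FALSE]
  rownames(out) <- NULL
  probe_annotation(out)
}

#' Merge methylation datasets over their common probes
#'
#' Combines several beta matrices (e.g. GEO series profiled on the same
#' 450K platform) into one matrix over the intersection of their probes,
#' keeping only normal-control samples by default and recording the source
#' dataset of every sample.
#'
#' @param datasets List of datasets, each a list with `betas` (probes x
#'   samples matrix), and `metadata` (data frame with `sample_id`, `tissue`,
#'   `is_control` logical, and optionally `dataset_id`).
#' @param control_only Drop samples with `is_control = FALSE` (default TRUE).
#' @return Object of class `merged_beta`: list with `betas` (common probes x
#'   all retained samples) and `metadata` (including `dataset_id`).
#' @export
merge_beta_datasets <- function(datasets, control_only = TRUE) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  probes <- Reduce(intersect, lapply(datasets, function(d) rownames(d$betas)))
  if (length(probes) == 0) stop("empty probe intersection across datasets")
  pieces <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    meta <- as.data.frame(d$metadata, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "tissue") %in% names(meta))) {
      stop("dataset metadata needs sample_id and tissue")
    }
    if (!"is_control" %in% names(meta)) meta$is_control <- TRUE
    if (!"dataset_id" %in% names(meta)) meta$dataset_id <- paste0("dataset", i)
    if (control_only) {
      keep <- meta$is_control
      meta <- meta[keep, , drop = FALSE]
    }
    list(betas = d$betas[probes, meta$sample_id, drop = FALSE], meta = meta)
  })
  betas <- do.call(cbind, lapply(pieces, `[[`, "betas"))
  metadata <- do.call(rbind, lapply(pieces, `[[`, "meta"))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids after merge")
  rownames(metadata) <- NULL
  structure(list(betas = betas, metadata = metadata), class = "merged_beta")
}

#' @export
print.merged_beta <- function(x, ...) {
  cat(sprintf("merged_beta: %d probes x %d samples from %d dataset(s)\n",
              nrow(x$betas), ncol(x$betas), length(unique(x$metadata$dataset_id))))
  invisible(x)
}

#' Mean arm-wide methylation features
#'
#' Aggregates probe betas into 39 arm-level features: the unweighted mean
#' beta of the probes on each arm, per sample or per tissue (grand mean over
#' probes and samples of the tissue). Values stay in [0, 1].
#'
#' @param merged A `merged_beta` object (or a list with `betas` and
#'   `metadata`).
#' @param probe_map Named vector probe_id -> arm id (see
#'   [assign_probes_to_arms()]).
#' @param level `"sample"` or `"tissue"`.
#' @param arms Arm definition table.
#' @return Numeric matrix, rows = samples or tissues, 39 arm columns.
#' @export
mean_arm_methylation <- function(merged, probe_map,
                                 level = c("sample", "tissue"),
                                 arms = arm_definition()) {
  level <- match.arg(level)
  keep_arms <- included_arms(arms)
  betas <- merged$betas
  probe_map <- probe_map[names(probe_map) %in% rownames(betas)]
  probe_map <- probe_map[probe_map %in% keep_arms]
  if (!length(probe_map)) stop("no probes map to included arms")
  counts <- table(factor(probe_map, levels = keep_arms))
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    stop("arm(s) with zero mapped probes: ", paste(empty, collapse = ", "))
  }
  vals <- betas[names(probe_map), , drop = FALSE]
  sums <- rowsum(vals, group = factor(probe_map, levels = keep_arms))
  feat <- t(sums / as.vector(counts))
  if (level == "sample") return(feat)
  g <- stats::setNames(merged$metadata$tissue, merged$metadata$sample_id)
  g <- g[rownames(feat)]
  grp <- rowsum(feat, g)
  grp / as.vector(table(g)[rownames(grp)])
}
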