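#' Construct an arm call matrix
#'
#' Container for discrete per-sample chromosome-arm copy-number calls:
#' -1 (arm lost), 0 (non-aneuploid), +1 (arm gained). Calls are stored as an
#' integer matrix over the 39 included autosomal arms together with per-sample
#' metadata (tissue of origin, optional cancer type and AJCC stage).
#'
#' @param calls Integer matrix, samples x arms, entries in \{-1, 0, 1\};
#'   rownames are sample ids, colnames arm ids.
#' @param metadata Data frame with one row per sample; must contain
#'   `sample_id` and `tissue`; `cancer_type` and `stage` are optional.
#' @param arms Arm definition table, see [arm_definition()].
#' @return An object of class `arm_calls`.
#' @export
arm_calls <- function(calls, metadata, arms = arm_definition()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  keep <- included_arms(arms)
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("'calls' must carry sample ids as rownames and arm ids as colnames")
  }
  missing_arms <- setdiff(keep, colnames(calls))
  if (length(missing_arms)) {
    stop("missing arm columns: ", paste(missing_arms, collapse = ", "))
  }
  calls <- calls[, keep, drop = FALSE]
  bad <- !(calls %in% c(-1L, 0L, 1L))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(calls)), arr.ind = TRUE)[1, ]
    stop(sprintf("call value outside {-1,0,1} for sample '%s', arm '%s'",
                 rownames(calls)[idx[1]], colnames(calls)[idx[2]]))
  }
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(metadata))) {
    stop("metadata must contain 'sample_id' and 'tissue'")
  }
  if (!setequal(metadata$sample_id, rownames(calls))) {
    stop("metadata sample ids do not match call matrix rownames")
  }
  metadata <- metadata[match(rownames(calls), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (any(is.na(metadata$tissue)) || any(metadata$tissue == "")) {
    stop("every sample needs a tissue label")
  }
  structure(list(calls = calls, metadata = metadata), class = "arm_calls")
}

#' @export
print.arm_calls <- function(x, ...) {
  cat(sprintf("arm_calls: %d samples x %d arms, %d tissues\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$metadata$tissue))))
  invisible(x)
}

#' @export
dim.arm_calls <- function(x) dim(x$calls)

#' Read per-sample chromosome arm gain/loss calls
#'
#' Reads a TSV with columns `sample_id`, `tissue`, optional `cancer_type` and
#' `stage`, and one column per chromosome arm holding -1/0/+1 calls. `NA` or
#' empty cells are re-set to 0, i.e. such samples are treated as non-aneuploid
#' for that arm. Columns naming arms outside the 39 included autosomal arms
#' are dropped with a warning; any call value outside \{-1, 0, 1, NA\} is an
#' error naming the offending sample and arm.
#'
#' @param path Path to the TSV file.
#' @param arms Arm definition table.
#' @return An [arm_calls] object.
#' @export
read_arm_calls <- function(path, arms = arm_definition()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  meta_cols <- intersect(c("sample_id", "tissue", "cancer_type", "stage"), names(df))
  arm_cols <- setdiff(names(df), meta_cols)
  keep <- included_arms(arms)
  unknown <- setdiff(arm_cols, keep)
  if (length(unknown)) {
    warning("dropping unknown arm column(s): ", paste(unknown, collapse = ", "))
    arm_cols <- setdiff(arm_cols, unknown)
  }
  vals <- as.matrix(df[, arm_cols, drop = FALSE])
  vals[vals %in% c("", "NA", "na")] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(df$sample_id, arm_cols)))
  bad <- (!is.na(vals)) & (is.na(num) | !(num %in% c(-1, 0, 1)))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid call '%s' for sample '%s', arm '%s'",
                 vals[idx[1], idx[2]], df$sample_id[idx[1]], arm_cols[idx[2]]))
  }
  num[is.na(num)] <- 0
  metadata <- df[, meta_cols, drop = FALSE]
  arm_calls(num, metadata, arms = arms)
}

#' Write arm calls to TSV
#'
#' Inverse of [read_arm_calls()]: metadata columns first, then one column per
#' arm. Round-trips labels and values exactly.
#'
#' @param x An [arm_calls] object.
#' @param path Output path.
#' @export
write_arm_calls <- function(x, path) {
  out <- cbind(x$metadata, as.data.frame(x$calls, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix
#'
#' Genes x samples matrix of non-negative expression values (RPKM scale) with
#' per-sample metadata.
#'
#' @param values Numeric matrix, genes x samples, values >= 0, with gene ids
#'   as rownames and sample ids as colnames.
#' @param metadata Data frame with `sample_id` and `tissue` (and optionally
#'   `stage`) per sample.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(is.na(values)) || any(values < 0)) {
    stop("expression values must be non-negative and non-missing")
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(metadata))) {
    stop("metadata must contain 'sample_id' and 'tissue'")
  }
  if (!setequal(metadata$sample_id, colnames(values))) {
    stop("metadata sample ids do not match expression colnames")
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$metadata$tissue))))
  invisible(x)
}

#' Read an expression matrix with sample metadata
#'
#' @param path TSV with first column `gene_id` and one column per sample.
#' @param metadata_path TSV with columns `sample_id`, `tissue` and optionally
#'   `stage`.
#' @return An [expression_matrix] object.
#' @export
read_expression <- function(path, metadata_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' Write an expression matrix and its metadata
#'
#' @param x An [expression_matrix] object.
#' @param path Output TSV for the values.
#' @param metadata_path Output TSV for the sample metadata.
#' @export
write_expression <- function(x, path, metadata_path = NULL) {
  out <- data.frame(gene_id = rownames(x$values),
                    as.data.frame(x$values, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Assign genes to chromosome arms from coordinates
#'
#' Maps each gene to one of the 39 included autosomal arms using a cytoband
#' table. The centromere boundary of a chromosome is the start of its first
#' q band; a gene whose start coordinate (1-based) lies before that boundary
#' is on the p arm, otherwise on the q arm. Genes on sex chromosomes, on
#' chromosomes absent from the cytoband table, or on excluded acrocentric
#' short arms map to `"unassigned"`. The assignment depends only on
#' coordinates, never on input row order.
#'
#' @param gene_coords Data frame with columns `gene_id`, `chrom`, `start`
#'   (1-based) and optionally `end`.
#' @param cytobands Cytoband table in the UCSC `cytoBand.txt` dialect
#'   (`chrom`, 0-based `start`, `end`, `band`, `stain`).
#' @param arms Arm definition table.
#' @return Named character vector mapping `gene_id` to an arm id or
#'   `"unassigned"`.
#' @export
assign_genes_to_arms <- function(gene_coords, cytobands,
                                 arms = arm_definition()) {
  gene_coords <- as.data.frame(gene_coords, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "start") %in% names(gene_coords))) {
    stop("gene_coords needs columns gene_id, chrom, start")
  }
  if (anyDuplicated(gene_coords$gene_id)) stop("duplicate gene ids")
  boundary <- centromere_boundaries(cytobands)
  ch <- normalize_chrom(gene_coords$chrom)
  out <- rep("unassigned", nrow(gene_coords))
  names(out) <- gene_coords$gene_id
  bnd <- boundary[as.character(ch)]
  assignable <- !is.na(ch) & !is.na(bnd)
  letter <- ifelse(gene_coords$start < bnd, "p", "q")
  candidate <- paste0(ch, letter)
  ok <- assignable & candidate %in% included_arms(arms)
  out[ok] <- candidate[ok]
  n_un <- sum(!ok)
  if (n_un > 0) {
    message(sprintf("%d gene(s) left unassigned", n_un))
  }
  out
}

# 1-based centromere boundary (first q-band start + 1) per autosome present
# in the cytoband table; named by chromosome number.
centromere_boundaries <- function(cytobands) {
  cytobands <- as.data.frame(cytobands, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "band") %in% names(cytobands))) {
    stop("cytobands needs columns chrom, start, end, band")
  }
  ch <- normalize_chrom(cytobands$chrom)
  is_q <- grepl("^q", cytobands$band)
  keep <- !is.na(ch) & is_q
  if (!any(keep)) stop("cytoband table contains no q bands on autosomes")
  tapply(cytobands$start[keep] + 1, ch[keep], min)
}

#' Read a UCSC-dialect cytoband file
#'
#' @param path Tab-separated file with columns chrom, start (0-based), end,
#'   band, stain; no header.
#' @return Data frame with those five columns.
#' @export
read_cytobands <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("cytoband file needs at least 4 columns")
  names(df)[1:5] <- c("chrom", "start", "end", "band", "stain")[seq_len(min(5, ncol(df)))]
  df
}

#' Read a 450K-style probe annotation table
#'
#' @param path TSV with columns `probe_id`, `chrom`, `position` (1-based),
#'   `probe_type` (I/II) and `snp_distance` (bp to the nearest SNP; may be
#'   missing).
#' @return Validated data frame of class `probe_annotation`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probe_annotation(df)
}

#' Validate a probe annotation table
#'
#' @param df Data frame with columns `probe_id`, `chrom`, `position`, and
#'   optionally `probe_type` and `snp_distance`.
#' @return The validated data frame, classed `probe_annotation`.
#' @export
probe_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "chrom", "position") %in% names(df))) {
    stop("probe annotation needs columns probe_id, chrom, position")
  }
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids")
  if (any(df$position < 1, na.rm = TRUE)) stop("probe positions must be >= 1")
  if (!"snp_distance" %in% names(df)) df$snp_distance <- NA_real_
  if (!"probe_type" %in% names(df)) df$probe_type <- NA_character_
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Assign methylation probes to chromosome arms
#'
#' Applies the same start-coordinate rule as [assign_genes_to_arms()] to probe
#' positions, so gene and probe features share one coordinate convention.
#'
#' @param annotation A `probe_annotation` table.
#' @param cytobands Cytoband table (UCSC dialect).
#' @param arms Arm definition table.
#' @return Named character vector probe_id -> arm id or `"unassigned"`.
#' @export
assign_probes_to_arms <- function(annotation, cytobands,
                                  arms = arm_definition()) {
  coords <- data.frame(gene_id = annotation$probe_id,
                       chrom = annotation$chrom,
                       start = annotation$position,
                       stringsAsFactors = FALSE)
  assign_genes_to_arms(coords, cytobands, arms = arms)
}

#' Read a beta-value methylation matrix
#'
#' Reads a probes x samples TSV of Illumina 450K beta values. Values must lie
#' in [0, 1] up to a numerical tolerance of 1e-6 (tiny excursions are
#' clipped); anything farther outside is an error. Probes absent from the
#' annotation are dropped and their count reported.
#'
#' @param path TSV, first column `probe_id`, one column per sample.
#' @param annotation A `probe_annotation` table.
#' @return List with `betas` (matrix probes x samples) and `annotation`
#'   (subset matching the retained probes).
#' @export
read_beta_matrix <- function(path, annotation) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id'")
  betas <- as.matrix(df[, -1, drop = FALSE])
  rownames(betas) <- df$probe_id
  check_beta_range(betas)
  betas[] <- pmin(pmax(betas, 0), 1)
  known <- rownames(betas) %in% annotation$probe_id
  if (any(!known)) {
    message(sprintf("dropping %d probe(s) absent from annotation", sum(!known)))
    betas <- betas[known, , drop = FALSE]
  }
  ann <- annotation[match(rownames(betas), annotation$probe_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(betas = betas, annotation = probe_annotation(ann))
}

check_beta_range <- function(betas, tol = 1e-6) {
  bad <- which(!is.na(betas) & (betas < -tol | betas > 1 + tol), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value %g out of [0,1] for probe '%s'",
                 betas[bad[1, 1], bad[1, 2]], rownames(betas)[bad[1, 1]]))
  }
  invisible(TRUE)
}

#' Read a driver-gene table
#'
#' @param path TSV with columns `gene_id`, `tissue`, `role`
#'   (`oncogene`/`tumor_suppressor`).
#' @param gene_arm_map Optional named vector gene_id -> arm id, as produced by
#'   [assign_genes_to_arms()]; when given, an `arm_id` column is added
#'   (`"unassigned"` for unmapped genes).
#' @return Data frame of class `driver_table`.
#' @export
read_driver_table <- function(path, gene_arm_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  driver_table(df, gene_arm_map)
}

#' Validate a driver table
#'
#' @param df Data frame with `gene_id`, `tissue`, `role` and optionally
#'   `arm_id`.
#' @param gene_arm_map Optional named vector used to (re)fill `arm_id`.
#' @return The validated, classed data frame.
#' @export
driver_table <- function(df, gene_arm_map = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tissue", "role") %in% names(df))) {
    stop("driver table needs columns gene_id, tissue, role")
  }
  if (!all(df$role %in% c("oncogene", "tumor_suppressor"))) {
    stop("role must be 'oncogene' or 'tumor_suppressor'")
  }
  if (!is.null(gene_arm_map)) {
    df$arm_id <- unname(gene_arm_map[df$gene_id])
    df$arm_id[is.na(df$arm_id)] <- "unassigned"
  } else if (!"arm_id" %in% names(df)) {
    df$arm_id <- "unassigned"
  }
  ok_arm <- df$arm_id %in% c(included_arms(), "unassigned")
  if (!all(ok_arm)) {
    stop("arm_id values must be included arms or 'unassigned'")
  }
  class(df) <- c("driver_table", "data.frame")
  df
}
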