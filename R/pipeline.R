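#' Assemble a pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. In
#' `"synthetic"` mode a cohort is generated from `cohort` (arguments to
#' [cohort_config()]); in `"real"` mode the file paths below are read with
#' the package's TSV readers. Every stochastic stage derives its seed from
#' the single `seed` by a fixed offset, so one integer pins the whole run.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param cohort List of arguments for [cohort_config()] (synthetic mode).
#' @param paths Named list of input paths (real mode): `calls`,
#'   `normal_expression`, `normal_expression_metadata`, `gene_coords`,
#'   `cytobands`; optional `cancer_expression`, `cancer_expression_metadata`,
#'   `drivers`, `beta_matrix`, `probe_annotation`, `beta_metadata`.
#' @param grouping Metadata column used to group samples (default
#'   `"tissue"`).
#' @param n_perm Permutations for the pairing-shuffle tests.
#' @param n_perm_shuffle Permutations for the gene-aggregation shuffle test
#'   (each iteration refits a LOOCV classifier, hence the smaller default).
#' @param k KNN neighbours.
#' @param n_folds Folds for the k-fold check.
#' @param linkage,metric Hierarchical clustering parameters.
#' @param n_clusters Clusters reported from each dendrogram cut.
#' @param seed Master seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            cohort = list(),
                            paths = list(),
                            grouping = "tissue",
                            n_perm = 1000L,
                            n_perm_shuffle = 100L,
                            k = 5L,
                            n_folds = 5L,
                            linkage = "complete",
                            metric = "euclidean",
                            n_clusters = 4L,
                            seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, cohort = cohort, paths = paths,
              grouping = grouping, n_perm = as.integer(n_perm),
              n_perm_shuffle = as.integer(n_perm_shuffle),
              k = as.integer(k), n_folds = as.integer(n_folds),
              linkage = linkage, metric = metric,
              n_clusters = as.integer(n_clusters), seed = as.integer(seed))
  if (mode == "real") {
    required <- c("calls", "normal_expression", "normal_expression_metadata",
                  "gene_coords", "cytobands")
    missing <- setdiff(required, names(paths))
    if (length(missing)) {
      stop("real mode config is missing path(s): ",
           paste(missing, collapse = ", "))
    }
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent)) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  if (cfg$n_perm < 1 || cfg$n_perm_shuffle < 1) stop("n_perm must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_tsv_out <- function(x, path, rowname_col = NULL) {
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                     check.names = FALSE)
    if (!is.null(rowname_col)) names(df)[1] <- rowname_col
    x <- df
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full arm-aneuploidy analysis pipeline
#'
#' Executes, in dependency order: cohort simulation (or input loading), arm
#' imbalance scoring, arm-level expression aggregation,
#' expression-vs-imbalance correlation profiles with pairing-shuffle
#' permutation tests, driver-gene imbalance analysis, KNN tissue-of-origin
#' classification (LOOCV, k-fold, and the gene-aggregation shuffle null),
#' the four hierarchical clusterings with cophenetic comparisons, and
#' arm-level methylation analysis. All tables are written as TSV and the
#' summary as JSON under `out_dir`; a manifest records an MD5 content hash
#' per file, so identical configurations reproduce identical manifests.
#'
#' @param config A `pipeline_config` (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return List with `summary` (named list of headline numbers) and
#'   `manifest` (data frame file/md5), invisibly also written to
#'   `out_dir/summary.json` and `out_dir/manifest.tsv`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("aneuarm_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  summary <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## ---- inputs ----
  inputs <- stage("inputs", {
    if (config$mode == "synthetic") {
      cc <- do.call(cohort_config,
                    utils::modifyList(list(seed = config$seed), config$cohort))
      cohort <- gen_cohort(cc)
      profile0 <- arm_imbalance_score(cohort$calls, config$grouping)
      drivers <- gen_driver_table(cc, profile0)
      meth <- gen_methylation(cc, cohort$ground_truth)
      list(calls = cohort$calls, cancer_expr = cohort$cancer_expr,
           normal_expr = cohort$normal_expr, gene_map = cohort$gene_map,
           drivers = drivers, meth = meth, cohort_config = cc)
    } else {
      p <- config$paths
      cytobands <- read_cytobands(p$cytobands)
      coords <- utils::read.delim(p$gene_coords, stringsAsFactors = FALSE)
      gene_map <- assign_genes_to_arms(coords, cytobands)
      calls <- read_arm_calls(p$calls)
      normal_expr <- read_expression(p$normal_expression,
                                     p$normal_expression_metadata)
      cancer_expr <- if (!is.null(p$cancer_expression)) {
        read_expression(p$cancer_expression, p$cancer_expression_metadata)
      }
      drivers <- if (!is.null(p$drivers)) read_driver_table(p$drivers, gene_map)
      meth <- if (!is.null(p$beta_matrix)) {
        ann <- read_probe_annotation(p$probe_annotation)
        bm <- read_beta_matrix(p$beta_matrix, ann)
        meta <- utils::read.delim(p$beta_metadata, stringsAsFactors = FALSE)
        list(betas = bm$betas, annotation = bm$annotation, metadata = meta,
             probe_map = assign_probes_to_arms(bm$annotation, cytobands))
      }
      list(calls = calls, cancer_expr = cancer_expr,
           normal_expr = normal_expr, gene_map = gene_map,
           drivers = drivers, meth = meth)
    }
  })

  ## ---- arm scores ----
  scores <- stage("arm_scores", {
    profile <- arm_imbalance_score(inputs$calls, config$grouping)
    normal_group <- mean_arm_expression(inputs$normal_expr, inputs$gene_map,
                                        level = "group", grouping = "tissue")
    normal_sample <- mean_arm_expression(inputs$normal_expr, inputs$gene_map,
                                         level = "sample")
    cancer_group <- if (!is.null(inputs$cancer_expr)) {
      mean_arm_expression(inputs$cancer_expr, inputs$gene_map,
                          level = "group", grouping = config$grouping)
    }
    files <- c(files,
               write_tsv_out(profile$score, file.path(out_dir, "imbalance_score.tsv"), "group"),
               write_tsv_out(profile$gain_freq, file.path(out_dir, "gain_freq.tsv"), "group"),
               write_tsv_out(profile$loss_freq, file.path(out_dir, "loss_freq.tsv"), "group"),
               write_tsv_out(normal_group, file.path(out_dir, "normal_arm_expression.tsv"), "tissue"))
    if (!is.null(cancer_group)) {
      files <- c(files, write_tsv_out(cancer_group,
                                      file.path(out_dir, "cancer_arm_expression.tsv"), "group"))
    }
    files <- files
    list(profile = profile, normal_group = normal_group,
         normal_sample = normal_sample, cancer_group = cancer_group)
  })

  ## ---- expression vs imbalance correlations ----
  stage("correlations", {
    prof <- correlation_profiles(scores$normal_group, scores$profile$score)
    pt_arm <- permutation_positive_count_test(
      scores$normal_group, scores$profile$score, axis = "by_arm",
      n_perm = config$n_perm, seed = config$seed + 11L)
    pt_grp <- permutation_positive_count_test(
      scores$normal_group, scores$profile$score, axis = "by_group",
      n_perm = config$n_perm, seed = config$seed + 12L)
    files <- c(files,
                write_tsv_out(prof$by_arm, file.path(out_dir, "corr_by_arm.tsv")),
                write_tsv_out(prof$by_group, file.path(out_dir, "corr_by_tissue.tsv")))
    summary$armwise_positive_correlations <- pt_arm$observed
    summary$armwise_perm_p <- pt_arm$p
    summary$tissuewise_positive_correlations <- pt_grp$observed
    summary$tissuewise_perm_p <- pt_grp$p
    summary$median_tissue_rho <- stats::median(prof$by_group$rho, na.rm = TRUE)
  })

  ## ---- drivers ----
  driver_scores <- stage("drivers", {
    if (is.null(inputs$drivers)) NULL else {
      di <- onco_ts_imbalance(inputs$drivers)
      pt_ts <- permutation_positive_count_test(
        di$frac_ts, scores$profile$loss_freq, axis = "by_group",
        n_perm = config$n_perm, seed = config$seed + 13L)
      files <- c(files,
                 write_tsv_out(di$score, file.path(out_dir, "driver_imbalance.tsv"), "tissue"))
      summary$ts_loss_positive_correlations <- pt_ts$observed
      summary$ts_loss_perm_p <- pt_ts$p
      di
    }
  })

  ## ---- classification ----
  stage("classification", {
    labels <- stats::setNames(inputs$normal_expr$metadata$tissue,
                              inputs$normal_expr$metadata$sample_id)
    rep_loocv <- knn_cv(scores$normal_sample, labels, k = config$k,
                        mode = "loocv")
    rep_kfold <- knn_cv(scores$normal_sample, labels, k = config$k,
                        mode = "kfold", n_folds = config$n_folds,
                        seed = config$seed + 21L)
    shuffle <- gene_group_shuffle_test(inputs$normal_expr, inputs$gene_map,
                                       labels, k = config$k,
                                       n_perm = config$n_perm_shuffle,
                                       seed = config$seed + 22L)
    files <- c(files,
                write_tsv_out(rep_loocv$per_class,
                              file.path(out_dir, "knn_per_class.tsv")))
    summary$knn_loocv_accuracy <- rep_loocv$accuracy
    summary$knn_kfold_accuracy <- rep_kfold$accuracy
    summary$gene_shuffle_p <- shuffle$p
    summary$gene_shuffle_observed_accuracy <- shuffle$observed
  })

  ## ---- clustering ----
  stage("clustering", {
    feature_sets <- list(imbalance = scores$profile$score,
                         normal_expression = scores$normal_group)
    if (!is.null(scores$cancer_group)) {
      feature_sets$cancer_expression <- scores$cancer_group
    }
    if (!is.null(driver_scores)) {
      feature_sets$driver_imbalance <- driver_scores$score
    }
    dend <- lapply(feature_sets, hierarchical_cluster,
                   linkage = config$linkage, metric = config$metric)
    coph <- lapply(dend, cophenetic_matrix)
    cuts <- lapply(dend, function(d) {
      cut_clusters(d, min(config$n_clusters, length(d$leaf_ids)))
    })
    cut_df <- data.frame(group = names(cuts[[1]]),
                         do.call(cbind, cuts), check.names = FALSE)
    files <- c(files, write_tsv_out(cut_df, file.path(out_dir, "cluster_cuts.tsv")))
    pairs <- utils::combn(names(coph), 2, simplify = FALSE)
    sims <- lapply(pairs, function(pr) {
      s <- cophenetic_similarity(coph[[pr[1]]], coph[[pr[2]]])
      data.frame(a = pr[1], b = pr[2], rho = s$rho, p = s$p,
                 n_pairs = s$n_pairs, stringsAsFactors = FALSE)
    })
    sims <- do.call(rbind, sims)
    files <- c(files, write_tsv_out(sims, file.path(out_dir, "cophenetic_similarity.tsv")))
    get_rho <- function(a, b) {
      hit <- sims$rho[(sims$a == a & sims$b == b) | (sims$a == b & sims$b == a)]
      if (length(hit)) hit[1] else NA_real_
    }
    summary$coph_imbalance_vs_normal_expr <- get_rho("imbalance", "normal_expression")
    summary$coph_imbalance_vs_cancer_expr <- get_rho("imbalance", "cancer_expression")
    summary$coph_imbalance_vs_drivers <- get_rho("imbalance", "driver_imbalance")
  })

  ## ---- methylation ----
  stage("methylation", {
    if (!is.null(inputs$meth)) {
      ann <- filter_snp_proximal_probes(inputs$meth$annotation)
      merged <- merge_beta_datasets(list(list(
        betas = inputs$meth$betas[ann$probe_id, , drop = FALSE],
        metadata = inputs$meth$metadata)))
      probe_map <- inputs$meth$probe_map[ann$probe_id]
      tissue_meth <- mean_arm_methylation(merged, probe_map, level = "tissue")
      files <- c(files, write_tsv_out(tissue_meth,
                                      file.path(out_dir, "arm_methylation.tsv"), "tissue"))
      shared <- intersect(rownames(tissue_meth), rownames(scores$normal_group))
      if (length(shared) >= 2) {
        prof <- correlation_profiles(tissue_meth[shared, , drop = FALSE],
                                     scores$normal_group[shared, , drop = FALSE])
        summary$meth_expr_median_tissue_rho <- stats::median(prof$by_group$rho,
                                                             na.rm = TRUE)
        summary$meth_expr_negative_fraction <- mean(prof$by_group$rho < 0,
                                                    na.rm = TRUE)
      }
    }
  })

  ## ---- manifest + summary ----
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, summary_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(summary = summary, manifest = manifest, out_dir = out_dir)
}
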