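#' Configuration for the synthetic cohort generator
#'
#' Collects and validates the parameters of the generative model used for
#' end-to-end validation of the pipeline. For tissue t and arm a the model
#' draws a per-tissue, per-arm log-expression baseline b[t,a] ~ N(0, tau^2);
#' each cancer sample gains an arm with probability plogis(alpha + beta*b)
#' and loses it with probability plogis(alpha - beta*b) (renormalized to sum
#' at most 1), so arms highly expressed in a tissue tend to be gained and
#' lowly expressed arms lost. Expression of a gene g on arm a in sample s is
#' RPKM = exp(mu_g + b[t,a] + dosage * call[s,a] + eps), eps ~ N(0, noise_sd^2),
#' with gene baselines mu_g ~ N(log 10, 1) shared across tissues; normal
#' samples carry no calls. Arm-level methylation is anti-coupled to the same
#' baselines (see [gen_methylation()]) and driver genes are placed
#' preferentially on frequently lost (tumor suppressors) or gained
#' (oncogenes) arms (see [gen_driver_table()]).
#'
#' @param n_tissues Number of tissues.
#' @param samples_per_tissue Cancer (and, equally, normal) samples per tissue.
#' @param genes_per_arm Genes simulated on each of the 39 arms.
#' @param tissue_arm_sd Standard deviation tau of the per-tissue per-arm
#'   log-expression baseline b.
#' @param coupling Slope beta linking the baseline to gain/loss log-odds.
#' @param base_logodds Intercept alpha of the gain/loss log-odds.
#' @param dosage Log-scale expression shift per unit arm call (lambda);
#'   the default log(1.5) corresponds to a 3:2 copy ratio for a single-copy
#'   gain on a diploid background.
#' @param noise_sd Residual sd sigma of log expression.
#' @param meth_slope,meth_intercept Parameters gamma1 (>= 0) and gamma0 of the
#'   arm-level methylation mean m = plogis(gamma0 - gamma1 * b).
#' @param beta_concentration Beta-distribution concentration kappa of probe
#'   betas around the arm mean.
#' @param driver_fidelity Probability phi in [0,1] that a driver gene is
#'   placed according to the tissue's gain/loss profile rather than uniformly.
#' @param n_drivers_per_tissue Driver genes generated per tissue.
#' @param probes_per_arm Methylation probes per arm.
#' @param meth_samples_per_tissue Normal methylation samples per tissue.
#' @param snp_probe_fraction Fraction of probes annotated as lying within
#'   15 bp of a SNP.
#' @param seed Integer RNG seed; all generators derive their streams from it
#'   (R's default Mersenne-Twister).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tissues = 8L,
                          samples_per_tissue = 60L,
                          genes_per_arm = 20L,
                          tissue_arm_sd = 0.5,
                          coupling = 2,
                          base_logodds = -1.5,
                          dosage = log(1.5),
                          noise_sd = 0.5,
                          meth_slope = 2,
                          meth_intercept = 0,
                          beta_concentration = 50,
                          driver_fidelity = 0.8,
                          n_drivers_per_tissue = 40L,
                          probes_per_arm = 15L,
                          meth_samples_per_tissue = 10L,
                          snp_probe_fraction = 0.1,
                          seed = 1L) {
  cfg <- list(n_tissues = as.integer(n_tissues),
              samples_per_tissue = as.integer(samples_per_tissue),
              genes_per_arm = as.integer(genes_per_arm),
              tissue_arm_sd = tissue_arm_sd,
              coupling = coupling,
              base_logodds = base_logodds,
              dosage = dosage,
              noise_sd = noise_sd,
              meth_slope = meth_slope,
              meth_intercept = meth_intercept,
              beta_concentration = beta_concentration,
              driver_fidelity = driver_fidelity,
              n_drivers_per_tissue = as.integer(n_drivers_per_tissue),
              probes_per_arm = as.integer(probes_per_arm),
              meth_samples_per_tissue = as.integer(meth_samples_per_tissue),
              snp_probe_fraction = snp_probe_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_tissues >= 1, cfg$samples_per_tissue >= 1,
            cfg$genes_per_arm >= 1, cfg$probes_per_arm >= 1,
            cfg$meth_samples_per_tissue >= 1, cfg$n_drivers_per_tissue >= 1)
  if (cfg$tissue_arm_sd <= 0 || cfg$noise_sd <= 0) {
    stop("standard deviations must be positive")
  }
  if (cfg$beta_concentration <= 0) stop("beta_concentration must be positive")
  if (cfg$driver_fidelity < 0 || cfg$driver_fidelity > 1) {
    stop("driver_fidelity must lie in [0,1]")
  }
  if (cfg$meth_slope < 0) stop("meth_slope must be >= 0")
  if (cfg$snp_probe_fraction < 0 || cfg$snp_probe_fraction > 1) {
    stop("snp_probe_fraction must lie in [0,1]")
  }
  # probabilities derived from (alpha, beta, b) must stay inside (0,1);
  # plogis guarantees this for finite arguments
  if (!is.finite(cfg$base_logodds) || !is.finite(cfg$coupling)) {
    stop("base_logodds and coupling must be finite")
  }
  structure(cfg, class = "cohort_config")
}

# gain/loss probabilities for one baseline value; renormalized so that
# P(gain) + P(loss) <= 1, preserving symmetry under b -> -b
call_probabilities <- function(b, alpha, beta) {
  pg <- stats::plogis(alpha + beta * b)
  pl <- stats::plogis(alpha - beta * b)
  s <- pg + pl
  over <- s > 1
  pg[over] <- pg[over] / s[over]
  pl[over] <- pl[over] / s[over]
  list(gain = pg, loss = pl)
}

#' Generate a synthetic cancer/normal cohort
#'
#' Draws tissue baselines, arm calls and expression matrices under the model
#' described in [cohort_config()]. Cancer samples receive -1/0/+1 arm calls
#' whose gain/loss odds are coupled to the tissue's arm baseline; normal
#' samples are call-free. Identical seeds reproduce the output bit for bit.
#'
#' @param config A [cohort_config()].
#' @return List with elements `calls` ([arm_calls] for the cancer samples),
#'   `cancer_expr` and `normal_expr` ([expression_matrix] objects),
#'   `gene_map` (named vector gene -> arm), `ground_truth` (tissue x arm
#'   matrix of baselines b), and `config`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arms <- included_arms()
  n_arms <- length(arms)
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))

  b <- matrix(stats::rnorm(config$n_tissues * n_arms, 0, config$tissue_arm_sd),
              nrow = config$n_tissues,
              dimnames = list(tissues, arms))

  gene_arm <- rep(arms, each = config$genes_per_arm)
  gene_ids <- paste0("g_", gene_arm, "_", seq_len(config$genes_per_arm))
  mu <- stats::rnorm(length(gene_ids), log(10), 1)
  names(mu) <- gene_ids
  gene_map <- stats::setNames(gene_arm, gene_ids)

  n_cancer <- config$n_tissues * config$samples_per_tissue
  sample_tissue <- rep(tissues, each = config$samples_per_tissue)
  cancer_ids <- sprintf("%s_c%03d", sample_tissue,
                        rep(seq_len(config$samples_per_tissue), config$n_tissues))

  # per sample-arm call: draw U and compare against stacked (loss, gain) bins
  calls <- matrix(0L, n_cancer, n_arms, dimnames = list(cancer_ids, arms))
  probs <- call_probabilities(b, config$base_logodds, config$coupling)
  pg <- probs$gain
  pl <- probs$loss
  t_idx <- match(sample_tissue, tissues)
  u <- matrix(stats::runif(n_cancer * n_arms), n_cancer, n_arms)
  pg_s <- pg[t_idx, , drop = FALSE]
  pl_s <- pl[t_idx, , drop = FALSE]
  calls[u < pg_s] <- 1L
  calls[u >= pg_s & u < pg_s + pl_s] <- -1L

  stages <- sample(c("Stage 0", "Stage I", "Stage IA", "Stage IB",
                     "Stage II", "Stage III", "Stage IV"),
                   n_cancer, replace = TRUE)
  cancer_meta <- data.frame(sample_id = cancer_ids,
                            tissue = sample_tissue,
                            cancer_type = paste0(sample_tissue, "_cancer"),
                            stage = stages,
                            stringsAsFactors = FALSE)
  call_obj <- arm_calls(calls, cancer_meta)

  arm_idx <- match(gene_map, arms)
  # shift per sample and arm: tissue baseline plus dosage effect of the call
  shift_cancer <- b[t_idx, , drop = FALSE] + config$dosage * calls
  expr_cancer <- exp(matrix(mu, length(mu), n_cancer) +
                     t(shift_cancer[, arm_idx, drop = FALSE]) +
                     matrix(stats::rnorm(length(mu) * n_cancer, 0, config$noise_sd),
                            length(mu), n_cancer))
  dimnames(expr_cancer) <- list(gene_ids, cancer_ids)
  cancer_expr <- expression_matrix(expr_cancer, cancer_meta)

  normal_ids <- sprintf("%s_n%03d", sample_tissue,
                        rep(seq_len(config$samples_per_tissue), config$n_tissues))
  shift_normal <- b[t_idx, , drop = FALSE]
  expr_normal <- exp(matrix(mu, length(mu), n_cancer) +
                     t(shift_normal[, arm_idx, drop = FALSE]) +
                     matrix(stats::rnorm(length(mu) * n_cancer, 0, config$noise_sd),
                            length(mu), n_cancer))
  dimnames(expr_normal) <- list(gene_ids, normal_ids)
  normal_meta <- data.frame(sample_id = normal_ids,
                            tissue = sample_tissue,
                            stringsAsFactors = FALSE)
  normal_expr <- expression_matrix(expr_normal, normal_meta)

  list(calls = call_obj,
       cancer_expr = cancer_expr,
       normal_expr = normal_expr,
       gene_map = gene_map,
       ground_truth = b,
       config = config)
}

#' Generate synthetic arm-level methylation data
#'
#' Arm-level mean beta for tissue t and arm a is
#' m = plogis(gamma0 - gamma1 * b[t,a]), anti-coupled to the expression
#' baseline; individual probe betas are drawn from
#' Beta(m * kappa, (1 - m) * kappa). Probe coordinates are placed on the
#' synthetic cytoband genome so that coordinate-based arm assignment
#' recovers the generating arm; a configurable fraction of probes is
#' annotated as SNP-proximal (snp_distance <= 15 bp). Uses its own seed
#' stream (`config$seed + 1`) so it is reproducible independently of
#' [gen_cohort()].
#'
#' @param config A [cohort_config()].
#' @param ground_truth Tissue x arm baseline matrix b from [gen_cohort()].
#' @return List with `betas` (probes x samples), `annotation`
#'   (`probe_annotation`), `metadata` (sample_id, tissue, dataset_id,
#'   is_control), and `probe_map` (probe -> arm).
#' @export
gen_methylation <- function(config, ground_truth) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$beta_concentration <= 0) stop("beta_concentration must be positive")
  arms <- included_arms()
  if (is.null(dim(ground_truth)) || ncol(ground_truth) != length(arms)) {
    stop("ground_truth must be a tissue x 39 arm matrix")
  }
  set.seed(config$seed + 1L)
  tissues <- rownames(ground_truth)
  n_arms <- length(arms)
  kappa <- config$beta_concentration
  m <- stats::plogis(config$meth_intercept - config$meth_slope * ground_truth)

  probe_arm <- rep(arms, each = config$probes_per_arm)
  probe_ids <- paste0("cg_", probe_arm, "_", seq_len(config$probes_per_arm))
  n_probes <- length(probe_ids)

  n_samp <- length(tissues) * config$meth_samples_per_tissue
  sample_tissue <- rep(tissues, each = config$meth_samples_per_tissue)
  sample_ids <- sprintf("%s_m%03d", sample_tissue,
                        rep(seq_len(config$meth_samples_per_tissue), length(tissues)))
  t_idx <- match(sample_tissue, tissues)
  a_idx <- match(probe_arm, arms)
  mm <- m[t_idx, , drop = FALSE][, a_idx, drop = FALSE] # samples x probes
  mp <- t(mm) # probes x samples arm-level means
  betas <- matrix(stats::rbeta(length(mp), mp * kappa, (1 - mp) * kappa),
                  n_probes, n_samp)
  dimnames(betas) <- list(probe_ids, sample_ids)

  # coordinates inside the generating arm of the synthetic genome
  cyto <- synthetic_cytobands()
  bnd <- centromere_boundaries(cyto)
  chrom_len <- tapply(cyto$end, normalize_chrom(cyto$chrom), max)
  arm_chr <- as.integer(sub("[pq]$", "", probe_arm))
  is_p <- grepl("p$", probe_arm)
  lo <- ifelse(is_p, 1, bnd[as.character(arm_chr)])
  hi <- ifelse(is_p, bnd[as.character(arm_chr)] - 1, chrom_len[as.character(arm_chr)])
  pos <- floor(lo + stats::runif(n_probes) * (hi - lo))
  snp_near <- stats::runif(n_probes) < config$snp_probe_fraction
  snp_distance <- ifelse(snp_near, sample(0:15, n_probes, replace = TRUE),
                         sample(16:5000, n_probes, replace = TRUE))
  annotation <- probe_annotation(data.frame(
    probe_id = probe_ids,
    chrom = paste0("chr", arm_chr),
    position = pos,
    probe_type = sample(c("I", "II"), n_probes, replace = TRUE, prob = c(0.3, 0.7)),
    snp_distance = snp_distance,
    stringsAsFactors = FALSE))

  metadata <- data.frame(sample_id = sample_ids,
                         tissue = sample_tissue,
                         dataset_id = paste0("synthetic_", sample_tissue),
                         is_control = TRUE,
                         stringsAsFactors = FALSE)
  list(betas = betas,
       annotation = annotation,
       metadata = metadata,
       probe_map = stats::setNames(probe_arm, probe_ids))
}

#' Generate a synthetic driver-gene table
#'
#' For each tissue, driver genes are drawn with a 50/50 oncogene /
#' tumor-suppressor split. With probability `driver_fidelity` a tumor
#' suppressor is placed on an arm sampled proportionally to that tissue's
#' loss frequency (an oncogene proportionally to its gain frequency);
#' otherwise the arm is uniform over the 39 arms. Uses seed stream
#' `config$seed + 2`.
#'
#' @param config A [cohort_config()].
#' @param profile An [imbalance_profile] (per tissue) providing `gain_freq`
#'   and `loss_freq`.
#' @return A [driver_table()] with columns gene_id, tissue, role, arm_id.
#' @export
gen_driver_table <- function(config, profile) {
  stopifnot(inherits(config, "cohort_config"))
  if (!inherits(profile, "imbalance_profile") || nrow(profile$score) == 0) {
    stop("profile must be a non-empty imbalance_profile")
  }
  set.seed(config$seed + 2L)
  arms <- colnames(profile$score)
  tissues <- rownames(profile$score)
  rows <- lapply(tissues, function(t) {
    n <- config$n_drivers_per_tissue
    role <- sample(c("oncogene", "tumor_suppressor"), n, replace = TRUE)
    faithful <- stats::runif(n) < config$driver_fidelity
    arm <- character(n)
    for (i in seq_len(n)) {
      w <- if (role[i] == "oncogene") profile$gain_freq[t, ] else profile$loss_freq[t, ]
      if (faithful[i] && sum(w) > 0) {
        arm[i] <- sample(arms, 1, prob = w / sum(w))
      } else {
        arm[i] <- sample(arms, 1)
      }
    }
    data.frame(gene_id = sprintf("drv_%s_%03d", t, seq_len(n)),
               tissue = t, role = role, arm_id = arm,
               stringsAsFactors = FALSE)
  })
  driver_table(do.call(rbind, rows))
}
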