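# Shared fixture builders. Everything is generated in code; no data files.

ARMS <- included_arms()

# calls matrix with all zeros except explicitly set columns
make_calls_matrix <- function(n, set = list()) {
  m <- matrix(0L, n, length(ARMS),
              dimnames = list(sprintf("s%02d", seq_len(n)), ARMS))
  for (arm in names(set)) m[, arm] <- as.integer(set[[arm]])
  m
}

make_arm_calls <- function(n, set = list(), tissue = "tissueA", stage = NULL) {
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     tissue = rep_len(tissue, n),
                     stringsAsFactors = FALSE)
  if (!is.null(stage)) meta$stage <- rep_len(stage, n)
  arm_calls(make_calls_matrix(n, set), meta)
}

# random -1/0/+1 call object over several groups
random_arm_calls <- function(n, n_groups = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c(-1L, 0L, 1L), n * length(ARMS), replace = TRUE,
                     prob = c(0.2, 0.6, 0.2)),
              n, length(ARMS),
              dimnames = list(sprintf("s%03d", seq_len(n)), ARMS))
  meta <- data.frame(sample_id = rownames(m),
                     tissue = rep_len(sprintf("g%d", seq_len(n_groups)), n),
                     stringsAsFactors = FALSE)
  arm_calls(m, meta)
}

# independent brute-force imbalance oracle: explicit loops, no shared code
brute_imbalance <- function(calls_matrix, groups) {
  out <- list()
  for (g in sort(unique(groups))) {
    rows <- which(groups == g)
    score <- numeric(ncol(calls_matrix))
    for (j in seq_len(ncol(calls_matrix))) {
      n_gain <- 0
      n_loss <- 0
      for (i in rows) {
        if (calls_matrix[i, j] == 1) n_gain <- n_gain + 1
        if (calls_matrix[i, j] == -1) n_loss <- n_loss + 1
      }
      score[j] <- (n_gain - n_loss) / length(rows)
    }
    out[[g]] <- score
  }
  do.call(rbind, out)
}

# independent empirical-quantile oracle on plotting positions (i-0.5)/m
# using findInterval, a different code path from the implementation's approx()
brute_ref_quantiles <- function(reference, probs) {
  s <- sort(reference)
  m <- length(s)
  pp <- (seq_len(m) - 0.5) / m
  vapply(probs, function(p) {
    if (p <= pp[1]) return(s[1])
    if (p >= pp[m]) return(s[m])
    i <- findInterval(p, pp)
    w <- (p - pp[i]) / (pp[i + 1] - pp[i])
    (1 - w) * s[i] + w * s[i + 1]
  }, numeric(1))
}

# small cohort used across classifier/correlation tests
small_cohort <- function(seed = 11, n_tissues = 4, samples_per_tissue = 12) {
  gen_cohort(cohort_config(n_tissues = n_tissues,
                           samples_per_tissue = samples_per_tissue,
                           seed = seed))
}

tissue_labels <- function(expr) {
  stats::setNames(expr$metadata$tissue, expr$metadata$sample_id)
}

# exhaustive triple check of the ultrametric inequality
is_ultrametric <- function(cm, tol = 1e-8) {
  n <- nrow(cm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (cm[i, k] > max(cm[i, j], cm[j, k]) + tol) return(FALSE)
      }
    }
  }
  TRUE
}
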