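test_that("invalid configurations are rejected before any sampling", {
  expect_error(cohort_config(tissue_arm_sd = 0), "positive")
  expect_error(cohort_config(noise_sd = -1), "positive")
  expect_error(cohort_config(driver_fidelity = 1.5), "driver_fidelity")
  expect_error(cohort_config(beta_concentration = 0), "beta_concentration")
})

test_that("identical seeds reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_tissues = 3, samples_per_tissue = 5, seed = 123)
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a$calls$calls, b$calls$calls)
  expect_identical(a$cancer_expr$values, b$cancer_expr$values)
  expect_identical(a$ground_truth, b$ground_truth)
  m1 <- gen_methylation(cfg, a$ground_truth)
  m2 <- gen_methylation(cfg, a$ground_truth)
  expect_identical(m1$betas, m2$betas)
})

test_that("gain frequencies honor the renormalized logistic probabilities", {
  cfg <- cohort_config(n_tissues = 1, samples_per_tissue = 2000,
                       genes_per_arm = 1, seed = 5)
  co <- gen_cohort(cfg)
  b <- co$ground_truth[1, ]
  pg <- stats::plogis(cfg$base_logodds + cfg$coupling * b)
  pl <- stats::plogis(cfg$base_logodds - cfg$coupling * b)
  s <- pmax(pg + pl, 1)
  pg <- pg / s
  emp <- colMeans(co$calls$calls == 1L)
  sd3 <- 3 * sqrt(pg * (1 - pg) / 2000)
  expect_true(all(abs(emp - pg) <= sd3 + 1e-12))
})

test_that("log-expression residuals have the configured spread", {
  cfg <- cohort_config(n_tissues = 1, samples_per_tissue = 20,
                       genes_per_arm = 15, noise_sd = 0.5, seed = 9)
  co <- gen_cohort(cfg)
  expect_true(all(co$normal_expr$values > 0))
  # within one tissue, normal log expression varies around mu + b with sd sigma
  sds <- apply(log(co$normal_expr$values), 1, stats::sd)
  pooled <- sqrt(mean(sds^2)) # 585 genes x 20 samples > 10,000 draws
  expect_lt(abs(pooled - cfg$noise_sd) / cfg$noise_sd, 0.05)
})

test_that("uncoupled cohorts show no expression-imbalance correlation", {
  rhos <- vapply(1:10, function(seed) {
    cfg <- cohort_config(n_tissues = 6, samples_per_tissue = 20,
                         genes_per_arm = 5, coupling = 0, dosage = 0,
                         seed = seed)
    co <- gen_cohort(cfg)
    prof <- arm_imbalance_score(co$calls, "tissue")
    nm <- mean_arm_expression(co$normal_expr, co$gene_map, "group")
    pr <- correlation_profiles(nm, prof$score)
    mean(pr$by_group$rho, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("coupled cohorts plant predominantly positive arm-wise correlations", {
  frac_pos <- vapply(1:5, function(seed) {
    co <- gen_cohort(cohort_config(seed = seed)) # beta = 2, tau = 0.5, 8 x 60
    prof <- arm_imbalance_score(co$calls, "tissue")
    nm <- mean_arm_expression(co$normal_expr, co$gene_map, "group")
    pr <- correlation_profiles(nm, prof$score)
    mean(pr$by_arm$rho > 0, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(frac_pos > 0.8))
})

test_that("methylation is anti-coupled to expression baselines when planted", {
  cfg <- cohort_config(n_tissues = 6, samples_per_tissue = 10,
                       meth_slope = 2, seed = 31)
  co <- gen_cohort(cfg)
  meth <- gen_methylation(cfg, co$ground_truth)
  merged <- merge_beta_datasets(list(list(betas = meth$betas,
                                          metadata = meth$metadata)))
  tm <- mean_arm_methylation(merged, meth$probe_map, "tissue")
  nm <- mean_arm_expression(co$normal_expr, co$gene_map, "group")
  pr <- correlation_profiles(tm, nm)
  expect_true(all(pr$by_group$rho < 0))

  # gamma1 = 0 removes the coupling
  cfg0 <- cohort_config(n_tissues = 6, samples_per_tissue = 10,
                        meth_slope = 0, seed = 31)
  m0 <- gen_methylation(cfg0, co$ground_truth)
  tm0 <- mean_arm_methylation(merge_beta_datasets(list(list(
    betas = m0$betas, metadata = m0$metadata))), m0$probe_map, "tissue")
  pr0 <- correlation_profiles(tm0, nm)
  expect_lt(abs(mean(pr0$by_group$rho)), 0.35)
})

test_that("large beta concentration collapses probe betas onto the arm mean", {
  cfg <- cohort_config(n_tissues = 2, samples_per_tissue = 5,
                       beta_concentration = 1e5, seed = 2)
  co <- gen_cohort(cfg)
  meth <- gen_methylation(cfg, co$ground_truth)
  m <- stats::plogis(cfg$meth_intercept - cfg$meth_slope * co$ground_truth)
  # probes of the first arm, first tissue's samples
  probes <- names(meth$probe_map)[meth$probe_map == "1p"]
  samp <- meth$metadata$sample_id[meth$metadata$tissue == "tissue01"]
  expect_lt(stats::sd(meth$betas[probes, samp]), 0.02)
  expect_lt(abs(mean(meth$betas[probes, samp]) - m["tissue01", "1p"]), 0.02)
})

test_that("driver placement follows the gain/loss profile at high fidelity", {
  # phi = 1 with a single frequently lost arm puts every TS on that arm
  score <- matrix(0, 1, 39, dimnames = list("t1", ARMS))
  gain <- loss <- score
  loss[, "17p"] <- 0.9
  prof <- structure(list(score = gain - loss, gain_freq = gain,
                         loss_freq = loss, n_samples = c(t1 = 10)),
                    class = "imbalance_profile")
  cfg <- cohort_config(n_tissues = 1, samples_per_tissue = 5,
                       driver_fidelity = 1, seed = 77)
  dt <- gen_driver_table(cfg, prof)
  ts <- dt[dt$role == "tumor_suppressor", ]
  expect_true(all(ts$arm_id == "17p"))

  # phi = 0.8: loss frequency and TS fraction correlate positively
  hits <- vapply(1:5, function(seed) {
    cfg <- cohort_config(n_tissues = 6, samples_per_tissue = 40,
                         n_drivers_per_tissue = 60, seed = seed)
    co <- gen_cohort(cfg)
    prof <- arm_imbalance_score(co$calls, "tissue")
    dt <- gen_driver_table(cfg, prof)
    di <- onco_ts_imbalance(dt)
    pr <- correlation_profiles(di$frac_ts, prof$loss_freq)
    all(pr$by_group$rho > 0)
  }, logical(1))
  expect_true(mean(hits) > 0.9)
})

test_that("the empty imbalance profile is rejected", {
  cfg <- cohort_config(seed = 1)
  empty <- structure(list(score = matrix(0, 0, 39), gain_freq = NULL,
                          loss_freq = NULL), class = "imbalance_profile")
  expect_error(gen_driver_table(cfg, empty), "non-empty")
})
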