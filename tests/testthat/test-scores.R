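test_that("arm imbalance score is the gain-minus-loss frequency", {
  ac <- make_arm_calls(4, set = list(`1p` = c(1, 1, -1, 0)))
  prof <- arm_imbalance_score(ac, "tissue")
  expect_equal(unname(prof$score[, "1p"]), 0.25)
  expect_equal(unname(prof$gain_freq[, "1p"]), 0.5)
  expect_equal(unname(prof$loss_freq[, "1p"]), 0.25)
  expect_true(all(prof$score[, setdiff(ARMS, "1p")] == 0))
})

test_that("a zero-call cell loaded from an NA entry counts as non-aneuploid", {
  df <- data.frame(sample_id = sprintf("s%d", 1:4), tissue = "t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (a in ARMS) df[[a]] <- "0"
  df[["2q"]] <- c("1", "NA", "-1", "1")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- arm_imbalance_score(read_arm_calls(path), "tissue")
  expect_equal(unname(prof$score[, "2q"]), 0.25)
})

test_that("imbalance scores match a brute-force count and are antisymmetric", {
  for (seed in 1:5) {
    ac <- random_arm_calls(30, n_groups = 3, seed = seed)
    prof <- arm_imbalance_score(ac, "tissue")
    oracle <- brute_imbalance(ac$calls, ac$metadata$tissue)
    expect_equal(unname(prof$score), unname(oracle))
    # negating every call negates every score exactly
    neg <- arm_calls(-ac$calls, ac$metadata)
    expect_equal(arm_imbalance_score(neg, "tissue")$score, -prof$score)
    expect_true(all(abs(prof$score) <= 1))
    expect_true(all(prof$gain_freq + prof$loss_freq <= 1))
  }
})

test_that("a singleton group's score equals the sample's calls", {
  set.seed(42)
  m <- make_calls_matrix(1)
  m[1, ] <- sample(c(-1L, 0L, 1L), length(ARMS), replace = TRUE)
  ac <- arm_calls(m, data.frame(sample_id = "s01", tissue = "solo"))
  prof <- arm_imbalance_score(ac, "tissue")
  expect_equal(unname(prof$score["solo", ]), as.numeric(m[1, ]))
})

test_that("empty groups are rejected by name", {
  ac <- make_arm_calls(3)
  grouping <- stats::setNames(c("a", "a", NA), ac$metadata$sample_id)
  expect_error(arm_imbalance_score(ac, grouping), "group")
})

test_that("mean arm expression averages assigned genes and is order-invariant", {
  vals <- matrix(10, 2 * length(ARMS), 3)
  gene_ids <- paste0("g", seq_len(nrow(vals)))
  rownames(vals) <- gene_ids
  colnames(vals) <- c("s1", "s2", "s3")
  map <- stats::setNames(rep(ARMS, each = 2), gene_ids)
  vals[map == "5q", 1] <- c(4, 6)
  expr <- expression_matrix(vals, data.frame(sample_id = colnames(vals),
                                             tissue = "t"))
  feat <- mean_arm_expression(expr, map, level = "sample")
  expect_equal(unname(feat["s1", "5q"]), 5.0)
  expect_equal(dim(feat), c(3, 39))

  perm <- sample(gene_ids)
  expr2 <- expression_matrix(vals[perm, ], expr$metadata)
  expect_equal(mean_arm_expression(expr2, map, level = "sample"), feat)
})

test_that("per-group arm expression equals the mean of per-sample features", {
  co <- small_cohort(seed = 7, n_tissues = 2, samples_per_tissue = 2)
  per_sample <- mean_arm_expression(co$normal_expr, co$gene_map, "sample")
  per_group <- mean_arm_expression(co$normal_expr, co$gene_map, "group",
                                   grouping = "tissue")
  for (t in rownames(per_group)) {
    idx <- co$normal_expr$metadata$sample_id[co$normal_expr$metadata$tissue == t]
    expect_equal(unname(per_group[t, ]), unname(colMeans(per_sample[idx, ])))
  }
})

test_that("arms without assigned genes are an error listing the arm", {
  co <- small_cohort(seed = 7, n_tissues = 2, samples_per_tissue = 2)
  map <- co$gene_map
  map[map == "8q"] <- "unassigned"
  expect_error(mean_arm_expression(co$normal_expr, map, "sample"), "8q")
})

test_that("oncogene/tumor-suppressor imbalance follows the fraction difference", {
  dt <- driver_table(data.frame(
    gene_id = paste0("g", 1:4), tissue = "t",
    role = c("oncogene", "oncogene", "tumor_suppressor", "tumor_suppressor"),
    arm_id = c("1q", "1q", "1q", "9p"), stringsAsFactors = FALSE))
  di <- onco_ts_imbalance(dt)
  expect_equal(unname(di$score["t", "1q"]), 2 / 3 - 1 / 3)
  expect_equal(unname(di$score["t", "9p"]), -1)
  expect_true(is.na(di$score["t", "5p"])) # no drivers -> undefined, not 0
  defined <- !is.na(di$score)
  expect_true(all(abs(di$score[defined]) <= 1))
  expect_equal(di$score[defined], 2 * di$frac_onco[defined] - 1)
})

test_that("an empty driver table yields an all-undefined row with a warning", {
  dt <- driver_table(data.frame(gene_id = character(), tissue = character(),
                                role = character(), arm_id = character(),
                                stringsAsFactors = FALSE))
  expect_warning(di <- onco_ts_imbalance(dt), "empty")
  expect_true(all(is.na(di$score)))
})

test_that("quantile normalization maps ranks onto reference quantiles", {
  expect_equal(quantile_normalize_to_reference(c(10, 20, 30), c(-1, 0, 1)),
               c(-1, 0, 1))
  # reference == values is the identity up to ties
  v <- c(3, 1, 4, 1.5, 9)
  expect_equal(quantile_normalize_to_reference(v, v), v)
  # ties share the quantile of their average rank
  out <- quantile_normalize_to_reference(c(2, 2, 5), c(0, 10, 20))
  expect_equal(out[1], out[2])
})

test_that("quantile normalization matches the brute-force quantile oracle", {
  set.seed(99)
  for (rep in 1:20) {
    v <- stats::rnorm(5)
    ref <- stats::rnorm(39)
    out <- quantile_normalize_to_reference(v, ref)
    expected <- brute_ref_quantiles(ref, (rank(v) - 0.5) / 5)
    expect_equal(sort(out), sort(expected))
    # monotone: rank order preserved
    expect_equal(order(out), order(v))
  }
  expect_error(quantile_normalize_to_reference(1:5, 3), "reference")
})

test_that("NA values pass through quantile normalization untouched", {
  out <- quantile_normalize_to_reference(c(1, NA, 3), c(0, 1, 2, 3))
  expect_true(is.na(out[2]))
  expect_false(anyNA(out[c(1, 3)]))
})
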