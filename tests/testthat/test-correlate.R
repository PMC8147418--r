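test_that("spearman_rho handles monotone, tied and degenerate inputs", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))$rho))
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))$rho))

  # tied case against the average-rank Pearson formula written out by hand
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  rx <- rank(x)
  ry <- rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- spearman_rho(x, y)
  expect_equal(r$rho, manual)
  # and against the standard library estimate
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate))
  expect_equal(r$p, ct$p.value, tolerance = 1e-10)
})

test_that("spearman_rho is invariant under strictly increasing transforms", {
  set.seed(3)
  for (i in 1:10) {
    x <- stats::rnorm(15)
    y <- stats::rnorm(15)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, base)
    expect_equal(spearman_rho(x, y^3 + 5 * y)$rho, base)
  }
})

test_that("correlation profiles recover perfect agreement and disagreement", {
  set.seed(8)
  A <- matrix(stats::rnorm(10 * 39), 10, 39,
              dimnames = list(paste0("g", 1:10), ARMS))
  pr <- correlation_profiles(A, A)
  expect_equal(pr$by_arm$rho, rep(1, 39))
  expect_equal(pr$by_group$rho, rep(1, 10))
  pr_neg <- correlation_profiles(A, -A)
  expect_equal(pr_neg$by_arm$rho, rep(-1, 39))
  expect_equal(pr_neg$by_group$rho, rep(-1, 10))
})

test_that("correlation profiles match per-row/per-column recomputation", {
  set.seed(21)
  A <- matrix(stats::rnorm(8 * 39), 8, 39,
              dimnames = list(paste0("g", 1:8), ARMS))
  B <- matrix(stats::rnorm(8 * 39), 8, 39, dimnames = dimnames(A))
  pr <- correlation_profiles(A, B)
  for (j in sample(39, 5)) {
    expect_equal(pr$by_arm$rho[j], spearman_rho(A[, j], B[, j])$rho)
  }
  for (i in seq_len(8)) {
    expect_equal(pr$by_group$rho[i], spearman_rho(A[i, ], B[i, ])$rho)
  }
  expect_true(mean(abs(pr$by_arm$rho)) < 0.5)
})

test_that("misaligned profiles are aligned by shared labels", {
  A <- matrix(stats::rnorm(4 * 39), 4, 39,
              dimnames = list(paste0("g", 1:4), ARMS))
  B <- A[c(2, 3, 4, 1), ]
  rownames(B) <- paste0("g", c(2, 3, 4, 1))
  pr <- correlation_profiles(A, B)
  expect_true(all(pr$by_group$rho == 1))
  B2 <- rbind(B, other = stats::rnorm(39))
  expect_warning(correlation_profiles(A, B2), "unmatched")
  expect_error(correlation_profiles(A, matrix(1, 2, 39,
    dimnames = list(c("x", "y"), ARMS))), "no shared groups")
})

test_that("identical matrices give permutation p = 0 and reproducible nulls", {
  set.seed(13)
  A <- matrix(stats::rnorm(6 * 39), 6, 39,
              dimnames = list(paste0("g", 1:6), ARMS))
  r1 <- permutation_positive_count_test(A, A, "by_arm", n_perm = 200, seed = 4)
  expect_equal(r1$observed, 39)
  expect_equal(r1$p, 0) # no null count can strictly exceed the maximum
  r2 <- permutation_positive_count_test(A, A, "by_arm", n_perm = 200, seed = 4)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p, r2$p)
})

test_that("the fast path agrees with explicit per-correlation counting", {
  set.seed(17)
  A <- matrix(stats::rnorm(7 * 39), 7, 39,
              dimnames = list(paste0("g", 1:7), ARMS))
  B <- matrix(stats::rnorm(7 * 39), 7, 39, dimnames = dimnames(A))
  for (axis in c("by_arm", "by_group")) {
    r <- permutation_positive_count_test(A, B, axis, n_perm = 5, seed = 1)
    pr <- correlation_profiles(A, B)
    rho <- if (axis == "by_arm") pr$by_arm$rho else pr$by_group$rho
    expect_equal(r$observed, sum(rho > 0, na.rm = TRUE))
  }
})

test_that("undefined correlations count as non-positive", {
  A <- matrix(stats::rnorm(6 * 39), 6, 39,
              dimnames = list(paste0("g", 1:6), ARMS))
  B <- A
  B[, "3q"] <- 1 # constant column: rho undefined for 3q
  r <- permutation_positive_count_test(A, B, "by_arm", n_perm = 10, seed = 2)
  expect_equal(r$observed, 38)
})

test_that("permutation p is invariant to joint relabeling of the groups", {
  set.seed(31)
  A <- matrix(stats::rnorm(6 * 39), 6, 39,
              dimnames = list(paste0("g", 1:6), ARMS))
  B <- A + matrix(stats::rnorm(6 * 39), 6, 39)
  dimnames(B) <- dimnames(A)
  r1 <- permutation_positive_count_test(A, B, "by_group", n_perm = 100, seed = 9)
  relabel <- paste0("h", 1:6)
  A2 <- A
  B2 <- B
  rownames(A2) <- relabel
  rownames(B2) <- relabel
  r2 <- permutation_positive_count_test(A2, B2, "by_group", n_perm = 100, seed = 9)
  expect_identical(r1$observed, r2$observed)
  expect_identical(r1$p, r2$p)
})

test_that("the add-one empirical p variant is applied on request", {
  A <- matrix(stats::rnorm(5 * 39), 5, 39,
              dimnames = list(paste0("g", 1:5), ARMS))
  r <- permutation_positive_count_test(A, A, "by_arm", n_perm = 50, seed = 1,
                                       add_one = TRUE)
  expect_equal(r$p, (sum(r$null >= r$observed) + 1) / 51)
  expect_error(permutation_positive_count_test(A, A, n_perm = 0), "n_perm")
})

test_that("early-stage filtering keeps AJCC stage 0/I and drops the rest", {
  stages <- c("Stage 0", "Stage I", "Stage IA", "Stage IB", "Stage II",
              "Stage IIA", "Stage III", "Stage IV", NA)
  ac <- make_arm_calls(9, stage = stages)
  filtered <- suppressMessages(filter_early_stage(ac))
  expect_setequal(filtered$metadata$sample_id, sprintf("s%02d", 1:4))
  expect_message(filter_early_stage(ac), "missing stage")
  no_stage <- make_arm_calls(3)
  expect_error(filter_early_stage(no_stage), "stage")
})
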