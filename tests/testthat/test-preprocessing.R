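make_two_group_table <- function(x, y) {
  feature_table(cbind(v = c(x, y)), rep(c(1L, 0L), c(length(x), length(y))))
}

test_that("t-test screen matches the hand-coded Welch formula", {
  # frozen worked example: A = 1..5 vs B = 3..7
  tab <- make_two_group_table(1:5, 3:7)
  rep <- ttest_screen(tab, "v")
  expect_equal(rep$t, -2, tolerance = 1e-12)
  expect_equal(rep$p, 0.0805162380, tolerance = 1e-8)
  expect_false(rep$flagged)

  # identical symmetric samples: t = 0, p = 1
  rep0 <- ttest_screen(make_two_group_table(c(1, 2, 3), c(3, 1, 2)), "v")
  expect_equal(rep0$t, 0)
  expect_equal(rep0$p, 1)

  # extreme separation with tiny jitter is flagged
  repx <- ttest_screen(make_two_group_table(c(0, 0, 0, 0) + 1e-6 * (1:4),
                                            c(1, 1, 1, 1) + 1e-6 * (4:1)),
                       "v")
  expect_lt(repx$p, 0.05)
  expect_true(repx$flagged)

  # agreement with an independent implementation on random samples
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    tab_i <- make_two_group_table(x, y)
    for (ve in c(FALSE, TRUE)) {
      got <- ttest_screen(tab_i, "v", var_equal = ve)
      want <- oracle_ttest(x, y, var_equal = ve)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  }
})

test_that("zero-variance features are reported, not fatal", {
  tab <- make_two_group_table(rep(2, 4), rep(2, 5))
  expect_warning(rep <- ttest_screen(tab, "v"), "zero variance")
  expect_equal(rep$p, 1)
  expect_true(rep$degenerate)
  expect_false(rep$flagged)
})

test_that("block PCA recovers known structure", {
  # 17 perfectly correlated columns: first component carries everything
  base <- rnorm(40)
  X <- outer(base, seq(0.5, 2.5, length.out = 17))
  colnames(X) <- sprintf("B_%02d", 1:17)
  tab <- feature_table(X, rep(c(0, 1), 20))
  m <- fit_block_pca(tab, colnames(X), 2)
  expect_gt(m$eigenvalues[1] / sum(m$eigenvalues), 1 - 1e-8)

  # 2-feature toy: first loading close to (1,1)/sqrt(2), and exactly the
  # closed-form eigenvector of the 2x2 sample covariance
  Y <- cbind(a = c(1, 2, 3, 4) + c(.01, -.01, .01, -.01),
             b = c(1, 2, 3, 4) + c(-.01, .01, -.01, .01))
  tb <- feature_table(Y, c(0, 1, 0, 1))
  m2 <- fit_block_pca(tb, c("a", "b"), 2, scale. = FALSE)
  expect_equal(unname(m2$loadings[, 1]), c(1, 1) / sqrt(2),
               tolerance = 1e-2)
  S <- cov(Y)
  lam1 <- ((S[1, 1] + S[2, 2]) +
             sqrt((S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2)) / 2
  v1 <- c(S[1, 2], lam1 - S[1, 1])
  v1 <- v1 / sqrt(sum(v1^2))
  expect_equal(unname(m2$loadings[, 1]), v1, tolerance = 1e-10)
  expect_equal(m2$eigenvalues[1], lam1, tolerance = 1e-10)
  # sign convention: largest-magnitude element positive
  expect_true(all(apply(m2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))

  # isotropic data: eigenvalues roughly equal
  set.seed(32)
  Z <- matrix(rnorm(4000 * 5), 4000, 5)
  colnames(Z) <- paste0("z", 1:5)
  m3 <- fit_block_pca(feature_table(Z, rep(c(0, 1), 2000)),
                      colnames(Z), 5)
  expect_lt(max(m3$eigenvalues) / min(m3$eigenvalues), 1.3)

  # loading columns orthonormal
  G <- crossprod(m3$loadings)
  expect_equal(G, diag(5), tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(fit_block_pca(tb, c("a", "b"), 3), "exceeds block size")
})

test_that("reconstruction error is non-increasing in component count", {
  tab <- test_cohort(80, seed = 33)
  block <- feature_schema()$ste_blocks$PSS
  X <- scale(tab$features[, block])
  errs <- vapply(1:17, function(k) {
    m <- fit_block_pca(tab, block, k)
    S <- X %*% m$loadings
    sum((X - S %*% t(m$loadings))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("component-count rules follow the fixed counts and the elbow", {
  expect_equal(choose_components(rep(1, 17), "fixed", block = "PSS"), 3L)
  expect_equal(choose_components(rep(1, 17), "fixed", block = "SSR"), 3L)
  expect_equal(choose_components(rep(1, 17), "fixed", block = "TP"), 2L)
  expect_equal(choose_components(c(10, 1, 0.9, 0.8), "elbow"), 1L)
  expect_equal(choose_components(c(10, 8, 1, 0.9), "elbow"), 2L)
  expect_error(choose_components(numeric(0), "elbow"), "empty")
  expect_error(choose_components(c(1, 2), "elbow"), "non-increasing")
})

test_that("reduction replaces blocks and passes through the rest", {
  tab <- test_cohort(100, seed = 34)
  models <- fit_default_pca(tab, seq_len(60))
  red <- apply_reduction(tab, models)
  expect_equal(ncol(red$features), 71 - 51 + (3 + 3 + 2))  # 28
  expect_true(all(c("PSS_PC1", "SSR_PC3", "TP_PC2", "GLPS_MID", "age",
                    "smoke") %in% colnames(red$features)))
  expect_identical(red$features[, "age"], tab$features[, "age"])

  # training-subject scores are centered at zero
  train_scores <- red$features[1:60, c("PSS_PC1", "SSR_PC1", "TP_PC1")]
  expect_lt(max(abs(colMeans(train_scores))), 1e-8)

  # zero components retained for every block: 20 predictors remain
  none <- lapply(models, function(m) {
    m$loadings <- m$loadings[, 0, drop = FALSE]
    m$n_components <- 0L
    m
  })
  expect_equal(ncol(apply_reduction(tab, none)$features), 20)

  # mismatched block errors
  bad <- models[[1]]
  bad$features[1] <- "NOT_A_COLUMN"
  expect_error(apply_reduction(tab, list(bad)), "mismatch")
})

test_that("split plan reproduces the canonical design arithmetic", {
  labels <- rep(c(1L, 0L), c(217, 207))
  plan <- make_split_plan(labels, seed = 5)
  expect_equal(length(plan$test_idx), 64)
  expect_equal(length(plan$validation0_idx), 72)
  expect_equal(length(plan$train_pool_idx), 288)
  expect_equal(length(plan$first_step), 10)
  for (fs in plan$first_step) {
    expect_equal(length(fs$train_idx), 230)
    expect_equal(length(fs$val_idx), 58)
    # each pair partitions the training pool
    expect_setequal(c(fs$train_idx, fs$val_idx), plan$train_pool_idx)
  }
  # determinism
  expect_identical(plan, make_split_plan(labels, seed = 5))
  expect_false(identical(plan$test_idx,
                         make_split_plan(labels, seed = 6)$test_idx))
})

test_that("small stratified splits keep one subject of each class", {
  plan <- make_split_plan(rep(c(1, 0), 5), test_frac = 0.2,
                          first_val_frac = 1 / 3, K = 2, seed = 7)
  lab <- rep(c(1, 0), 5)
  expect_equal(sum(lab[plan$test_idx]), 1)
  expect_equal(sum(1 - lab[plan$test_idx]), 1)
  expect_error(make_split_plan(rep(1, 10)), "both classes")
  expect_error(make_split_plan(c(1, 0, 1, 0), test_frac = 0.05), "stratum")
})

test_that("split parts are disjoint, exhaustive and ratio-preserving", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(60:400, 1)
    n_pos <- sample(seq(round(0.3 * n), round(0.7 * n)), 1)
    labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    K <- sample(1:4, 1)
    plan <- make_split_plan(labels, K = K, seed = i)
    parts <- list(plan$test_idx, plan$validation0_idx, plan$train_pool_idx)
    all_idx <- sort(unlist(parts))
    expect_identical(all_idx, seq_along(labels))     # disjoint + exhaustive
    ratio <- mean(labels)
    for (p in c(parts, unlist(lapply(plan$first_step, unname),
                              recursive = FALSE))) {
      # class count within 1 subject of the stratified target
      expect_lt(abs(sum(labels[p]) - ratio * length(p)), 1 + 1e-9)
    }
  }
})

test_that("split plans survive a JSON round trip", {
  plan <- make_split_plan(rep(c(1L, 0L), c(30, 25)), K = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  split_plan_to_json(plan, path)
  back <- split_plan_from_json(path)
  expect_identical(back$test_idx, plan$test_idx)
  expect_identical(back$first_step, plan$first_step)
  expect_identical(back$sizes, plan$sizes)
})
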