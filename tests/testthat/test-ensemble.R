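test_that("vote rules follow the >= 0.5 indicator semantics", {
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c(0, 0, 0)), 0L)
  expect_equal(majority_vote(c(0, 1, 0, 1)), 1L)  # exact tie is positive
  expect_error(majority_vote(c(0, 2)), "binary")
  expect_error(majority_vote(numeric(0)), "non-empty")

  expect_equal(weighted_vote(c(1, 0), c(0.7, 0.3)), 1L)
  expect_equal(weighted_vote(c(1, 1, 0), c(-0.2, 0.9, 0.3)), 1L)  # sum 0.7
  expect_equal(weighted_vote(c(1, 1), c(0.2, 0.2)), 0L)
  expect_error(weighted_vote(c(1, 0), 1), "equal length")
  expect_error(weighted_vote(c(1, 0), c(Inf, 0)), "finite")
})

test_that("equal weights 1/L reduce weighted voting to majority voting", {
  for (L in c(1, 2, 3, 5, 10)) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), L)))
    for (i in seq_len(nrow(patterns))) {
      v <- patterns[i, ]
      expect_equal(weighted_vote(v, rep(1 / L, L)), majority_vote(v))
    }
  }
})

test_that("stack fitting guards against train/validation leakage", {
  tab <- separable_cohort()
  expect_error(fit_stack(fast_specs(), tab[1:50], tab[40:80],
                         fast_config()),
               "leakage")
})

test_that("an L = 1 stack reproduces its base classifier", {
  tab <- separable_cohort()
  red <- apply_reduction(tab, fit_default_pca(tab, 1:100))
  train <- red[1:100]; val <- red[101:130]; probe <- red[131:150]
  spec <- list_registry()["LDA"]
  st <- fit_stack(spec, train, val, fast_config())
  base <- predict_labels(st$base[[1]], probe)
  pr <- predict(st, probe)
  expect_identical(pr$label, base)
})

test_that("the meta-learner can learn to copy an oracle base classifier", {
  # base roster: always-positive, always-negative, and a real model that is
  # an oracle on separable data; the stack must match the oracle
  tab <- separable_table(120)
  train <- tab[1:60]; val <- tab[61:90]; probe <- tab[91:120]
  spec_const <- function(name, const) {
    sp <- list_registry()[[1]]
    sp$name <- name; sp$id <- paste0("const", const)
    sp
  }
  # constant classifiers built as degenerate fitted objects
  oracle <- fit_classifier(list_registry()[["LDA"]], train, seed = 1)
  always <- function(const) {
    structure(list(spec = structure(list(name = paste0("always", const),
                                         id = "glm_logistic",
                                         grid = data.frame(dummy = 1),
                                         scale = FALSE),
                                    class = "classifier_spec"),
                   fit = list(coef = c(`(Intercept)` = if (const == 1) 50
                                       else -50,
                                       rep(0, ncol(train$features)))),
                   params = list(), features = colnames(train$features),
                   center = NULL, scale = NULL, seed = 1L),
              class = "fitted_classifier")
  }
  base <- list(always(1), always(0), oracle)
  M <- vapply(base, function(m) as.numeric(predict_labels(m, val)),
              numeric(30))
  meta <- echostack:::.fit_meta(M, val$labels, ntree = 200, seed = 4)
  Mp <- vapply(base, function(m) as.numeric(predict_labels(m, probe)),
               numeric(30))
  stack_lab <- as.integer(echostack:::.predict_meta(meta, Mp) >= 0.5)
  expect_identical(stack_lab, predict_labels(oracle, probe))
})

test_that("K = 1 two-step reduces to its single first-step stack", {
  tab <- separable_cohort()
  red <- apply_reduction(tab, fit_default_pca(tab, 1:100))
  plan <- make_split_plan(tab$labels, K = 1, seed = 6)
  cfg <- fast_config(K = 1L)
  model <- fit_two_step(fast_specs(), red, plan, cfg)
  test <- red[plan$test_idx]
  two <- predict_two_step(model, test)
  one <- predict(model$stacks[[1]], test)
  expect_identical(two$label, one$label)
})

test_that("two-step model holds K stacks of L classifiers", {
  tab <- test_cohort(424, seed = 55)
  red <- apply_reduction(tab, fit_default_pca(tab))
  plan <- make_split_plan(tab$labels, K = 10, seed = 2)
  cfg <- fast_config(K = 10L)
  model <- fit_two_step(default_ensemble_specs(), red, plan, cfg)
  expect_length(model$stacks, 10)
  for (s in model$stacks) expect_length(s$base, 14)
  # second-step meta-learner takes a K-dimensional input
  expect_equal(length(model$meta2$forest$ncat), 10)
  pr <- predict_two_step(model, red[plan$test_idx])
  expect_length(pr$label, 64)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  # K mismatch between plan and config is an error
  expect_error(fit_two_step(fast_specs(), red, plan, fast_config(K = 3L)),
               "does not match")
})

test_that("ensembles reach perfect accuracy in the separable limit", {
  tab <- separable_cohort()
  red <- apply_reduction(tab, fit_default_pca(tab, 1:100))
  plan <- make_split_plan(tab$labels, K = 2, seed = 3)
  cfg <- fast_config(K = 2L)
  model <- fit_two_step(fast_specs(), red, plan, cfg)
  pr <- predict_two_step(model, red[plan$test_idx])
  expect_equal(pr$label, tab$labels[plan$test_idx])
})

test_that("unanimous first-step votes force the two-step label", {
  tab <- separable_cohort()
  red <- apply_reduction(tab, fit_default_pca(tab, 1:100))
  plan <- make_split_plan(tab$labels, K = 2, seed = 4)
  model <- fit_two_step(fast_specs(), red, plan, fast_config(K = 2L))
  test <- red[plan$test_idx]
  votes <- vapply(model$stacks, function(s) predict(s, test)$label,
                  integer(length(test$labels)))
  un_pos <- rowSums(votes) == ncol(votes)
  un_neg <- rowSums(votes) == 0
  pr <- predict_two_step(model, test)
  # on separable data the meta-learner is a monotone function of the votes
  expect_true(all(pr$label[un_pos] == 1L))
  expect_true(all(pr$label[un_neg] == 0L))
})

test_that("two-step prediction is equivariant to stack order", {
  tab <- separable_cohort(200, seed = 57)
  red <- apply_reduction(tab, fit_default_pca(tab))
  plan <- make_split_plan(tab$labels, K = 3, seed = 5)
  cfg <- fast_config(K = 3L)
  model <- fit_two_step(fast_specs(), red, plan, cfg)
  test <- red[plan$test_idx]

  perm <- c(3, 1, 2)
  permuted <- model
  permuted$stacks <- model$stacks[perm]
  val0 <- red[plan$validation0_idx]
  M <- vapply(permuted$stacks, function(s)
    as.numeric(predict(s, val0)$label), numeric(length(val0$labels)))
  permuted$meta2 <- echostack:::.fit_meta(M, val0$labels, cfg$meta_ntree,
                                          seed = cfg$seed + 2000L)
  expect_identical(predict_two_step(permuted, test)$label,
                   predict_two_step(model, test)$label)
})
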