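# Shared fixtures, built in code. Cohorts are cached per (n, seed, effect)
# so repeated tests do not regenerate them.

.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function(n = 120, seed = 1, effect = NULL) {
  key <- paste(n, seed, paste(effect, collapse = "_"), sep = "|")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  args <- list(n_subjects = n, seed = seed)
  if (!is.null(effect)) args$class_effect <- effect
  tab <- generate_cohort(do.call(generator_params, args))
  .cohort_cache[[key]] <- tab
  tab
}

# strongly separated two-feature toy problem (linearly separable)
separable_table <- function(n = 60, gap = 6, seed = 3) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  X <- cbind(f1 = rnorm(n) + gap * y, f2 = rnorm(n) - gap * y)
  feature_table(X, y)
}

# a 71-predictor cohort with huge class separation on the strain features,
# for separable-limit checks of the full pipeline
separable_cohort <- function(n = 150, seed = 4) {
  test_cohort(n, seed,
              effect = c(PSS = 4, SSR = 4, TP = 4, GS = 0, GLPS = 5, PSD = 0))
}

# independently coded Welch / pooled t-test oracle (textbook formulas)
oracle_ttest <- function(x, y, var_equal = FALSE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# brute-force AUC oracle: concordance over all positive-negative pairs
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# tiny ensemble configuration for fast unit tests (not the study defaults)
fast_config <- function(...) {
  ensemble_config(meta_ntree = 100L, tune_base = FALSE, ...)
}

# a compact roster of fast, deterministic base learners for plumbing tests
fast_specs <- function() {
  list_registry()[c("logistic regression", "LDA", "naive Bayes")]
}
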