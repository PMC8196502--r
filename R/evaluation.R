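#' Confusion-matrix metrics for a binary screen
#'
#' @param truth binary 0/1 vector of true labels.
#' @param predicted binary 0/1 vector of predictions, same length.
#' @return An object of class `confusion_metrics` with counts `TP`, `FP`,
#'   `TN`, `FN` and `accuracy`, `sensitivity` (NA when no true positives
#'   exist), `specificity` (NA when no true negatives exist).
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) == 0) stop("inputs must be non-empty")
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(all(truth %in% c(0L, 1L)), all(predicted %in% c(0L, 1L)))
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fn <- sum(truth == 1L & predicted == 0L)
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0("<confusion_metrics> acc %.3f | sens %.3f | spec %.3f",
                     "  (TP %d FP %d TN %d FN %d)\n"),
              x$accuracy, x$sensitivity, x$specificity, x$TP, x$FP, x$TN,
              x$FN))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold-swept ROC with AUC by the trapezoidal rule, which equals the
#' probability that a random positive scores above a random negative with
#' ties counted 1/2 (the concordance interpretation).
#'
#' @param truth binary 0/1 vector; both classes must be present.
#' @param scores numeric scores, higher meaning more likely positive.
#' @return An object of class `roc_curve`: a data frame of `(fpr, tpr)`
#'   points from (0,0) to (1,1) with the `auc` attached.
#' @examples
#' roc_auc(c(0, 1, 1, 0), c(0.1, 0.8, 0.4, 0.5))$auc  # 0.75
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores))
    stop("truth and scores must have equal length")
  if (length(unique(truth)) < 2)
    stop("both classes must be present to sweep an ROC curve")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  structure(list(curve = curve, auc = as.numeric(r$auc)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%d points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    plot(x$curve$fpr, x$curve$tpr, type = "l", col = col,
         xlab = "False positive rate", ylab = "True positive rate",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$curve$fpr, x$curve$tpr, col = col, ...)
  }
  invisible(x)
}

.eval_method <- function(truth, label, score) {
  cm <- confusion_metrics(truth, label)
  auc <- if (length(unique(truth)) < 2) NA_real_ else
    roc_auc(truth, score)$auc
  c(accuracy = cm$accuracy, auc = auc, sensitivity = cm$sensitivity,
    specificity = cm$specificity)
}

#' Replicated comparison of the ensemble methods
#'
#' The evaluation protocol behind the method comparison: for each
#' replicate r, a fresh stratified split plan is drawn with seed
#' `base_seed + r` (the whole plan is redrawn, test set included), the
#' 17-segment blocks are reduced by PCA fitted on that replicate's
#' training pool, every requested method is run on the identical splits
#' (a paired design), and accuracy, AUC, sensitivity and specificity are
#' measured on the replicate's test set. Results are aggregated as mean
#' and SD (n-1 denominator) over replicates.
#'
#' Methods: `"voting"` (weighted voting with non-negative weights
#' proportional to validation-0 accuracy), `"stacking"` (one-step stack:
#' base classifiers on the training pool, meta-learner on validation 0),
#' `"two_step"` (the two-step stacking estimator), `"individual"` (each
#' base classifier fitted on the training pool and evaluated directly).
#'
#' @param table a `feature_table` large enough for the split plan.
#' @param methods character vector from
#'   `c("voting", "stacking", "two_step", "individual")`.
#' @param config an [ensemble_config()].
#' @param R number of replicates (default 50). With `R = 1` the SD is NA.
#' @param base_seed base seed; replicate r uses `base_seed + r`.
#' @param specs base classifier roster (default: the 14 retained
#'   families).
#' @param pca reduce the 17-segment blocks by training-pool PCA
#'   (default `TRUE`; automatically off for schema-free tables).
#' @param test_frac,val_frac,first_val_frac split fractions, see
#'   [make_split_plan()].
#' @return An object of class `replicate_report`: per-method R x 4 metric
#'   matrices plus a `summary` data frame of means and SDs.
#' @export
run_replicates <- function(table,
                           methods = c("voting", "stacking", "two_step"),
                           config = ensemble_config(), R = 50L,
                           base_seed = 1L, specs = default_ensemble_specs(),
                           pca = TRUE, test_frac = 0.15, val_frac = 0.20,
                           first_val_frac = 0.20) {
  stopifnot(inherits(table, "feature_table"))
  known <- c("voting", "stacking", "two_step", "individual")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  if (pca && is.null(table$schema)) pca <- FALSE
  R <- as.integer(R)
  res <- list()
  record <- function(method, r, v) {
    if (is.null(res[[method]]))
      res[[method]] <<- matrix(NA_real_, R, 4,
                               dimnames = list(NULL, names(v)))
    res[[method]][r, ] <<- v
  }

  for (r in seq_len(R)) {
    seed_r <- base_seed + r
    plan <- make_split_plan(table$labels, test_frac = test_frac,
                            val_frac = val_frac,
                            first_val_frac = first_val_frac,
                            K = config$K, seed = seed_r)
    tab_r <- if (pca) {
      apply_reduction(table, fit_default_pca(table, plan$train_pool_idx))
    } else table
    test <- tab_r[plan$test_idx]
    val0 <- tab_r[plan$validation0_idx]
    pool <- tab_r[plan$train_pool_idx]
    cfg <- config
    cfg$seed <- seed_r * 10000L
    truth <- test$labels

    if (any(c("voting", "stacking", "individual") %in% methods)) {
      base <- lapply(seq_along(specs), function(l)
        fit_classifier(specs[[l]], pool, seed = cfg$seed + l,
                       tune = cfg$tune_base))
      if ("individual" %in% methods) {
        for (m in base) {
          sc <- predict_scores(m, test)
          record(m$spec$name, r,
                 .eval_method(truth, as.integer(sc >= 0.5), sc))
        }
      }
      if ("voting" %in% methods) {
        Mv <- .base_pred_matrix(base, val0, "label")
        acc <- colMeans(Mv == val0$labels)
        w <- acc / sum(acc)
        Mt <- .base_pred_matrix(base, test, "label")
        score <- as.numeric(Mt %*% w)
        record("voting", r,
               .eval_method(truth, as.integer(score >= cfg$threshold),
                            score))
      }
      if ("stacking" %in% methods) {
        Mv <- .base_pred_matrix(base, val0, cfg$stack_on)
        meta <- .fit_meta(Mv, val0$labels, cfg$meta_ntree,
                          seed = cfg$seed + 1000L)
        Mt <- .base_pred_matrix(base, test, cfg$stack_on)
        score <- .predict_meta(meta, Mt)
        record("stacking", r,
               .eval_method(truth, as.integer(score >= cfg$threshold),
                            score))
      }
    }
    if ("two_step" %in% methods) {
      model <- fit_two_step(specs, tab_r, plan, cfg)
      pr <- predict_two_step(model, test)
      record("two_step", r, .eval_method(truth, pr$label, pr$score))
    }
  }

  summ <- do.call(rbind, lapply(names(res), function(m) {
    M <- res[[m]]
    data.frame(method = m, metric = colnames(M),
               mean = colMeans(M, na.rm = TRUE),
               sd = if (R >= 2) apply(M, 2, stats::sd, na.rm = TRUE)
                    else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(replicates = res, summary = summ, R = R,
                 base_seed = as.integer(base_seed)),
            class = "replicate_report")
}

#' @export
print.replicate_report <- function(x, ...) {
  cat("<replicate_report> ", x$R, " replicates (base seed ", x$base_seed,
      ")\n", sep = "")
  s <- x$summary
  for (m in unique(s$method)) {
    sm <- s[s$method == m, ]
    cat(sprintf("  %-28s %s\n", m,
                paste(sprintf("%s %.3f (%.3f)", sm$metric, sm$mean, sm$sd),
                      collapse = " | ")))
  }
  invisible(x)
}

#' Two-step stacking on the GLPS block only
#'
#' Ablation protocol: identical replicate harness with the predictors
#' restricted to the three layer-specific GLPS features; no PCA is
#' applied.
#'
#' @param table a schema-bound `feature_table` whose schema includes GLPS.
#' @param config an [ensemble_config()].
#' @param R replicates.
#' @param base_seed base seed.
#' @param specs base classifier roster.
#' @return A `replicate_report` for method `"two_step"`.
#' @export
glps_only_run <- function(table, config = ensemble_config(), R = 50L,
                          base_seed = 1L,
                          specs = default_ensemble_specs()) {
  if (is.null(table$schema) || length(table$schema$glps) == 0)
    stop("table schema does not declare the GLPS columns")
  glps_tab <- select_features(table, table$schema$glps)
  run_replicates(glps_tab, methods = "two_step", config = config, R = R,
                 base_seed = base_seed, specs = specs, pca = FALSE)
}
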