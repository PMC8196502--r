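#' Ensemble configuration
#'
#' @param L number of base classifiers per first-step stack (default 14,
#'   the post-screening roster size).
#' @param K number of resampled first-step stacks combined by the second
#'   step (default 10).
#' @param threshold decision threshold on ensemble scores; ties at exactly
#'   0.5 classify as positive (the `>=` indicator convention).
#' @param meta_ntree trees in each random-forest meta-learner (default 500,
#'   stratified bootstrap).
#' @param stack_on what the meta-learners see from the layer below:
#'   `"label"` (default) feeds hard 0/1 predictions, `"score"` feeds
#'   positive-class scores.
#' @param tune_base tune base-classifier grids by cross-validation
#'   (default `TRUE`).
#' @param seed base seed; per-classifier and per-stack seeds are derived
#'   from it by fixed offsets.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(L = 14L, K = 10L, threshold = 0.5,
                            meta_ntree = 500L,
                            stack_on = c("label", "score"),
                            tune_base = TRUE, seed = 1L) {
  stack_on <- match.arg(stack_on)
  stopifnot(L >= 1, K >= 1)
  structure(list(L = as.integer(L), K = as.integer(K), threshold = threshold,
                 meta_ntree = as.integer(meta_ntree), stack_on = stack_on,
                 tune_base = isTRUE(tune_base), seed = as.integer(seed)),
            class = "ensemble_config")
}

.check_votes <- function(votes) {
  if (length(votes) < 1) stop("votes must be non-empty")
  if (!all(votes %in% c(0, 1))) stop("votes must be binary 0/1")
  votes
}

#' Majority vote over L binary classifier outputs
#'
#' `1(mean(votes) >= 0.5)`: the indicator convention classifies exact ties
#' as positive.
#'
#' @param votes binary vector of votes, one per classifier.
#' @return 0 or 1.
#' @examples
#' majority_vote(c(1, 1, 0))   # 1
#' majority_vote(c(0, 1, 0, 1))  # tie -> 1
#' @export
majority_vote <- function(votes) {
  votes <- .check_votes(votes)
  as.integer(mean(votes) >= 0.5)
}

#' Weighted vote over L binary classifier outputs
#'
#' `1(sum(weights * votes) >= 0.5)`. Weights are unconstrained finite
#' reals (they may be negative, as when estimated by an unpenalized
#' second-level regression); with all weights equal to `1/L` the rule
#' coincides with [majority_vote()].
#'
#' @param votes binary vector.
#' @param weights numeric vector aligned with `votes`.
#' @return 0 or 1.
#' @export
weighted_vote <- function(votes, weights) {
  votes <- .check_votes(votes)
  if (length(weights) != length(votes))
    stop("votes and weights must have equal length")
  if (!all(is.finite(weights))) stop("weights must be finite")
  as.integer(sum(weights * votes) >= 0.5)
}

# Random-forest meta-learner on an n x m prediction matrix. Validation
# sets in this design are small (58-72 subjects), so terminal nodes scale
# with n (nodesize n/5): each leaf averages several vote patterns instead
# of memorizing individual validation subjects.
.fit_meta <- function(M, y, ntree, seed) {
  yf <- factor(y, levels = c(0, 1))
  df <- as.data.frame(M)
  colnames(df) <- paste0("m", seq_len(ncol(df)))
  set.seed(seed)
  cnt <- as.vector(table(yf))
  randomForest::randomForest(df, yf, ntree = ntree, strata = yf,
                             sampsize = cnt,
                             nodesize = max(1L, floor(length(y) / 5)))
}

.predict_meta <- function(meta, M) {
  df <- as.data.frame(M)
  colnames(df) <- paste0("m", seq_len(ncol(df)))
  stats::predict(meta, df, type = "prob")[, "1"]
}

.base_pred_matrix <- function(models, table, stack_on) {
  M <- vapply(models, function(m) {
    sc <- predict_scores(m, table)
    if (stack_on == "label") as.numeric(sc >= 0.5) else sc
  }, numeric(length(table$labels)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(table$labels))
  M
}

#' Fit a one-step stack of base classifiers
#'
#' Base classifiers are fitted on `train`; the random-forest meta-learner
#' is then fitted on their predictions over `validation` (hard labels by
#' default, scores with `stack_on = "score"`) against the validation
#' labels. Overlapping subject ids between the two sets are a leakage
#' error.
#'
#' @param specs list of `classifier_spec` objects (length L).
#' @param train,validation disjoint `feature_table`s, both classes present
#'   in each.
#' @param config an [ensemble_config()].
#' @return An object of class `fitted_stack`.
#' @export
fit_stack <- function(specs, train, validation,
                      config = ensemble_config(L = length(specs))) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  overlap <- intersect(train$subject_ids, validation$subject_ids)
  if (length(overlap) > 0)
    stop("leakage: subject(s) present in both train and validation: ",
         paste(utils::head(overlap, 3), collapse = ", "))
  base <- lapply(seq_along(specs), function(l)
    fit_classifier(specs[[l]], train, seed = config$seed + l,
                   tune = config$tune_base))
  M <- .base_pred_matrix(base, validation, config$stack_on)
  meta <- .fit_meta(M, validation$labels, config$meta_ntree,
                    seed = config$seed + 1000L)
  structure(list(base = base, meta = meta, config = config),
            class = "fitted_stack")
}

#' @export
print.fitted_stack <- function(x, ...) {
  cat("<fitted_stack> ", length(x$base),
      " base classifiers + random-forest meta-learner\n", sep = "")
  invisible(x)
}

#' @export
predict.fitted_stack <- function(object, table, ...) {
  M <- .base_pred_matrix(object$base, table, object$config$stack_on)
  score <- .predict_meta(object$meta, M)
  list(label = as.integer(score >= object$config$threshold), score = score)
}

#' Fit the two-step stacking model
#'
#' First step: for each of the K resampled (train, validation) pairs of the
#' split plan, a full stack of L base classifiers plus meta-learner is
#' fitted ([fit_stack()]). Second step: the K first-step stacks predict the
#' held-out "validation 0" set, and a second random-forest meta-learner is
#' fitted on that K-column prediction matrix against the validation-0
#' labels. Test subjects are never touched during fitting.
#'
#' @param specs list of L `classifier_spec`s.
#' @param table the full `feature_table` the plan indexes into.
#' @param plan a [make_split_plan()] result with K first-step splits.
#' @param config an [ensemble_config()]; `config$K` must equal the plan's K.
#' @return An object of class `two_step_model`.
#' @export
fit_two_step <- function(specs, table, plan,
                         config = ensemble_config(L = length(specs))) {
  stopifnot(inherits(plan, "split_plan"))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (config$K != length(plan$first_step))
    stop("config K (", config$K, ") does not match the plan's ",
         length(plan$first_step), " first-step splits")
  stacks <- lapply(seq_len(config$K), function(k) {
    fs <- plan$first_step[[k]]
    cfg_k <- config
    cfg_k$seed <- config$seed + 100L * k
    fit_stack(specs, table[fs$train_idx], table[fs$val_idx], cfg_k)
  })
  val0 <- table[plan$validation0_idx]
  M <- vapply(stacks, function(s) {
    pr <- predict(s, val0)
    if (config$stack_on == "label") as.numeric(pr$label) else pr$score
  }, numeric(length(val0$labels)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(val0$labels))
  meta2 <- .fit_meta(M, val0$labels, config$meta_ntree,
                     seed = config$seed + 2000L)
  structure(list(stacks = stacks, meta2 = meta2, plan = plan,
                 config = config), class = "two_step_model")
}

#' @export
print.two_step_model <- function(x, ...) {
  cat("<two_step_model> ", length(x$stacks), " first-step stacks x ",
      length(x$stacks[[1]]$base),
      " base classifiers; second-step random-forest meta-learner\n",
      sep = "")
  invisible(x)
}

#' Predict with a fitted two-step model
#'
#' @param model a `two_step_model`.
#' @param table a `feature_table` with the training features.
#' @return List with `label` (0/1; `score >= threshold`, ties positive)
#'   and `score` (second-step meta-learner positive-class score in
#'   `[0, 1]`).
#' @export
predict_two_step <- function(model, table) {
  stopifnot(inherits(model, "two_step_model"))
  M <- vapply(model$stacks, function(s) {
    pr <- predict(s, table)
    if (model$config$stack_on == "label") as.numeric(pr$label) else pr$score
  }, numeric(length(table$labels)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(table$labels))
  score <- .predict_meta(model$meta2, M)
  list(label = as.integer(score >= model$config$threshold), score = score)
}

#' @export
predict.two_step_model <- function(object, table, ...)
  predict_two_step(object, table)
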