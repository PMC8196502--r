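#' Registry of the 19 base classifier families
#'
#' The ensemble draws on 19 commonly used binary classifiers spanning
#' parametric models, kernel machines, tree ensembles and neural networks.
#' Method-family names -- not backend package names -- are the interface;
#' each entry carries a small hyperparameter grid (tuned by stratified
#' cross-validation when it has more than one row) and a flag for whether
#' the adapter standardizes features.
#'
#' Family notes: the cumulative probability model for a binary outcome has
#' the same likelihood as logistic regression and is fitted as such; the
#' weighted subspace random forest samples split candidates with
#' per-feature weights derived from univariate t statistics; sparsed LDA is
#' fitted by lasso-penalized optimal scoring (for two classes, optimal
#' scoring is a penalized regression on a centered class indicator); the
#' Bayes generalized linear model is logistic regression under a Gaussian
#' coefficient prior, i.e. ridge-penalized logistic; the monotone
#' multi-layer perceptron constrains both weight layers to be non-negative
#' so the fitted score is non-decreasing in every feature; stochastic
#' gradient boosting uses row-subsampled gradient-boosted trees.
#'
#' @return `list_registry()`: named list of 19 `classifier_spec` objects,
#'   in the conventional reporting order.
#' @export
list_registry <- function() {
  spec <- function(name, id, grid = data.frame(dummy = 1), scale = FALSE)
    structure(list(name = name, id = id, grid = grid, scale = scale),
              class = "classifier_spec")
  specs <- list(
    spec("logistic regression", "glm_logistic"),
    spec("penalized logistic regression", "glmnet_enet",
         grid = data.frame(alpha = c(1, 0.5, 0))),
    spec("cumulative probability model", "cpm"),
    spec("random forest", "rf", grid = data.frame(mtry_rule = c("sqrt", "third"))),
    spec("weighted subspace random forest", "wsrf"),
    spec("SVM with class weight", "svm_linear_cw",
         grid = data.frame(cost = c(0.5, 2)), scale = TRUE),
    spec("SVM with polynomial kernel", "svm_poly",
         grid = data.frame(degree = c(2, 3)), scale = TRUE),
    spec("SVM with radial kernel", "svm_rbf",
         grid = data.frame(cost = c(0.5, 2)), scale = TRUE),
    spec("K-nearest neighbor", "knn",
         grid = data.frame(k = c(5, 9, 15)), scale = TRUE),
    spec("LDA", "lda"),
    spec("sparsed LDA", "slda", scale = TRUE),
    spec("naive Bayes", "nb"),
    spec("Bayes generalized linear model", "bayes_glm",
         grid = data.frame(lambda = c(0.01, 0.1)), scale = TRUE),
    spec("Gaussian process with polynomial kernel", "gp_poly", scale = TRUE),
    spec("Gaussian process with radial kernel", "gp_rbf", scale = TRUE),
    spec("neural network", "nnet",
         grid = data.frame(size = c(3, 5)), scale = TRUE),
    spec("monotone multi-layer perceptron neural network", "mono_mlp",
         scale = TRUE),
    spec("model average neural network", "avnnet", scale = TRUE),
    spec("stochastic gradient boosting", "sgb")
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> '", x$name, "' (", nrow(x$grid),
      " grid configuration", if (nrow(x$grid) > 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Reference mean testing accuracies of the 19 base classifiers
#'
#' Mean test-set accuracies (over 50 replicates) of the 19 classifier
#' families as reported in a published CHD screening benchmark on a
#' 424-subject 2D-STE cohort. They are the canonical worked example for
#' the sub-60\% exclusion rule ([filter_by_accuracy()]), under which 14
#' families are retained and 5 excluded.
#'
#' @return Named numeric vector of length 19 (fractions, not percent).
#' @export
chd_benchmark_accuracies <- function() {
  c("logistic regression" = 0.677,
    "penalized logistic regression" = 0.708,
    "cumulative probability model" = 0.686,
    "random forest" = 0.592,
    "weighted subspace random forest" = 0.593,
    "SVM with class weight" = 0.702,
    "SVM with polynomial kernel" = 0.663,
    "SVM with radial kernel" = 0.637,
    "K-nearest neighbor" = 0.582,
    "LDA" = 0.696,
    "sparsed LDA" = 0.588,
    "naive Bayes" = 0.644,
    "Bayes generalized linear model" = 0.680,
    "Gaussian process with polynomial kernel" = 0.701,
    "Gaussian process with radial kernel" = 0.652,
    "neural network" = 0.628,
    "monotone multi-layer perceptron neural network" = 0.692,
    "model average neural network" = 0.651,
    "stochastic gradient boosting" = 0.578)
}

#' Exclude classifiers below an accuracy threshold
#'
#' The screening rule that precedes ensembling: classifiers whose accuracy
#' falls below the threshold (default 60\%) are excluded; the rest are
#' retained in their input order. Applied to the benchmark accuracies of
#' [chd_benchmark_accuracies()] this retains 14 of the 19 families.
#'
#' @param evals named numeric vector of accuracies (fractions).
#' @param threshold retention threshold; a classifier is retained when its
#'   accuracy is `>= threshold`.
#' @return List with character vectors `retained` and `excluded`.
#' @export
filter_by_accuracy <- function(evals, threshold = 0.60) {
  if (length(evals) == 0) stop("evals must be non-empty")
  if (is.null(names(evals))) stop("evals must be named")
  keep <- evals >= threshold
  list(retained = names(evals)[keep], excluded = names(evals)[!keep])
}

#' The default 14-classifier ensemble roster
#'
#' The registry entries retained after applying the 60\% exclusion rule to
#' the benchmark accuracies.
#'
#' @return Named list of 14 `classifier_spec` objects.
#' @export
default_ensemble_specs <- function() {
  keep <- filter_by_accuracy(chd_benchmark_accuracies(), 0.60)$retained
  list_registry()[keep]
}

# ---- internal fitting helpers ------------------------------------------

.feature_matrix <- function(table, features) {
  missing <- setdiff(features, colnames(table$features))
  if (length(missing) > 0)
    stop("table lacks feature(s) the model was trained on: ",
         paste(missing, collapse = ", "))
  table$features[, features, drop = FALSE]
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# softplus used by the monotone MLP weight parameterization
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.fit_backend <- function(id, X, y, params) {
  # X standardized numeric matrix where spec$scale, y integer 0/1
  yf <- factor(y, levels = c(0, 1))
  p <- ncol(X)
  switch(id,
    glm_logistic = ,
    cpm = {
      # binary cumulative-link likelihood coincides with logistic regression
      fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                                             family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    glmnet_enet = {
      cv <- glmnet::cv.glmnet(X, yf, family = "binomial",
                              alpha = params$alpha, nfolds = 5,
                              foldid = .stratified_folds(y, 5))
      list(fit = cv$glmnet.fit, lambda = cv$lambda.min)
    },
    rf = {
      mtry <- if (params$mtry_rule == "sqrt") max(1L, floor(sqrt(p)))
              else max(1L, floor(p / 3))
      randomForest::randomForest(X, yf, ntree = 300, mtry = mtry)
    },
    wsrf = {
      tt <- abs(apply(X, 2, function(v) {
        s <- stats::sd(v[y == 1]) ^ 2 / sum(y == 1) +
             stats::sd(v[y == 0]) ^ 2 / sum(y == 0)
        if (s == 0) 0 else (mean(v[y == 1]) - mean(v[y == 0])) / sqrt(s)
      }))
      w <- tt / max(tt, 1e-8)
      w <- pmax(w, 0.01)
      df <- data.frame(X, .y = yf, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = 300, probability = TRUE,
                     split.select.weights = unname(w), num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1))
    },
    svm_linear_cw = {
      cw <- rev(as.vector(table(yf))); names(cw) <- levels(yf)
      cw <- cw / sum(cw) * 2
      e1071::svm(X, yf, kernel = "linear", cost = params$cost,
                 class.weights = cw, scale = FALSE)
    },
    svm_poly = e1071::svm(X, yf, kernel = "polynomial",
                          degree = params$degree, coef0 = 1, cost = 1,
                          scale = FALSE),
    svm_rbf = e1071::svm(X, yf, kernel = "radial", cost = params$cost,
                         scale = FALSE),
    knn = list(X = X, y = y, k = params$k),
    lda = MASS::lda(X, grouping = yf),
    slda = {
      # lasso-penalized optimal scoring with a 1-d logistic calibration
      z <- ifelse(y == 1, 1, -1)
      cv <- glmnet::cv.glmnet(X, z, family = "gaussian", alpha = 1,
                              nfolds = 5, foldid = .stratified_folds(y, 5))
      lin <- as.numeric(stats::predict(cv$glmnet.fit, X, s = cv$lambda.min))
      cal <- suppressWarnings(stats::glm.fit(cbind(1, lin), y,
                                             family = stats::binomial()))
      cf <- cal$coefficients
      cf[is.na(cf)] <- 0  # all-null lasso fit: calibrate on intercept only
      list(fit = cv$glmnet.fit, lambda = cv$lambda.min, cal = cf)
    },
    nb = e1071::naiveBayes(as.data.frame(X), yf),
    bayes_glm = {
      # Gaussian coefficient prior == ridge penalty
      glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                     lambda = params$lambda)
    },
    gp_poly = kernlab::gausspr(X, yf, kernel = "polydot",
                               kpar = list(degree = 2, scale = 1 / p,
                                           offset = 1)),
    gp_rbf = kernlab::gausspr(X, yf, kernel = "rbfdot",
                              kpar = list(sigma = 1 / p)),
    nnet = nnet::nnet(X, y, size = params$size, decay = 0.1, maxit = 200,
                      entropy = TRUE, trace = FALSE),
    mono_mlp = .fit_mono_mlp(X, y, hidden = 3L, maxit = 80L),
    avnnet = lapply(1:5, function(i)
      nnet::nnet(X, y, size = 3, decay = 0.1, maxit = 200, entropy = TRUE,
                 trace = FALSE)),
    sgb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3, subsample = 0.7,
                      colsample_bytree = 0.8, nthread = 1,
                      seed = sample.int(1e9, 1)),
        data = dtrain, nrounds = 80, verbose = 0)
    },
    stop("unknown backend id: ", id))
}

.predict_backend <- function(id, fit, X) {
  # returns a positive-class score in [0, 1] per row
  switch(id,
    glm_logistic = ,
    cpm = as.numeric(stats::plogis(cbind(1, X) %*% fit$coef)),
    glmnet_enet = as.numeric(stats::predict(fit$fit, X, s = fit$lambda,
                                            type = "response")),
    rf = stats::predict(fit, X, type = "prob")[, "1"],
    wsrf = {
      pr <- stats::predict(fit, data = as.data.frame(X),
                           num.threads = 1)$predictions
      pr[, "1"]
    },
    svm_linear_cw = ,
    svm_poly = ,
    svm_rbf = {
      dv <- attr(stats::predict(fit, X, decision.values = TRUE),
                 "decision.values")
      # orient the decision value toward the positive class
      flip <- grepl("^0/", colnames(dv)[1L])
      as.numeric(stats::plogis(if (flip) -dv[, 1L] else dv[, 1L]))
    },
    knn = {
      pred <- class::knn(fit$X, X, cl = factor(fit$y, levels = c(0, 1)),
                         k = fit$k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    lda = stats::predict(fit, X)$posterior[, "1"],
    slda = {
      lin <- as.numeric(stats::predict(fit$fit, X, s = fit$lambda))
      as.numeric(stats::plogis(cbind(1, lin) %*% fit$cal))
    },
    nb = stats::predict(fit, as.data.frame(X), type = "raw")[, "1"],
    bayes_glm = as.numeric(stats::predict(fit, X, type = "response")),
    gp_poly = ,
    gp_rbf = {
      pr <- kernlab::predict(fit, X, type = "probabilities")
      pr[, which(colnames(pr) == "1")]
    },
    nnet = as.numeric(stats::predict(fit, X)),
    mono_mlp = .predict_mono_mlp(fit, X),
    avnnet = rowMeans(vapply(fit, function(f) as.numeric(stats::predict(f, X)),
                             numeric(nrow(X)))),
    sgb = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X))),
    stop("unknown backend id: ", id))
}

# Monotone single-hidden-layer perceptron: both weight layers constrained
# non-negative through a softplus parameterization, so the output is
# non-decreasing in every (standardized) input. Trained by BFGS on the
# cross-entropy (analytic gradient) with a small L2 penalty.
.fit_mono_mlp <- function(X, y, hidden = 3L, maxit = 100L, decay = 1e-3) {
  n <- nrow(X); p <- ncol(X); h <- hidden
  unpack <- function(th) list(
    A = matrix(th[seq_len(p * h)], p, h),
    b1 = th[p * h + seq_len(h)],
    a2 = th[p * h + h + seq_len(h)],
    b2 = th[p * h + 2 * h + 1L])
  fwd <- function(th) {
    par <- unpack(th)
    H <- tanh(sweep(X %*% .softplus(par$A), 2, par$b1, "+"))
    list(H = H, pr = stats::plogis(as.numeric(H %*% .softplus(par$a2) +
                                                par$b2)))
  }
  obj <- function(th) {
    pr <- pmin(pmax(fwd(th)$pr, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr)) + decay * sum(th ^ 2)
  }
  grad <- function(th) {
    par <- unpack(th)
    f <- fwd(th)
    w2 <- .softplus(par$a2)
    dz <- (f$pr - y) / n                       # d loss / d output logit
    g_b2 <- sum(dz)
    g_w2 <- as.numeric(crossprod(f$H, dz))     # d/d softplus(a2)
    g_a2 <- g_w2 * stats::plogis(par$a2)       # softplus' = logistic
    dpre <- (dz %*% t(w2)) * (1 - f$H ^ 2)     # back through tanh
    g_b1 <- colSums(dpre)
    g_A <- crossprod(X, dpre) * stats::plogis(par$A)
    c(as.numeric(g_A), g_b1, g_a2, g_b2) + 2 * decay * th
  }
  th0 <- stats::rnorm(p * h + 2 * h + 1L, 0, 0.3)
  opt <- suppressWarnings(stats::optim(th0, obj, grad, method = "BFGS",
                                       control = list(maxit = maxit)))
  list(theta = opt$par, p = p, hidden = h)
}

.predict_mono_mlp <- function(fit, X) {
  p <- fit$p; h <- fit$hidden; th <- fit$theta
  A <- matrix(th[seq_len(p * h)], p, h)
  b1 <- th[p * h + seq_len(h)]
  a2 <- th[p * h + h + seq_len(h)]
  b2 <- th[p * h + 2 * h + 1L]
  H <- tanh(sweep(X %*% .softplus(A), 2, b1, "+"))
  stats::plogis(as.numeric(H %*% .softplus(a2) + b2))
}

#' Fit one base classifier, tuning its grid by cross-validation
#'
#' When the spec's grid has more than one row, each configuration is scored
#' by stratified k-fold cross-validated accuracy on the training table only
#' and the best (first on ties) is refitted on all training subjects.
#' All randomness is governed by `seed`.
#'
#' @param spec a `classifier_spec` from [list_registry()].
#' @param train a `feature_table`; both classes must be present.
#' @param seed integer seed.
#' @param folds cross-validation folds used for grid tuning (default 5).
#' @param tune set `FALSE` to skip tuning and use the first grid row.
#' @return An object of class `fitted_classifier`.
#' @export
fit_classifier <- function(spec, train, seed = 1L, folds = 5L, tune = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "feature_table"))
  y <- train$labels
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  X <- train$features
  center <- scale_ <- NULL
  if (spec$scale) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  grid <- spec$grid
  best <- 1L
  if (tune && nrow(grid) > 1) {
    if (min(table(y)) < folds)
      stop("need at least ", folds, " subjects per class for ", folds,
           "-fold tuning")
    set.seed(seed)
    fold <- .stratified_folds(y, folds)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      params <- as.list(grid[g, , drop = FALSE])
      hits <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        set.seed(seed + f)
        fit <- .fit_backend(spec$id, X[tr, , drop = FALSE], y[tr], params)
        sc <- .predict_backend(spec$id, fit, X[!tr, , drop = FALSE])
        hits <- hits + sum(as.integer(sc >= 0.5) == y[!tr])
      }
      hits / length(y)
    }, numeric(1))
    best <- which.max(acc)
  }
  params <- as.list(grid[best, , drop = FALSE])
  set.seed(seed)
  fit <- .fit_backend(spec$id, X, y, params)
  structure(list(spec = spec, fit = fit, params = params,
                 features = colnames(train$features),
                 center = center, scale = scale_, seed = as.integer(seed)),
            class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat("<fitted_classifier> '", x$spec$name, "' on ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' Predict with a fitted base classifier
#'
#' Features are matched by name, so any column order (and any superset of
#' columns) is accepted. The hard label is `score >= 0.5`.
#'
#' @param model a `fitted_classifier`.
#' @param table a `feature_table` containing the training features.
#' @return `predict_labels()`: integer 0/1 vector. `predict_scores()`:
#'   numeric positive-class score in `[0, 1]`.
#' @export
predict_labels <- function(model, table) {
  as.integer(predict_scores(model, table) >= 0.5)
}

#' @rdname predict_labels
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "fitted_classifier"))
  X <- .feature_matrix(table, model$features)
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  sc <- .predict_backend(model$spec$id, model$fit, X)
  pmin(pmax(as.numeric(sc), 0), 1)
}
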