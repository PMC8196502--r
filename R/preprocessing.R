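#' Two-sample t-test screen over features
#'
#' Screens each named feature for a class difference with a two-sided
#' two-sample t-test (Welch by default, pooled-variance optionally) and
#' flags features with p-value at or below `alpha`. The screen is
#' descriptive -- features are not removed from the pipeline -- mirroring
#' the role of a univariate screening table in a clinical study.
#'
#' Features with zero variance in both classes carry no information for the
#' test; they are reported with `t = 0`, `p = 1` and `degenerate = TRUE`
#' rather than raising an error.
#'
#' @param table a `feature_table` with both classes present (>= 2 subjects
#'   per class).
#' @param features feature names to test; defaults to the schema's 2D-STE
#'   predictors, or all columns for schema-free tables.
#' @param alpha significance threshold (default 0.05, flag when `p <= alpha`).
#' @param var_equal `FALSE` (default) for Welch's unequal-variance test,
#'   `TRUE` for the pooled-variance test.
#' @return A `ttest_report` data frame with columns `feature`, `t`, `p`,
#'   `flagged`, `degenerate`.
#' @export
ttest_screen <- function(table, features = NULL, alpha = 0.05,
                         var_equal = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(features)) {
    features <- if (!is.null(table$schema))
      schema_ste_predictors(table$schema) else colnames(table$features)
  }
  missing <- setdiff(features, colnames(table$features))
  if (length(missing) > 0)
    stop("feature(s) not present: ", paste(missing, collapse = ", "))
  pos <- table$labels == 1L
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("both classes need at least 2 subjects")
  rows <- lapply(features, function(f) {
    x <- table$features[pos, f]
    y <- table$features[!pos, f]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      warning("feature '", f, "' has zero variance in both classes")
      return(data.frame(feature = f, t = 0, p = 1, flagged = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    ht <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(feature = f, t = unname(ht$statistic), p = ht$p.value,
               flagged = ht$p.value <= alpha, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "variant") <- if (var_equal) "pooled" else "welch"
  class(out) <- c("ttest_report", "data.frame")
  out
}

#' Fit a principal component model on one 17-segment strain block
#'
#' Correlation-matrix PCA by default (each segment centered and scaled):
#' the strain blocks mix measurement scales (\%, 1/s, ms), and
#' correlation-based loadings make bullseye-style loading maps comparable
#' across blocks. Covariance PCA is available with `scale. = FALSE`. The
#' sign of each loading column is fixed so that its largest-magnitude
#' element is positive, removing the eigenvector sign ambiguity.
#'
#' The model must be fitted on training subjects only and applied to
#' held-out subjects by projection ([apply_reduction()]); fitting on all
#' subjects would leak test information into the representation.
#'
#' @param table a `feature_table` (training subjects).
#' @param block character vector of the block's feature names.
#' @param n_components number of components to retain.
#' @param scale. scale each feature to unit variance (default `TRUE`).
#' @param block_name label stored in the model (defaults to the common
#'   feature-name prefix).
#' @return An object of class `block_pca`: center/scale vectors, all
#'   eigenvalues (non-increasing), the loading matrix restricted to the
#'   retained components, and `n_components`.
#' @export
fit_block_pca <- function(table, block, n_components,
                          scale. = TRUE, block_name = NULL) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(block, colnames(table$features))
  if (length(missing) > 0)
    stop("feature(s) not present: ", paste(missing, collapse = ", "))
  if (n_components > length(block))
    stop("n_components (", n_components, ") exceeds block size (",
         length(block), ")")
  X <- table$features[, block, drop = FALSE]
  if (nrow(X) < n_components + 1)
    stop("need at least n_components + 1 subjects")
  sds <- apply(X, 2, stats::sd)
  if (scale. && any(sds == 0))
    stop("zero-variance feature(s) in block: ",
         paste(block[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  rot <- pc$rotation
  # sign convention: largest-magnitude loading element positive
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  if (is.null(block_name)) {
    block_name <- sub("_.*$", "", block[1L])
  }
  structure(list(block = block_name, features = block,
                 center = pc$center,
                 scale = if (scale.) pc$scale else NULL,
                 eigenvalues = pc$sdev^2,
                 loadings = rot[, seq_len(n_components), drop = FALSE],
                 n_components = as.integer(n_components)),
            class = "block_pca")
}

#' @export
print.block_pca <- function(x, ...) {
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat("<block_pca> block '", x$block, "': ", x$n_components,
      " of ", length(x$features), " components (",
      sprintf("%.1f%%", 100 * sum(ev[seq_len(x$n_components)])),
      " of variance)\n", sep = "")
  invisible(x)
}

#' Choose how many principal components to retain
#'
#' Two rules: `"fixed"` returns the pre-registered per-block counts
#' (defaults: 3 components for PSS and SSR, 2 for TP -- the counts chosen
#' from scree-plot elbows for this feature set), and `"elbow"` returns the
#' largest drop-ratio point, `argmax_j eigenvalues[j] / eigenvalues[j+1]`.
#'
#' @param eigenvalues non-increasing, non-negative eigenvalue sequence.
#' @param rule `"fixed"` or `"elbow"`.
#' @param block block name, required for `rule = "fixed"`.
#' @param fixed_counts named per-block counts for the fixed rule.
#' @return Integer component count.
#' @export
choose_components <- function(eigenvalues, rule = c("fixed", "elbow"),
                              block = NULL,
                              fixed_counts = c(PSS = 3L, SSR = 3L, TP = 2L)) {
  rule <- match.arg(rule)
  if (length(eigenvalues) == 0) stop("empty eigenvalue list")
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be non-increasing")
  if (rule == "fixed") {
    if (is.null(block) || !block %in% names(fixed_counts))
      stop("rule 'fixed' needs a block named in fixed_counts")
    return(as.integer(fixed_counts[[block]]))
  }
  if (length(eigenvalues) == 1L) return(1L)
  ratios <- eigenvalues[-length(eigenvalues)] / eigenvalues[-1L]
  as.integer(which.max(ratios))
}

#' Project strain blocks onto fitted components
#'
#' Replaces each 17-segment block by its retained principal component
#' scores (named e.g. `PSS_PC1`); all features not belonging to a fitted
#' block pass through unchanged. With the default component counts
#' (3 + 3 + 2) a 71-predictor table is reduced to 28 predictors.
#'
#' @param table a `feature_table`.
#' @param models list of `block_pca` models.
#' @return A schema-free `feature_table` with reduced columns.
#' @export
apply_reduction <- function(table, models) {
  stopifnot(inherits(table, "feature_table"))
  if (inherits(models, "block_pca")) models <- list(models)
  consumed <- character(0)
  score_list <- list()
  for (m in models) {
    stopifnot(inherits(m, "block_pca"))
    missing <- setdiff(m$features, colnames(table$features))
    if (length(missing) > 0)
      stop("block '", m$block, "' mismatch: table lacks ",
           paste(missing, collapse = ", "))
    if (any(m$features %in% consumed))
      stop("blocks overlap: ", m$block)
    if (m$n_components > 0) {
      X <- table$features[, m$features, drop = FALSE]
      X <- sweep(X, 2, m$center)
      if (!is.null(m$scale)) X <- sweep(X, 2, m$scale, "/")
      S <- X %*% m$loadings
      colnames(S) <- paste0(m$block, "_PC", seq_len(m$n_components))
      score_list[[m$block]] <- S
    }
    consumed <- c(consumed, m$features)
  }
  keep <- setdiff(colnames(table$features), consumed)
  feats <- do.call(cbind, c(score_list,
                            list(table$features[, keep, drop = FALSE])))
  feature_table(feats, table$labels, subject_ids = table$subject_ids)
}

# Round-half-up stratum allocation reconciled to the round-half-up total.
# Each reconciliation unit goes to the stratum with the largest remaining
# rounding residual (most under-allocated when adding, most over-allocated
# when removing), which keeps every stratum within one subject of its
# stratified target; ties fall to the larger stratum.
.allocate_stratified <- function(stratum_n, frac) {
  rhu <- function(x) floor(x + 0.5)
  counts <- rhu(stratum_n * frac)
  diff <- rhu(sum(stratum_n) * frac) - sum(counts)
  while (diff != 0) {
    resid <- stratum_n * frac - counts
    k <- if (diff > 0) which.max(resid + 1e-9 * stratum_n)
         else which.min(resid - 1e-9 * stratum_n)
    counts[k] <- counts[k] + sign(diff)
    diff <- diff - sign(diff)
  }
  if (any(counts < 1) || any(counts > stratum_n - 1))
    stop("a stratum is too small to populate every part")
  as.integer(counts)
}

#' Stratified test / validation / training split architecture
#'
#' Partitions subjects into (i) a testing set, (ii) a second-step
#' validation set ("validation 0"), and (iii) a training pool from which K
#' stratified first-step (train, validation) pairs are resampled
#' independently. Every part preserves the class ratio to within one
#' subject per class. Per-stratum sizes use round-half-up on
#' `stratum_n * frac`, reconciled to the round-half-up total by adjusting
#' the largest stratum; with 217/207 labels and fractions 0.15/0.20/0.20
#' this yields parts of 64 / 72 / 288 subjects and first-step pairs of
#' (230, 58).
#'
#' @param labels binary vector (0/1) for all subjects.
#' @param test_frac fraction of all subjects held out for testing
#'   (default 0.15).
#' @param val_frac fraction of the remainder held out as validation 0
#'   (default 0.20).
#' @param first_val_frac fraction of the training pool used as each
#'   first-step validation set (default 0.20).
#' @param K number of first-step resampled (train, validation) pairs
#'   (default 10).
#' @param seed integer seed; the plan is deterministic given it.
#' @return An object of class `split_plan` with components `test_idx`,
#'   `validation0_idx`, `train_pool_idx`, `first_step` (list of K
#'   `(train_idx, val_idx)` pairs), `sizes` and `seed`.
#' @export
make_split_plan <- function(labels, test_frac = 0.15, val_frac = 0.20,
                            first_val_frac = 0.20, K = 10L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), K >= 1)
  for (f in c(test_frac, val_frac, first_val_frac))
    if (!(f > 0 && f < 1)) stop("fractions must lie in (0, 1)")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(as.integer(seed))

  strata <- list(`1` = which(labels == 1L), `0` = which(labels == 0L))
  strata <- lapply(strata, sample)  # seeded shuffle within stratum

  take <- function(strata, counts) {
    out <- list(taken = integer(0), rest = list())
    for (i in seq_along(strata)) {
      idx <- strata[[i]]
      out$taken <- c(out$taken, idx[seq_len(counts[i])])
      out$rest[[i]] <- idx[-seq_len(counts[i])]
    }
    names(out$rest) <- names(strata)
    out
  }
  ns <- lengths(strata)
  sp_test <- take(strata, .allocate_stratified(ns, test_frac))
  ns2 <- lengths(sp_test$rest)
  sp_val0 <- take(sp_test$rest, .allocate_stratified(ns2, val_frac))
  pool <- sp_val0$rest
  ns3 <- lengths(pool)
  if (any(ns3 < 2)) stop("a stratum is too small to populate every part")

  first_step <- vector("list", K)
  val_counts <- .allocate_stratified(ns3, first_val_frac)
  for (k in seq_len(K)) {
    shuffled <- lapply(pool, sample)
    sp <- take(shuffled, val_counts)
    first_step[[k]] <- list(
      train_idx = unname(sort(unlist(sp$rest))),
      val_idx = unname(sort(sp$taken)))
  }
  structure(list(
    test_idx = unname(sort(sp_test$taken)),
    validation0_idx = unname(sort(sp_val0$taken)),
    train_pool_idx = unname(sort(unlist(pool))),
    first_step = first_step,
    sizes = c(test = length(sp_test$taken),
              validation0 = length(sp_val0$taken),
              train_pool = sum(ns3),
              first_train = sum(ns3) - sum(val_counts),
              first_val = sum(val_counts)),
    K = as.integer(K), seed = as.integer(seed)), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  s <- x$sizes
  cat("<split_plan> test ", s[["test"]], " | validation0 ",
      s[["validation0"]], " | training pool ", s[["train_pool"]], " -> ",
      x$K, " x (", s[["first_train"]], ", ", s[["first_val"]],
      ") first-step splits (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path JSON file path.
#' @return `split_plan_to_json` returns `path` invisibly;
#'   `split_plan_from_json` returns the restored `split_plan`.
#' @export
split_plan_to_json <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  x <- unclass(plan)
  x$sizes <- as.list(x$sizes)  # keep part names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname split_plan_to_json
#' @export
split_plan_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$first_step <- lapply(seq_len(nrow_or_len(x$first_step)), function(k) {
    fs <- if (is.data.frame(x$first_step)) x$first_step[k, ] else x$first_step[[k]]
    list(train_idx = as.integer(unlist(fs$train_idx)),
         val_idx = as.integer(unlist(fs$val_idx)))
  })
  for (f in c("test_idx", "validation0_idx", "train_pool_idx"))
    x[[f]] <- as.integer(x[[f]])
  x$sizes <- vapply(x$sizes, as.integer, integer(1))
  x$K <- as.integer(x$K); x$seed <- as.integer(x$seed)
  structure(x, class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Fit the default block PCA models on training subjects
#'
#' Convenience wrapper fitting one [fit_block_pca()] model per 17-segment
#' block (PSS, SSR, TP) on the given subjects, with component counts from
#' [choose_components()].
#'
#' @param table a schema-bound `feature_table`.
#' @param train_idx row indices of the training subjects to fit on.
#' @param rule component-count rule passed to [choose_components()].
#' @param scale. passed to [fit_block_pca()].
#' @return List of three `block_pca` models.
#' @export
fit_default_pca <- function(table, train_idx = seq_along(table$labels),
                            rule = "fixed", scale. = TRUE) {
  if (is.null(table$schema)) stop("needs a schema-bound table")
  train <- table[train_idx]
  lapply(names(table$schema$ste_blocks), function(b) {
    block <- table$schema$ste_blocks[[b]]
    full <- fit_block_pca(train, block, n_components = length(block),
                          scale. = scale., block_name = b)
    k <- choose_components(full$eigenvalues, rule = rule, block = b)
    full$loadings <- full$loadings[, seq_len(k), drop = FALSE]
    full$n_components <- k
    full
  })
}
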