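#' Canonical 71-predictor feature schema
#'
#' Defines the canonical data model for CHD screening from 2D-STE strain
#' features: 64 strain-derived numeric predictors plus 7 clinical risk
#' factors. The strain predictors comprise three 17-segment longitudinal
#' blocks over the AHA 17-segment model -- peak systolic strain (PSS),
#' systolic strain rate (SSR) and time-to-peak (TP) -- nine radial global
#' strain features (mitral valve, papillary muscle and apical levels, each
#' in endocardial/mid/epicardial layers), three layer-specific global
#' longitudinal peak strain (GLPS) features, and the peak standard
#' deviation (PSD) of time-to-peak across segments. Clinical predictors are
#' age (numeric) and six binary risk factors.
#'
#' Segment columns follow AHA numbering: segments 1--6 basal, 7--12
#' mid-cavity, 13--16 apical, 17 apex. Canonical column names are
#' `PSS_seg01`..`PSS_seg17`, `SSR_seg01`.., `TP_seg01`.., `GS_MV_ENDO` ..
#' `GS_AP_EPI`, `GLPS_ENDO`/`GLPS_MID`/`GLPS_EPI`, `PSD`, `age`, `gender`,
#' `hypertension`, `diabetes`, `hyperlipemia`, `smoke`, `family_history`.
#' Arbitrary CSV headers can be bound to these names through the
#' `column_map` argument of [read_feature_table()].
#'
#' @param include character vector of feature groups to keep; any subset of
#'   `c("PSS", "SSR", "TP", "GS", "GLPS", "PSD", "clinical")`. May be
#'   `character(0)` for an empty schema.
#' @param label_name name of the binary outcome column (1 = CHD positive).
#' @return An object of class `chd_schema`.
#' @examples
#' sch <- feature_schema()
#' count_predictors(sch)
#' count_predictors(feature_schema(include = "GLPS"))
#' @export
feature_schema <- function(include = c("PSS", "SSR", "TP", "GS", "GLPS",
                                       "PSD", "clinical"),
                           label_name = "CHD") {
  all_groups <- c("PSS", "SSR", "TP", "GS", "GLPS", "PSD", "clinical")
  if (length(include) > 0 && !all(include %in% all_groups)) {
    stop("unknown feature group(s): ",
         paste(setdiff(include, all_groups), collapse = ", "))
  }
  seg <- function(prefix) sprintf("%s_seg%02d", prefix, 1:17)
  levels_ <- c("MV", "PM", "AP")
  layers <- c("ENDO", "MID", "EPI")

  ste_blocks <- list()
  for (b in c("PSS", "SSR", "TP")) if (b %in% include) ste_blocks[[b]] <- seg(b)

  schema <- structure(list(
    ste_blocks = ste_blocks,
    radial_gs = if ("GS" %in% include)
      as.vector(t(outer(levels_, layers, function(l, y) paste("GS", l, y, sep = "_"))))
    else character(0),
    glps = if ("GLPS" %in% include) paste0("GLPS_", layers) else character(0),
    psd = if ("PSD" %in% include) "PSD" else character(0),
    clinical_numeric = if ("clinical" %in% include) "age" else character(0),
    clinical_binary = if ("clinical" %in% include)
      c("gender", "hypertension", "diabetes", "hyperlipemia", "smoke",
        "family_history")
    else character(0),
    label_name = label_name
  ), class = "chd_schema")

  for (b in names(schema$ste_blocks)) {
    stopifnot(length(schema$ste_blocks[[b]]) == 17,
              !anyDuplicated(schema$ste_blocks[[b]]))
  }
  if (anyDuplicated(schema_predictors(schema)))
    stop("schema defines duplicated feature names")
  schema
}

#' Ordered predictor names of a schema
#'
#' @param schema a `chd_schema`.
#' @return Character vector of predictor column names in canonical order
#'   (strain blocks, radial, GLPS, PSD, clinical).
#' @export
schema_predictors <- function(schema) {
  stopifnot(inherits(schema, "chd_schema"))
  c(unlist(schema$ste_blocks, use.names = FALSE), schema$radial_gs,
    schema$glps, schema$psd, schema$clinical_numeric, schema$clinical_binary)
}

#' Numeric 2D-STE predictor names (everything except clinical columns)
#' @param schema a `chd_schema`.
#' @return Character vector.
#' @export
schema_ste_predictors <- function(schema) {
  c(unlist(schema$ste_blocks, use.names = FALSE), schema$radial_gs,
    schema$glps, schema$psd)
}

#' Count the predictors declared by a schema
#'
#' Totals are computed from the schema's block sizes. The default schema
#' declares 71 predictors, 64 of them 2D-STE strain features
#' (17 + 17 + 17 + 9 + 3 + 1).
#'
#' @param schema a `chd_schema`.
#' @return Named list with `total` and `ste` counts.
#' @export
count_predictors <- function(schema) {
  stopifnot(inherits(schema, "chd_schema"))
  ste <- length(schema_ste_predictors(schema))
  list(total = ste + length(schema$clinical_numeric) +
         length(schema$clinical_binary),
       ste = ste)
}

#' @export
print.chd_schema <- function(x, ...) {
  n <- count_predictors(x)
  cat("<chd_schema> ", n$total, " predictors (", n$ste, " 2D-STE), label '",
      x$label_name, "'\n", sep = "")
  invisible(x)
}

#' Construct a validated feature table
#'
#' The universal data container of the pipeline: an ordered subject
#' identifier vector, a numeric subjects-by-features matrix, and a binary
#' outcome vector (1 = CHD positive). When a schema is supplied the table
#' is validated against it: all declared predictors must be present
#' (columns are reordered to canonical order), binary clinical columns must
#' be coded 0/1, and missing values are rejected rather than imputed.
#'
#' @param features numeric matrix or data frame (subjects x features) with
#'   column names.
#' @param labels binary vector (0/1), one per subject.
#' @param subject_ids optional unique identifiers; defaults to
#'   `S0001, S0002, ...`.
#' @param schema optional `chd_schema` to validate against. Tables without
#'   a schema (e.g. PCA-reduced tables) only undergo structural checks.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, labels, subject_ids = NULL, schema = NULL) {
  features <- as.matrix(features)
  rownames(features) <- NULL
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) stop("feature columns must be named")
  n <- nrow(features)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n)
    stop("subject_ids length (", length(subject_ids),
         ") does not match row count (", n, ")")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id: ",
         subject_ids[duplicated(subject_ids)][1L])
  if (length(labels) != n)
    stop("labels length (", length(labels),
         ") does not match row count (", n, ")")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must contain only 0 and 1")
  if (!is.numeric(features)) stop("feature matrix must be numeric")

  tab <- structure(list(subject_ids = subject_ids, features = features,
                        labels = labels, schema = schema),
                   class = "feature_table")
  if (!is.null(schema)) tab <- validate_feature_table(tab, schema)
  tab
}

#' Validate a feature table against a schema
#'
#' @param table a `feature_table`.
#' @param schema a `chd_schema`; defaults to the table's own schema.
#' @return The table, with predictor columns reordered to canonical order
#'   and the schema attached.
#' @export
validate_feature_table <- function(table, schema = table$schema) {
  stopifnot(inherits(table, "feature_table"), inherits(schema, "chd_schema"))
  wanted <- schema_predictors(schema)
  missing <- setdiff(wanted, colnames(table$features))
  if (length(missing) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  feats <- table$features[, wanted, drop = FALSE]
  if (anyNA(feats)) {
    bad <- which(is.na(feats), arr.ind = TRUE)[1L, ]
    stop("missing value at subject '", table$subject_ids[bad[1L]],
         "', column '", wanted[bad[2L]], "' (missing values are rejected, ",
         "not imputed)")
  }
  for (col in schema$clinical_binary) {
    if (!all(feats[, col] %in% c(0, 1)))
      stop("binary clinical column '", col, "' contains values other than 0/1")
  }
  table$features <- feats
  table$schema <- schema
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$subject_ids), " subjects x ",
      ncol(x$features), " features; ", sum(x$labels), " positive / ",
      sum(x$labels == 0L), " negative\n", sep = "")
  invisible(x)
}

#' @export
`[.feature_table` <- function(x, i, ...) {
  structure(list(subject_ids = x$subject_ids[i],
                 features = x$features[i, , drop = FALSE],
                 labels = x$labels[i], schema = x$schema),
            class = "feature_table")
}

#' Restrict a feature table to a subset of feature columns
#'
#' Drops the schema binding (the reduced table no longer conforms to the
#' full 71-predictor schema).
#'
#' @param table a `feature_table`.
#' @param keep character vector of column names to retain.
#' @return A `feature_table` without schema.
#' @export
select_features <- function(table, keep) {
  missing <- setdiff(keep, colnames(table$features))
  if (length(missing) > 0)
    stop("feature(s) not present: ", paste(missing, collapse = ", "))
  structure(list(subject_ids = table$subject_ids,
                 features = table$features[, keep, drop = FALSE],
                 labels = table$labels, schema = NULL),
            class = "feature_table")
}

.norm_binary <- function(x, col) {
  if (is.numeric(x)) return(x)
  up <- toupper(trimws(as.character(x)))
  map <- c("Y" = 1, "N" = 0, "YES" = 1, "NO" = 0, "M" = 1, "F" = 0,
           "1" = 1, "0" = 0, "TRUE" = 1, "FALSE" = 0)
  out <- unname(map[up])
  if (anyNA(out) & !anyNA(x))
    stop("cannot interpret value '", x[which(is.na(out))[1L]],
         "' in binary column '", col, "' (expected 0/1, Y/N or M/F)")
  out
}

#' Read a feature table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first CSV with `.` as decimal
#' separator and validates it against a schema. Binary clinical columns and
#' the label accept `Y`/`N` and `M`/`F` codings (case-insensitive) and are
#' normalized to 1/0 (`M` -> 1, `F` -> 0, `Y` -> 1, `N` -> 0). Vendor or
#' study-specific headers are bound to the canonical names through
#' `column_map`.
#'
#' @param path CSV file path.
#' @param schema a `chd_schema` (default: the full 71-predictor schema).
#' @param column_map optional named character vector mapping canonical names
#'   (names) to the CSV's column headers (values), e.g.
#'   `c(PSS_seg01 = "pss1", CHD = "outcome")`.
#' @param id_col optional name of a subject-id column; when absent, ids are
#'   generated.
#' @return A validated `feature_table`.
#' @export
read_feature_table <- function(path, schema = feature_schema(),
                               column_map = NULL, id_col = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0)
      stop("column_map refers to absent CSV column(s): ",
           paste(missing_src, collapse = ", "))
    names(df)[match(unname(column_map), names(df))] <- names(column_map)
  }
  lbl <- schema$label_name
  if (!lbl %in% names(df))
    stop("schema error: missing required column(s): ", lbl)
  wanted <- schema_predictors(schema)
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))

  ids <- if (!is.null(id_col)) {
    if (!id_col %in% names(df)) stop("id column '", id_col, "' not found")
    as.character(df[[id_col]])
  } else NULL

  for (col in c(schema$clinical_binary, lbl))
    df[[col]] <- .norm_binary(df[[col]], col)

  numeric_cols <- c(schema_ste_predictors(schema), schema$clinical_numeric)
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad) > 0)
        stop("parse error: non-numeric value '", v[bad[1L]], "' at row ",
             bad[1L], ", column '", col, "'")
      df[[col]] <- parsed
    }
  }
  feature_table(as.matrix(df[, wanted, drop = FALSE]), df[[lbl]],
                subject_ids = ids, schema = schema)
}

#' Write a feature table to CSV
#'
#' Numeric cells are written with 17 significant digits (`%.17g`) so that a
#' write -> read round trip reproduces the doubles bit-exactly.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @param id_col name for the subject-id column, or `NULL` to omit it.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_col = "subject_id") {
  feats <- table$features
  out <- as.data.frame(lapply(seq_len(ncol(feats)), function(j) {
    v <- feats[, j]
    if (all(v == round(v))) format(v, scientific = FALSE, trim = TRUE)
    else sprintf("%.17g", v)
  }), col.names = colnames(feats), check.names = FALSE,
  stringsAsFactors = FALSE)
  lbl <- if (!is.null(table$schema)) table$schema$label_name else "CHD"
  out[[lbl]] <- table$labels
  if (!is.null(id_col)) out <- cbind(stats::setNames(
    data.frame(table$subject_ids, stringsAsFactors = FALSE), id_col), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-class cohort summary
#'
#' Mean and standard deviation (n-1 denominator) of each numeric feature
#' and the per-class proportion of each binary clinical feature, by CHD
#' status, in the style of a clinical baseline-characteristics table.
#'
#' @param table a schema-bound `feature_table`.
#' @return An object of class `cohort_summary` with components `counts`,
#'   `numeric` and `binary`.
#' @export
summarize_cohort <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  schema <- table$schema
  if (is.null(schema)) stop("summarize_cohort needs a schema-bound table")
  pos <- table$labels == 1L
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop("both classes must contain at least one subject")
  num_cols <- c(schema_ste_predictors(schema), schema$clinical_numeric)
  bin_cols <- schema$clinical_binary
  f <- table$features
  numeric <- data.frame(
    feature = num_cols,
    mean_pos = colMeans(f[pos, num_cols, drop = FALSE]),
    sd_pos = apply(f[pos, num_cols, drop = FALSE], 2, stats::sd),
    mean_neg = colMeans(f[!pos, num_cols, drop = FALSE]),
    sd_neg = apply(f[!pos, num_cols, drop = FALSE], 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  binary <- data.frame(
    feature = bin_cols,
    prop_pos = if (length(bin_cols)) colMeans(f[pos, bin_cols, drop = FALSE])
               else numeric(0),
    prop_neg = if (length(bin_cols)) colMeans(f[!pos, bin_cols, drop = FALSE])
               else numeric(0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = c(positive = sum(pos), negative = sum(!pos)),
                 numeric = numeric, binary = binary),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$counts["positive"], " CHD positive / ",
      x$counts["negative"], " negative\n", sep = "")
  cl <- x$numeric[x$numeric$feature == "age", , drop = FALSE]
  if (nrow(cl)) {
    cat(sprintf("  age: %.2f +/- %.2f (pos) vs %.2f +/- %.2f (neg)\n",
                cl$mean_pos, cl$sd_pos, cl$mean_neg, cl$sd_neg))
  }
  if (nrow(x$binary)) {
    for (i in seq_len(nrow(x$binary)))
      cat(sprintf("  %s: %.1f%% vs %.1f%%\n", x$binary$feature[i],
                  100 * x$binary$prop_pos[i], 100 * x$binary$prop_neg[i]))
  }
  invisible(x)
}
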