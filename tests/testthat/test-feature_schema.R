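test_that("default schema enumerates 71 predictors, 64 of them 2D-STE", {
  sch <- feature_schema()
  n <- count_predictors(sch)
  expect_equal(n$total, 71)
  expect_equal(n$ste, 64)
  # totals equal the sum of declared block sizes, not a constant
  expect_equal(n$ste, sum(lengths(sch$ste_blocks)) + length(sch$radial_gs) +
                 length(sch$glps) + length(sch$psd))
  expect_equal(lengths(sch$ste_blocks), c(PSS = 17L, SSR = 17L, TP = 17L))
  expect_false(anyDuplicated(schema_predictors(sch)) > 0)
})

test_that("restricted and empty schemas count from their own blocks", {
  glps <- count_predictors(feature_schema(include = "GLPS"))
  expect_equal(glps$total, 3)
  expect_equal(glps$ste, 3)
  empty <- count_predictors(feature_schema(include = character(0)))
  expect_equal(empty$total, 0)
  expect_equal(empty$ste, 0)
})

test_that("write -> read round trip preserves values bit-exactly", {
  tab <- test_cohort(20, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path, feature_schema(), id_col = "subject_id")
  expect_identical(back$features, tab$features)
  expect_identical(back$labels, tab$labels)
  expect_identical(back$subject_ids, tab$subject_ids)
})

test_that("missing required columns are reported by name", {
  tab <- test_cohort(10, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(write_feature_table(tab, path))
  df$smoke <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_feature_table(path), "smoke")
})

test_that("Y/N and M/F codings are normalized to 1/0 on read", {
  tab <- test_cohort(10, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(write_feature_table(tab, path),
                        stringsAsFactors = FALSE)
  df$gender <- ifelse(df$gender == 1, "M", "F")
  df$smoke <- ifelse(df$smoke == 1, "Y", "N")
  df$CHD <- ifelse(df$CHD == 1, "y", "n")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_feature_table(path, id_col = "subject_id")
  expect_identical(back$features[, "gender"], tab$features[, "gender"])
  expect_identical(back$features[, "smoke"], tab$features[, "smoke"])
  expect_identical(back$labels, tab$labels)
})

test_that("column_map binds arbitrary CSV headers to the canonical schema", {
  tab <- test_cohort(8, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(write_feature_table(tab, path))
  names(df)[names(df) == "PSS_seg01"] <- "pss.basal.anterior"
  names(df)[names(df) == "CHD"] <- "outcome"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_feature_table(path), "missing required column")
  back <- read_feature_table(
    path, feature_schema(),
    column_map = c(PSS_seg01 = "pss.basal.anterior", CHD = "outcome"))
  expect_equal(back$features[, "PSS_seg01"], tab$features[, "PSS_seg01"],
               tolerance = 1e-12)
})

test_that("structural defects are rejected with informative errors", {
  tab <- test_cohort(10, seed = 15)
  # duplicate subject id
  expect_error(feature_table(tab$features, tab$labels,
                             subject_ids = rep("A", 10)),
               "duplicate subject id")
  # missing value is a validation error, not imputed
  f2 <- tab$features
  f2[3, "GLPS_MID"] <- NA
  expect_error(feature_table(f2, tab$labels, schema = feature_schema()),
               "missing value")
  # non-binary clinical coding
  f3 <- tab$features
  f3[1, "smoke"] <- 2
  expect_error(feature_table(f3, tab$labels, schema = feature_schema()),
               "smoke")
  # non-numeric cell in a numeric column reports row and column
  path <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(write_feature_table(tab, path),
                        stringsAsFactors = FALSE)
  df$age <- as.character(df$age)
  df$age[4] <- "sixty"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_feature_table(path), "row 4.*age")
})

test_that("validation reorders columns to canonical schema order", {
  tab <- test_cohort(12, seed = 16)
  shuffled <- tab$features[, sample(ncol(tab$features))]
  back <- feature_table(shuffled, tab$labels, schema = feature_schema())
  expect_identical(colnames(back$features),
                   schema_predictors(feature_schema()))
  expect_identical(back$features, tab$features[, colnames(back$features)])
})

test_that("cohort summary computes per-class moments and proportions", {
  sch <- feature_schema()
  tab <- test_cohort(30, seed = 17)
  s <- summarize_cohort(tab)
  pos <- tab$labels == 1
  expect_equal(s$counts[["positive"]], sum(pos))
  expect_equal(s$numeric$mean_pos[s$numeric$feature == "age"],
               mean(tab$features[pos, "age"]))
  expect_equal(s$numeric$sd_neg[s$numeric$feature == "PSD"],
               stats::sd(tab$features[!pos, "PSD"]))
  expect_equal(s$binary$prop_pos[s$binary$feature == "smoke"],
               mean(tab$features[pos, "smoke"]))

  # hand-checked example: labels 1,1,0,0 with smoke 1,0,1,1
  f <- tab$features[1:4, ]
  f[, "smoke"] <- c(1, 0, 1, 1)
  small <- feature_table(f, c(1, 1, 0, 0), schema = sch)
  s2 <- summarize_cohort(small)
  expect_equal(s2$binary$prop_pos[s2$binary$feature == "smoke"], 0.5)
  expect_equal(s2$binary$prop_neg[s2$binary$feature == "smoke"], 1.0)

  # identical classes give identical per-class summaries
  f4 <- rbind(f, f)
  dup <- feature_table(f4, rep(c(1, 0), each = 4),
                       subject_ids = sprintf("D%02d", 1:8), schema = sch)
  s3 <- summarize_cohort(dup)
  expect_equal(s3$numeric$mean_pos, s3$numeric$mean_neg)
  expect_equal(s3$numeric$sd_pos, s3$numeric$sd_neg)
  expect_equal(s3$binary$prop_pos, s3$binary$prop_neg)

  # single-class table is an error
  expect_error(summarize_cohort(small[1:2]), "both classes")
})
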