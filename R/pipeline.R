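#' Versioned run configuration
#'
#' One document controlling an end-to-end run: data source (synthetic
#' generator parameters or an input CSV), preprocessing options, the
#' classifier roster, the ensemble configuration, the evaluation protocol
#' and the base seed from which every stage seed is derived by a fixed
#' offset. Round-trips through YAML unchanged.
#'
#' @param data either `list(kind = "generate", n_subjects =, prevalence =)`
#'   or `list(kind = "csv", path =)`; generator fields beyond these fall
#'   back to [generator_params()] defaults.
#' @param preprocess list: `pca` one of `"fixed"`, `"elbow"`, `"off"`;
#'   `ttest` one of `"welch"`, `"pooled"`; `alpha` screening threshold.
#' @param models character vector of registry names, or `"retained"` for
#'   the default 14-family roster, or `"all"` for all 19.
#' @param ensemble list of [ensemble_config()] arguments (minus `seed`).
#' @param evaluate list: `methods`, `replicates`, and split fractions
#'   `test_frac`, `val_frac`, `first_val_frac`.
#' @param seed base seed for the whole run.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data = list(kind = "generate", n_subjects = 424,
                                   prevalence = 217 / 424),
                       preprocess = list(pca = "fixed", ttest = "welch",
                                         alpha = 0.05),
                       models = "retained",
                       ensemble = list(L = 14L, K = 10L, threshold = 0.5,
                                       meta_ntree = 500L,
                                       stack_on = "label",
                                       tune_base = TRUE),
                       evaluate = list(methods = c("voting", "stacking",
                                                   "two_step"),
                                       replicates = 5L, test_frac = 0.15,
                                       val_frac = 0.20,
                                       first_val_frac = 0.20),
                       seed = 1L, out_dir = "echostack_run") {
  stopifnot(data$kind %in% c("generate", "csv"))
  stopifnot(preprocess$pca %in% c("fixed", "elbow", "off"),
            preprocess$ttest %in% c("welch", "pooled"))
  structure(list(data = data, preprocess = preprocess, models = models,
                 ensemble = ensemble, evaluate = evaluate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

.resolve_specs <- function(models) {
  reg <- list_registry()
  if (identical(models, "retained")) return(default_ensemble_specs())
  if (identical(models, "all")) return(reg)
  missing <- setdiff(models, names(reg))
  if (length(missing) > 0)
    stop("unknown model(s): ", paste(missing, collapse = ", "))
  reg[models]
}

#' Run the full pipeline from a configuration
#'
#' Stages: (1) generate or read the cohort; (2) draw the stratified split
#' plan; (3) univariate t-test screen (descriptive report); (4) block PCA
#' reduction fitted on the training pool; (5) fit the two-step stacking
#' model on the plan and write per-subject test-set predictions; (6) run
#' the replicated method comparison. All stage outputs are written under
#' `config$out_dir` together with a manifest (config snapshot, artifact
#' checksums, per-stage wall times, package version). A rerun from the
#' same configuration reproduces identical CSV/JSON outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]
  times <- c()
  stamp <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    times[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  paths <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    paths <<- c(paths, p)
    p
  }

  # stage 1: data
  schema <- feature_schema()
  if (config$data$kind == "generate") {
    gp_args <- config$data[setdiff(names(config$data), "kind")]
    gp_args$seed <- config$seed
    params <- do.call(generator_params, gp_args)
    table <- generate_cohort(params)
    write_feature_table(table, out("cohort.csv"))
    say("generated ", length(table$labels), " subjects (",
        sum(table$labels), " positive)")
  } else {
    table <- read_feature_table(config$data$path, schema)
    say("read ", length(table$labels), " subjects from ", config$data$path)
  }
  stamp("data")

  # stage 2: split plan (seed offset 1)
  ev <- config$evaluate
  ens <- config$ensemble
  plan <- make_split_plan(table$labels, test_frac = ev$test_frac,
                          val_frac = ev$val_frac,
                          first_val_frac = ev$first_val_frac,
                          K = ens$K, seed = config$seed + 1L)
  split_plan_to_json(plan, out("split_plan.json"))
  stamp("split")

  # stage 3: t-test screen (descriptive)
  screen <- ttest_screen(table, alpha = config$preprocess$alpha,
                         var_equal = config$preprocess$ttest == "pooled")
  utils::write.csv(as.data.frame(screen), out("ttest_screen.csv"),
                   row.names = FALSE)
  stamp("screen")

  # stage 4: reduction
  tab_r <- if (config$preprocess$pca == "off") table else
    apply_reduction(table, fit_default_pca(table, plan$train_pool_idx,
                                           rule = config$preprocess$pca))
  stamp("reduce")

  # stage 5: train + predict (seed offset 2)
  specs <- .resolve_specs(config$models)
  cfg <- do.call(ensemble_config,
                 c(ens[setdiff(names(ens), "seed")],
                   list(seed = config$seed + 2L)))
  model <- fit_two_step(specs, tab_r, plan, cfg)
  pr <- predict_two_step(model, tab_r[plan$test_idx])
  pred <- data.frame(subject_id = table$subject_ids[plan$test_idx],
                     truth = table$labels[plan$test_idx],
                     label = pr$label, score = pr$score)
  utils::write.csv(pred, out("test_predictions.csv"), row.names = FALSE)
  say("two-step model: test accuracy ",
      round(mean(pred$label == pred$truth), 3))
  stamp("train")

  # stage 6: replicated evaluation (seed offset 3)
  report <- run_replicates(table, methods = ev$methods, config = cfg,
                           R = ev$replicates, base_seed = config$seed + 3L,
                           specs = specs,
                           pca = config$preprocess$pca != "off",
                           test_frac = ev$test_frac, val_frac = ev$val_frac,
                           first_val_frac = ev$first_val_frac)
  jsonlite::write_json(list(summary = report$summary,
                            replicates = lapply(report$replicates,
                                                as.data.frame)),
                       out("evaluation.json"), dataframe = "columns",
                       digits = NA)
  stamp("evaluate")

  manifest <- list(
    package_version = as.character(utils::packageVersion("echostack")),
    config = unclass(config),
    artifacts = as.list(tools::md5sum(paths)),
    wall_time_s = as.list(times))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("manifest written to ", file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
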