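#' Validate a pipeline configuration
#'
#' Schema-checks a YAML pipeline config (or an already-parsed list) without
#' side effects. Unknown top-level keys produce warnings, violations
#' produce errors; both are returned, nothing is thrown.
#'
#' @param config Path to a YAML file or a named list.
#' @return List of class `config_report`: `config` (parsed), `errors`,
#'   `warnings`; valid iff `errors` is empty.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      return(structure(list(config = NULL,
                            errors = paste("unreadable YAML:",
                                           conditionMessage(e)),
                            warnings = character(0)),
                       class = "config_report")))
    if (inherits(config, "config_report")) return(config)
  }
  errors <- character(0); warnings <- character(0)
  known <- c("seed", "output", "bin_size", "assembly", "bins", "counts",
             "metadata", "simulate", "caller", "classifier", "gc_span",
             "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warnings <- c(warnings, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  if (is.null(config$seed)) errors <- c(errors, "seed is required")
  bs <- config$bin_size
  if (!is.null(bs) && (!is.numeric(bs) || bs <= 0))
    errors <- c(errors, "bin_size must be a positive number")
  sim <- isTRUE(config$simulate$enabled) || !is.null(config$simulate$preset)
  if (!sim) {
    if (is.null(config$counts))
      errors <- c(errors, "either simulate or a counts table is required")
    if (is.null(config$metadata))
      errors <- c(errors, "metadata is required when not simulating")
    for (f in c("counts", "metadata", "bins")) {
      p <- config[[f]]
      if (!is.null(p) && !file.exists(p))
        errors <- c(errors, paste0(f, " path does not exist: ", p))
    }
  }
  zt <- config$caller$z_threshold
  if (!is.null(zt) && (!is.numeric(zt) || zt <= 0))
    errors <- c(errors, "caller z_threshold must be > 0")
  structure(list(config = config, errors = errors, warnings = warnings),
            class = "config_report")
}

#' Run the whole analysis as one pipeline
#'
#' Stages, in order: obtain counts (simulate a cohort, or load a counts
#' table + metadata), GC-correct, aggregate to arm fractions, fit the
#' control reference panel, z-score (leave-one-out for controls), call arms
#' at the configured threshold, evaluate the cohort, then train/evaluate
#' the boosted classifier (split, top-k selection, test ROC/AUC,
#' cross-validation, attributions). All artifacts are written under the
#' output directory together with a manifest (input checksums, seed,
#' package version). Any stage failure halts with a stage-named error.
#'
#' @param config Path to YAML or list (see
#'   [validate_pipeline_config()]).
#' @param output Output directory; overrides `config$output`.
#' @return Invisibly, a list with the main in-memory results (`calls`,
#'   `eval`, `classifier`) and the output path.
#' @export
run_pipeline <- function(config, output = NULL) {
  rep <- validate_pipeline_config(config)
  if (length(rep$errors))
    stop("config validation failed: ", paste(rep$errors, collapse = "; "),
         call. = FALSE)
  for (w in rep$warnings) warning(w, call. = FALSE)
  cfg <- rep$config
  out <- output %||% cfg$output %||% stop("no output directory given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[armcnv] %-12s %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  inputs <- character(0)

  # --- counts + metadata -------------------------------------------------
  if (isTRUE(cfg$simulate$enabled) || !is.null(cfg$simulate$preset)) {
    sim <- stage("simulate", {
      preset <- cfg$simulate$preset %||% "default"
      scfg <- switch(preset,
        default   = paper_sim_config(separable = FALSE, seed = seed),
        separable = paper_sim_config(separable = TRUE, seed = seed),
        stop("unknown simulate preset: ", preset))
      if (!is.null(cfg$simulate$n_cases)) scfg$n_cases <- cfg$simulate$n_cases
      if (!is.null(cfg$simulate$n_controls))
        scfg$n_controls <- cfg$simulate$n_controls
      if (!is.null(cfg$simulate$reads_per_sample))
        scfg$reads_per_sample <- cfg$simulate$reads_per_sample
      grid <- if (!is.null(cfg$bins)) read_bin_bed(cfg$bins)
              else build_bin_grid(scfg$arms, cfg$bin_size %||% 1e5)
      if (all(is.na(grid$gc)))
        grid <- annotate_gc_synthetic(grid, seed = seed)
      list(cohort = simulate_cohort(scfg, grid), grid = grid)
    })
    grid <- sim$grid
    counts <- sim$cohort$counts
    meta <- sim$cohort$meta
    write_cohort(sim$cohort, file.path(out, "simulated"))
  } else {
    grid <- stage("bins", read_bin_bed(cfg$bins))
    counts <- stage("counts", read_counts_table(cfg$counts, grid))
    meta <- stage("metadata", utils::read.csv(cfg$metadata,
                                              stringsAsFactors = FALSE))
    inputs <- c(cfg$bins, cfg$counts, cfg$metadata)
  }

  # --- correction, z-scores, calls --------------------------------------
  corrected <- stage("gc-correct",
                     gc_correct(counts, grid, span = cfg$gc_span %||% 0.3))
  fractions <- stage("arm-fractions", arm_fractions(corrected, grid))
  ctrl_ids <- meta$sample_id[meta$group == "control"]
  panel <- stage("reference", fit_reference(fractions[ctrl_ids, , drop = FALSE]))
  loo <- cfg$caller$leave_one_out %||% TRUE
  z <- stage("z-scores", z_scores(fractions, panel, control_ids = ctrl_ids,
                                  leave_one_out = loo))
  calls <- stage("call", call_arms(z, cfg$caller$z_threshold %||% 2.96))
  eval <- stage("evaluate", evaluate_cohort(calls, meta))
  prev <- arm_prevalence(calls, meta)
  write_callset(calls, file.path(out, "calls"))
  export_heatmap(calls, file.path(out, "heatmap.tsv"))
  utils::write.table(prev, file.path(out, "prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sensitivity = eval$sensitivity,
                            specificity = eval$specificity,
                            counts = as.list(eval$counts),
                            positives_by_stage = as.list(eval$positives_by_stage)),
                       file.path(out, "evaluation.json"), auto_unbox = TRUE)

  # --- classifier --------------------------------------------------------
  clf <- stage("classify", {
    ccfg <- cfg$classifier %||% list()
    fm <- assemble_features(z, meta)
    params <- xgb_params(
      max_depth = ccfg$max_depth %||% 3, lambda = ccfg$lambda %||% 1,
      eta = ccfg$eta %||% 0.1, nrounds = ccfg$nrounds %||% 100)
    split <- split_cohort(fm, ccfg$train_per_class %||% 28, seed = seed)
    full <- train_classifier(subset_fm(fm, split$train_ids), params, seed)
    sel <- select_and_refit(subset_fm(fm, split$train_ids), full,
                            k = ccfg$k_features %||% 6)
    fm_sel <- assemble_features(z, meta, features = sel$features)
    test <- subset_fm(fm_sel, split$test_ids)
    probs <- predict_classifier(sel$model, test)
    roc <- roc_auc(probs, test$y)
    cv <- cross_validate(fm_sel, k = ccfg$cv_folds %||% 5, seed = seed,
                         params = params)
    shap <- explain_model(sel$model, fm_sel)
    list(split = split, selection = sel, test_roc = roc,
         test_metrics = classification_metrics(probs, test$y), cv = cv,
         shap = shap)
  })
  utils::write.table(data.frame(clf$selection$ranking),
                     file.path(out, "feature_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(fpr = clf$test_roc$fpr, tpr = clf$test_roc$tpr),
                     file.path(out, "test_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(clf$shap$shap),
                                base = clf$shap$base, clf$shap$shap,
                                check.names = FALSE),
                     file.path(out, "shap.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  xgboost::xgb.dump(clf$selection$model$booster,
                    fname = file.path(out, "model_dump.txt"),
                    with_stats = TRUE)
  jsonlite::write_json(list(
    selected_features = clf$selection$features,
    test_auc = clf$test_roc$auc,
    test_sensitivity = unname(clf$test_metrics["sensitivity"]),
    test_specificity = unname(clf$test_metrics["specificity"]),
    cv_auc = clf$cv$auc, cv_mean_auc = clf$cv$mean_auc,
    hyperparameters = clf$selection$model$params, seed = seed),
    file.path(out, "classifier_report.json"), auto_unbox = TRUE, digits = NA)

  # --- manifest ----------------------------------------------------------
  arts <- list.files(out, recursive = TRUE, full.names = TRUE)
  arts <- setdiff(arts, file.path(out, "manifest.json"))
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("armcnv")),
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
      else list(),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(arts)),
                                        substring(arts, nchar(out) + 2))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(calls = calls, eval = eval, classifier = clf, output = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
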