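#' End-to-end pipeline run configuration
#'
#' Collects every tunable of a full run: the cohort source (a
#' [cohort_spec()] to simulate, or a tidy cohort CSV path), the progression
#' scenario, the model ids to evaluate, cross-validation parameters and the
#' master seed. All paper-unstated parameters surface here with defaults.
#'
#' @param cohort A `cohort_spec`, or a path to a cohort CSV.
#' @param scenario Scenario id 1--4.
#' @param models Integer vector of model ids (subset of 1..18).
#' @param reference_model Model id against which ROC comparisons are run
#'   (default 5, the clinical reference; skipped if not in `models`).
#' @param folds,repeats Cross-validation shape.
#' @param selection `"fold"` (leak-free, default), `"pre"` (selection
#'   before CV, the published procedure) or `"none"`.
#' @param compartments Optional texture-compartment subset.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort, scenario = 2L, models = c(5L, 15L),
                       reference_model = 5L, folds = 10L, repeats = 50L,
                       selection = "fold", compartments = NULL,
                       seed = 1L, out_dir = NULL) {
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort file not found: ", cohort)
  if (!all(models %in% 1:18)) stop("models must be a subset of 1..18")
  if (!scenario %in% 1:4) stop("scenario must be in 1..4")
  structure(list(cohort = cohort, scenario = as.integer(scenario),
                 models = as.integer(models),
                 reference_model = as.integer(reference_model),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 selection = selection, compartments = compartments,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full progression-prediction pipeline
#'
#' Simulates or loads the cohort, builds the scenario analysis dataset,
#' cross-validates every requested model, compares each model's ROC curve
#' against the reference model, and (when `out_dir` is set) writes
#' `results.json`, `consort.json`, `selection_map.csv` and a `manifest.json`
#' recording the configuration and seeds for exact re-runs.
#'
#' @param config A `run_config`.
#' @return List (class `koa_run`): `dataset`, `consort`, `cv` (named list
#'   of `koa_cv`), `comparisons` (vs the reference model), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (is.character(config$cohort)) {
    if (!file.exists(config$cohort))
      stop("cohort file not found: ", config$cohort)
    read_cohort(config$cohort)
  } else if (inherits(config$cohort, "cohort_spec")) {
    simulate_cohort(config$cohort)
  } else config$cohort

  dataset <- build_analysis_dataset(cohort, config$scenario)
  cv <- list()
  for (id in config$models) {
    cv[[as.character(id)]] <- repeated_cv(
      model_spec(id), dataset, folds = config$folds,
      repeats = config$repeats, seed = config$seed,
      selection = config$selection, compartments = config$compartments)
  }
  comparisons <- list()
  ref <- as.character(config$reference_model)
  if (ref %in% names(cv)) {
    for (id in setdiff(names(cv), ref))
      comparisons[[paste0(id, "_vs_", ref)]] <-
        compare_roc(cv[[id]], cv[[ref]])
  }
  run <- structure(list(dataset = dataset,
                        consort = consort_counts(dataset),
                        cv = cv, comparisons = comparisons,
                        config = config),
                   class = "koa_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

run_results_list <- function(run) {
  fmt <- function(cv) list(
    model = cv$spec$id, label = cv$spec$label, n = cv$n,
    prevalence = cv$prevalence, auc = cv$auc,
    auc_ci_low = cv$auc_ci[1], auc_ci_high = cv$auc_ci[2],
    bacc = cv$bacc, prec = cv$precision, ppv = cv$ppv, npv = cv$npv)
  list(models = lapply(unname(run$cv), fmt),
       comparisons = lapply(unname(run$comparisons), function(cm)
         list(model_a = cm$model_a, model_b = cm$model_b,
              delta_auc = cm$delta_auc, z = cm$z, p_value = cm$p_value)))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  jsonlite::write_json(run_results_list(run),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(run$consort, file.path(out_dir, "consort.json"),
                       auto_unbox = TRUE, digits = NA)
  maps <- do.call(rbind, lapply(names(run$cv), function(id) {
    m <- selection_frequency_map(run$cv[[id]])
    if (nrow(m)) cbind(model = as.integer(id), m) else NULL
  }))
  if (!is.null(maps))
    utils::write.csv(maps, file.path(out_dir, "selection_map.csv"),
                     row.names = FALSE)
  manifest <- list(
    scenario = cfg$scenario, models = cfg$models,
    reference_model = cfg$reference_model, folds = cfg$folds,
    repeats = cfg$repeats, selection = cfg$selection,
    compartments = cfg$compartments, seed = cfg$seed,
    cohort = if (inherits(cfg$cohort, "cohort_spec"))
      cfg$cohort[setdiff(names(cfg$cohort), "signal_descriptors")]
    else if (is.character(cfg$cohort)) cfg$cohort else "in-memory table")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a human-readable report of a pipeline run
#'
#' Prints one metrics row per evaluated model (BACC, PREC, PPV, NPV, AUC
#' with 95% interval, and the DeLong p-value against the reference model)
#' followed by the 16-cell ROI selection-frequency grids per direction and
#' scale. Undefined PPV/NPV (no positive or negative predictions) print as
#' `NaN`.
#'
#' @param run A `koa_run` from [run_pipeline()].
#' @return The report lines, invisibly (also printed).
#' @export
render_report <- function(run) {
  stopifnot(inherits(run, "koa_run"))
  lines <- character()
  emit <- function(...) lines <<- c(lines, sprintf(...))
  emit("Scenario %d: n = %d knees, %d progressors (%.1f%%)",
       run$config$scenario, nrow(run$dataset), sum(run$dataset$outcome),
       100 * mean(run$dataset$outcome))
  if (length(run$cv)) {
    emit("%-3s %-36s %6s %6s %6s %6s %19s %8s",
         "No", "Model", "BACC", "PREC", "PPV", "NPV", "AUC (95% CI)", "p")
    ref <- as.character(run$config$reference_model)
    for (id in names(run$cv)) {
      cv <- run$cv[[id]]
      cmp <- run$comparisons[[paste0(id, "_vs_", ref)]]
      fnum <- function(v) ifelse(is.na(v), "NaN", sprintf("%.3f", v))
      emit("%-3s %-36s %6s %6s %6s %6s %.3f (%.3f-%.3f) %8s",
           id, cv$spec$label, fnum(cv$bacc), fnum(cv$precision),
           fnum(cv$ppv), fnum(cv$npv), cv$auc, cv$auc_ci[1], cv$auc_ci[2],
           if (is.null(cmp)) "-" else sprintf("%.4f", cmp$p_value))
    }
  }
  for (id in names(run$cv)) {
    m <- selection_frequency_map(run$cv[[id]])
    if (!nrow(m)) next
    emit("")
    emit("Model %s stepwise-AIC selection frequency (rows distal, cols lateral->medial):",
         id)
    for (blk in unique(m$block)) for (dir in unique(m$direction))
      for (sc in unique(m$scale)) {
        p <- m[m$block == blk & m$direction == dir & m$scale == sc, ]
        if (!nrow(p)) next
        grid <- matrix(0, 2, 8)
        grid[cbind(p$roi %/% 8 + 1, p$roi %% 8 + 1)] <- p$frequency
        emit("  %s %s %s: %s | %s", blk, dir, sc,
             paste(sprintf("%.2f", grid[1, ]), collapse = " "),
             paste(sprintf("%.2f", grid[2, ]), collapse = " "))
      }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.koa_run <- function(x, ...) {
  render_report(x)
  invisible(x)
}
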