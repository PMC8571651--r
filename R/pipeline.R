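#' Experiment configuration
#'
#' Describes a full train/test classification experiment: a labeled training
#' cohort, named held-out testing cohorts, the feature modes to compare, the
#' preprocessing and peak-fitting settings, the hyperparameter grid with its
#' randomized-search budget, and the CV scheme.
#'
#' Cohorts may be given as in-memory `spectra_set` objects (raw,
#' summed-accumulation scale) or as paths to spectral-matrix CSVs; paths are
#' validated before any computation. Give metadata paths as
#' `list(path, meta_path)`.
#'
#' @param task experiment name.
#' @param training raw training cohort (`spectra_set`, path, or
#'   `list(path, meta_path)`).
#' @param testing named list of raw testing cohorts (same forms).
#' @param feature_modes character subset of
#'   `c("intensity", "peak", "combined")`.
#' @param preprocess a [preprocess_config()].
#' @param peak_opts peak-fitting options (see [fit_mode_model()]).
#' @param grid a [default_hyper_grid()]-style list.
#' @param budget randomized grid-search budget.
#' @param scheme CV scheme list (`folds`, `repeats`, `grouped`).
#' @param positive positive-class label (default: second sorted label).
#' @param threshold_policy `"per_roc"` (default) re-derives the operating
#'   threshold on each testing ROC; `"training"` carries the training-ROC
#'   threshold over.
#' @param seed integer master seed; recorded in every output.
#' @param out_dir optional output directory for reports and artifacts.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(task, training, testing = list(),
                              feature_modes = c("intensity", "peak", "combined"),
                              preprocess = preprocess_config(),
                              peak_opts = NULL,
                              grid = default_hyper_grid(), budget = 50L,
                              scheme = list(folds = 5L, repeats = 5L),
                              positive = NULL,
                              threshold_policy = c("per_roc", "training"),
                              seed = 1L, out_dir = NULL) {
  feature_modes <- match.arg(feature_modes, several.ok = TRUE)
  threshold_policy <- match.arg(threshold_policy)
  check_cohort_ref <- function(ref, name) {
    if (inherits(ref, "spectra_set")) return(invisible())
    paths <- if (is.character(ref)) ref else unlist(ref)
    for (p in paths)
      if (!file.exists(p))
        stop("configuration error: ", name, " file not found: ", p)
  }
  check_cohort_ref(training, "training")
  for (nm in names(testing)) check_cohort_ref(testing[[nm]], nm)
  structure(list(task = task, training = training, testing = testing,
                 feature_modes = feature_modes, preprocess = preprocess,
                 peak_opts = peak_opts, grid = grid,
                 budget = as.integer(budget), scheme = scheme,
                 positive = positive, threshold_policy = threshold_policy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

load_cohort_ref <- function(ref) {
  if (inherits(ref, "spectra_set")) return(ref)
  if (is.character(ref)) return(read_spectra_matrix(ref))
  read_spectra_matrix(ref[[1L]], ref[[2L]])
}

#' Run a full classification experiment
#'
#' Orchestrates the end-to-end workflow: preprocess every cohort, run the
#' cross-validated randomized grid search on the training cohort for each
#' feature mode, refit the winning model on the full training cohort, score
#' the held-out cohorts, and compare the feature modes' ROC curves pairwise
#' (paired DeLong test) on each testing cohort. No information from any
#' testing cohort reaches training: the positivity offset, peak registry,
#' feature rankings and classifier are all fitted on the training cohort
#' alone.
#'
#' @param cfg an [experiment_config()].
#' @return list with `models` (per feature mode), `cv` (per-mode search
#'   summaries), `reports` (per mode x dataset [eval_report()]s), `scores`,
#'   `comparisons` (pairwise DeLong p-values per testing cohort), and `seed`.
#'   When `cfg$out_dir` is set, reports, manifests and a structured log are
#'   written there as JSON/CSV.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  train_raw <- load_cohort_ref(cfg$training)
  test_raw <- lapply(cfg$testing, load_cohort_ref)

  train <- preprocess_cohort(train_raw, cfg$preprocess)
  tests <- lapply(test_raw, preprocess_cohort, cfg = cfg$preprocess)
  labels <- set_labels(train)
  positive <- cfg$positive %||% default_positive(labels)
  opts <- modifyList(default_peak_opts(), cfg$peak_opts %||% list())

  need_peaks <- any(cfg$feature_modes %in% c("peak", "combined"))
  contexts <- cv_fold_contexts(train, within_scheme(cfg$scheme), cfg$seed,
                               need_peaks, opts)
  models <- list(); cv <- list(); reports <- list(); scores <- list()
  for (mode in cfg$feature_modes) {
    search <- cv_grid_search(train, grid = cfg$grid,
                             scheme = within_scheme(cfg$scheme),
                             feature_mode = mode, seed = cfg$seed,
                             budget = cfg$budget, positive = positive,
                             peak_opts = opts, contexts = contexts)
    model <- fit_mode_model(train, search$best, feature_mode = mode,
                            positive = positive, peak_opts = opts,
                            task = cfg$task)
    model$cv_auc <- search$cv_auc
    models[[mode]] <- model
    cv[[mode]] <- search[c("best", "cv_auc", "cv_auc_sd")]

    tr_scores <- predict_scores(model, train)
    scores[[mode]] <- list(training = tr_scores)
    reports[[mode]] <- list(
      training = eval_report(tr_scores, labels,
                             threshold = model$decision_threshold,
                             positive = positive, task = cfg$task,
                             model = mode))
    for (nm in names(tests)) {
      te_scores <- predict_scores(model, tests[[nm]])
      scores[[mode]][[nm]] <- te_scores
      thr <- if (cfg$threshold_policy == "training")
        model$decision_threshold else NULL
      reports[[mode]][[nm]] <- eval_report(te_scores, set_labels(tests[[nm]]),
                                           threshold = thr,
                                           positive = positive,
                                           task = cfg$task, model = mode)
    }
  }

  comparisons <- list()
  if (length(cfg$feature_modes) > 1L) {
    pairs <- utils::combn(cfg$feature_modes, 2, simplify = FALSE)
    for (nm in names(tests)) {
      labs <- set_labels(tests[[nm]])
      comparisons[[nm]] <- lapply(pairs, function(pr) {
        cmp <- compare_rocs(scores[[pr[1]]][[nm]], scores[[pr[2]]][[nm]],
                            labs, positive)
        c(list(model_a = pr[1], model_b = pr[2]), cmp)
      })
    }
  }

  result <- list(task = cfg$task, models = models, cv = cv, reports = reports,
                 scores = scores, comparisons = comparisons, seed = cfg$seed,
                 positive = positive)
  if (!is.null(cfg$out_dir)) write_experiment_outputs(result, cfg)
  result
}

within_scheme <- function(scheme) {
  list(folds = scheme$folds %||% 5L, repeats = scheme$repeats %||% 5L,
       grouped = scheme$grouped %||% TRUE)
}

write_experiment_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # flat metrics table mirroring the standard report layout:
  # one row per (dataset, metric), one column per feature mode
  rows <- list()
  for (mode in names(result$reports))
    for (nm in names(result$reports[[mode]])) {
      r <- result$reports[[mode]][[nm]]
      rows[[length(rows) + 1L]] <-
        data.frame(dataset = nm, model = mode, accuracy = r$accuracy,
                   sensitivity = r$sensitivity, specificity = r$specificity,
                   auc = r$auc, threshold = r$threshold)
    }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
  report <- list(schema_version = "1.0", task = cfg$task, seed = cfg$seed,
                 positive = result$positive,
                 hyperparams = lapply(result$cv, function(x) x$best),
                 cv_auc = lapply(result$cv, function(x) x$cv_auc),
                 metrics = metrics,
                 comparisons = result$comparisons)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (mode in names(result$models)) {
    m <- result$models[[mode]]
    if (!is.null(m$peaks))
      write_peak_registry(m$peaks,
                          file.path(cfg$out_dir,
                                    paste0("peaks_", mode, ".json")))
    manifest <- m$manifest
    manifest$key <- m$feature_keys
    write.csv(manifest,
              file.path(cfg$out_dir, paste0("features_", mode, ".csv")),
              row.names = FALSE)
  }
  invisible(cfg$out_dir)
}
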