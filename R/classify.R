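#' Hyperparameter grid defaults
#'
#' Candidate values for the randomized grid search. The default bounds follow
#' the method's published search space: `k_intensity`, `k_peak` in \[5, 100\],
#' `C_rbf` in \[0.001, 1\], `gamma` in \[0.001, 0.01\], `n_neighbor` in
#' \[0, 10\], `C_intensity`, `C_peak` in \[1e-6, 1e-4\]. Every entry is
#' overridable.
#'
#' @param k_intensity,k_peak integer candidate counts of retained features.
#' @param C_intensity,C_peak candidate L1-SVM strengths.
#' @param C_rbf,gamma candidate RBF-SVM cost and kernel width values.
#' @param n_neighbor candidate redundancy-removal radii (cm^-1).
#' @return a named list of candidate vectors (`hyper_grid`).
#' @export
default_hyper_grid <- function(k_intensity = c(5L, 10L, 20L, 40L, 70L, 100L),
                               k_peak = c(5L, 10L, 20L, 40L, 70L, 100L),
                               C_intensity = 10^seq(-6, -4, length.out = 5),
                               C_peak = 10^seq(-6, -4, length.out = 5),
                               C_rbf = 10^seq(-3, 0, length.out = 7),
                               gamma = 10^seq(-3, -2, length.out = 5),
                               n_neighbor = 0:10) {
  structure(list(k_intensity = as.integer(k_intensity),
                 k_peak = as.integer(k_peak),
                 C_intensity = C_intensity, C_peak = C_peak,
                 C_rbf = C_rbf, gamma = gamma,
                 n_neighbor = as.numeric(n_neighbor)),
            class = "hyper_grid")
}

#' Benchmark hyperparameter grid
#'
#' Grid used for the synthetic benchmark experiments. The L1 strengths extend
#' above 1e-4 and `C_rbf` above 1 because on column-standardized features an
#' objective of the form `||w||_1 + C * sum(loss)` yields the all-zero
#' coefficient vector for very small `C`; the published per-task optima
#' themselves include such larger values (C up to 5, L1 strengths up to 1e-2).
#'
#' @inheritParams default_hyper_grid
#' @return a `hyper_grid` list.
#' @export
benchmark_hyper_grid <- function(k_intensity = c(5L, 10L, 16L, 24L),
                                 k_peak = c(4L, 8L, 12L, 16L),
                                 C_intensity = 10^seq(-3, 0, length.out = 4),
                                 C_peak = 10^seq(-3, 0, length.out = 4),
                                 C_rbf = 10^seq(-2, 1, length.out = 5),
                                 gamma = 10^seq(-3, -1, length.out = 5),
                                 n_neighbor = c(0, 2, 5, 10)) {
  default_hyper_grid(k_intensity, k_peak, C_intensity, C_peak, C_rbf, gamma,
                     n_neighbor)
}

# Randomized sample of `budget` distinct points from the grid product space.
sample_grid <- function(grid, budget, seed) {
  lens <- vapply(grid, length, integer(1))
  total <- prod(lens)
  idx <- if (total <= budget) seq_len(total)
         else with_seed(seed, sort(sample.int(total, budget)))
  # decode mixed-radix indices into one row per grid point
  out <- vector("list", length(grid))
  names(out) <- names(grid)
  rem <- idx - 1L
  for (j in seq_along(grid)) {
    out[[j]] <- grid[[j]][(rem %% lens[j]) + 1L]
    rem <- rem %/% lens[j]
  }
  as.data.frame(out)
}

#' Train an RBF-kernel SVM
#'
#' Maximum-margin classifier with Gaussian kernel `exp(-gamma * ||u - v||^2)`
#' exposing continuous decision scores oriented so that higher means the
#' positive class. Features are taken as-is (`scale = FALSE`); callers
#' standardize columns beforehand.
#'
#' @param x numeric feature matrix.
#' @param y binary class labels.
#' @param C_rbf cost parameter (> 0).
#' @param gamma kernel width parameter (> 0).
#' @param positive the positive-class label.
#' @return an `rbf_svm` list wrapping the fitted e1071 model.
#' @export
train_rbf_svm <- function(x, y, C_rbf, gamma, positive = NULL) {
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("argument error: training labels contain a single class")
  stopifnot(C_rbf > 0, gamma > 0)
  positive <- positive %||% default_positive(y)
  negative <- setdiff(unique(y), positive)[1L]
  yf <- factor(y, levels = c(negative, positive))
  fit <- e1071::svm(x = as.matrix(x), y = yf, kernel = "radial",
                    cost = C_rbf, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, positive = positive, negative = negative),
            class = "rbf_svm")
}

#' Decision scores of a fitted RBF-SVM
#'
#' @param model an `rbf_svm` from [train_rbf_svm()].
#' @param x feature matrix on the training column layout.
#' @return numeric scores, higher favoring the positive class.
#' @export
svm_scores <- function(model, x) {
  pred <- predict(model$fit, as.matrix(x), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lab <- colnames(dv)[1L]
  s <- drop(dv)
  # e1071 orients decision values toward the first class named in the column
  if (startsWith(lab, paste0(model$positive, "/"))) s else -s
}

# ---------------------------------------------------------------------------
# Model fitting for one feature mode on a (training) cohort.

default_peak_opts <- function() {
  list(tolerance = 2, presence_min = 0.5, height_threshold = NULL,
       smooth_window = 7L, snv_axis = "column")
}

#' Fit a classification model for one feature mode
#'
#' Runs the full modeling pipeline on a preprocessed (unshifted) training
#' cohort: positivity shift, consensus peak detection and Gaussian fitting
#' (for modes using peak features), L1-SVM ranking, neighborhood removal (on
#' intensity features), top-k selection, column standardization and RBF-SVM
#' fitting. The operating threshold is the closest-to-corner point of the
#' training ROC.
#'
#' @param set preprocessed `spectra_set` with class labels.
#' @param hp named list/row of hyperparameters (`k_intensity`, `k_peak`,
#'   `C_intensity`, `C_peak`, `C_rbf`, `gamma`, `n_neighbor`).
#' @param feature_mode one of `"intensity"`, `"peak"`, `"combined"`.
#' @param positive positive-class label.
#' @param peak_opts list of peak-fitting options (see the defaults in
#'   `ramanpeaks:::default_peak_opts`).
#' @param task optional task name carried into the model.
#' @return a `trained_model`.
#' @export
fit_mode_model <- function(set, hp, feature_mode = c("combined", "intensity", "peak"),
                           positive = NULL, peak_opts = NULL, task = NULL) {
  feature_mode <- match.arg(feature_mode)
  opts <- modifyList(default_peak_opts(), peak_opts %||% list())
  labels <- set_labels(set)
  if (anyNA(labels)) stop("training set has unlabeled spectra")
  positive <- positive %||% default_positive(labels)
  sp <- shift_positive(set)

  int_sel <- peak_sel <- NULL
  int_rank <- peak_rank <- NULL
  peaks <- NULL
  if (feature_mode %in% c("intensity", "combined")) {
    int_tab <- intensity_features(sp$set)
    int_rank <- rank_features_l1(int_tab, labels, hp$C_intensity)
    int_rank <- remove_neighbors(int_rank, hp$n_neighbor)
    int_rank <- select_top_k(int_rank, min(hp$k_intensity, nrow(int_rank)))
    int_sel <- subset_features(int_tab, int_rank$column)
  }
  if (feature_mode %in% c("peak", "combined")) {
    thr <- opts$height_threshold %||% default_height_threshold(sp$set)
    peaks <- consensus_peaks(sp$set, tolerance = opts$tolerance,
                             presence_min = opts$presence_min,
                             height_threshold = thr,
                             smooth_window = opts$smooth_window)
    if (length(peaks) == 0L) stop("no consensus peaks found in training set")
    ptab <- build_peak_features(sp$set, peaks, tolerance = opts$tolerance,
                                snv_axis = opts$snv_axis,
                                smooth_window = opts$smooth_window)
    peak_rank <- rank_features_l1(ptab, labels, hp$C_peak)
    peak_rank <- select_top_k(peak_rank, min(hp$k_peak, nrow(peak_rank)))
    peak_sel <- subset_features(ptab, peak_rank$column)
  }
  sel <- combine_features(int_sel, peak_sel)
  std <- standardize_columns(sel$values)
  svm <- train_rbf_svm(std$x, labels, hp$C_rbf, hp$gamma, positive)
  scores <- svm_scores(svm, std$x)
  roc <- roc_curve(scores, labels, positive)
  corner <- closest_to_corner_threshold(roc)
  thr_op <- if (is.finite(corner$threshold)) corner$threshold else max(scores)
  structure(list(feature_mode = feature_mode, offset = sp$offset,
                 peaks = peaks, manifest = sel$ids,
                 feature_keys = colnames(sel$values),
                 std = std[c("center", "scale")], svm = svm,
                 hyperparams = as.list(hp), decision_threshold = thr_op,
                 training_auc = roc$auc, positive = positive, task = task,
                 peak_opts = opts, axis = set$axis),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model [%s]%s: %d features, training AUC %.3f>\n",
              x$feature_mode,
              if (!is.null(x$task)) paste0(" ", x$task) else "",
              length(x$feature_keys), x$training_auc))
  invisible(x)
}

#' Score a spectra set with a trained model
#'
#' Applies the stored training offset, rebuilds exactly the features named in
#' the model manifest (intensity bands looked up on the axis; peak features
#' re-fitted against the stored peak registry), standardizes with the stored
#' training statistics and returns RBF-SVM decision scores.
#'
#' @param model a `trained_model`.
#' @param set a preprocessed (unshifted) `spectra_set` on a compatible axis.
#' @return numeric decision scores, one per spectrum, higher = positive class.
#' @export
predict_scores <- function(model, set) {
  stopifnot(inherits(model, "trained_model"), inherits(set, "spectra_set"))
  shifted <- suppressWarnings(apply_offset(set, model$offset))
  blocks <- list()
  ids <- model$manifest
  if (any(ids$kind == "intensity")) {
    pos <- ids$position[ids$kind == "intensity"]
    j <- vapply(pos, function(p) {
      hit <- which(abs(set$axis - p) < 1e-6)
      if (length(hit) == 0L) NA_integer_ else hit[1L]
    }, integer(1))
    if (anyNA(j))
      stop("manifest error: bands absent from this set: ",
           paste(pos[is.na(j)], collapse = ", "), " cm^-1")
    blocks$intensity <- shifted$matrix[, j, drop = FALSE]
  }
  if (any(ids$kind %in% c("height", "width"))) {
    if (is.null(model$peaks)) stop("manifest error: model lacks a peak registry")
    ptab <- build_peak_features(shifted, model$peaks,
                                tolerance = model$peak_opts$tolerance,
                                snv_axis = model$peak_opts$snv_axis,
                                smooth_window = model$peak_opts$smooth_window)
    want <- model$feature_keys[ids$kind %in% c("height", "width")]
    j <- match(want, colnames(ptab$values))
    if (anyNA(j))
      stop("manifest error: peak features unavailable: ",
           paste(want[is.na(j)], collapse = ", "))
    blocks$peak <- ptab$values[, j, drop = FALSE]
  }
  x <- do.call(cbind, blocks)
  colnames(x) <- model$feature_keys
  z <- sweep(sweep(x, 2, model$std$center), 2, model$std$scale, "/")
  scores <- svm_scores(model$svm, z)
  names(scores) <- set$meta$spectrum_id
  scores
}

# ---------------------------------------------------------------------------
# Patient-grouped repeated cross-validation.

# Assign patients (stratified by class) to folds; returns per-spectrum fold
# ids for each repeat.
assign_folds <- function(meta, labels, folds, repeats, seed, grouped = TRUE) {
  unit <- if (grouped) meta$patient_id else meta$spectrum_id
  units <- unique(unit)
  unit_class <- vapply(units, function(u) {
    cls <- labels[unit == u]
    names(sort(table(cls), decreasing = TRUE))[1L]
  }, character(1))
  for (cls in unique(unit_class))
    if (sum(unit_class == cls) < folds)
      stop("scheme error: class '", cls, "' has ",
           sum(unit_class == cls), " ", if (grouped) "patients" else "spectra",
           " but ", folds, " folds requested")
  with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold_of_unit <- setNames(integer(length(units)), units)
      for (cls in unique(unit_class)) {
        members <- sample(units[unit_class == cls])
        fold_of_unit[members] <- rep_len(seq_len(folds), length(members))
      }
      fold_of_unit[unit]
    })
  })
}

# Precompute per-(repeat, fold) training artifacts shared across grid points:
# positivity offset, intensity/peak feature tables and an L1-ranking cache.
cv_fold_contexts <- function(set, scheme, seed, need_peaks, opts) {
  labels <- set_labels(set)
  fold_ids <- assign_folds(set$meta, labels, scheme$folds, scheme$repeats,
                           derive_seed(seed, "folds"),
                           grouped = scheme$grouped %||% TRUE)
  contexts <- list()
  for (r in seq_len(scheme$repeats)) {
    for (f in seq_len(scheme$folds)) {
      val <- which(fold_ids[[r]] == f)
      train <- which(fold_ids[[r]] != f)
      if (length(val) == 0L) next
      train_set <- subset_spectra(set, train)
      val_set <- subset_spectra(set, val)
      sp <- shift_positive(train_set)
      val_shifted <- suppressWarnings(apply_offset(val_set, sp$offset))
      ctx <- list(repeat_id = r, fold = f, train = train, val = val,
                  labels_train = labels[train], labels_val = labels[val],
                  int_train = intensity_features(sp$set),
                  int_val = intensity_features(val_shifted),
                  cache = new.env(parent = emptyenv()))
      if (need_peaks) {
        thr <- opts$height_threshold %||% default_height_threshold(sp$set)
        peaks <- consensus_peaks(sp$set, tolerance = opts$tolerance,
                                 presence_min = opts$presence_min,
                                 height_threshold = thr,
                                 smooth_window = opts$smooth_window)
        if (length(peaks) > 0L) {
          ctx$peak_train <- build_peak_features(sp$set, peaks,
                                                tolerance = opts$tolerance,
                                                snv_axis = opts$snv_axis,
                                                smooth_window = opts$smooth_window)
          ctx$peak_val <- build_peak_features(val_shifted, peaks,
                                              tolerance = opts$tolerance,
                                              snv_axis = opts$snv_axis,
                                              smooth_window = opts$smooth_window)
        }
      }
      contexts[[length(contexts) + 1L]] <- ctx
    }
  }
  contexts
}

cached_ranking <- function(ctx, kind, table, labels, C) {
  key <- paste0(kind, "_", format(C, digits = 12))
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  r <- rank_features_l1(table, labels, C)
  ctx$cache[[key]] <- r
  r
}

# Evaluate one grid point on one fold context; returns validation scores.
score_fold <- function(ctx, hp, feature_mode, positive) {
  int_sel_tr <- int_sel_va <- peak_sel_tr <- peak_sel_va <- NULL
  if (feature_mode %in% c("intensity", "combined")) {
    nn_key <- paste0("int_nn_", format(hp$C_intensity, digits = 12), "_",
                     hp$n_neighbor)
    rk <- ctx$cache[[nn_key]]
    if (is.null(rk)) {
      rk <- cached_ranking(ctx, "int", ctx$int_train, ctx$labels_train,
                           hp$C_intensity)
      rk <- remove_neighbors(rk, hp$n_neighbor)
      ctx$cache[[nn_key]] <- rk
    }
    rk <- select_top_k(rk, min(hp$k_intensity, nrow(rk)))
    int_sel_tr <- ctx$int_train$values[, rk$column, drop = FALSE]
    int_sel_va <- ctx$int_val$values[, rk$column, drop = FALSE]
  }
  if (feature_mode %in% c("peak", "combined")) {
    if (is.null(ctx$peak_train)) return(NULL)
    rk <- cached_ranking(ctx, "peak", ctx$peak_train, ctx$labels_train,
                         hp$C_peak)
    rk <- select_top_k(rk, min(hp$k_peak, nrow(rk)))
    peak_sel_tr <- ctx$peak_train$values[, rk$column, drop = FALSE]
    peak_sel_va <- ctx$peak_val$values[, rk$column, drop = FALSE]
  }
  x_tr <- cbind(int_sel_tr, peak_sel_tr)
  x_va <- cbind(int_sel_va, peak_sel_va)
  std <- standardize_columns(x_tr)
  model <- train_rbf_svm(std$x, ctx$labels_train, hp$C_rbf, hp$gamma, positive)
  z_va <- sweep(sweep(x_va, 2, std$center), 2, std$scale, "/")
  svm_scores(model, z_va)
}

#' Cross-validated randomized grid search
#'
#' Repeated, patient-grouped k-fold cross validation over a randomized sample
#' of the hyperparameter grid. Within every training fold the full modeling
#' pipeline is refit from scratch (positivity offset, consensus peaks where
#' the feature mode uses them, L1 ranking, neighborhood removal, top-k
#' selection, RBF fit); validation AUC is computed on the pooled validation
#' scores of each repeat and averaged across repeats. The grid point with the
#' highest mean AUC wins.
#'
#' @param set preprocessed (unshifted) labeled `spectra_set`.
#' @param grid a [default_hyper_grid()]-style list of candidate values.
#' @param scheme list with `folds` (default 5), `repeats` (default 5),
#'   `grouped` (default `TRUE`, folds partitioned by patient).
#' @param feature_mode `"intensity"`, `"peak"` or `"combined"`.
#' @param seed integer seed controlling folds and grid sampling.
#' @param budget maximum number of grid points evaluated (default 50).
#' @param positive positive-class label.
#' @param peak_opts peak-fitting options (see [fit_mode_model()]).
#' @param contexts optional precomputed fold contexts (internal reuse across
#'   feature modes; must come from the same `set`, `scheme` and `seed`).
#' @return list with `best` (hyperparameter list), `cv_auc`, `cv_auc_sd`,
#'   `results` (per grid point), and `contexts` for reuse.
#' @export
cv_grid_search <- function(set, grid = default_hyper_grid(),
                           scheme = list(folds = 5L, repeats = 5L),
                           feature_mode = c("combined", "intensity", "peak"),
                           seed = 1L, budget = 50L, positive = NULL,
                           peak_opts = NULL, contexts = NULL) {
  feature_mode <- match.arg(feature_mode)
  scheme$folds <- scheme$folds %||% 5L
  scheme$repeats <- scheme$repeats %||% 5L
  labels <- set_labels(set)
  if (anyNA(labels)) stop("cross validation requires labels on every spectrum")
  positive <- positive %||% default_positive(labels)
  opts <- modifyList(default_peak_opts(), peak_opts %||% list())
  need_peaks <- feature_mode != "intensity"
  if (is.null(contexts) ||
      (need_peaks && is.null(contexts[[1]]$peak_train)))
    contexts <- cv_fold_contexts(set, scheme, seed, need_peaks, opts = opts)
  combos <- sample_grid(grid, budget, derive_seed(seed, "grid"))
  n_combo <- nrow(combos)
  mean_auc <- sd_auc <- rep(NA_real_, n_combo)
  for (g in seq_len(n_combo)) {
    hp <- as.list(combos[g, ])
    by_repeat <- split(seq_along(contexts),
                       vapply(contexts, function(c) c$repeat_id, numeric(1)))
    aucs <- vapply(by_repeat, function(ix) {
      scores <- labs <- NULL
      for (i in ix) {
        s <- score_fold(contexts[[i]], hp, feature_mode, positive)
        if (is.null(s)) return(NA_real_)
        scores <- c(scores, s)
        labs <- c(labs, contexts[[i]]$labels_val)
      }
      auc_mw(scores, labs == positive)
    }, numeric(1))
    mean_auc[g] <- mean(aucs)
    sd_auc[g] <- sd(aucs)
  }
  # among grid points tied on CV AUC prefer the most parsimonious model
  # (fewest retained features), then the smoothest kernel, then lowest cost
  top <- which(mean_auc >= max(mean_auc, na.rm = TRUE) - 1e-12)
  best_i <- top[order(combos$k_intensity[top] + combos$k_peak[top],
                      combos$gamma[top], combos$C_rbf[top], top)][1L]
  list(best = as.list(combos[best_i, ]), cv_auc = mean_auc[best_i],
       cv_auc_sd = sd_auc[best_i],
       results = cbind(combos, mean_auc = mean_auc, sd_auc = sd_auc),
       feature_mode = feature_mode, contexts = contexts)
}
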