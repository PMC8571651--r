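blob_data <- function(seed = 1, n = 50, gap = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, gap), n))
  y <- rep(c("neg", "pos"), each = n)
  list(x = x, y = y)
}

test_that("well-separated blobs classify perfectly and deterministically", {
  d <- blob_data()
  m <- train_rbf_svm(d$x, d$y, C_rbf = 1, gamma = 0.1, positive = "pos")
  s <- svm_scores(m, d$x)
  expect_equal(roc_curve(s, d$y, positive = "pos")$auc, 1.0)
  # score orientation: higher score on the positive-class blob
  expect_gt(mean(s[d$y == "pos"]), mean(s[d$y == "neg"]))

  m2 <- train_rbf_svm(d$x, d$y, C_rbf = 1, gamma = 0.1, positive = "pos")
  expect_equal(svm_scores(m2, d$x), s)

  expect_error(train_rbf_svm(d$x, rep("pos", 100), 1, 0.1), "single class")
})

test_that("identical feature rows for both classes give chance-level AUC", {
  x <- matrix(rep(c(1, 2), each = 40), 40)
  y <- rep(c("a", "b"), 20)
  m <- train_rbf_svm(x, y, C_rbf = 1, gamma = 0.1, positive = "b")
  s <- svm_scores(m, x)
  expect_equal(roc_curve(s, y, positive = "b")$auc, 0.5)
})

test_that("fold assignment groups by patient and is class-stratified", {
  coh <- generate_cohort(default_two_class_benchmark("separable", seed = 61L,
                                                     n_patients = 8L))
  pp <- preprocess_cohort(coh$set)
  folds <- ramanpeaks:::assign_folds(pp$meta, set_labels(pp), folds = 4L,
                                     repeats = 3L, seed = 9L)
  for (f in folds) {
    for (k in unique(f)) {
      val_patients <- unique(pp$meta$patient_id[f == k])
      train_patients <- unique(pp$meta$patient_id[f != k])
      expect_length(intersect(val_patients, train_patients), 0L)
    }
  }
  expect_error(
    ramanpeaks:::assign_folds(pp$meta, set_labels(pp), folds = 9L,
                              repeats = 1L, seed = 1L),
    "scheme error")
})

test_that("a one-point grid returns that point with its CV AUC", {
  coh <- generate_cohort(default_two_class_benchmark("separable", seed = 62L,
                                                     n_patients = 6L))
  pp <- preprocess_cohort(coh$set)
  grid <- default_hyper_grid(k_intensity = 10L, k_peak = 8L,
                             C_intensity = 0.1, C_peak = 0.1,
                             C_rbf = 1, gamma = 0.01, n_neighbor = 5)
  out <- cv_grid_search(pp, grid, scheme = list(folds = 3L, repeats = 2L),
                        feature_mode = "intensity", seed = 4L, budget = 10L)
  expect_equal(nrow(out$results), 1L)
  expect_equal(out$best$C_rbf, 1)
  expect_true(out$cv_auc >= 0 && out$cv_auc <= 1)
  expect_equal(out$cv_auc, out$results$mean_auc[1])
})

test_that("the search is reproducible from data, grid and seed", {
  coh <- generate_cohort(default_two_class_benchmark("separable", seed = 63L,
                                                     n_patients = 6L))
  pp <- preprocess_cohort(coh$set)
  run <- function() cv_grid_search(pp, benchmark_hyper_grid(),
                                   scheme = list(folds = 3L, repeats = 2L),
                                   feature_mode = "intensity", seed = 11L,
                                   budget = 6L)
  a <- run(); b <- run()
  expect_equal(a$best, b$best)
  expect_equal(a$results, b$results)
})

test_that("fold-level fitting never sees validation spectra", {
  coh <- generate_cohort(default_two_class_benchmark("separable", seed = 64L,
                                                     n_patients = 6L))
  pp <- preprocess_cohort(coh$set)
  opts <- ramanpeaks:::default_peak_opts()
  scheme <- list(folds = 3L, repeats = 1L, grouped = TRUE)
  ctx1 <- ramanpeaks:::cv_fold_contexts(pp, scheme, 5L, TRUE, opts)

  # scramble every validation spectrum of fold 1 and rebuild
  tampered <- pp
  val_rows <- ctx1[[1]]$val
  tampered$matrix[val_rows, ] <- tampered$matrix[val_rows, ncol(tampered$matrix):1]
  ctx2 <- ramanpeaks:::cv_fold_contexts(tampered, scheme, 5L, TRUE, opts)

  r1 <- ramanpeaks:::cached_ranking(ctx1[[1]], "int", ctx1[[1]]$int_train,
                                    ctx1[[1]]$labels_train, 0.1)
  r2 <- ramanpeaks:::cached_ranking(ctx2[[1]], "int", ctx2[[1]]$int_train,
                                    ctx2[[1]]$labels_train, 0.1)
  expect_equal(r1, r2)
  expect_equal(ctx1[[1]]$peak_train$values, ctx2[[1]]$peak_train$values)
})

test_that("trained models refuse sets lacking manifest bands", {
  coh <- generate_cohort(default_two_class_benchmark("separable", seed = 65L,
                                                     n_patients = 6L))
  pp <- preprocess_cohort(coh$set)
  hp <- list(k_intensity = 10L, k_peak = 8L, C_intensity = 0.1, C_peak = 0.1,
             C_rbf = 1, gamma = 0.01, n_neighbor = 5)
  model <- fit_mode_model(pp, hp, feature_mode = "intensity")
  s1 <- predict_scores(model, pp)
  expect_length(s1, nrow(pp$matrix))

  # scores are invariant to spectrum order
  perm <- rev(seq_len(nrow(pp$matrix)))
  permuted <- spectra_set(pp$axis, pp$matrix[perm, ], pp$meta[perm, ])
  s2 <- predict_scores(model, permuted)
  expect_equal(unname(s2), unname(s1[perm]))

  chopped <- restrict_axis(pp, 700, 800)
  expect_error(predict_scores(model, chopped), "manifest error")
})
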