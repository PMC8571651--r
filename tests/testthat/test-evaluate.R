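test_that("ROC endpoints and extreme orderings behave as defined", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), positive = 1)
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  expect_equal(roc_curve(c(0.2, 0.8), c(1, 0), positive = 1)$auc, 0.0)
  expect_error(roc_curve(c(1, 2), c(1, 1), positive = 1), "both classes")
})

test_that("AUC equals the all-pairs concordance oracle to 1e-12", {
  for (i in 1:5) {
    set.seed(500 + i)
    scores <- round(rnorm(50), 1)  # rounding forces ties
    y <- runif(50) < 0.4
    y[1:2] <- c(TRUE, FALSE)
    r <- roc_curve(scores, ifelse(y, "pos", "neg"), positive = "pos")
    expect_equal(r$auc, brute_auc(scores, y), tolerance = 1e-12)
  }
})

test_that("AUC respects the sign-flip and monotone-transform identities", {
  set.seed(42)
  scores <- rnorm(60)  # tie-free
  y <- ifelse(runif(60) < 0.5, "a", "b")
  a1 <- roc_curve(scores, y, positive = "b")$auc
  a2 <- roc_curve(-scores, y, positive = "b")$auc
  expect_equal(a1 + a2, 1)
  a3 <- roc_curve(exp(2 * scores) + 5, y, positive = "b")$auc
  expect_equal(a1, a3)
})

test_that("the corner threshold minimizes distance with stated tie-breaks", {
  roc <- structure(list(points = data.frame(
    threshold = c(Inf, 0.7, -Inf),
    fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1))), class = "roc_curve")
  got <- closest_to_corner_threshold(roc)
  expect_equal(got$fpr, 0.2); expect_equal(got$tpr, 0.9)
  expect_equal(got$distance, sqrt(0.05))

  # a point at (0, 1) wins outright with distance zero
  perfect <- roc_curve(c(3, 2, 1), c("p", "p", "n"), positive = "p")
  expect_equal(closest_to_corner_threshold(perfect)$distance, 0)

  # equal distances sqrt(0.05): the higher-tpr point wins
  tie <- structure(list(points = data.frame(
    threshold = c(Inf, 0.9, 0.4, -Inf),
    fpr = c(0, 0.1, 0.2, 1), tpr = c(0, 0.8, 0.9, 1))),
    class = "roc_curve")
  got2 <- closest_to_corner_threshold(tie)
  expect_equal(c(got2$fpr, got2$tpr), c(0.2, 0.9))
})

test_that("corner selection equals exhaustive minimization on random curves", {
  for (i in 1:20) {
    set.seed(700 + i)
    scores <- rnorm(40)
    y <- ifelse(runif(40) < 0.5, "x", "y")
    if (length(unique(y)) < 2) next
    roc <- roc_curve(scores, y, positive = "y")
    got <- closest_to_corner_threshold(roc)
    d <- sqrt(roc$points$fpr^2 + (1 - roc$points$tpr)^2)
    expect_equal(got$distance, min(d))
  }
})

test_that("confusion metrics count the table the standard way", {
  m <- confusion_metrics(c(0.9, 0.6, 0.4, 0.1), c(1, 1, 0, 0), 0.5,
                         positive = 1)
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(100, 100, 100))

  m2 <- confusion_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), 0.5,
                          positive = 1)
  expect_equal(c(m2$accuracy, m2$sensitivity, m2$specificity), c(50, 50, 50))
  expect_equal(c(m2$tp, m2$fp, m2$tn, m2$fn), c(1, 1, 1, 1))

  # single-class input flags the undefined rate instead of reporting 0
  m3 <- confusion_metrics(c(0.9, 0.1), c(1, 1), 0.5, positive = 1)
  expect_true(is.na(m3$specificity))
  expect_true(m3$not_applicable[["specificity"]])
})

test_that("identical score vectors compare with AUC difference 0 and p = 1", {
  set.seed(8)
  s <- rnorm(40)
  y <- rep(c("a", "b"), 20)
  out <- compare_rocs(s, s, y, positive = "b")
  expect_equal(out$auc_a, out$auc_b)
  expect_equal(out$p_value, 1)
  expect_error(compare_rocs(s, s[-1], y), "alignment error")
})

test_that("the paired ROC test agrees with the pROC DeLong reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  base <- y + rnorm(n)
  sa <- base + rnorm(n, 0, 0.8)
  sb <- 0.5 * base + rnorm(n, 0, 0.8)
  mine <- compare_rocs(sa, sb, y, positive = 1)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("the paired ROC test agrees with a permutation oracle", {
  set.seed(33)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  base <- 0.8 * y + rnorm(n)
  sa <- base + rnorm(n, 0, 0.7)
  sb <- base + rnorm(n, 0, 0.7)
  got <- compare_rocs(sa, sb, y, positive = 1)

  ypos <- y == 1
  observed <- abs(brute_auc(sa, ypos) - brute_auc(sb, ypos))
  nperm <- 1e5
  swap <- matrix(runif(nperm * n) < 0.5, nperm)
  stat <- vapply(seq_len(nperm), function(k) {
    a <- ifelse(swap[k, ], sb, sa)
    b <- ifelse(swap[k, ], sa, sb)
    ra <- rank(a); rb <- rank(b)  # rank-based AUC, same midrank convention
    npos <- sum(ypos); nneg <- n - npos
    aa <- (sum(ra[ypos]) - npos * (npos + 1) / 2) / (npos * nneg)
    ab <- (sum(rb[ypos]) - npos * (npos + 1) / 2) / (npos * nneg)
    abs(aa - ab)
  }, numeric(1))
  p_perm <- mean(stat >= observed - 1e-12)
  expect_lt(abs(got$p_value - p_perm), 0.02)
})

test_that("evaluation reports use the percent scale and corner default", {
  set.seed(55)
  y <- rep(c("ben", "mal"), each = 20)
  s <- ifelse(y == "mal", 1, 0) + rnorm(40, 0, 0.4)
  rep_ <- eval_report(s, y, positive = "mal", task = "demo", model = "m")
  expect_true(rep_$auc > 50 && rep_$auc <= 100)
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 100)
  roc <- roc_curve(s, y, positive = "mal")
  corner <- closest_to_corner_threshold(roc)
  expect_equal(rep_$threshold, corner$threshold)
})
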