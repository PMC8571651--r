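test_that("candidate detection finds local maxima above the threshold", {
  axis <- seq(800, 1200)
  s <- make_spectrum(axis, peaks = list(c(1, 1000, 10)))
  cand <- detect_candidate_peaks(s, 0.1)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$position, 1000)

  expect_equal(nrow(detect_candidate_peaks(s, 2.0)), 0L)

  s2 <- make_spectrum(axis, peaks = list(c(1, 900, 8), c(0.8, 1000, 8)))
  cand2 <- detect_candidate_peaks(s2, 0.1)
  expect_equal(cand2$position, c(900, 1000))
})

test_that("consensus clustering applies the presence and tolerance rules", {
  axis <- seq(800, 1200)
  # all 10 spectra share a peak at 1000; 4 of 10 carry a decoy at 1100
  sets <- lapply(1:10, function(i) {
    pks <- list(c(1, 1000, 10))
    if (i <= 4) pks <- c(pks, list(c(1, 1100, 10)))
    pks
  })
  set <- make_set(axis, sets)
  pk <- consensus_peaks(set, tolerance = 2, presence_min = 0.5,
                        height_threshold = 0.1)
  expect_length(pk, 1L)
  expect_equal(pk[[1]]$center, 1000)
  expect_equal(pk[[1]]$presence_fraction, 1.0)

  # peaks at 999 vs 1001 merge under a +/-2 cm^-1 tolerance
  sets2 <- c(rep(list(list(c(1, 999, 10))), 5),
             rep(list(list(c(1, 1001, 10))), 5))
  set2 <- make_set(axis, sets2)
  pk2 <- consensus_peaks(set2, tolerance = 2, presence_min = 0.5,
                         height_threshold = 0.1)
  expect_length(pk2, 1L)
  expect_equal(pk2[[1]]$presence_fraction, 1.0)
  expect_true(abs(pk2[[1]]$center - 1000) <= 1)

  expect_error(consensus_peaks(set, presence_min = 1.5), "presence_min")
})

test_that("consensus detection is invariant to spectrum order", {
  coh <- generate_cohort(default_two_class_benchmark("separable", seed = 31L,
                                                     n_patients = 5L))
  pp <- preprocess_cohort(coh$set)
  sp <- shift_positive(pp)$set
  pk1 <- consensus_peaks(sp)
  perm <- rev(seq_len(nrow(sp$matrix)))
  shuffled <- spectra_set(sp$axis, sp$matrix[perm, ], sp$meta[perm, ])
  pk2 <- consensus_peaks(shuffled)
  expect_equal(vapply(pk1, function(d) d$center, numeric(1)),
               vapply(pk2, function(d) d$center, numeric(1)))
  expect_equal(vapply(pk1, function(d) d$presence_fraction, numeric(1)),
               vapply(pk2, function(d) d$presence_fraction, numeric(1)))
})

test_that("inflection points of a Gaussian sit one sigma from the center", {
  axis <- seq(900, 1100)
  s <- make_spectrum(axis, peaks = list(c(1, 1000, 10)))
  infl <- find_inflection_points(s, 1000)
  expect_lt(abs(infl[["left"]] - 990), 1)
  expect_lt(abs(infl[["right"]] - 1010), 1)

  # with 2% additive noise and smoothing, within 2 cm^-1 in >= 95% of draws
  ok <- vapply(1:200, function(i) {
    sn <- make_spectrum(axis, peaks = list(c(1, 1000, 10)), noise_sd = 0.02,
                        seed = 1000 + i)
    fl <- find_inflection_points(sn, 1000)
    abs(fl[["left"]] - 990) < 2 && abs(fl[["right"]] - 1010) < 2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("for overlapping peaks the right inflection precedes the valley", {
  axis <- seq(950, 1060, by = 0.5)
  y <- gaussian_curve(axis, 1, 1000, 6) + gaussian_curve(axis, 1, 1015, 6)
  s <- spectrum(axis, y)
  # brute-force valley of the noiseless mixture between the two summits
  between <- axis > 1000 & axis < 1015
  valley <- axis[between][which.min(y[between])]
  infl <- find_inflection_points(s, 1000)
  expect_lt(infl[["right"]], valley)
  expect_gt(infl[["right"]], 1000)
})

test_that("sigma estimation halves the inflection distance", {
  expect_equal(estimate_sigma(990, 1010), 10)
  expect_equal(estimate_sigma(0, 1), 0.5)
  expect_error(estimate_sigma(1010, 990), "argument error")
  expect_error(estimate_sigma(5, 5), "argument error")
})

test_that("the Gaussian fit is exact on noiseless model data", {
  axis <- seq(1150, 1250)
  s <- make_spectrum(axis, peaks = list(c(5, 1200, 8)))
  d <- list(window = c(1176, 1224))
  fit <- fit_gaussian(s, d, init = c(4.2, 1203, 9.5))  # within 20% of truth
  expect_true(fit$converged)
  expect_lt(abs(fit$height - 5) / 5, 1e-6)
  expect_lt(abs(fit$center - 1200) / 1200, 1e-6)
  expect_lt(abs(fit$sigma - 8) / 8, 1e-6)

  expect_error(fit_gaussian(s, list(window = c(1199, 1201))), "domain error")
})

test_that("a converged fit never has a larger residual than its start", {
  axis <- seq(1150, 1250)
  for (i in 1:20) {
    set.seed(i)
    s <- make_spectrum(axis, peaks = list(c(5, 1200, 8)), noise_sd = 0.3,
                       seed = i)
    init <- c(5 * runif(1, 0.5, 1.5), 1200 + runif(1, -5, 5),
              8 * runif(1, 0.5, 1.5))
    d <- list(window = c(1176, 1224))
    fit <- fit_gaussian(s, d, init = init)
    x <- axis[axis >= 1176 & axis <= 1224]
    yv <- s$intensity[axis >= 1176 & axis <= 1224]
    rn <- function(p) sum((yv - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))^2)
    expect_lte(fit$residual_norm, rn(fit$initial) + 1e-9)
  }
})

test_that("peak feature tables have the contracted shape and quality mask", {
  axis <- seq(800, 1200)
  sets <- rep(list(list(c(2, 950, 8), c(1.5, 1050, 10))), 10)
  set <- make_set(axis, sets)
  pk <- consensus_peaks(set, height_threshold = 0.2)
  expect_length(pk, 2L)
  ft <- build_peak_features(set, pk)
  expect_equal(dim(ft$values), c(10L, 4L))
  expect_setequal(unique(ft$ids$kind), c("height", "width"))

  # a spectrum lacking one consensus peak still gets a complete, flagged row
  sets2 <- c(rep(list(list(c(2, 950, 8), c(1.5, 1050, 10))), 9),
             list(list(c(2, 950, 8))))
  set2 <- make_set(axis, sets2)
  pk2 <- consensus_peaks(set2, height_threshold = 0.2)
  expect_length(pk2, 2L)
  ft2 <- build_peak_features(set2, pk2)
  expect_true(all(is.finite(ft2$values)))
  miss_col <- which(ft2$ids$kind == "height" &
                    abs(ft2$ids$position - 1050) < 3)
  expect_true(ft2$quality[10, miss_col])

  expect_error(build_peak_features(set, list()), "argument error")
})

test_that("class-differential heights survive into the fitted features", {
  # class B plants 1.5x the class A height at one center; the pre-normalized
  # fitted heights must recover that ratio
  axis <- seq(800, 1200)
  n_per <- 100
  mk <- function(h, seed) make_spectrum(axis, peaks = list(c(h, 1000, 10)),
                                        noise_sd = 0.02, seed = seed)
  specs <- c(lapply(1:n_per, function(i) mk(1.0, i)),
             lapply(1:n_per, function(i) mk(1.5, 1e4 + i)))
  mat <- t(vapply(specs, function(s) s$intensity, numeric(length(axis))))
  set <- spectra_set(axis, mat)
  pk <- consensus_peaks(set, height_threshold = 0.2)
  expect_length(pk, 1L)
  heights <- vapply(seq_len(nrow(mat)), function(i) {
    fit_gaussian(get_spectrum(set, i), pk[[1]])$height
  }, numeric(1))
  ratio <- mean(heights[(n_per + 1):(2 * n_per)]) / mean(heights[1:n_per])
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 1.6)
})

test_that("noiseless simulator peaks are recovered exactly by consensus", {
  pl <- default_peak_library()
  pl$presence_b[pl$center == 1094] <- 0.4  # decoy below the presence rule
  pl$presence_a[pl$center == 1094] <- 0.4
  pl$height_sd <- 0; pl$sigma_sd <- 0
  cfg <- synthetic_config(peak_library = pl, noise_sd = 0, spike_prob = 0,
                          baseline_poly = c(0, 0, 0, 0), baseline_exp_amp = 0,
                          patient_effect_sd = 0, n_patients = 10L, seed = 9L)
  coh <- generate_cohort(cfg)
  pp <- preprocess_cohort(coh$set)
  sp <- shift_positive(pp)$set
  pk <- consensus_peaks(sp)
  centers <- vapply(pk, function(d) d$center, numeric(1))
  planted <- setdiff(pl$center, 1094)
  expect_equal(length(centers), length(planted))
  expect_true(all(abs(sort(centers) - sort(planted)) <= 2))
})
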