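test_that("accumulation summing is a band-wise sum with identity checks", {
  axis <- seq(600, 700)
  acc <- lapply(1:5, function(i)
    spectrum(axis, rep(2, length(axis)),
             list(spectrum_id = "s1", accumulation_index = i)))
  out <- sum_accumulations(acc)
  expect_equal(out$intensity, rep(10, length(axis)))
  expect_true(is.na(out$meta$accumulation_index))

  expect_equal(sum_accumulations(acc[1])$intensity, acc[[1]]$intensity)
  short <- spectrum(seq(600, 650), rep(1, 51))
  expect_error(sum_accumulations(list(acc[[1]], short)), "alignment error")
  expect_error(sum_accumulations(list()), "at least one")
})

test_that("cosmic-ray removal deletes narrow spikes but keeps real peaks", {
  axis <- seq(600, 1000)
  clean <- make_spectrum(axis, peaks = list(c(5, 700, 10), c(3, 850, 8)))
  spiked <- clean
  spike_i <- 150L
  spiked$intensity[spike_i] <- 50 * max(clean$intensity)
  out <- remove_cosmic_rays(spiked, preprocess_config())
  scale <- max(clean$intensity)
  expect_true(all(abs(out$intensity - clean$intensity) < 0.01 * scale))

  # spike-free smooth spectrum passes through unchanged
  out2 <- remove_cosmic_rays(clean, preprocess_config())
  expect_equal(out2$intensity, clean$intensity)

  # a genuine sigma = 8 peak is wider than the spike criterion: preserved
  noisy <- make_spectrum(axis, peaks = list(c(5, 850, 8)), noise_sd = 0.01,
                         seed = 3)
  out3 <- remove_cosmic_rays(noisy, preprocess_config())
  i_top <- which.min(abs(axis - 850))
  expect_equal(out3$intensity[i_top], noisy$intensity[i_top])
})

test_that("rolling-ball baseline matches a brute-force opening oracle", {
  set.seed(7)
  axis <- seq(600, 900)
  y <- 2 + 0.01 * (axis - 600) + gaussian_curve(axis, 4, 750, 5) +
    abs(rnorm(length(axis), 0, 0.05))
  s <- spectrum(axis, y)
  cfg <- preprocess_config(ball_radius = 50)
  rb <- rolling_ball_baseline(s, cfg)
  expect_equal(rb$baseline$intensity, brute_opening(y, 50))
  # morphology properties: baseline below signal, exact reconstruction
  expect_true(all(rb$baseline$intensity <= y + 1e-12))
  expect_true(all(rb$corrected$intensity >= -1e-12))
  expect_equal(rb$baseline$intensity + rb$corrected$intensity, y)
})

test_that("rolling ball recovers a peak on a linear ramp and flattens a constant", {
  axis <- seq(600, 1100)
  flat <- spectrum(axis, rep(3, length(axis)))
  out <- rolling_ball_baseline(flat, preprocess_config(ball_radius = 100))
  expect_true(all(abs(out$corrected$intensity) < 1e-9))

  # Gaussian of sigma = 5 bands on a ramp, radius 10x sigma
  y <- 1 + 0.002 * (axis - 600) + gaussian_curve(axis, 6, 850, 5)
  s <- spectrum(axis, y)
  rb <- rolling_ball_baseline(s, preprocess_config(ball_radius = 50))
  i_top <- which.min(abs(axis - 850))
  expect_lt(abs(rb$corrected$intensity[i_top] - 6) / 6, 0.05)

  expect_error(rolling_ball_baseline(flat, preprocess_config(ball_radius = 300)),
               "configuration error")
})

test_that("SNV normalization has exact moments and is idempotent", {
  expect_equal(snv_normalize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(11)
  x <- rnorm(200, 5, 3)
  z <- snv_normalize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(snv_normalize(z), z)
  expect_error(snv_normalize(rep(4, 10), id = "s9"),
               "zero variance.*s9")
})

test_that("core averaging needs a shared core and axis", {
  axis <- seq(600, 650)
  mk <- function(v, core) spectrum(axis, rep(v, length(axis)),
                                   list(spectrum_id = paste0(core, v),
                                        core_id = core))
  expect_equal(average_core(list(mk(0, "c1"), mk(2, "c1")))$intensity,
               rep(1, length(axis)))
  four <- replicate(4, mk(3, "c1"), simplify = FALSE)
  expect_equal(average_core(four)$intensity, four[[1]]$intensity)
  expect_error(average_core(list(mk(1, "c1"), mk(1, "c2"))), "mixed core_id")
  expect_error(average_core(list()), "at least one")
})

test_that("positivity shift uses one global offset and is reusable", {
  axis <- c(600, 601, 602)
  set <- spectra_set(axis, rbind(c(-3.2, 0, 1), c(2, 5, 4)))
  sh <- shift_positive(set)
  expect_equal(sh$offset, -3.2)
  expect_equal(min(sh$set$matrix), 0)
  expect_equal(sh$set$matrix[1, ], c(0, 3.2, 4.2), ignore_attr = TRUE)

  already <- spectra_set(axis, rbind(c(0, 1, 2)))
  sh2 <- shift_positive(already)
  expect_equal(sh2$offset, 0)
  expect_equal(sh2$set$matrix, already$matrix)

  lower <- spectra_set(axis, rbind(c(-5, 0, 1)))
  expect_warning(apply_offset(lower, -3.2), "negative")
})

test_that("the preprocessing chain is deterministic", {
  coh <- generate_cohort(synthetic_config(n_patients = 2L, seed = 5L))
  a <- preprocess_cohort(coh$set)
  b <- preprocess_cohort(coh$set)
  expect_identical(a, b)
  expect_equal(nrow(a$matrix), 4L)  # one averaged spectrum per core
  expect_true(all(a$axis >= 669 & a$axis <= 1707))
})
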