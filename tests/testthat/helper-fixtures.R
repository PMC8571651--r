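# Shared fixture builders: everything is generated in code at test time.

gaussian_curve <- function(axis, A, mu, sigma) {
  A * exp(-(axis - mu)^2 / (2 * sigma^2))
}

# Single spectrum made of Gaussian peaks on an optional baseline.
make_spectrum <- function(axis = seq(600, 1400), peaks = list(),
                          baseline = 0, noise_sd = 0, id = "s1",
                          seed = NULL) {
  y <- rep(0, length(axis)) + baseline
  for (p in peaks) y <- y + gaussian_curve(axis, p[1], p[2], p[3])
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(axis), 0, noise_sd)
  }
  spectrum(axis, y, list(spectrum_id = id))
}

# Small labeled spectra set; `peak_sets` is a list of per-spectrum peak lists.
make_set <- function(axis, peak_sets, labels = NULL, noise_sd = 0,
                     baseline = 0, seed = 1) {
  set.seed(seed)
  mat <- t(vapply(peak_sets, function(pks) {
    y <- rep(0, length(axis)) + baseline
    for (p in pks) y <- y + gaussian_curve(axis, p[1], p[2], p[3])
    y + if (noise_sd > 0) rnorm(length(axis), 0, noise_sd) else 0
  }, numeric(length(axis))))
  meta <- data.frame(spectrum_id = paste0("s", seq_along(peak_sets)))
  if (!is.null(labels)) meta$class_label <- labels
  spectra_set(axis, mat, meta)
}

# Brute-force grey-scale opening with a flat structuring element of
# half-width r (the independent oracle for the rolling-ball baseline).
brute_opening <- function(x, r) {
  n <- length(x)
  er <- vapply(seq_len(n), function(i)
    min(x[max(1, i - r):min(n, i + r)]), numeric(1))
  vapply(seq_len(n), function(i)
    max(er[max(1, i - r):min(n, i + r)]), numeric(1))
}

# Brute-force all-pairs concordance (Mann-Whitney) AUC oracle.
brute_auc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Brute-force implementation of the iterative neighborhood-removal rule,
# written independently of the package version (explicit survivor recursion).
brute_remove_neighbors <- function(positions, n_neighbor) {
  order_idx <- seq_along(positions)   # already in rank order
  accepted <- integer(0)
  remaining <- order_idx
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    accepted <- c(accepted, best)
    keep <- abs(positions[remaining] - positions[best]) > n_neighbor
    remaining <- remaining[keep]
  }
  accepted
}
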