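#' Preprocessing configuration
#'
#' Parameters for the per-spectrum preprocessing chain: accumulation summing,
#' cosmic-ray despiking, rolling-ball baseline subtraction, SNV normalization
#' and per-core averaging.
#'
#' @param ball_radius structuring-element half-width of the rolling-ball
#'   baseline, in bands (default 100).
#' @param cosmic_ray_window running-median window for spike detection, in
#'   bands; odd, >= 3 (default 11).
#' @param cosmic_ray_z robust z-score threshold above the running median for a
#'   band to count as a spike (default 8).
#' @param trim_keep wavenumber window (cm^-1) retained after baseline removal;
#'   default `c(669, 1707)`, absorbing the rolling-ball border artifact.
#' @param accumulations_expected nominal accumulations per spectrum (default 5).
#' @param core_spectra_expected nominal spectra per core (default 4).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(ball_radius = 100L, cosmic_ray_window = 11L,
                              cosmic_ray_z = 8, trim_keep = c(669, 1707),
                              accumulations_expected = 5L,
                              core_spectra_expected = 4L) {
  ball_radius <- as.integer(ball_radius)
  cosmic_ray_window <- as.integer(cosmic_ray_window)
  if (ball_radius < 1L) stop("ball_radius must be >= 1")
  if (cosmic_ray_window < 3L || cosmic_ray_window %% 2L == 0L)
    stop("cosmic_ray_window must be odd and >= 3")
  if (cosmic_ray_z <= 0) stop("cosmic_ray_z must be > 0")
  if (length(trim_keep) != 2L || trim_keep[1] >= trim_keep[2])
    stop("trim_keep must be c(lo, hi) with lo < hi")
  structure(list(ball_radius = ball_radius,
                 cosmic_ray_window = cosmic_ray_window,
                 cosmic_ray_z = cosmic_ray_z,
                 trim_keep = as.numeric(trim_keep),
                 accumulations_expected = as.integer(accumulations_expected),
                 core_spectra_expected = as.integer(core_spectra_expected)),
            class = "preprocess_config")
}

#' Sum repeated accumulations of one acquisition
#'
#' Band-wise sum of the (typically five) short accumulations recorded at one
#' spot; the first preprocessing step.
#'
#' @param accumulations list of `raman_spectrum` objects sharing an identical
#'   axis and spot identity.
#' @return one `raman_spectrum` with `accumulation_index` cleared.
#' @export
sum_accumulations <- function(accumulations) {
  if (length(accumulations) == 0L) stop("need at least one accumulation")
  ref <- accumulations[[1L]]
  total <- ref$intensity
  for (s in accumulations[-1L]) {
    if (length(s$axis) != length(ref$axis) || any(s$axis != ref$axis))
      stop("alignment error: accumulations must share an identical axis")
    total <- total + s$intensity
  }
  meta <- ref$meta
  meta$accumulation_index <- NA_integer_
  spectrum(ref$axis, total, meta)
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Bands exceeding the running median by more than `cosmic_ray_z` robust
#' standard deviations, in excursions at most two bands wide, are replaced by
#' the local median. Genuine Raman peaks are wider than two bands and pass
#' through untouched.
#'
#' @param s a `raman_spectrum`.
#' @param cfg a [preprocess_config()].
#' @return the despiked `raman_spectrum`.
#' @export
remove_cosmic_rays <- function(s, cfg = preprocess_config()) {
  x <- s$intensity
  med <- runmed(x, cfg$cosmic_ray_window, endrule = "median")
  resid <- x - med
  s_rob <- mad(resid, center = 0)
  if (s_rob <= 0) s_rob <- sd(resid)
  if (!is.finite(s_rob) || s_rob <= 0) return(s)
  flagged <- resid > cfg$cosmic_ray_z * s_rob
  if (!any(flagged)) return(s)
  n <- length(x)
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values & runs$lengths <= 2L)) {
    idx <- starts[k]:ends[k]
    # a cosmic ray also jumps sharply against its immediate neighbors; a
    # smooth peak apex exceeding the running median does not
    lo <- max(1L, starts[k] - 1L); hi <- min(n, ends[k] + 1L)
    nb <- x[setdiff(c(lo, hi), idx)]
    if (length(nb) && min(x[idx]) - max(nb) <= cfg$cosmic_ray_z * s_rob) next
    x[idx] <- med[idx]
  }
  spectrum(s$axis, x, s$meta)
}

# Flat-structuring-element grey-scale erosion/dilation with truncated windows.
running_extreme <- function(x, radius, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(x)
  pad <- if (op == "min") Inf else -Inf
  out <- x
  f <- if (op == "min") pmin else pmax
  for (k in seq_len(radius)) {
    left <- c(rep(pad, k), x[seq_len(n - k)])
    right <- c(x[(k + 1L):n], rep(pad, k))
    out <- f(out, left, right)
  }
  out
}

#' Rolling-ball baseline estimation
#'
#' Morphological baseline estimate: a grey-scale opening of the spectrum with
#' a flat structuring element of half-width `ball_radius` bands (running
#' minimum followed by running maximum). The opening lies at or below the
#' signal everywhere, so the corrected spectrum is non-negative. Within
#' `ball_radius` bands of either end the estimate is distorted by the border
#' effect; the trim window of [preprocess_config()] exists to discard those
#' regions.
#'
#' @param s a `raman_spectrum`.
#' @param cfg a [preprocess_config()]; `ball_radius` must be < n_bands / 2.
#' @return list with elements `baseline` and `corrected`, both
#'   `raman_spectrum` objects satisfying `corrected + baseline == s` exactly.
#' @export
rolling_ball_baseline <- function(s, cfg = preprocess_config()) {
  n <- length(s$intensity)
  r <- cfg$ball_radius
  if (r >= n / 2)
    stop("configuration error: ball_radius (", r, ") must be < n_bands/2 (",
         n / 2, ")")
  eroded <- running_extreme(s$intensity, r, "min")
  baseline <- running_extreme(eroded, r, "max")
  list(baseline = spectrum(s$axis, baseline, s$meta),
       corrected = spectrum(s$axis, s$intensity - baseline, s$meta))
}

#' Standard normal variate normalization
#'
#' Centers and scales a vector to mean 0 and sample standard deviation 1
#' (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @param id optional identifier used in the error message for zero-variance
#'   input.
#' @return the normalized numeric vector.
#' @export
snv_normalize <- function(values, id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("SNV needs at least two values")
  s <- sd(values)
  if (!is.finite(s) || s <= .Machine$double.eps * max(abs(values), 1))
    stop("normalization error: zero variance",
         if (!is.null(id)) paste0(" in spectrum '", id, "'") else "")
  (values - mean(values)) / s
}

#' Average the spectra of one core
#'
#' Band-wise arithmetic mean of the (typically four) spectra acquired on one
#' tissue-microarray core.
#'
#' @param spectra list of `raman_spectrum` objects with identical axes and a
#'   common `core_id`.
#' @return one `raman_spectrum` whose identity collapses to the core.
#' @export
average_core <- function(spectra) {
  if (length(spectra) == 0L) stop("need at least one spectrum to average")
  ref <- spectra[[1L]]
  cores <- vapply(spectra, function(s) s$meta$core_id, character(1))
  if (length(unique(cores)) != 1L)
    stop("argument error: spectra from mixed core_ids: ",
         paste(unique(cores), collapse = ", "))
  acc <- ref$intensity
  for (s in spectra[-1L]) {
    if (length(s$axis) != length(ref$axis) || any(s$axis != ref$axis))
      stop("alignment error: spectra must share an identical axis")
    acc <- acc + s$intensity
  }
  meta <- ref$meta
  meta$spectrum_id <- ref$meta$core_id
  spectrum(ref$axis, acc / length(spectra), meta)
}

#' Shift a dataset to strictly non-negative intensities
#'
#' Subtracts the single global minimum over all bands of all spectra, so the
#' dataset minimum becomes exactly zero. The Gaussian model fitted later is
#' strictly positive, hence this dataset-wide positivity shift. The offset is
#' returned so held-out sets can reuse the training offset via
#' [apply_offset()].
#'
#' @param set a non-empty `spectra_set`.
#' @return list with elements `set` (shifted) and `offset` (the subtracted
#'   global minimum).
#' @export
shift_positive <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  offset <- min(set$matrix)
  list(set = spectra_set(set$axis, set$matrix - offset, set$meta),
       offset = offset)
}

#' Apply a stored positivity offset to another set
#'
#' Used on held-out cohorts with the training cohort's offset. If the set's
#' own minimum is smaller than the offset, some values remain negative; this
#' is expected and reported with a warning.
#'
#' @param set a `spectra_set`.
#' @param offset the training offset from [shift_positive()].
#' @return the shifted `spectra_set`.
#' @export
apply_offset <- function(set, offset) {
  shifted <- set$matrix - offset
  if (min(shifted) < 0)
    warning("applied offset leaves negative intensities (min ",
            signif(min(shifted), 4), "); training offset smaller than this ",
            "set's minimum")
  spectra_set(set$axis, shifted, set$meta)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in order: cosmic-ray removal, rolling-ball baseline subtraction,
#' border trimming to `cfg$trim_keep`, SNV normalization, and per-core
#' averaging. Input spectra are expected at the summed-accumulation scale
#' (see [sum_accumulations()]). The positivity shift is not applied here;
#' model-fitting code derives the offset from training data only (see
#' [shift_positive()]).
#'
#' @param set a raw `spectra_set`.
#' @param cfg a [preprocess_config()].
#' @return a preprocessed `spectra_set` with one row per core.
#' @export
preprocess_cohort <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  n <- nrow(set$matrix)
  mat <- set$matrix
  for (i in seq_len(n)) {
    s <- spectrum(set$axis, mat[i, ], as.list(set$meta[i, ]))
    s <- remove_cosmic_rays(s, cfg)
    s <- rolling_ball_baseline(s, cfg)$corrected
    mat[i, ] <- s$intensity
  }
  corrected <- spectra_set(set$axis, mat, set$meta)
  trimmed <- restrict_axis(corrected, cfg$trim_keep[1], cfg$trim_keep[2])
  m2 <- trimmed$matrix
  for (i in seq_len(n))
    m2[i, ] <- snv_normalize(m2[i, ], id = trimmed$meta$spectrum_id[i])
  snved <- spectra_set(trimmed$axis, m2, trimmed$meta)
  average_cores_set(snved)
}

# Collapse a set to one averaged spectrum per core.
average_cores_set <- function(set) {
  cores <- unique(set$meta$core_id)
  mat <- matrix(0, length(cores), length(set$axis))
  meta <- set$meta[match(cores, set$meta$core_id), , drop = FALSE]
  for (k in seq_along(cores)) {
    idx <- which(set$meta$core_id == cores[k])
    mat[k, ] <- colMeans(set$matrix[idx, , drop = FALSE])
  }
  meta$spectrum_id <- cores
  spectra_set(set$axis, mat, meta)
}
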