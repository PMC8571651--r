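#' Default candidate-peak height threshold
#'
#' Scale-aware default on SNV-shifted data: 25% of the 99th percentile of the
#' dataset's intensities. The dataset-wide positivity shift subtracts the
#' global minimum, which places peak-free background regions well above zero
#' (typically 15-25% of the intensity range on SNV-scale data), so the
#' threshold must clear that background level or smoothed noise maxima would
#' qualify as candidates everywhere.
#'
#' @param set a preprocessed, positivity-shifted `spectra_set`.
#' @return numeric threshold.
#' @export
default_height_threshold <- function(set) {
  as.numeric(0.25 * quantile(set$matrix, 0.99))
}

# Savitzky-Golay projection matrices are reused heavily; memoize them.
.sg_cache <- new.env(parent = emptyenv())

sgolay_filter <- function(p, n, m = 0, ts = 1) {
  key <- paste(p, n, m, format(ts, digits = 12), sep = "_")
  f <- .sg_cache[[key]]
  if (is.null(f)) {
    f <- signal::sgolay(p = p, n = n, m = m, ts = ts)
    .sg_cache[[key]] <- f
  }
  f
}

smooth_intensity <- function(x, window = 7L) {
  window <- max(5L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= length(x)) return(x)
  signal::sgolayfilt(x, sgolay_filter(p = 2, n = window))
}

second_derivative <- function(x, step, window = 7L) {
  window <- max(5L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  signal::sgolayfilt(x, sgolay_filter(p = 3, n = window, m = 2, ts = step))
}

# Precompute the smoothed signal and second derivative once per spectrum.
# The second derivative uses a wider window than the signal smoothing: a
# curvature filter amplifies stochastic noise far more than a smoothing
# filter, so locating inflection sign changes reliably needs more support,
# while peak maxima are best located with light smoothing.
spectrum_smoothing <- function(s, window = 7L, deriv_window = 15L) {
  dw <- max(deriv_window, window)
  list(y = smooth_intensity(s$intensity, window),
       yd = smooth_intensity(s$intensity, dw),
       d2 = second_derivative(s$intensity, mean(diff(s$axis)), dw))
}

#' Detect candidate peaks in one spectrum
#'
#' Local maxima of the lightly smoothed signal (strictly greater than both
#' neighbors) whose original intensity exceeds `height_threshold`.
#'
#' @param s a preprocessed `raman_spectrum` (SNV-normalized, shifted positive).
#' @param height_threshold minimum intensity for a candidate.
#' @param smooth_window Savitzky-Golay smoothing window in bands (default 7).
#' @return data.frame with columns `position` (cm^-1) and `height`, in axis
#'   order; may have zero rows.
#' @export
detect_candidate_peaks <- function(s, height_threshold, smooth_window = 7L) {
  y <- smooth_intensity(s$intensity, smooth_window)
  n <- length(y)
  if (n < 3L) return(data.frame(position = numeric(0), height = numeric(0)))
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] > y[i + 1L]
  idx <- i[is_max]
  idx <- idx[s$intensity[idx] > height_threshold]
  data.frame(position = s$axis[idx], height = s$intensity[idx])
}

#' Find consensus peaks across a cohort
#'
#' Pools candidate peak positions from every spectrum and clusters them
#' greedily: the position with the most supporting spectra within
#' `+/- tolerance` anchors a cluster, its members are removed, and the
#' procedure repeats. Clusters supported by at least `presence_min` of the
#' spectra become consensus peaks (the default rule: present in at least 50%
#' of spectra at the same location or within +/-2 cm^-1).
#'
#' @param set a preprocessed, positivity-shifted `spectra_set`.
#' @param tolerance clustering half-width in cm^-1 (default 2).
#' @param presence_min minimum fraction of spectra exhibiting the peak
#'   (default 0.5).
#' @param height_threshold candidate threshold; default
#'   [default_height_threshold()] of `set`.
#' @param smooth_window smoothing window passed to [detect_candidate_peaks()].
#' @return list of `peak_descriptor` objects sorted by center, each with
#'   fields `center`, `presence_fraction`, `window`, `member_positions`
#'   (named by spectrum id), `init` (pooled `c(A0, mu0, sigma0)`), and
#'   `n_members`.
#' @export
consensus_peaks <- function(set, tolerance = 2, presence_min = 0.5,
                            height_threshold = NULL, smooth_window = 7L) {
  stopifnot(inherits(set, "spectra_set"))
  n <- nrow(set$matrix)
  if (n == 0L) stop("argument error: empty spectra set")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (presence_min <= 0 || presence_min > 1)
    stop("presence_min must be in (0, 1]")
  if (is.null(height_threshold)) height_threshold <- default_height_threshold(set)

  cand <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- detect_candidate_peaks(get_spectrum(set, i), height_threshold,
                                smooth_window)
    if (nrow(d) == 0L) return(NULL)
    cbind(d, spec = set$meta$spectrum_id[i])
  }))
  mean_spec <- spectrum(set$axis, colMeans(set$matrix),
                        list(spectrum_id = ".mean"))
  descriptors <- list()
  while (!is.null(cand) && nrow(cand) > 0L) {
    up <- sort(unique(cand$position))
    counts <- vapply(up, function(p)
      length(unique(cand$spec[abs(cand$position - p) <= tolerance])),
      integer(1))
    anchor <- up[which.max(counts)]          # ties -> lower wavenumber
    in_win <- which(abs(cand$position - anchor) <= tolerance)
    memb <- cand[in_win, , drop = FALSE]
    # each spectrum contributes its nearest candidate to the anchor
    memb <- memb[order(abs(memb$position - anchor), memb$position), ]
    memb <- memb[!duplicated(memb$spec), , drop = FALSE]
    center <- median(memb$position)
    keep <- abs(memb$position - center) <= tolerance
    memb <- memb[keep, , drop = FALSE]
    presence <- length(unique(memb$spec)) / n
    if (presence >= presence_min) {
      infl <- find_inflection_points(mean_spec, center,
                                     smooth_window = smooth_window)
      sigma0 <- tryCatch(estimate_sigma(infl[1], infl[2]),
                         error = function(e) 5)
      # keep the fitting window at least a few bands wide
      sigma0 <- max(sigma0, 1.5 * mean(diff(set$axis)))
      a0 <- mean_spec$intensity[which.min(abs(mean_spec$axis - center))]
      win <- c(max(min(set$axis), center - 3 * sigma0),
               min(max(set$axis), center + 3 * sigma0))
      descriptors[[length(descriptors) + 1L]] <- structure(
        list(center = center, presence_fraction = presence, window = win,
             member_positions = setNames(memb$position, memb$spec),
             init = c(A0 = max(a0, height_threshold), mu0 = center,
                      sigma0 = sigma0),
             n_members = nrow(memb)),
        class = "peak_descriptor")
    }
    cand <- cand[-in_win, , drop = FALSE]
  }
  descriptors[order(vapply(descriptors, function(d) d$center, numeric(1)))]
}

#' @export
print.peak_descriptor <- function(x, ...) {
  cat(sprintf("<peak %.1f cm^-1: presence %.2f, window [%.1f, %.1f]>\n",
              x$center, x$presence_fraction, x$window[1], x$window[2]))
  invisible(x)
}

#' Locate the inflection points flanking a peak
#'
#' Finds the nearest sign changes of the smoothed second derivative on each
#' side of `center`, searching no farther than the nearest flanking local
#' minimum of the smoothed signal. For a Gaussian these sit at `mu +/- sigma`.
#' If no sign change occurs before the flanking minimum, the half-maximum
#' crossing is used instead (flagged via the `"fallback"` attribute).
#'
#' @param s a `raman_spectrum` with a local maximum at/near `center`.
#' @param center approximate peak position in cm^-1.
#' @param smooth_window Savitzky-Golay window for the signal and its second
#'   derivative (default 15 bands).
#' @return numeric `c(left, right)` in cm^-1 with `left < center < right`;
#'   attribute `fallback` is a logical pair flagging half-maximum fallbacks.
#' @export
find_inflection_points <- function(s, center, smooth_window = 7L,
                                   .pre = NULL) {
  x <- s$axis
  n <- length(x)
  if (is.null(.pre)) .pre <- spectrum_smoothing(s, smooth_window)
  y <- .pre$yd %||% .pre$y
  d2 <- .pre$d2
  i0 <- which.min(abs(x - center))
  # snap to the nearest local maximum of the smoothed signal
  lo <- max(2L, i0 - 3L); hi <- min(n - 1L, i0 + 3L)
  seg <- lo:hi
  i0 <- seg[which.max(y[seg])]

  mins <- which(c(FALSE, diff(y) < 0) & c(diff(y) > 0, FALSE) |
                seq_len(n) %in% c(1L, n))
  right_bound <- mins[mins > i0]
  right_bound <- if (length(right_bound)) min(right_bound) else n
  left_bound <- mins[mins < i0]
  left_bound <- if (length(left_bound)) max(left_bound) else 1L

  cross <- function(i_from, i_to, dir) {
    idx <- if (dir > 0) seq(i_from + 1L, i_to) else seq(i_from - 1L, i_to)
    if (dir > 0 && i_from + 1L > i_to) idx <- integer(0)
    if (dir < 0 && i_from - 1L < i_to) idx <- integer(0)
    for (i in idx) {
      prev <- i - dir
      if (d2[prev] <= 0 && d2[i] > 0) {
        # linear interpolation of the zero crossing
        f <- d2[prev] / (d2[prev] - d2[i])
        return(x[prev] + f * (x[i] - x[prev]))
      }
    }
    NA_real_
  }
  right <- if (right_bound > i0) cross(i0, right_bound, +1L) else NA_real_
  left <- if (left_bound < i0) cross(i0, left_bound, -1L) else NA_real_

  fb <- c(left = FALSE, right = FALSE)
  half_cross <- function(bound, dir) {
    hm <- y[i0] - 0.5 * (y[i0] - y[bound])
    idx <- if (dir > 0) seq(i0, bound) else seq(i0, bound, by = -1L)
    for (i in idx[-1L]) {
      if (y[i] <= hm) {
        prev <- i - dir
        f <- (y[prev] - hm) / (y[prev] - y[i])
        return(x[prev] + f * (x[i] - x[prev]))
      }
    }
    x[bound]
  }
  if (is.na(right)) { right <- half_cross(right_bound, +1L); fb["right"] <- TRUE }
  if (is.na(left)) { left <- half_cross(left_bound, -1L); fb["left"] <- TRUE }
  if (!(left < x[i0]) || !(right > x[i0])) {
    # degenerate smoothing near borders: fall back to one grid step
    if (!(left < x[i0])) { left <- x[max(1L, i0 - 1L)]; fb["left"] <- TRUE }
    if (!(right > x[i0])) { right <- x[min(n, i0 + 1L)]; fb["right"] <- TRUE }
  }
  structure(c(left = left, right = right), fallback = fb)
}

#' Approximate Gaussian standard deviation from inflection points
#'
#' A Gaussian's inflection points sit one standard deviation either side of
#' its center, so `sigma0 = (right - left) / 2`.
#'
#' @param left,right inflection-point positions in cm^-1, `left < right`.
#' @return the starting standard deviation in cm^-1.
#' @export
estimate_sigma <- function(left, right) {
  if (!(right > left))
    stop("argument error: right inflection must exceed left (",
         left, " >= ", right, ")")
  (right - left) / 2
}

#' Fit a Gaussian over a peak's window
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` against the spectrum within the
#' descriptor's fitting window, with bounds `A >= 0`, `mu` inside the window,
#' `sigma` in (0, window width].
#'
#' @param s a `raman_spectrum`.
#' @param d a `peak_descriptor` (or any list with a `window` element and,
#'   optionally, `init`).
#' @param init starting values `c(A0, mu0, sigma0)`; default the descriptor's
#'   pooled init.
#' @return a `gaussian_fit` list: `height`, `center`, `sigma`,
#'   `residual_norm`, `converged`, `initial`. A failed optimization returns
#'   `converged = FALSE` carrying the initial values.
#' @export
fit_gaussian <- function(s, d, init = NULL) {
  win <- d$window
  idx <- which(s$axis >= win[1] & s$axis <= win[2])
  if (length(idx) < 5L)
    stop("domain error: fitting window [", win[1], ", ", win[2],
         "] contains ", length(idx), " bands (need >= 5)")
  x <- s$axis[idx]; yv <- s$intensity[idx]
  if (is.null(init)) init <- d$init
  init <- as.numeric(init)
  width <- win[2] - win[1]
  lower <- c(0, win[1], 1e-6)
  upper <- c(Inf, win[2], width)
  par0 <- pmin(pmax(init, lower + c(0, 0, 1e-9)), c(Inf, upper[2:3]))
  gauss_resid <- function(p) yv - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = gauss_resid, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  init_norm <- sum(gauss_resid(par0)^2)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(structure(list(height = par0[1], center = par0[2], sigma = par0[3],
                          residual_norm = init_norm, converged = FALSE,
                          initial = par0),
                     class = "gaussian_fit"))
  }
  p <- fit$par
  norm <- sum(gauss_resid(p)^2)
  if (norm > init_norm) {  # never accept a step worse than the start
    p <- par0; norm <- init_norm
  }
  structure(list(height = p[1], center = p[2], sigma = p[3],
                 residual_norm = norm, converged = TRUE, initial = par0),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit: A=%.4g mu=%.2f sigma=%.3g %s>\n", x$height,
              x$center, x$sigma, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Per-spectrum initialisation for one consensus peak: if the spectrum shows a
# local maximum within +/- tolerance of the consensus center, derive inits
# from its own maximum and inflection points; otherwise use the pooled init.
spectrum_peak_init <- function(s, d, tolerance = 2, smooth_window = 7L,
                               .pre = NULL) {
  if (is.null(.pre)) .pre <- spectrum_smoothing(s, smooth_window)
  y <- .pre$y
  n <- length(y)
  in_tol <- which(abs(s$axis - d$center) <= tolerance)
  in_tol <- in_tol[in_tol > 1L & in_tol < n]
  is_max <- in_tol[y[in_tol] > y[in_tol - 1L] & y[in_tol] > y[in_tol + 1L]]
  if (length(is_max) == 0L)
    return(list(init = d$init, window = d$window, exhibited = FALSE))
  i <- is_max[which.max(y[is_max])]
  pos <- s$axis[i]
  infl <- find_inflection_points(s, pos, smooth_window, .pre = .pre)
  sigma0 <- tryCatch(estimate_sigma(infl[1], infl[2]),
                     error = function(e) d$init[["sigma0"]])
  sigma0 <- max(sigma0, 1.5 * mean(diff(s$axis)))
  # the fitting domain is a property of the consensus peak, shared by every
  # spectrum; per-spectrum data supplies only the starting values (a
  # spectrum-specific window would modulate how much background enters each
  # fit and needlessly inflate the variance of the fitted width)
  list(init = c(A0 = s$intensity[i], mu0 = pos, sigma0 = sigma0),
       window = d$window, exhibited = TRUE)
}

#' Build the fitted peak-feature table for a cohort
#'
#' For every spectrum and every consensus peak, fits a Gaussian (per-spectrum
#' inflection-based initialisation where the spectrum exhibits the peak, the
#' descriptor's pooled initialisation otherwise) and emits one `height@center`
#' and one `width@center` feature per peak. The fitted values are then
#' normalized: by default each feature column is standardized across spectra
#' (`snv_axis = "column"`); `snv_axis = "row"` instead SNV-normalizes each
#' spectrum's concatenated height+width vector, mirroring spectral SNV
#' semantics. Column standardization is the default because a short row of
#' mixed units (heights in intensity units, widths in cm^-1) has row moments
#' driven by feature content rather than by any per-spectrum nuisance, so a
#' row-wise SNV leaks every feature into every other. Non-converged or
#' pooled-init fits are flagged in the quality mask.
#'
#' @param set a preprocessed, positivity-shifted `spectra_set`.
#' @param peaks list of `peak_descriptor` objects (from [consensus_peaks()]
#'   run on the training cohort).
#' @param tolerance matching half-width in cm^-1 for deciding whether a
#'   spectrum exhibits a peak (default 2).
#' @param snv_axis `"column"` (default) or `"row"` normalization of the
#'   fitted values.
#' @param smooth_window smoothing window for per-spectrum initialisation.
#' @return a [feature_table()] with `2 * length(peaks)` columns.
#' @export
build_peak_features <- function(set, peaks, tolerance = 2,
                                snv_axis = c("column", "row"),
                                smooth_window = 7L) {
  snv_axis <- match.arg(snv_axis)
  if (length(peaks) == 0L) stop("argument error: empty peak list")
  n <- nrow(set$matrix)
  p <- length(peaks)
  heights <- widths <- matrix(NA_real_, n, p)
  flagged <- matrix(FALSE, n, p)
  for (i in seq_len(n)) {
    s <- get_spectrum(set, i)
    pre <- spectrum_smoothing(s, smooth_window)
    for (j in seq_len(p)) {
      d <- peaks[[j]]
      ini <- spectrum_peak_init(s, d, tolerance, smooth_window, .pre = pre)
      fit <- tryCatch(
        fit_gaussian(s, list(window = ini$window, init = ini$init)),
        error = function(e) NULL)
      if (is.null(fit)) {
        fit <- list(height = ini$init[[1]], center = ini$init[[2]],
                    sigma = ini$init[[3]], converged = FALSE)
      }
      heights[i, j] <- fit$height
      widths[i, j] <- fit$sigma
      flagged[i, j] <- !isTRUE(fit$converged) || !ini$exhibited
    }
  }
  centers <- vapply(peaks, function(d) d$center, numeric(1))
  values <- cbind(heights, widths)
  ids <- data.frame(kind = rep(c("height", "width"), each = p),
                    position = rep(centers, 2))
  if (snv_axis == "row") {
    for (i in seq_len(n)) values[i, ] <- snv_normalize(values[i, ])
  } else {
    for (j in seq_len(ncol(values))) {
      s_j <- sd(values[, j])
      values[, j] <- if (s_j > 0) (values[, j] - mean(values[, j])) / s_j
                     else values[, j] - mean(values[, j])
    }
  }
  feature_table(values, ids, quality = cbind(flagged, flagged),
                meta = set$meta)
}

#' Serialize a peak registry to JSON
#'
#' @param peaks list of `peak_descriptor` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_registry <- function(peaks, path) {
  reg <- lapply(peaks, function(d)
    list(center = d$center, presence_fraction = d$presence_fraction,
         window = d$window, n_members = d$n_members))
  jsonlite::write_json(reg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
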