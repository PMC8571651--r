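#' Synthetic Raman cohort configuration
#'
#' Describes a two-class synthetic Raman cohort: a wavenumber axis, a library
#' of Gaussian peaks with class-dependent heights, widths and presence
#' probabilities, a smooth fluorescence-like baseline (third-degree
#' polynomial plus a decaying exponential producing the steep low-wavenumber
#' gradient), additive Gaussian noise, occasional narrow cosmic-ray spikes,
#' and a per-patient multiplicative height effect shared across a patient's
#' spectra.
#'
#' @param axis_lo,axis_hi,axis_step wavenumber axis in cm^-1 (defaults
#'   602-1726 at 1 cm^-1).
#' @param peak_library data.frame with columns `center`, `height_a`,
#'   `height_b`, `height_sd`, `sigma_a`, `sigma_b`, `sigma_sd`,
#'   `presence_a`, `presence_b`.
#' @param baseline_poly length-4 polynomial coefficients over the normalized
#'   axis position t in \[0, 1\] (`b0 + b1 t + b2 t^2 + b3 t^3`).
#' @param baseline_exp_amp,baseline_exp_scale amplitude and decay scale
#'   (cm^-1) of the low-wavenumber exponential term.
#' @param center_jitter_sd standard deviation (cm^-1) of the per-spectrum
#'   random shift of each peak's center, emulating the small positional
#'   wander of real Raman bands (the reason consensus detection uses a
#'   +/-2 cm^-1 tolerance). Default 0.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param spike_prob per-spectrum cosmic-ray probability.
#' @param spike_amplitude spike height as a multiple of the local signal level.
#' @param n_patients patients per class.
#' @param spectra_per_patient spectra per patient (one core; default 4).
#' @param patient_effect_sd standard deviation of the per-patient log-normal
#'   height factor.
#' @param cohort cohort name stamped into the metadata.
#' @param seed integer seed; generation is bit-reproducible given the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(axis_lo = 602, axis_hi = 1726, axis_step = 1,
                             peak_library = default_peak_library(),
                             baseline_poly = c(4, -1, 1, -0.5),
                             baseline_exp_amp = 3, baseline_exp_scale = 25,
                             center_jitter_sd = 0, noise_sd = 0.02,
                             spike_prob = 0.05,
                             spike_amplitude = 25, n_patients = 20L,
                             spectra_per_patient = 4L, patient_effect_sd = 0.1,
                             cohort = "synthetic", seed = 1L) {
  if (axis_step <= 0) stop("configuration error: axis_step must be > 0")
  if (n_patients < 1L) stop("configuration error: n_patients must be >= 1")
  pl <- as.data.frame(peak_library)
  need <- c("center", "height_a", "height_b", "height_sd", "sigma_a",
            "sigma_b", "sigma_sd", "presence_a", "presence_b")
  if (!all(need %in% names(pl)))
    stop("configuration error: peak_library missing columns: ",
         paste(setdiff(need, names(pl)), collapse = ", "))
  if (any(pl$sigma_a <= 0 | pl$sigma_b <= 0))
    stop("configuration error: sigma means must be > 0")
  if (any(pl$presence_a < 0 | pl$presence_a > 1 |
          pl$presence_b < 0 | pl$presence_b > 1))
    stop("configuration error: presence probabilities must lie in [0, 1]")
  structure(list(axis_lo = axis_lo, axis_hi = axis_hi, axis_step = axis_step,
                 peak_library = pl, baseline_poly = as.numeric(baseline_poly),
                 baseline_exp_amp = baseline_exp_amp,
                 baseline_exp_scale = baseline_exp_scale,
                 center_jitter_sd = center_jitter_sd,
                 noise_sd = noise_sd, spike_prob = spike_prob,
                 spike_amplitude = spike_amplitude,
                 n_patients = as.integer(n_patients),
                 spectra_per_patient = as.integer(spectra_per_patient),
                 patient_effect_sd = patient_effect_sd,
                 cohort = cohort, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default tissue-like peak library
#'
#' Eight Gaussian peaks at band positions typical of tissue Raman spectra
#' (nucleic-acid and aromatic ring-breathing modes, C-C stretches, CH
#' deformation, amide I), shared between the two classes.
#'
#' @return a peak-library data.frame (see [synthetic_config()]).
#' @export
default_peak_library <- function() {
  h <- c(0.8, 1.0, 0.7, 1.6, 0.6, 0.9, 1.2, 1.4)
  s <- c(6, 7, 6, 5, 9, 10, 9, 11)
  data.frame(center = c(721, 782, 853, 1004, 1094, 1245, 1450, 1660),
             height_a = h, height_b = h, height_sd = 0.05,
             sigma_a = s, sigma_b = s, sigma_sd = 0.3,
             presence_a = 1, presence_b = 1)
}

baseline_values <- function(cfg, axis) {
  t <- (axis - cfg$axis_lo) / (cfg$axis_hi - cfg$axis_lo)
  p <- cfg$baseline_poly
  p[1] + p[2] * t + p[3] * t^2 + p[4] * t^3 +
    cfg$baseline_exp_amp * exp(-(axis - cfg$axis_lo) / cfg$baseline_exp_scale)
}

#' Generate a synthetic Raman cohort with recorded ground truth
#'
#' Every spectrum is a sum of present Gaussian peaks (heights and widths
#' drawn per spectrum, heights scaled by a patient-shared log-normal factor)
#' plus the configured baseline, additive Gaussian noise and, with
#' `spike_prob`, one narrow cosmic-ray spike. Classes are labeled `"A"` and
#' `"B"`. Generation is bit-reproducible from the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `set` (the raw `spectra_set`, summed-accumulation scale)
#'   and `truth` (list with the baseline, per-spectrum drawn peak parameters,
#'   presence indicators, spike locations and patient factors).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  axis <- seq(cfg$axis_lo, cfg$axis_hi, by = cfg$axis_step)
  base <- baseline_values(cfg, axis)
  pl <- cfg$peak_library
  np <- nrow(pl)
  with_seed(cfg$seed, {
    rows <- list(); meta <- list(); truth_rows <- list(); spikes <- list()
    patient_factors <- list()
    for (cls in c("A", "B")) {
      h_mean <- if (cls == "A") pl$height_a else pl$height_b
      s_mean <- if (cls == "A") pl$sigma_a else pl$sigma_b
      pres <- if (cls == "A") pl$presence_a else pl$presence_b
      for (p in seq_len(cfg$n_patients)) {
        pid <- sprintf("%s_p%02d", cls, p)
        pf <- exp(rnorm(1, 0, cfg$patient_effect_sd))
        patient_factors[[pid]] <- pf
        for (s in seq_len(cfg$spectra_per_patient)) {
          sid <- sprintf("%s_s%d", pid, s)
          present <- runif(np) < pres
          heights <- pmax(rnorm(np, h_mean * pf, pl$height_sd), 0.05)
          sigmas <- pmax(rnorm(np, s_mean, pl$sigma_sd), 1)
          centers <- pl$center +
            if (cfg$center_jitter_sd > 0)
              rnorm(np, 0, cfg$center_jitter_sd) else 0
          sig <- base
          for (j in which(present))
            sig <- sig + heights[j] *
              exp(-(axis - centers[j])^2 / (2 * sigmas[j]^2))
          sig <- sig + rnorm(length(axis), 0, cfg$noise_sd)
          spike_at <- NA_integer_
          if (runif(1) < cfg$spike_prob) {
            spike_at <- sample.int(length(axis), 1)
            sig[spike_at] <- sig[spike_at] +
              cfg$spike_amplitude * max(abs(sig[spike_at]), 1)
          }
          rows[[sid]] <- sig
          meta[[sid]] <- data.frame(spectrum_id = sid, patient_id = pid,
                                    core_id = paste0(pid, "_c1"),
                                    cohort = cfg$cohort, class_label = cls)
          truth_rows[[sid]] <- data.frame(spectrum_id = sid, class = cls,
                                          peak = pl$center,
                                          center = centers, present = present,
                                          height = ifelse(present, heights, NA),
                                          sigma = ifelse(present, sigmas, NA))
          spikes[[sid]] <- spike_at
        }
      }
    }
    set <- spectra_set(axis, do.call(rbind, rows), do.call(rbind, meta))
    truth <- list(baseline = base, axis = axis,
                  peaks = do.call(rbind, truth_rows),
                  spike_band = unlist(spikes),
                  patient_factor = unlist(patient_factors),
                  config = cfg)
    list(set = set, truth = truth)
  })
}

#' Curated two-class benchmark configurations
#'
#' Returns a [synthetic_config()] for the standard benchmark difficulties.
#' `"separable"` plants, on top of the shared eight-peak library, two
#' class-differential peak heights (class B / class A ratio 1.5 at 1004 and
#' 1245 cm^-1) and one class-differential width (sigma ratio 1.3 at
#' 1450 cm^-1), with noise sd 0.02. `"moderate"` halves the effects
#' (ratios 1.25 / 1.15) and `"hard"` quarters them (1.125 / 1.075) while
#' doubling the noise. The `"width_only"` variant keeps only width
#' differentials (sigma ratio 1.3 at 1094 and 1450 cm^-1) with identical
#' class height distributions, and makes the nuisance structure realistic:
#' larger class-shared amplitude variability (`height_sd` 0.25,
#' `patient_effect_sd` 0.3, `sigma_sd` 0.5), band positions wandering by
#' `center_jitter_sd = 3` cm^-1, nuisance peaks present in only 70% of
#' spectra, and noise sd 0.08. Under amplitude variability, positional
#' wander and intermittent neighboring bands, a fixed-band flank intensity
#' confounds several latent quantities, whereas a fitted width is invariant
#' to them, so the class signal lives in peak shape rather than in any
#' single band.
#'
#' @param difficulty `"separable"`, `"moderate"` or `"hard"`.
#' @param seed integer seed for the generated cohort.
#' @param variant `"standard"` or `"width_only"`.
#' @param n_patients patients per class (default 20 for the standard
#'   variant, 14 for `width_only`).
#' @param cohort cohort name.
#' @return a `synthetic_config`.
#' @export
default_two_class_benchmark <- function(difficulty = c("separable", "moderate",
                                                       "hard"),
                                        seed = 1L,
                                        variant = c("standard", "width_only"),
                                        n_patients = NULL,
                                        cohort = "synthetic") {
  difficulty <- match.arg(difficulty)
  variant <- match.arg(variant)
  # width-only cohorts default to the size of a small disease class (the
  # regime where model-based features matter most); standard cohorts to 20
  n_patients <- n_patients %||% if (variant == "width_only") 14L else 20L
  pl <- default_peak_library()
  eff <- switch(difficulty,
                separable = list(h = 1.5, w = 1.3, noise = 0.02),
                moderate = list(h = 1.25, w = 1.15, noise = 0.02),
                hard = list(h = 1.125, w = 1.075, noise = 0.04))
  if (variant == "standard") {
    pl$height_b[pl$center %in% c(1004, 1245)] <-
      pl$height_a[pl$center %in% c(1004, 1245)] * eff$h
    pl$sigma_b[pl$center == 1450] <- pl$sigma_a[pl$center == 1450] * eff$w
    synthetic_config(peak_library = pl, noise_sd = eff$noise,
                     n_patients = n_patients, cohort = cohort, seed = seed)
  } else {
    diff_peaks <- pl$center %in% c(1094, 1450)
    pl$sigma_b[diff_peaks] <- pl$sigma_a[diff_peaks] * 1.3
    pl$height_sd <- 0.25
    pl$sigma_sd <- 0.5
    # nuisance bands come and go between samples; their overlap tails
    # contaminate fixed-band intensities but not the differential widths
    pl$presence_a[!diff_peaks] <- 0.7
    pl$presence_b[!diff_peaks] <- 0.7
    synthetic_config(peak_library = pl, noise_sd = 0.08,
                     center_jitter_sd = 3, n_patients = n_patients,
                     patient_effect_sd = 0.3, cohort = cohort, seed = seed)
  }
}

#' Write a generated cohort to disk
#'
#' Emits the spectral-matrix CSV, the metadata CSV and a ground-truth JSON.
#'
#' @param cohort a list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra_path <- file.path(dir, paste0(prefix, "_spectra.csv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_spectra_matrix(cohort$set, spectra_path, meta_path)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(c(spectra = spectra_path, meta = meta_path, truth = truth_path))
}
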