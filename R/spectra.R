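#' Construct a single Raman spectrum
#'
#' The atomic record: a strictly increasing Raman-shift axis (cm^-1), one
#' intensity value per band, and identifying metadata.
#'
#' @param axis numeric vector of Raman shifts in cm^-1, strictly increasing.
#' @param intensity numeric vector of signal values, same length as `axis`,
#'   all finite.
#' @param meta named list; recognised fields are `spectrum_id`, `patient_id`,
#'   `core_id`, `cohort`, `class_label`, `accumulation_index`. Missing ids
#'   default from `spectrum_id`.
#' @return an object of class `raman_spectrum`.
#' @export
spectrum <- function(axis, intensity, meta = list()) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("axis and intensity must have equal length (", length(axis), " vs ",
         length(intensity), ")")
  if (length(axis) <= 1L)
    stop("a spectrum needs more than one band")
  d <- diff(axis)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("axis must be strictly increasing; violation at index ", bad,
         " (", axis[bad - 1L], " -> ", axis[bad], ")")
  }
  if (any(!is.finite(intensity)))
    stop("non-finite intensity at band index ", which(!is.finite(intensity))[1L])
  meta <- normalize_meta_record(meta)
  structure(list(axis = axis, intensity = intensity, meta = meta),
            class = "raman_spectrum")
}

normalize_meta_record <- function(meta) {
  meta <- as.list(meta)
  sid <- meta$spectrum_id %||% "s1"
  list(spectrum_id = as.character(sid),
       patient_id = as.character(meta$patient_id %||% sid),
       core_id = as.character(meta$core_id %||% sid),
       cohort = as.character(meta$cohort %||% "unknown"),
       class_label = if (is.null(meta$class_label)) NA_character_
                     else as.character(meta$class_label),
       accumulation_index = if (is.null(meta$accumulation_index)) NA_integer_
                            else as.integer(meta$accumulation_index))
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum %s: %d bands, %.1f-%.1f cm^-1>\n",
              x$meta$spectrum_id, length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Construct a set of spectra on a shared axis
#'
#' The dataset unit: an `n_spectra x n_bands` intensity matrix whose rows all
#' conform to one Raman-shift grid, with per-spectrum metadata (patient
#' grouping, class labels).
#'
#' @param axis shared Raman-shift grid (cm^-1), strictly increasing.
#' @param matrix numeric matrix, one row per spectrum, `length(axis)` columns.
#' @param meta data.frame with one row per spectrum; columns `spectrum_id`,
#'   `patient_id`, `core_id`, `cohort`, `class_label` (missing columns are
#'   filled with defaults, `patient_id` defaulting to `spectrum_id`).
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(axis, matrix, meta = NULL) {
  axis <- as.numeric(axis)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (ncol(matrix) != length(axis))
    stop("matrix must have one column per band (", ncol(matrix), " vs ",
         length(axis), ")")
  if (length(axis) <= 1L) stop("axis needs more than one band")
  d <- diff(axis)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("axis must be strictly increasing; violation at index ", bad)
  }
  if (any(!is.finite(matrix)))
    stop("non-finite intensity values in spectra matrix")
  n <- nrow(matrix)
  meta <- normalize_meta_table(meta, n)
  if (nrow(meta) != n)
    stop("metadata rows (", nrow(meta), ") do not match spectra (", n, ")")
  if (any(!nzchar(meta$patient_id)))
    stop("patient_id must be non-empty for every spectrum")
  rownames(matrix) <- meta$spectrum_id
  structure(list(axis = axis, matrix = matrix, meta = meta),
            class = "spectra_set")
}

normalize_meta_table <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(spectrum_id = paste0("s", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$spectrum_id)) meta$spectrum_id <- paste0("s", seq_len(n))
  meta$spectrum_id <- as.character(meta$spectrum_id)
  nr <- nrow(meta)
  if (is.null(meta$patient_id)) meta$patient_id <- meta$spectrum_id
  meta$patient_id <- as.character(meta$patient_id)
  if (is.null(meta$core_id)) meta$core_id <- meta$spectrum_id
  meta$core_id <- as.character(meta$core_id)
  if (is.null(meta$cohort)) meta$cohort <- rep_len("unknown", nr)
  meta$cohort <- as.character(meta$cohort)
  if (is.null(meta$class_label)) meta$class_label <- rep_len(NA_character_, nr)
  meta$class_label <- as.character(meta$class_label)
  meta[, c("spectrum_id", "patient_id", "core_id", "cohort", "class_label")]
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set: %d spectra x %d bands, %.1f-%.1f cm^-1, %d patients>\n",
              nrow(x$matrix), length(x$axis), min(x$axis), max(x$axis),
              length(unique(x$meta$patient_id))))
  invisible(x)
}

#' @rdname spectra_set
#' @param x a `spectra_set`.
#' @export
n_spectra <- function(x) nrow(x$matrix)

#' Per-spectrum class labels of a set
#' @param x a `spectra_set`.
#' @return character vector (may contain `NA` for unlabelled spectra).
#' @export
set_labels <- function(x) x$meta$class_label

#' Per-spectrum patient groups of a set
#' @param x a `spectra_set`.
#' @export
set_groups <- function(x) x$meta$patient_id

#' Extract one spectrum from a set
#' @param x a `spectra_set`.
#' @param i row index.
#' @return a `raman_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  spectrum(x$axis, x$matrix[i, ], as.list(x$meta[i, ]))
}

# Row subset preserving label/group/meta pairing.
subset_spectra <- function(x, idx) {
  spectra_set(x$axis, x$matrix[idx, , drop = FALSE], x$meta[idx, , drop = FALSE])
}

#' Read a spectral matrix (and optional metadata) from CSV
#'
#' The on-disk convention is a comma-separated table whose first column
#' (`wavenumber`) is the Raman-shift axis and whose remaining columns each
#' hold one spectrum. The optional metadata CSV is keyed by `spectrum_id`
#' matching the spectrum column names.
#'
#' @param path path to the spectral-matrix CSV.
#' @param meta_path optional path to the metadata CSV with columns
#'   `spectrum_id`, `patient_id`, `core_id`, `cohort`, `class_label`.
#' @return a validated [spectra_set()].
#' @export
read_spectra_matrix <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("spectral matrix file not found: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE, colClasses = "character"),
                 error = function(e) stop("format error reading ", path, ": ",
                                          conditionMessage(e)))
  if (ncol(df) < 2L) stop("format error: need a wavenumber column plus >=1 spectrum")
  num <- vector("list", ncol(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v) & !is.na(df[[j]]))[1L]
      bad <- if (is.na(bad)) which(is.na(v))[1L] else bad
      stop("parse error: unreadable numeric at row ", bad, ", column '",
           names(df)[j], "'")
    }
    num[[j]] <- v
  }
  axis <- num[[1L]]
  d <- diff(axis)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("validation error: non-monotonic wavenumber axis at row ", bad)
  }
  mat <- t(do.call(cbind, num[-1L]))
  ids <- names(df)[-1L]
  meta <- data.frame(spectrum_id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
    md <- read.csv(meta_path, stringsAsFactors = FALSE)
    if (is.null(md$spectrum_id)) stop("metadata must have a spectrum_id column")
    md$spectrum_id <- as.character(md$spectrum_id)
    meta <- merge(meta, md, by = "spectrum_id", all.x = TRUE, sort = FALSE)
    meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
    # spectra absent from the metadata fall back to defaults
    if (!is.null(meta$patient_id)) {
      missing_pid <- is.na(meta$patient_id)
      meta$patient_id[missing_pid] <- meta$spectrum_id[missing_pid]
    }
  }
  spectra_set(axis, mat, meta)
}

#' Write a spectra set to CSV
#'
#' Inverse of [read_spectra_matrix()]; values are written with enough digits
#' for float round-trip.
#'
#' @param set a `spectra_set` with at least one spectrum.
#' @param path output path for the spectral-matrix CSV.
#' @param meta_path optional output path for the metadata CSV.
#' @return `path`, invisibly.
#' @export
write_spectra_matrix <- function(set, path, meta_path = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$matrix) == 0L) stop("refusing to write an empty spectra set")
  df <- data.frame(wavenumber = format_full(set$axis), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(set$matrix)))
    df[[set$meta$spectrum_id[i]]] <- format_full(set$matrix[i, ])
  ok <- tryCatch({write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE},
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e)))
  if (!is.null(meta_path))
    write.csv(set$meta, meta_path, row.names = FALSE)
  invisible(path)
}

format_full <- function(x) sprintf("%.17g", x)

#' Restrict a spectra set to a wavenumber window
#'
#' Drops all bands outside `[keep_lo, keep_hi]`. Used to discard the border
#' regions distorted by the rolling-ball baseline estimate (by default the
#' ends of a 602-1726 cm^-1 acquisition outside 669-1707 cm^-1).
#'
#' @param set a `spectra_set`.
#' @param keep_lo,keep_hi window bounds in cm^-1, `keep_lo < keep_hi`.
#' @return the restricted `spectra_set`; metadata unchanged.
#' @export
restrict_axis <- function(set, keep_lo, keep_hi) {
  stopifnot(inherits(set, "spectra_set"))
  if (!(keep_lo < keep_hi)) stop("keep_lo must be < keep_hi")
  keep <- set$axis >= keep_lo & set$axis <= keep_hi
  if (!any(keep))
    stop("range error: no bands inside [", keep_lo, ", ", keep_hi, "]")
  spectra_set(set$axis[keep], set$matrix[, keep, drop = FALSE], set$meta)
}
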