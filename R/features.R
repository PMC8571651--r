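#' Construct a feature table
#'
#' Holds an `n_spectra x n_features` value matrix together with feature
#' identities (`kind` in intensity/height/width plus a wavenumber position)
#' and an optional per-cell quality mask, row-aligned with a `spectra_set`.
#'
#' @param values numeric matrix, finite.
#' @param ids data.frame with columns `kind` and `position` (cm^-1), one row
#'   per feature; `kind`/`position` pairs must be unique.
#' @param quality optional logical matrix of flagged cells, same shape as
#'   `values`.
#' @param meta optional per-spectrum metadata (carried through from the
#'   originating `spectra_set`).
#' @return a `feature_table`.
#' @export
feature_table <- function(values, ids, quality = NULL, meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- as.data.frame(ids, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "position") %in% names(ids)))
  if (nrow(ids) != ncol(values))
    stop("ids must describe each column (", nrow(ids), " vs ", ncol(values), ")")
  key <- paste(ids$kind, signif(ids$position, 10), sep = "@")
  if (anyDuplicated(key)) stop("feature ids must be unique")
  if (any(!is.finite(values))) stop("feature values must be finite")
  colnames(values) <- key
  structure(list(values = values, ids = ids, quality = quality, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d spectra x %d features (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$ids$kind), collapse = "+")))
  invisible(x)
}

#' Feature table from SNV spectral intensities
#'
#' The intensity feature set: one feature per band, its position being the
#' band's Raman shift.
#'
#' @param set a preprocessed `spectra_set`.
#' @return a `feature_table` with `kind = "intensity"`.
#' @export
intensity_features <- function(set) {
  feature_table(set$matrix,
                data.frame(kind = "intensity", position = set$axis),
                meta = set$meta)
}

# Column subset of a feature table by integer index.
subset_features <- function(table, cols) {
  feature_table(table$values[, cols, drop = FALSE],
                table$ids[cols, , drop = FALSE],
                quality = if (!is.null(table$quality))
                  table$quality[, cols, drop = FALSE],
                meta = table$meta)
}

#' Rank features by L1-SVM coefficient magnitude
#'
#' Fits an L1-regularized linear SVM ([l1svm_fit()]) on the internally
#' column-standardized table and orders features by `|coefficient|`
#' descending. Ties among non-zero coefficients break toward the lower
#' wavenumber; zero-coefficient features are retained at the tail in stable
#' input order.
#'
#' @param table a `feature_table`.
#' @param labels binary class labels, one per row.
#' @param C regularization strength of the L1 SVM (> 0).
#' @return a `ranked_features` data.frame with columns `kind`, `position`,
#'   `importance`, `rank`, `column` (index into the source table).
#' @export
rank_features_l1 <- function(table, labels, C) {
  stopifnot(inherits(table, "feature_table"))
  labels <- labels[!is.na(labels)]
  if (length(unique(labels)) < 2L)
    stop("argument error: feature ranking needs two classes")
  z <- standardize_columns(table$values)
  fit <- l1svm_fit(z$x, labels, C)
  imp <- abs(fit$w)
  nz <- which(imp > 0)
  zero <- which(imp == 0)
  ord_nz <- nz[order(-imp[nz], table$ids$position[nz], nz)]
  ord <- c(ord_nz, zero)
  out <- data.frame(kind = table$ids$kind[ord],
                    position = table$ids$position[ord],
                    importance = imp[ord],
                    rank = seq_along(ord),
                    column = ord)
  class(out) <- c("ranked_features", class(out))
  out
}

standardize_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv <= 0 | !is.finite(sdv)] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), center = mu, scale = sdv)
}

#' Remove wavenumber-neighboring redundant features
#'
#' Iterative redundancy pruning: accept the highest-ranked remaining feature,
#' remove every other feature whose position lies within `+/- n_neighbor`
#' cm^-1 of it, and repeat on the survivors in rank order. Neighboring bands
#' are strongly correlated and carry the same information; this rule thins
#' them (e.g. a top feature at 780 cm^-1 with `n_neighbor = 5` removes all
#' features between 775 and 785 cm^-1 before the next acceptance).
#'
#' @param ranking a `ranked_features` data.frame (positions required).
#' @param n_neighbor removal half-width in cm^-1, >= 0. Zero removes only
#'   exact-position duplicates.
#' @return the accepted subset, in original rank order.
#' @export
remove_neighbors <- function(ranking, n_neighbor) {
  if (n_neighbor < 0) stop("n_neighbor must be >= 0")
  pos <- ranking$position
  n <- length(pos)
  alive <- rep(TRUE, n)
  accepted <- logical(n)
  for (i in seq_len(n)) {        # rows are already in rank order
    if (!alive[i]) next
    accepted[i] <- TRUE
    alive[alive & abs(pos - pos[i]) <= n_neighbor] <- FALSE
  }
  out <- ranking[accepted, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Keep the top-k ranked features
#'
#' @param ranking a `ranked_features` data.frame.
#' @param k number of features to keep, >= 1. If `k` exceeds availability the
#'   full ranking is returned with a warning.
#' @return the first `min(k, nrow(ranking))` rows in rank order.
#' @export
select_top_k <- function(ranking, k) {
  if (k < 1) stop("argument error: k must be >= 1")
  if (k > nrow(ranking)) {
    warning("k = ", k, " exceeds the ", nrow(ranking), " available features")
    k <- nrow(ranking)
  }
  ranking[seq_len(k), , drop = FALSE]
}

#' Combine the selected intensity and peak feature tables
#'
#' Column-wise concatenation of the two selected sets into the single vector
#' passed to the RBF-SVM classifier; feature kinds are preserved.
#'
#' @param intensity_sel,peak_sel `feature_table` objects with identical row
#'   alignment (either may be `NULL`).
#' @return the combined `feature_table`.
#' @export
combine_features <- function(intensity_sel, peak_sel) {
  if (is.null(intensity_sel)) return(peak_sel)
  if (is.null(peak_sel)) return(intensity_sel)
  if (nrow(intensity_sel$values) != nrow(peak_sel$values))
    stop("alignment error: row counts differ (",
         nrow(intensity_sel$values), " vs ", nrow(peak_sel$values), ")")
  feature_table(cbind(intensity_sel$values, peak_sel$values),
                rbind(intensity_sel$ids, peak_sel$ids),
                meta = intensity_sel$meta %||% peak_sel$meta)
}

#' Write a selected-feature manifest to JSON
#'
#' @param ranking a `ranked_features` data.frame.
#' @param path output path.
#' @param task optional task name stored alongside.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(ranking, path, task = NULL) {
  entries <- lapply(seq_len(nrow(ranking)), function(i)
    list(task = task, kind = ranking$kind[i], position = ranking$position[i],
         importance = ranking$importance[i], rank = ranking$rank[i]))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
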