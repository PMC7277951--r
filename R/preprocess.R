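# Internal-standard recalibration, m/z alignment, prevalence filtering,
# isotopologue linking.

#' Construct a feature matrix
#'
#' @param mz Numeric vector of consensus m/z values (Da), strictly increasing.
#' @param intensities Numeric matrix, features x samples; 0 means "not
#'   detected".
#' @param sample_ids Character vector matching the matrix columns.
#' @param isotope_parent Optional integer vector: for each feature, the row
#'   index of the monoisotopic feature it is an isotopologue of, or `NA`.
#' @return An object of class `ldt_features`.
#' @export
feature_matrix <- function(mz, intensities, sample_ids,
                           isotope_parent = rep(NA_integer_, length(mz))) {
  intensities <- as.matrix(intensities)
  stopifnot(length(mz) == nrow(intensities),
            length(sample_ids) == ncol(intensities),
            length(isotope_parent) == length(mz))
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("feature m/z values must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  dimnames(intensities) <- list(NULL, as.character(sample_ids))
  structure(list(mz = as.numeric(mz), intensities = intensities,
                 sample_ids = as.character(sample_ids),
                 isotope_parent = as.integer(isotope_parent)),
            class = "ldt_features")
}

#' @exportS3Method base::print
print.ldt_features <- function(x, ...) {
  cat(sprintf("<ldt_features> %d features x %d samples (%d isotopologue-linked)\n",
              length(x$mz), length(x$sample_ids), sum(!is.na(x$isotope_parent))))
  invisible(x)
}

#' @exportS3Method
dim.ldt_features <- function(x) dim(x$intensities)

#' Recalibrate intensities to an internal standard
#'
#' Divides every intensity by the intensity of the peak nearest to the
#' internal standard m/z (losartan, m/z 423.169, by default), so the standard
#' peak's recalibrated intensity is exactly 1. This removes per-sample global
#' intensity scale.
#'
#' @param s An [new_spectrum()] object.
#' @param standard_mz Internal-standard m/z (Da). Default 423.169.
#' @param tol Matching tolerance (Da) around `standard_mz`.
#' @return A recalibrated [new_spectrum()] object.
#' @export
recalibrate_intensities <- function(s, standard_mz = 423.169, tol = 0.005) {
  stopifnot(inherits(s, "ldt_spectrum"), tol > 0)
  d <- abs(s$mz - standard_mz)
  i <- which.min(d)
  if (d[i] > tol) {
    stop(sprintf("sample '%s': no peak within %g Da of internal standard m/z %g",
                 s$sample_id, tol, standard_mz), call. = FALSE)
  }
  ref <- s$intensity[i]
  if (ref <= 0) {
    stop(sprintf("sample '%s': internal standard peak has non-positive intensity",
                 s$sample_id), call. = FALSE)
  }
  s$intensity <- s$intensity / ref
  s
}

#' Align spectra into a feature matrix
#'
#' Pools all peaks, sorts them by m/z, and cuts the pooled sequence wherever
#' the gap between adjacent peaks exceeds `tol` (greedy single-linkage
#' clustering). Each resulting cluster is one feature; its consensus m/z is
#' the intensity-weighted mean of member peaks. If one sample contributes
#' several peaks to a feature their intensities are summed; samples without a
#' member peak get 0.
#'
#' @param spectra A list of [new_spectrum()] objects (>= 1), with unique sample
#'   IDs.
#' @param tol Gap tolerance (Da), > 0. Default 0.005.
#' @return An [feature_matrix()] object; column order follows the input order
#'   of `spectra`.
#' @export
align_spectra <- function(spectra, tol = 0.005) {
  if (length(spectra) == 0L) stop("need at least one spectrum", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, TRUE, "ldt_spectrum")))
  if (!(is.numeric(tol) && length(tol) == 1L && tol > 0)) {
    stop("tol must be a single positive number", call. = FALSE)
  }
  sample_ids <- vapply(spectra, `[[`, "", "sample_id")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs across spectra", call. = FALSE)
  }
  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  ity <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  samp <- rep(seq_along(spectra), vapply(spectra, function(s) length(s$mz), 1L))
  o <- order(mz)
  mz <- mz[o]; ity <- ity[o]; samp <- samp[o]
  # cut wherever the gap between adjacent pooled peaks exceeds tol
  cut_after <- diff(mz) > tol
  feat <- cumsum(c(1L, as.integer(cut_after)))
  n_feat <- feat[length(feat)]
  w <- ity
  w[w <= 0] <- .Machine$double.eps  # zero-intensity peaks still get a position
  cons <- as.numeric(rowsum(mz * w, feat) / rowsum(w, feat))
  m <- matrix(0, n_feat, length(spectra),
              dimnames = list(NULL, sample_ids))
  contrib <- rowsum(ity, group = (samp - 1L) * n_feat + feat)
  idx <- as.integer(rownames(contrib))
  m[cbind((idx - 1L) %% n_feat + 1L, (idx - 1L) %/% n_feat + 1L)] <- contrib
  feature_matrix(cons, m, sample_ids)
}

#' Filter features by detection prevalence
#'
#' Keeps features detected (nonzero intensity) in at least `min_nonzero`
#' samples. The default of 10 keeps features seen in more than nine samples.
#'
#' @param fm An [feature_matrix()] object.
#' @param min_nonzero Minimum number of samples with nonzero intensity
#'   (>= 1). Default 10.
#' @return A filtered [feature_matrix()]; feature order preserved, isotopologue
#'   links re-indexed (links to dropped parents are cleared).
#' @export
filter_features <- function(fm, min_nonzero = 10L) {
  stopifnot(inherits(fm, "ldt_features"), min_nonzero >= 1L)
  keep <- rowSums(fm$intensities > 0) >= min_nonzero
  subset_features(fm, keep)
}

# keep: logical over features; remaps isotope_parent indices
subset_features <- function(fm, keep) {
  new_index <- rep(NA_integer_, length(fm$mz))
  new_index[keep] <- seq_len(sum(keep))
  parent <- fm$isotope_parent[keep]
  parent <- ifelse(is.na(parent), NA_integer_, new_index[parent])
  feature_matrix(fm$mz[keep], fm$intensities[keep, , drop = FALSE],
                 fm$sample_ids, parent)
}

#' Link isotopologue features to their monoisotopic parents
#'
#' Feature j is marked an isotopologue of a lower-mass feature i when the m/z
#' spacing matches k heavy-isotope increments (k in 1:2, increment 1.00336 Da
#' for 13C) within `tol`, and the across-sample intensity correlation between
#' i and j is at least `min_corr`. Correlations use pairwise-complete nonzero
#' cells. Isotopologues are retained in the matrix but excluded from candidate
#' search downstream.
#'
#' @param fm An [feature_matrix()] with >= 2 samples.
#' @param delta Isotope spacing (Da). Default 1.00336.
#' @param tol Spacing tolerance (Da). Default 0.005.
#' @param min_corr Minimum intensity correlation. Default 0.7.
#' @param min_obs Minimum pairwise-complete nonzero observations for a
#'   correlation to be evaluated. Default 5.
#' @return `fm` with `isotope_parent` filled in.
#' @export
link_isotopologues <- function(fm, delta = 1.00336, tol = 0.005,
                               min_corr = 0.7, min_obs = 5L) {
  stopifnot(inherits(fm, "ldt_features"))
  if (length(fm$sample_ids) < 2L) {
    stop("need >= 2 samples to correlate intensities", call. = FALSE)
  }
  n <- length(fm$mz)
  parent <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (k in 1:2) {
      target <- fm$mz[j] - k * delta
      if (target <= 0) next
      cand <- which(abs(fm$mz - target) <= tol)
      cand <- cand[cand != j & is.na(parent[cand])]  # parent must be monoisotopic
      if (length(cand) == 0L) next
      for (i in cand[order(abs(fm$mz[cand] - target))]) {
        xi <- fm$intensities[i, ]; xj <- fm$intensities[j, ]
        ok <- xi > 0 & xj > 0
        if (sum(ok) < min_obs) next
        if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
        if (stats::cor(xi[ok], xj[ok]) >= min_corr) {
          parent[j] <- i
          break
        }
      }
      if (!is.na(parent[j])) break
    }
  }
  fm$isotope_parent <- parent
  fm
}

#' Read spectra listed in a manifest and build a recalibrated feature matrix
#'
#' Convenience wrapper: reads every peak list in the manifest, recalibrates
#' each to the internal standard, aligns, prevalence-filters, and links
#' isotopologues.
#'
#' @param manifest A manifest `data.frame` from [read_manifest()].
#' @param tol Alignment / search tolerance (Da). Default 0.005.
#' @param standard_mz Internal-standard m/z. Default 423.169.
#' @param min_nonzero Prevalence filter. Default 10.
#' @param min_corr Isotopologue correlation threshold. Default 0.7.
#' @return An [feature_matrix()].
#' @export
build_feature_matrix <- function(manifest, tol = 0.005, standard_mz = 423.169,
                                 min_nonzero = 10L, min_corr = 0.7) {
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    recalibrate_intensities(
      read_peaklist(manifest$path[i], sample_id = manifest$sample_id[i]),
      standard_mz = standard_mz, tol = tol
    )
  })
  fm <- align_spectra(spectra, tol = tol)
  fm <- filter_features(fm, min_nonzero = min_nonzero)
  link_isotopologues(fm, tol = tol, min_corr = min_corr)
}

#' Read or write a feature matrix as tab-delimited text
#'
#' First column `mz`, second column `isotope_parent` (empty when
#' monoisotopic), remaining columns per-sample intensities with sample IDs as
#' the header.
#'
#' @param fm An [feature_matrix()] object.
#' @param path File path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "ldt_features"))
  df <- data.frame(mz = sprintf("%.6f", fm$mz),
                   isotope_parent = ifelse(is.na(fm$isotope_parent), "",
                                           as.character(fm$isotope_parent)),
                   fm$intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  parent <- suppressWarnings(as.integer(df[[2L]]))
  ints <- vapply(df[-(1:2)], as.numeric, numeric(nrow(df)))
  feature_matrix(as.numeric(df[[1L]]), matrix(ints, nrow = nrow(df)),
                 colnames(df)[-(1:2)], parent)
}
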