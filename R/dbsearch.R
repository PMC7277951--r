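# Positive-mode adduct search: feature m/z -> candidate metabolites.

# Singly charged cation offsets (Da): cation mass minus one electron.
ADDUCT_OFFSETS <- c("M+H" = 1.007276, "M+Na" = 22.989218, "M+K" = 38.963158)

#' Expected m/z of a positive-mode adduct
#'
#' @param neutral_mass Monoisotopic neutral mass (Da), > 0.
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M+K"`.
#' @return `neutral_mass` plus the singly charged cation offset
#'   (+1.007276, +22.989218, +38.963158 Da respectively).
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0", call. = FALSE)
  adduct <- as.character(adduct)
  if (!all(adduct %in% names(ADDUCT_OFFSETS))) {
    stop("unknown adduct: ",
         paste(setdiff(adduct, names(ADDUCT_OFFSETS)), collapse = ", "),
         "; known: ", paste(names(ADDUCT_OFFSETS), collapse = ", "),
         call. = FALSE)
  }
  neutral_mass + unname(ADDUCT_OFFSETS[adduct])
}

#' Match features to candidate metabolites by accurate mass
#'
#' For every non-isotopologue feature and every adduct in `adducts`, emits all
#' metabolites whose adduct m/z lies within `tol` (inclusive) of the feature
#' m/z. Uses interval lookup on the mass-sorted metabolite table.
#'
#' @param fm An [feature_matrix()] object.
#' @param db A [metabolite_db()] object (sorted by neutral mass).
#' @param tol Maximum absolute mass error (Da), inclusive. Default 0.005.
#' @param adducts Adducts to consider. Default all of `M+H`, `M+Na`, `M+K`.
#' @return A `data.frame` (class `ldt_candidates`) with columns
#'   `feature_index`, `metabolite_id`, `adduct`, `mass_error` (feature m/z
#'   minus adduct m/z, Da). Features without any match are absent.
#' @export
match_candidates <- function(fm, db, tol = 0.005,
                             adducts = names(ADDUCT_OFFSETS)) {
  stopifnot(inherits(fm, "ldt_features"), inherits(db, "ldt_metabolites"),
            tol > 0)
  masses <- db$neutral_mass  # ascending by construction
  feats <- which(is.na(fm$isotope_parent))
  out <- vector("list", length(adducts))
  for (a in seq_along(adducts)) {
    off <- ADDUCT_OFFSETS[[adducts[a]]]
    neutral <- fm$mz[feats] - off
    # interval lookup with a hair of slack; the exact inclusive comparison
    # |mz - adduct_mz| <= tol is applied below so boundary hits are kept
    slack <- 1e-9
    lo <- findInterval(neutral - tol - slack, masses, left.open = TRUE) + 1L
    hi <- findInterval(neutral + tol + slack, masses)
    n_hit <- pmax(hi - lo + 1L, 0L)
    if (sum(n_hit) == 0L) next
    fi <- rep(feats[n_hit > 0L], n_hit[n_hit > 0L])
    mi <- unlist(lapply(which(n_hit > 0L), function(k) lo[k]:hi[k]),
                 use.names = FALSE)
    err <- fm$mz[fi] - (masses[mi] + off)
    keep <- abs(err) <= tol
    out[[a]] <- data.frame(
      feature_index = fi[keep],
      metabolite_id = db$metabolite_id[mi[keep]],
      adduct = adducts[a],
      mass_error = err[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(feature_index = integer(0), metabolite_id = character(0),
                      adduct = character(0), mass_error = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$feature_index, res$metabolite_id, res$adduct), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ldt_candidates", "data.frame")
  res
}

#' Read or write a candidate table as tab-delimited text
#'
#' @param ct An `ldt_candidates` data frame from [match_candidates()].
#' @param path File path.
#' @export
write_candidates <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character",
                                         "numeric"))
  class(df) <- c("ldt_candidates", "data.frame")
  df
}
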