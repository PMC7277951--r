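#' mzldt: direct-infusion metabolomics pipeline for pathway-based diagnostics
#'
#' From per-sample peak lists (m/z, intensity) to putative metabolite
#' annotations, permutation-based pathway representation scores, a per-subject
#' diagnostic score, and a pathway-names-cloud visualization. See
#' `vignette("mzldt-methods")` for the underlying model and the design choices.
#'
#' @keywords internal
"_PACKAGE"

# ---- delimited-text helpers -------------------------------------------------

# Tab- or comma-delimited, auto-detected from the first line; decimal point
# only. Returns a character matrix plus whether a header row was present.
read_delim_table <- function(path, n_cols, numeric_cols, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  split_one <- function(x) {
    parts <- trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
    if (endsWith(x, sep)) parts <- c(parts, "")  # keep a trailing empty field
    parts
  }
  rows <- lapply(lines, split_one)
  widths <- lengths(rows)
  if (any(widths < n_cols)) {
    bad <- which(widths < n_cols)[1L]
    stop(sprintf("%s: line %d of %s has %d field(s), expected %d",
                 what, bad, path, widths[bad], n_cols), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(rows, function(r) r[seq_len(max(n_cols, length(r)))[seq_len(n_cols)]]))
  # optional header: every numeric-required field of row 1 is non-numeric
  # (a single bad cell is a parse error, not a header)
  header <- FALSE
  if (length(numeric_cols) > 0L && nrow(mat) >= 1L) {
    first_num <- suppressWarnings(as.numeric(mat[1L, numeric_cols]))
    if (all(is.na(first_num))) {
      header <- TRUE
      mat <- mat[-1L, , drop = FALSE]
      if (nrow(mat) == 0L) stop("empty file (header only): ", path, call. = FALSE)
    }
  }
  for (j in numeric_cols) {
    vals <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L] + as.integer(header)
      stop(sprintf("%s: non-numeric value '%s' at line %d of %s",
                   what, mat[which(is.na(vals))[1L], j], bad, path), call. = FALSE)
    }
  }
  list(mat = mat, header = header)
}

# ---- Spectrum ---------------------------------------------------------------

#' Construct a spectrum (one subject's peak list)
#'
#' Peaks are sorted by ascending m/z; rows with identical m/z are merged by
#' summing their intensities (vendor exports commonly split peaks).
#'
#' @param sample_id Sample identifier.
#' @param mz Numeric vector of m/z values (Da), strictly positive.
#' @param intensity Numeric vector of intensities (arbitrary units, >= 0).
#' @return An object of class `ldt_spectrum`: a list with `sample_id`, `mz`,
#'   `intensity`, and `n_merged` (number of duplicate rows merged).
#' @export
new_spectrum <- function(sample_id, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) == 0L) stop("spectrum has no peaks", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("m/z values must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  n_in <- length(mz)
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(
    list(sample_id = as.character(sample_id), mz = mz, intensity = intensity,
         n_merged = n_in - length(mz)),
    class = "ldt_spectrum"
  )
}

#' @exportS3Method base::print
print.ldt_spectrum <- function(x, ...) {
  cat(sprintf("<ldt_spectrum> sample '%s': %d peaks, m/z %.4f-%.4f\n",
              x$sample_id, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read a peak list from delimited text
#'
#' Two numeric columns (m/z, intensity), tab- or comma-delimited with an
#' optional header. Duplicate m/z rows are merged by intensity sum; the number
#' of merged rows is recorded in the returned object and reported via a
#' message.
#'
#' @param path Path to the peak-list file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return An [new_spectrum()] object.
#' @export
read_peaklist <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- read_delim_table(path, n_cols = 2L, numeric_cols = 1:2, what = "peak list")
  s <- new_spectrum(sample_id,
                mz = as.numeric(tab$mat[, 1L]),
                intensity = as.numeric(tab$mat[, 2L]))
  if (s$n_merged > 0L) {
    message(sprintf("read_peaklist: merged %d duplicate m/z row(s) in %s",
                    s$n_merged, path))
  }
  s
}

#' Write a peak list as tab-delimited text
#'
#' @param s An [new_spectrum()] object.
#' @param path Output path.
#' @export
write_peaklist <- function(s, path) {
  stopifnot(inherits(s, "ldt_spectrum"))
  utils::write.table(
    data.frame(mz = s$mz, intensity = s$intensity),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# ---- MetaboliteDB -----------------------------------------------------------

#' Construct a metabolite table
#'
#' @param metabolite_id,name,neutral_mass,xref_id Parallel vectors: unique
#'   identifiers, display names, monoisotopic neutral masses (Da, > 0), and a
#'   pathway-capable cross-reference (e.g. a KEGG compound ID).
#' @return A `data.frame` of class `ldt_metabolites`, sorted by neutral mass
#'   (ascending) so candidate search can use interval lookup.
#' @export
metabolite_db <- function(metabolite_id, name, neutral_mass, xref_id) {
  metabolite_id <- as.character(metabolite_id)
  if (anyDuplicated(metabolite_id)) {
    stop("duplicate metabolite_id: ",
         paste(unique(metabolite_id[duplicated(metabolite_id)]), collapse = ", "),
         call. = FALSE)
  }
  neutral_mass <- as.numeric(neutral_mass)
  if (any(!is.finite(neutral_mass)) || any(neutral_mass <= 0)) {
    stop("neutral masses must be finite and > 0", call. = FALSE)
  }
  df <- data.frame(metabolite_id = metabolite_id, name = as.character(name),
                   neutral_mass = neutral_mass, xref_id = as.character(xref_id),
                   stringsAsFactors = FALSE)
  df <- df[order(df$neutral_mass), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ldt_metabolites", "data.frame")
  df
}

#' Read a metabolite table (id, name, monoisotopic mass, xref)
#'
#' @param path Path to a delimited file with columns
#'   `metabolite_id, name, neutral_mass, xref_id`.
#' @return A [metabolite_db()] object, sorted by neutral mass.
#' @export
read_metabolite_db <- function(path) {
  tab <- read_delim_table(path, n_cols = 4L, numeric_cols = 3L,
                          what = "metabolite table")
  metabolite_db(tab$mat[, 1L], tab$mat[, 2L],
                as.numeric(tab$mat[, 3L]), tab$mat[, 4L])
}

#' @rdname read_metabolite_db
#' @param db A [metabolite_db()] object.
#' @export
write_metabolite_db <- function(db, path) {
  stopifnot(inherits(db, "ldt_metabolites"))
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- PathwayDB --------------------------------------------------------------

#' Construct a pathway database
#'
#' @param pathway_id Character vector of unique pathway identifiers.
#' @param name Pathway display names.
#' @param members List of character vectors of member metabolite IDs; each
#'   pathway must have at least one member. Members are deduplicated.
#' @return An object of class `ldt_pathways`.
#' @export
pathway_db <- function(pathway_id, name, members) {
  pathway_id <- as.character(pathway_id)
  if (anyDuplicated(pathway_id)) {
    stop("duplicate pathway_id: ",
         paste(unique(pathway_id[duplicated(pathway_id)]), collapse = ", "),
         call. = FALSE)
  }
  members <- lapply(members, function(m) unique(as.character(m[nzchar(m)])))
  if (any(lengths(members) == 0L)) {
    stop("pathway with zero members: ",
         paste(pathway_id[lengths(members) == 0L], collapse = ", "),
         call. = FALSE)
  }
  names(members) <- pathway_id
  structure(list(pathway_id = pathway_id, name = as.character(name),
                 members = members),
            class = "ldt_pathways")
}

#' @exportS3Method base::print
print.ldt_pathways <- function(x, ...) {
  cat(sprintf("<ldt_pathways> %d pathways, %d distinct member metabolites\n",
              length(x$pathway_id), length(unique(unlist(x$members)))))
  invisible(x)
}

#' Number of pathways in a pathway database
#' @param x An `ldt_pathways` object.
#' @export
n_pathways <- function(x) length(x$pathway_id)

#' Read a pathway table (pathway_id, name, semicolon-joined member IDs)
#'
#' @param path Path to a delimited file; the third column joins member
#'   metabolite IDs with `;`.
#' @return A [pathway_db()] object.
#' @export
read_pathway_db <- function(path) {
  tab <- read_delim_table(path, n_cols = 3L, numeric_cols = integer(0),
                          what = "pathway table")
  mat <- tab$mat
  # tolerate a header row by name convention
  if (tolower(mat[1L, 1L]) %in% c("pathway_id", "pathway")) {
    mat <- mat[-1L, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("empty pathway table: ", path, call. = FALSE)
  members <- strsplit(mat[, 3L], ";", fixed = TRUE)
  pathway_db(mat[, 1L], mat[, 2L], members)
}

#' @rdname read_pathway_db
#' @param pdb A [pathway_db()] object.
#' @export
write_pathway_db <- function(pdb, path) {
  stopifnot(inherits(pdb, "ldt_pathways"))
  utils::write.table(
    data.frame(pathway_id = pdb$pathway_id, name = pdb$name,
               members = vapply(pdb$members, paste, "", collapse = ";")),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# ---- SampleManifest ---------------------------------------------------------

#' Read a sample manifest (sample_id, group, path)
#'
#' Group labels must be `case` or `control`. Relative peak-list paths are
#' resolved against the manifest's directory.
#'
#' @param path Path to the manifest file.
#' @return A `data.frame` with columns `sample_id`, `group`, `path`.
#' @export
read_manifest <- function(path) {
  tab <- read_delim_table(path, n_cols = 3L, numeric_cols = integer(0),
                          what = "manifest")
  mat <- tab$mat
  if (tolower(mat[1L, 1L]) %in% c("sample_id", "sample")) {
    mat <- mat[-1L, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("empty manifest: ", path, call. = FALSE)
  sample_id <- mat[, 1L]
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  group <- tolower(mat[, 2L])
  if (!all(group %in% c("case", "control"))) {
    stop("manifest group labels must be 'case' or 'control'", call. = FALSE)
  }
  p <- mat[, 3L]
  rel <- !grepl("^(/|[A-Za-z]:)", p)
  p[rel] <- file.path(dirname(path), p[rel])
  data.frame(sample_id = sample_id, group = group, path = p,
             stringsAsFactors = FALSE)
}

#' @rdname read_manifest
#' @param manifest A manifest `data.frame` (`sample_id`, `group`, `path`).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("sample_id", "group", "path") %in% names(manifest)))
  utils::write.table(manifest[, c("sample_id", "group", "path")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
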