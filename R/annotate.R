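# Biochemical-context-driven putative annotation (MSI level 2).
#
# Compounds in the same pathway tend to co-vary in concentration, so the
# correlation neighborhood of a feature carries information about which of
# its accurate-mass candidates is real: the true candidate's pathway
# neighborhood is "bunched" with the candidates of correlated features.

#' Annotation parameters
#'
#' @param corr_threshold Correlation threshold rho in (0, 1] for the
#'   neighborhood. Default 0.7.
#' @param min_context_score Minimum context score for a candidate to be
#'   accepted (>= 1). Default 2.
#' @param corr_method `"pearson"` or `"spearman"`. Default pearson.
#' @param log_transform Log-transform nonzero intensities before correlating.
#'   Default `TRUE` (intensities are near log-normal).
#' @param min_obs Minimum pairwise-complete nonzero observations for a
#'   correlation to be evaluated. Default 10.
#' @return A list of class `ldt_annotation_params`.
#' @export
annotation_params <- function(corr_threshold = 0.7, min_context_score = 2L,
                              corr_method = c("pearson", "spearman"),
                              log_transform = TRUE, min_obs = 10L) {
  stopifnot(corr_threshold > 0, corr_threshold <= 1, min_context_score >= 1)
  structure(list(corr_threshold = corr_threshold,
                 min_context_score = as.integer(min_context_score),
                 corr_method = match.arg(corr_method),
                 log_transform = isTRUE(log_transform),
                 min_obs = as.integer(min_obs)),
            class = "ldt_annotation_params")
}

# Pairwise-complete-nonzero correlation matrix over features. Zeros mean "not
# detected" and are excluded pairwise; pairs with fewer than min_obs complete
# observations get NA.
feature_correlations <- function(fm, p) {
  x <- t(fm$intensities)  # samples x features
  x[x == 0] <- NA
  if (p$log_transform) x <- log(x)
  if (p$corr_method == "spearman") x <- apply(x, 2L, rank, na.last = "keep")
  cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                    method = "pearson"))
  n_obs <- crossprod(!is.na(x))
  cc[n_obs < p$min_obs] <- NA
  diag(cc) <- NA
  cc
}

#' Correlation neighborhood of a feature
#'
#' Returns the indices of features whose across-sample intensity correlation
#' with feature `i` is at least `p$corr_threshold`, computed on
#' pairwise-complete nonzero cells; pairs with fewer than `p$min_obs` complete
#' observations are skipped.
#'
#' @param fm An [feature_matrix()] object.
#' @param i Feature index.
#' @param p An [annotation_params()] object.
#' @return Integer vector of neighbor feature indices (excluding `i`).
#' @export
correlation_neighbors <- function(fm, i, p = annotation_params()) {
  cc <- feature_correlations(fm, p)
  which(!is.na(cc[i, ]) & cc[i, ] >= p$corr_threshold)
}

#' Context score of one candidate annotation
#'
#' The number of neighbor features carrying at least one candidate that shares
#' a pathway with candidate `c_id`; each neighbor feature counts at most once.
#'
#' @param c_id Candidate metabolite ID (must be a candidate of feature `i`).
#' @param i Feature index.
#' @param neighbors Integer vector of neighbor feature indices.
#' @param ct Candidate table from [match_candidates()].
#' @param pdb A [pathway_db()] object.
#' @return Non-negative integer count.
#' @export
context_score <- function(c_id, i, neighbors, ct, pdb) {
  cand_i <- ct$metabolite_id[ct$feature_index == i]
  if (!c_id %in% cand_i) {
    stop(sprintf("'%s' is not a candidate of feature %d", c_id, i),
         call. = FALSE)
  }
  m2p <- metabolite_pathways(pdb)
  pw_c <- m2p[[c_id]]
  if (is.null(pw_c)) return(0L)
  hits <- vapply(neighbors, function(j) {
    cand_j <- ct$metabolite_id[ct$feature_index == j]
    any(unlist(m2p[cand_j], use.names = FALSE) %in% pw_c)
  }, TRUE)
  sum(hits)
}

# metabolite_id -> character vector of pathway_ids
metabolite_pathways <- function(pdb) {
  ids <- unlist(pdb$members, use.names = FALSE)
  pws <- rep(pdb$pathway_id, lengths(pdb$members))
  split(pws, ids)
}

#' Annotate features by biochemical context
#'
#' For each feature with candidates, computes every candidate's context score
#' against the feature's correlation neighborhood and accepts the
#' maximal-scoring candidate(s) whose score reaches `p$min_context_score`.
#' Ties at the maximum are all accepted and flagged ambiguous. Features whose
#' best score falls below the threshold stay unannotated.
#'
#' @param fm An [feature_matrix()] object.
#' @param ct Candidate table from [match_candidates()].
#' @param pdb A [pathway_db()] object.
#' @param p An [annotation_params()] object.
#' @return A `data.frame` (class `ldt_annotations`) with columns
#'   `feature_index`, `metabolite_id`, `context_score`, `accepted`,
#'   `ambiguous`.
#' @export
annotate_features <- function(fm, ct, pdb, p = annotation_params()) {
  stopifnot(inherits(fm, "ldt_features"), inherits(pdb, "ldt_pathways"))
  if (nrow(ct) > 0L && max(ct$feature_index) > length(fm$mz)) {
    stop("candidate table refers to features beyond the matrix", call. = FALSE)
  }
  empty <- data.frame(feature_index = integer(0), metabolite_id = character(0),
                      context_score = integer(0), accepted = logical(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  if (nrow(ct) == 0L) {
    class(empty) <- c("ldt_annotations", "data.frame")
    return(empty)
  }
  cc <- feature_correlations(fm, p)
  m2p <- metabolite_pathways(pdb)
  cand_by_feature <- split(unique(ct[, c("feature_index", "metabolite_id")]),
                           unique(ct[, c("feature_index", "metabolite_id")])$feature_index)
  # pathway union carried by each feature's candidate set
  feat_pw <- lapply(cand_by_feature, function(d)
    unique(unlist(m2p[d$metabolite_id], use.names = FALSE)))
  feat_ids <- as.integer(names(cand_by_feature))
  res <- vector("list", length(feat_ids))
  for (k in seq_along(feat_ids)) {
    i <- feat_ids[k]
    nbr <- which(!is.na(cc[i, ]) & cc[i, ] >= p$corr_threshold)
    nbr <- nbr[as.character(nbr) %in% names(cand_by_feature)]
    cands <- cand_by_feature[[k]]$metabolite_id
    score <- vapply(cands, function(c_id) {
      pw_c <- m2p[[c_id]]
      if (is.null(pw_c) || length(nbr) == 0L) return(0L)
      sum(vapply(as.character(nbr),
                 function(j) any(feat_pw[[j]] %in% pw_c), TRUE))
    }, 0L)
    best <- max(score)
    acc <- score == best & best >= p$min_context_score
    res[[k]] <- data.frame(feature_index = i, metabolite_id = cands,
                           context_score = as.integer(score), accepted = acc,
                           ambiguous = acc & sum(acc) > 1L,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$feature_index, -out$context_score, out$metabolite_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ldt_annotations", "data.frame")
  out
}

#' Accepted metabolite IDs (the sample-set "annotated universe")
#'
#' @param at An `ldt_annotations` data frame from [annotate_features()].
#' @return Deduplicated character vector of accepted metabolite IDs.
#' @export
annotated_universe <- function(at) {
  unique(at$metabolite_id[at$accepted])
}

#' Read or write an annotation table as tab-delimited text
#' @param at An `ldt_annotations` data frame.
#' @param path File path.
#' @export
write_annotations <- function(at, path) {
  utils::write.table(as.data.frame(at), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$feature_index <- as.integer(df$feature_index)
  df$context_score <- as.integer(df$context_score)
  class(df) <- c("ldt_annotations", "data.frame")
  df
}
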