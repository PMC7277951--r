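# Permutation-based pathway overrepresentation.
#
# A selected metabolite set is projected onto the pathway membership matrix;
# the observed per-pathway counts are compared with a null built from draws of
# equally many metabolites taken uniformly without replacement from the
# annotated universe (30,000 draws by default).

#' Project a metabolite set onto pathways
#'
#' @param selected Character vector of metabolite IDs (treated as a set;
#'   unknown IDs are ignored).
#' @param pdb A [pathway_db()] object.
#' @return Named integer vector: per-pathway count of selected members.
#' @export
project_counts <- function(selected, pdb) {
  stopifnot(inherits(pdb, "ldt_pathways"))
  selected <- unique(as.character(selected))
  k <- vapply(pdb$members, function(m) sum(selected %in% m), 0L)
  names(k) <- pdb$pathway_id
  k
}

#' Permutation null for pathway projection counts
#'
#' Draws `n_sel` metabolite IDs uniformly without replacement from `universe`,
#' `R` times, and records the per-pathway mean and standard deviation of the
#' projected counts, plus (when `observed` is supplied) the tail count used
#' for empirical p-values.
#'
#' @param n_sel Size of the selected set (1 <= n_sel <= |universe|).
#' @param universe Character vector of metabolite IDs to draw from.
#' @param pdb A [pathway_db()] object.
#' @param R Number of draws. Default 30000.
#' @param seed Integer seed; the null is reproducible given the seed.
#' @return A list of class `ldt_null` with `null_mean`, `null_sd` (named per
#'   pathway), `count_freq` (pathways x possible counts frequency matrix, the
#'   full null count distribution), `R`, `n_sel`, `seed`.
#' @export
permutation_null <- function(n_sel, universe, pdb, R = 30000L, seed = 1L) {
  stopifnot(inherits(pdb, "ldt_pathways"), R >= 1L)
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (n_sel < 1L || n_sel > N) {
    stop(sprintf("n_sel (%d) must be between 1 and |universe| (%d)", n_sel, N),
         call. = FALSE)
  }
  P <- length(pdb$pathway_id)
  # membership indicator, universe x pathways (members outside the universe
  # cannot be drawn and do not matter)
  Mm <- Matrix::sparseMatrix(
    i = unlist(lapply(pdb$members, function(m) which(universe %in% m)),
               use.names = FALSE),
    j = rep(seq_len(P), vapply(pdb$members, function(m) sum(m %in% universe), 0L)),
    x = 1, dims = c(N, P)
  )
  draws <- withr_seed(seed, {
    vapply(seq_len(R), function(r) sample.int(N, n_sel), integer(n_sel))
  })
  draws <- matrix(draws, nrow = n_sel)
  S <- Matrix::sparseMatrix(i = as.vector(draws),
                            j = rep(seq_len(R), each = n_sel),
                            x = 1, dims = c(N, R))
  C <- as.matrix(Matrix::crossprod(Mm, S))  # pathways x draws
  null_mean <- rowMeans(C)
  null_sd <- apply(C, 1L, stats::sd)
  # full null distribution, compact: frequency of each count value 0..n_sel
  count_freq <- t(apply(C, 1L, function(v) tabulate(v + 1L, nbins = n_sel + 1L)))
  dimnames(count_freq) <- list(pdb$pathway_id, 0:n_sel)
  names(null_mean) <- names(null_sd) <- pdb$pathway_id
  structure(list(null_mean = null_mean, null_sd = null_sd,
                 count_freq = count_freq, R = as.integer(R),
                 n_sel = as.integer(n_sel), seed = as.integer(seed)),
            class = "ldt_null")
}

#' Null tail counts for observed pathway counts
#'
#' `#{draws with count >= k_p}` per pathway, from the stored null count
#' distribution.
#'
#' @param nul An `ldt_null` object from [permutation_null()].
#' @param observed Named integer vector from [project_counts()].
#' @return Named integer vector of tail counts.
#' @export
null_tail_counts <- function(nul, observed) {
  obs <- observed[rownames(nul$count_freq)]
  vapply(seq_along(obs), function(p) {
    k <- obs[p]
    if (k <= 0) return(nul$R)
    if (k > nul$n_sel) return(0L)
    as.integer(sum(nul$count_freq[p, (k + 1L):(nul$n_sel + 1L)]))
  }, 0L, USE.NAMES = FALSE) |> stats::setNames(rownames(nul$count_freq))
}

# run code under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pathway representation scores for one metabolite selection
#'
#' The representation score is the observed-to-expected fold
#' `s_p = k_p / max(null_mean_p, 1/R)`; pathways never hit in the null get the
#' `1/R` floor so the ratio stays finite. The empirical p-value uses the
#' add-one rule `(1 + #{draws >= k_p}) / (R + 1)` and therefore never equals 0.
#'
#' @param selected Character vector of metabolite IDs.
#' @param universe Character vector: the annotated universe to draw nulls
#'   from.
#' @param pdb A [pathway_db()] object.
#' @param R Number of null draws. Default 30000.
#' @param seed Integer seed.
#' @param id Label for the profile (sample or group ID).
#' @param score_fun Score normalization: `"ratio"` (default, observed /
#'   expected), `"z"` ((k - mean)/sd), or `"neglog10p"`.
#' @return A `data.frame` (class `ldt_scores`) with columns `pathway_id`,
#'   `name`, `observed`, `null_mean`, `null_sd`, `score`, `empirical_p`;
#'   attributes `id`, `seed`, `R`, `n_sel`.
#' @export
representation_scores <- function(selected, universe, pdb, R = 30000L,
                                  seed = 1L, id = "sample",
                                  score_fun = c("ratio", "z", "neglog10p")) {
  score_fun <- match.arg(score_fun)
  selected <- unique(as.character(selected))
  unknown <- setdiff(selected, universe)
  if (length(unknown) > 0L) {
    message(sprintf("representation_scores: %d selected ID(s) outside the universe ignored",
                    length(unknown)))
    selected <- intersect(selected, universe)
  }
  k <- project_counts(selected, pdb)
  nul <- permutation_null(length(selected), universe, pdb, R = R, seed = seed)
  emp_p <- (1 + null_tail_counts(nul, k)) / (R + 1)
  score <- switch(score_fun,
    ratio = k / pmax(nul$null_mean, 1 / R),
    z = ifelse(nul$null_sd > 0, (k - nul$null_mean) / nul$null_sd, 0),
    neglog10p = -log10(emp_p)
  )
  out <- data.frame(pathway_id = pdb$pathway_id, name = pdb$name,
                    observed = as.integer(k), null_mean = nul$null_mean,
                    null_sd = nul$null_sd, score = as.numeric(score),
                    empirical_p = emp_p, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "id") <- id
  attr(out, "seed") <- seed
  attr(out, "R") <- as.integer(R)
  attr(out, "n_sel") <- length(selected)
  class(out) <- c("ldt_scores", "data.frame")
  out
}

#' Fold overrepresentation between group mean scores
#'
#' @param mean_case,mean_control Group mean representation scores;
#'   `mean_control` must be > 0 (a zero control mean yields `NA`, reported as
#'   not available).
#' @return Fold rounded to one decimal for reporting; the unrounded value is
#'   attached as attribute `"unrounded"`.
#' @export
fold_change <- function(mean_case, mean_control) {
  raw <- ifelse(mean_control > 0, mean_case / mean_control, NA_real_)
  out <- round(raw, 1L)
  attr(out, "unrounded") <- raw
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there are
#' no ties; otherwise a normal approximation with tie correction and
#' continuity correction. Degenerate input (all values identical) yields
#' p = 1.
#'
#' @param case_scores,control_scores Numeric vectors (each >= 3 values).
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(case_scores, control_scores) {
  if (length(case_scores) < 3L || length(control_scores) < 3L) {
    stop("each group needs >= 3 observations", call. = FALSE)
  }
  all_v <- c(case_scores, control_scores)
  if (length(unique(all_v)) == 1L) return(1)
  has_ties <- anyDuplicated(all_v) > 0L
  use_exact <- length(all_v) <= 12L && !has_ties
  suppressWarnings(
    stats::wilcox.test(case_scores, control_scores, exact = use_exact,
                       correct = TRUE)$p.value
  )
}

#' Case-control pathway comparison
#'
#' Per-sample representation scores are averaged within groups; the fold is
#' the ratio of group means and the p-value a two-sided rank-sum test on the
#' per-sample scores, reported raw with a Benjamini-Hochberg column alongside.
#'
#' @param profiles Named list of per-sample `ldt_scores` data frames (one per
#'   subject, same pathway order).
#' @param groups Named character vector (`"case"` / `"control"`) over the same
#'   sample IDs.
#' @return A `data.frame` with columns `pathway_id`, `name`,
#'   `mean_case_score`, `mean_control_score`, `fold`, `ranksum_p`, `bh_q`,
#'   sorted by decreasing `mean_case_score`.
#' @export
compare_groups <- function(profiles, groups) {
  stopifnot(length(profiles) >= 2L, !is.null(names(profiles)))
  groups <- groups[names(profiles)]
  if (anyNA(groups)) stop("groups must cover every profile", call. = FALSE)
  smat <- vapply(profiles, function(p) p$score, numeric(nrow(profiles[[1L]])))
  case_cols <- groups == "case"
  if (sum(case_cols) < 1L || sum(!case_cols) < 1L) {
    stop("need at least one case and one control profile", call. = FALSE)
  }
  mean_case <- rowMeans(smat[, case_cols, drop = FALSE])
  mean_ctrl <- rowMeans(smat[, !case_cols, drop = FALSE])
  p <- if (sum(case_cols) >= 3L && sum(!case_cols) >= 3L) {
    apply(smat, 1L, function(v) ranksum_test(v[case_cols], v[!case_cols]))
  } else rep(NA_real_, nrow(smat))
  f <- fold_change(mean_case, mean_ctrl)
  out <- data.frame(pathway_id = profiles[[1L]]$pathway_id,
                    name = profiles[[1L]]$name,
                    mean_case_score = mean_case,
                    mean_control_score = mean_ctrl,
                    fold = as.numeric(f),
                    fold_unrounded = attr(f, "unrounded"),
                    ranksum_p = p,
                    bh_q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean_case_score), , drop = FALSE]
}

#' Read or write a score profile as tab-delimited text
#' @param sp An `ldt_scores` data frame.
#' @param path File path.
#' @export
write_scores <- function(sp, path) {
  utils::write.table(as.data.frame(sp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  class(df) <- c("ldt_scores", "data.frame")
  df
}
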