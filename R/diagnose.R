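# Per-subject Z-score metabolite selection against controls (leave-one-out),
# panel diagnostic score, threshold classification, confusion metrics.

#' Z-score metabolite selection for one subject
#'
#' Per feature, `z = (x_s - mean_controls) / sd_controls` where mean and sd
#' (sample, n-1 denominator) are computed over control samples only; when the
#' subject is itself a control it is left out of its own reference statistics.
#' Features with `|z| > z_crit` map through accepted annotations to the
#' selected metabolite set (each metabolite counted once).
#'
#' @param fm An [feature_matrix()] object.
#' @param s Sample ID of the subject.
#' @param controls Character vector of control sample IDs.
#' @param at Annotation table from [annotate_features()].
#' @param z_crit Critical value. Default 1.64 (one-tailed 5%).
#' @return A list of class `ldt_zselection`: `sample_id`, `z` (per feature,
#'   `NA` where the control sd is 0 or too few controls), `direction`
#'   (`"up"`, `"down"`, `"none"`), `selected_features`,
#'   `selected_metabolites`.
#' @export
zscore_select <- function(fm, s, controls, at, z_crit = 1.64) {
  stopifnot(inherits(fm, "ldt_features"))
  if (!s %in% fm$sample_ids) stop("unknown sample: ", s, call. = FALSE)
  ref <- setdiff(intersect(controls, fm$sample_ids), s)  # leave-one-out
  if (length(ref) < 3L) {
    stop("need >= 3 control samples (after leave-one-out)", call. = FALSE)
  }
  X <- fm$intensities[, ref, drop = FALSE]
  mu <- rowMeans(X)
  sdev <- apply(X, 1L, stats::sd)
  x <- fm$intensities[, s]
  z <- ifelse(sdev > 0, (x - mu) / sdev, NA_real_)
  n_skipped <- sum(sdev == 0)
  if (n_skipped > 0L) {
    message(sprintf("zscore_select: %d feature(s) with zero control sd skipped for sample '%s'",
                    n_skipped, s))
  }
  direction <- rep("none", length(z))
  direction[!is.na(z) & z > z_crit] <- "up"
  direction[!is.na(z) & z < -z_crit] <- "down"
  sel_feat <- which(direction != "none")
  sel_met <- unique(at$metabolite_id[at$accepted & at$feature_index %in% sel_feat])
  structure(list(sample_id = s, z = z, direction = direction,
                 selected_features = sel_feat, selected_metabolites = sel_met),
            class = "ldt_zselection")
}

#' Panel diagnostic score
#'
#' The sum of representation scores over a fixed panel of pathways (the 20 top
#' disease-associated pathways by default usage).
#'
#' @param profile An `ldt_scores` data frame from [representation_scores()].
#' @param panel Character vector of pathway IDs; every panel pathway must be
#'   present in the profile.
#' @return The diagnostic score `D` (sum of panel scores).
#' @export
diagnostic_score <- function(profile, panel) {
  idx <- match(panel, profile$pathway_id)
  if (anyNA(idx)) {
    stop("panel pathway(s) missing from profile: ",
         paste(panel[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(profile$score[idx])
}

#' Classify a diagnostic score against a threshold
#'
#' The disease pattern is called when the score strictly exceeds the
#' threshold.
#'
#' @param D Diagnostic score(s).
#' @param threshold Decision threshold; defaults used in practice are 12
#'   (screening) and 340 (high-confidence).
#' @return `"PD-pattern"` or `"no-pattern"` per score.
#' @export
classify <- function(D, threshold) {
  ifelse(D > threshold, "PD-pattern", "no-pattern")
}

#' Confusion metrics from classification counts
#'
#' @param tp,fp,tn,fn Non-negative counts; both `tp + fn` and `tn + fp` must
#'   be positive.
#' @return A list of class `ldt_confusion`: the counts plus `sensitivity`,
#'   `specificity`, `accuracy` in percent (unrounded; `round()` for reporting).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0) stop("no positive class (tp + fn = 0)", call. = FALSE)
  if (tn + fp == 0) stop("no negative class (tn + fp = 0)", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / (tp + fp + tn + fn)),
            class = "ldt_confusion")
}

#' @exportS3Method base::print
print.ldt_confusion <- function(x, ...) {
  cat(sprintf("<ldt_confusion> TP %d FP %d TN %d FN %d | sensitivity %d%% specificity %d%% accuracy %d%%\n",
              x$tp, x$fp, x$tn, x$fn, round(x$sensitivity),
              round(x$specificity), round(x$accuracy)))
  invisible(x)
}

#' Derive a top-k pathway panel from a case-control comparison
#'
#' Ranks pathways by mean case representation score, as when the panel is
#' learned from a cohort rather than fixed in advance.
#'
#' @param comparison Output of [compare_groups()].
#' @param k Panel size. Default 20.
#' @return Character vector of pathway IDs.
#' @export
derive_panel <- function(comparison, k = 20L) {
  o <- order(-comparison$mean_case_score, comparison$pathway_id)
  comparison$pathway_id[o][seq_len(min(k, nrow(comparison)))]
}

#' The packaged Parkinson's-disease pathway panel
#'
#' The 20 pathway names of the published case-control panel, shipped as an
#' editable table. Since pathway-database IDs differ between installations,
#' names must be mapped to IDs in the user's pathway table (via
#' `match_panel_names()` or a user-supplied mapping).
#'
#' @return A `data.frame` with columns `rank`, `pathway_name`.
#' @export
pd_panel <- function() {
  path <- system.file("extdata", "pd_panel.tsv", package = "mzldt",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Map panel pathway names to pathway-database IDs
#'
#' Case-insensitive exact name matching; unmatched names are dropped with a
#' message.
#'
#' @param panel_names Character vector of pathway names.
#' @param pdb A [pathway_db()] object.
#' @return Character vector of pathway IDs.
#' @export
match_panel_names <- function(panel_names, pdb) {
  idx <- match(tolower(trimws(panel_names)), tolower(trimws(pdb$name)))
  if (anyNA(idx)) {
    message("match_panel_names: unmatched panel name(s): ",
            paste(panel_names[is.na(idx)], collapse = "; "))
  }
  pdb$pathway_id[idx[!is.na(idx)]]
}

#' Per-subject diagnosis over a cohort
#'
#' For every sample in the manifest: Z-score metabolite selection against the
#' controls (leave-one-out for control subjects), pathway representation
#' scoring against the cohort's annotated universe, panel diagnostic score,
#' and classification at each threshold. Null statistics are cached per
#' selection size.
#'
#' @param fm An [feature_matrix()] covering all manifest samples.
#' @param at Annotation table from [annotate_features()].
#' @param pdb A [pathway_db()] object.
#' @param manifest Manifest `data.frame` (`sample_id`, `group`).
#' @param panel Character vector of panel pathway IDs; if `NULL`, a top-20
#'   panel is derived from the cohort's case-control comparison.
#' @param z_crit Z critical value. Default 1.64.
#' @param thresholds Numeric decision thresholds. Default `c(12, 340)`.
#' @param R Null draws per selection size. Default 30000.
#' @param seed Integer seed.
#' @return A list of class `ldt_diagnosis`: `results` (data frame with
#'   `sample_id`, `group`, `n_selected`, `D`, one `label_at_<t>` column per
#'   threshold), `profiles` (per-sample `ldt_scores`), `panel`, `comparison`.
#' @export
diagnose_cohort <- function(fm, at, pdb, manifest, panel = NULL,
                            z_crit = 1.64, thresholds = c(12, 340),
                            R = 30000L, seed = 1L) {
  controls <- manifest$sample_id[manifest$group == "control"]
  if (length(controls) < 4L) {
    stop("need >= 4 control samples for leave-one-out Z-scores", call. = FALSE)
  }
  universe <- annotated_universe(at)
  if (length(universe) == 0L) stop("empty annotated universe", call. = FALSE)
  null_cache <- new.env(parent = emptyenv())
  profiles <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    zs <- suppressMessages(zscore_select(fm, s, controls, at, z_crit = z_crit))
    sel <- intersect(zs$selected_metabolites, universe)
    if (length(sel) == 0L) {
      # no perturbed metabolites: all-zero profile
      prof <- data.frame(pathway_id = pdb$pathway_id, name = pdb$name,
                         observed = 0L, null_mean = NA_real_,
                         null_sd = NA_real_, score = 0,
                         empirical_p = 1, stringsAsFactors = FALSE)
      class(prof) <- c("ldt_scores", "data.frame")
    } else {
      key <- as.character(length(sel))
      # per-n_sel null statistics are reused across samples
      prof <- cached_scores(sel, universe, pdb, R, seed, s, null_cache, key)
    }
    attr(prof, "id") <- s
    profiles[[s]] <- prof
  }
  comparison <- compare_groups(profiles,
                               stats::setNames(manifest$group, manifest$sample_id))
  if (is.null(panel)) panel <- derive_panel(comparison, 20L)
  D <- vapply(profiles, diagnostic_score, 0, panel = panel)
  res <- data.frame(sample_id = manifest$sample_id, group = manifest$group,
                    n_selected = vapply(profiles, function(p) {
                      n <- attr(p, "n_sel"); if (is.null(n)) 0L else n
                    }, 0L),
                    D = as.numeric(D), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (t in thresholds) {
    res[[paste0("label_at_", format(t, trim = TRUE))]] <- classify(res$D, t)
  }
  structure(list(results = res, profiles = profiles, panel = panel,
                 comparison = comparison),
            class = "ldt_diagnosis")
}

# representation scores with per-n_sel null caching
cached_scores <- function(sel, universe, pdb, R, seed, id, cache, key) {
  k <- project_counts(sel, pdb)
  if (!exists(key, envir = cache, inherits = FALSE)) {
    assign(key, permutation_null(length(sel), universe, pdb, R = R,
                                 seed = seed + length(sel)),
           envir = cache)
  }
  nul <- get(key, envir = cache, inherits = FALSE)
  score <- k / pmax(nul$null_mean, 1 / R)
  emp_p <- (1 + null_tail_counts(nul, k)) / (R + 1)
  out <- data.frame(pathway_id = pdb$pathway_id, name = pdb$name,
                    observed = as.integer(k), null_mean = nul$null_mean,
                    null_sd = nul$null_sd, score = as.numeric(score),
                    empirical_p = emp_p, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "id") <- id
  attr(out, "R") <- as.integer(R)
  attr(out, "n_sel") <- length(sel)
  class(out) <- c("ldt_scores", "data.frame")
  out
}

#' @exportS3Method base::print
print.ldt_diagnosis <- function(x, ...) {
  cat(sprintf("<ldt_diagnosis> %d subjects, panel of %d pathways\n",
              nrow(x$results), length(x$panel)))
  print(utils::head(x$results, 10L))
  invisible(x)
}

#' Area under the ROC curve of the diagnostic score
#'
#' Rank-based (Mann-Whitney) AUC of `D` for cases versus controls.
#'
#' @param D Numeric vector of diagnostic scores.
#' @param is_case Logical vector (`TRUE` for cases).
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(D, is_case) {
  stopifnot(length(D) == length(is_case), any(is_case), any(!is_case))
  r <- rank(D)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
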