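# Synthetic direct-infusion metabolomics datasets with known ground truth.
#
# Emulates the structure the pipeline consumes: high-resolution peaks with an
# internal-standard peak at m/z 423.169, log-normal intensities that share a
# latent factor within each pathway (so pathway mates correlate), adduct and
# isotopologue peaks, decoy database entries at near-isobaric masses (so
# accurate mass alone is ambiguous, as in a real metabolite database), noise
# peaks, and case-specific fold perturbation of designated pathways.

#' Simulation configuration
#'
#' @param n_pathways Number of (disjoint) pathways. Default 40.
#' @param metabolites_per_pathway Members per pathway. Default 8.
#' @param n_cases,n_controls Cohort sizes. Default 20 each.
#' @param n_perturbed Number of case-perturbed pathways. Default 2.
#' @param perturbed_pathways Explicit pathway IDs to perturb; overrides
#'   `n_perturbed` when given.
#' @param effect_size Multiplicative fold applied to perturbed members' mean
#'   intensity in case samples. Default 3.
#' @param within_pathway_corr Target intensity correlation among pathway
#'   mates, in `[0, 1)`. Default 0.8.
#' @param noise_sd Independent log-scale intensity noise sd. Default 0.4.
#' @param n_noise_peaks Unassignable noise peaks per sample. Default 50.
#' @param adduct_probs Probabilities over `M+H`, `M+Na`, `M+K`; must sum to 1.
#' @param isotope_prob Probability a metabolite also emits a +1.00336 Da
#'   isotopologue peak. Default 0.3.
#' @param decoys_per_metabolite Near-isobaric decoy database entries per true
#'   metabolite (candidates that are never emitted). Default 2.
#' @param decoy_max_shift Maximum absolute neutral-mass shift of a decoy from
#'   its true metabolite (Da). Default 0.003.
#' @param mz_jitter_sd Per-peak m/z measurement jitter sd (Da). Default 5e-4.
#' @param mass_range Neutral-mass range (Da). Default `c(80, 900)`.
#' @param min_spacing Minimum neutral-mass spacing between true metabolites
#'   (Da). Default 0.02.
#' @param standard_mz Internal-standard m/z. Default 423.169.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A list of class `ldt_sim_config`.
#' @export
sim_config <- function(n_pathways = 40L, metabolites_per_pathway = 8L,
                       n_cases = 20L, n_controls = 20L, n_perturbed = 2L,
                       perturbed_pathways = NULL, effect_size = 3,
                       within_pathway_corr = 0.8, noise_sd = 0.4,
                       n_noise_peaks = 50L,
                       adduct_probs = c("M+H" = 0.7, "M+Na" = 0.2, "M+K" = 0.1),
                       isotope_prob = 0.3, decoys_per_metabolite = 2L,
                       decoy_max_shift = 0.003, mz_jitter_sd = 5e-4,
                       mass_range = c(80, 900), min_spacing = 0.02,
                       standard_mz = 423.169, seed = 1L) {
  stopifnot(n_pathways >= 1L, metabolites_per_pathway >= 1L,
            n_cases >= 1L, n_controls >= 1L, effect_size > 0,
            within_pathway_corr >= 0, within_pathway_corr < 1,
            noise_sd > 0, isotope_prob >= 0, isotope_prob <= 1,
            all(adduct_probs >= 0), abs(sum(adduct_probs) - 1) < 1e-8,
            all(names(adduct_probs) %in% names(ADDUCT_OFFSETS)))
  structure(as.list(environment()), class = "ldt_sim_config")
}

#' Simulate a full dataset with ground truth
#'
#' Writes peak lists (one per subject), the metabolite table, the pathway
#' table, the sample manifest, and a ground-truth table to `dir`, in the exact
#' formats the readers consume. Intensities follow a log-normal model: per
#' metabolite log-intensity = baseline + shared pathway latent factor +
#' independent noise, multiplied by a per-sample global scale that the
#' internal standard carries (so recalibration removes it exactly); in case
#' samples, members of perturbed pathways have their mean multiplied by
#' `effect_size`.
#'
#' @param cfg An [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return A list of class `ldt_simulation`: `manifest`, `db`
#'   ([metabolite_db()]), `pdb` ([pathway_db()]), `truth` (per true metabolite:
#'   pathway, adduct, adduct m/z, isotope m/z or `NA`, perturbed flag,
#'   candidate-ambiguity count), `perturbed_pathways`, file `paths`, `cfg`.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "ldt_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  withr_seed(cfg$seed, simulate_dataset_impl(cfg, dir))
}

simulate_dataset_impl <- function(cfg, dir) {
  n_met <- cfg$n_pathways * cfg$metabolites_per_pathway
  span <- diff(cfg$mass_range)
  if ((n_met - 1L) * cfg$min_spacing >= span) {
    stop(sprintf("cannot place %d metabolites at >= %g Da spacing in [%g, %g]",
                 n_met, cfg$min_spacing, cfg$mass_range[1L], cfg$mass_range[2L]),
         call. = FALSE)
  }
  # masses with guaranteed spacing: sorted uniforms plus a spacing ramp
  u <- sort(stats::runif(n_met, 0, span - (n_met - 1L) * cfg$min_spacing))
  mass <- cfg$mass_range[1L] + u + (seq_len(n_met) - 1L) * cfg$min_spacing
  adduct <- sample(names(cfg$adduct_probs), n_met, replace = TRUE,
                   prob = cfg$adduct_probs)
  a_mz <- adduct_mz(mass, adduct)
  # keep adduct peaks clear of the internal standard
  clash <- abs(a_mz - cfg$standard_mz) < 0.01
  while (any(clash)) {
    mass[clash] <- mass[clash] + 0.1
    a_mz <- adduct_mz(mass, adduct)
    clash <- abs(a_mz - cfg$standard_mz) < 0.01
  }

  pathway_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  pathway_names <- sprintf("Synthetic pathway %03d", seq_len(cfg$n_pathways))
  met_pathway <- rep(pathway_ids, each = cfg$metabolites_per_pathway)
  met_ids <- sprintf("M%04d", seq_len(n_met))

  perturbed <- cfg$perturbed_pathways
  if (is.null(perturbed)) {
    perturbed <- sample(pathway_ids, cfg$n_perturbed)
  }
  stopifnot(all(perturbed %in% pathway_ids))

  # decoy database entries: near-isobaric, never emitted, random pathway
  n_dec <- n_met * cfg$decoys_per_metabolite
  decoy_ids <- character(0); decoy_mass <- numeric(0); decoy_pw <- character(0)
  if (n_dec > 0L) {
    decoy_ids <- sprintf("D%04d", seq_len(n_dec))
    shift <- stats::runif(n_dec, -cfg$decoy_max_shift, cfg$decoy_max_shift)
    decoy_mass <- rep(mass, each = cfg$decoys_per_metabolite) + shift
    decoy_pw <- vapply(rep(met_pathway, each = cfg$decoys_per_metabolite),
                       function(p) sample(setdiff(pathway_ids, p), 1L), "")
  }

  db <- metabolite_db(
    c(met_ids, decoy_ids),
    c(sprintf("Metabolite %s", met_ids), sprintf("Decoy %s", decoy_ids)),
    c(mass, decoy_mass),
    c(sprintf("C%05d", seq_len(n_met)),
      if (n_dec > 0L) sprintf("C%05d", n_met + seq_len(n_dec)) else character(0))
  )
  all_pw_members <- split(c(met_ids, decoy_ids), c(met_pathway, decoy_pw))
  pdb <- pathway_db(names(all_pw_members),
                    pathway_names[match(names(all_pw_members), pathway_ids)],
                    all_pw_members)

  # intensity model
  n_samples <- cfg$n_cases + cfg$n_controls
  groups <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  sample_ids <- sprintf("S%02d_%s", seq_len(n_samples),
                        ifelse(groups == "case", "case", "ctrl"))
  r <- cfg$within_pathway_corr
  sigma_latent <- cfg$noise_sd * sqrt(r / (1 - r))
  mu <- stats::runif(n_met, log(0.02), log(5))  # baseline log intensity
  is_perturbed_met <- met_pathway %in% perturbed
  has_iso <- stats::runif(n_met) < cfg$isotope_prob
  iso_ratio <- stats::runif(n_met, 0.08, 0.35)

  latent <- matrix(stats::rnorm(cfg$n_pathways * n_samples, 0, sigma_latent),
                   cfg$n_pathways, n_samples)
  eps <- matrix(stats::rnorm(n_met * n_samples, 0, cfg$noise_sd),
                n_met, n_samples)
  log_i <- mu + latent[match(met_pathway, pathway_ids), ] + eps
  case_cols <- groups == "case"
  log_i[is_perturbed_met, case_cols] <-
    log_i[is_perturbed_met, case_cols] + log(cfg$effect_size)
  rel_intensity <- exp(log_i)

  scale <- exp(stats::rnorm(n_samples, log(1000), 0.3))  # per-sample global scale

  paths <- character(n_samples)
  for (s in seq_len(n_samples)) {
    mono_mz <- a_mz + stats::rnorm(n_met, 0, cfg$mz_jitter_sd)
    mono_int <- rel_intensity[, s] * scale[s]
    iso_mz <- a_mz[has_iso] + 1.00336 +
      stats::rnorm(sum(has_iso), 0, cfg$mz_jitter_sd)
    iso_int <- mono_int[has_iso] * iso_ratio[has_iso]
    noise_mz <- draw_noise_mz(cfg$n_noise_peaks, cfg$mass_range +
                                c(ADDUCT_OFFSETS[["M+H"]], ADDUCT_OFFSETS[["M+K"]]),
                              c(a_mz, a_mz[has_iso] + 1.00336, cfg$standard_mz))
    noise_int <- exp(stats::rnorm(cfg$n_noise_peaks, log(0.05), 1)) * scale[s]
    std_mz <- cfg$standard_mz + stats::rnorm(1L, 0, cfg$mz_jitter_sd)
    sp <- new_spectrum(sample_ids[s],
                   mz = c(mono_mz, iso_mz, noise_mz, std_mz),
                   intensity = c(mono_int, iso_int, noise_int, scale[s]))
    paths[s] <- file.path(dir, "peaks", paste0(sample_ids[s], ".tsv"))
    write_peaklist(sp, paths[s])
  }

  manifest <- data.frame(sample_id = sample_ids, group = groups,
                         path = file.path("peaks", paste0(sample_ids, ".tsv")),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  manifest$path <- paths  # absolute-ish paths for in-session use

  truth <- data.frame(
    metabolite_id = met_ids, pathway_id = met_pathway,
    neutral_mass = mass, adduct = adduct, adduct_mz = a_mz,
    isotope_mz = ifelse(has_iso, a_mz + 1.00336, NA_real_),
    perturbed = is_perturbed_met, stringsAsFactors = FALSE
  )
  db_path <- file.path(dir, "metabolites.tsv")
  pdb_path <- file.path(dir, "pathways.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write_metabolite_db(db, db_path)
  write_pathway_db(pdb, pdb_path)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(manifest = manifest, db = db, pdb = pdb, truth = truth,
                 perturbed_pathways = perturbed,
                 paths = list(dir = dir, manifest = manifest_path,
                              metabolites = db_path, pathways = pdb_path,
                              truth = truth_path, peaklists = paths),
                 cfg = cfg),
            class = "ldt_simulation")
}

# noise masses kept >= 0.05 Da from every true peak m/z so ground truth is
# unambiguous
draw_noise_mz <- function(n, range, forbidden) {
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    cand <- stats::runif(n, range[1L], range[2L])
    near <- vapply(cand, function(x) any(abs(forbidden - x) < 0.05), TRUE)
    out <- c(out, cand[!near])
    guard <- guard + 1L
    if (guard > 100L) stop("cannot place noise peaks", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Match aligned features to the simulation ground truth
#'
#' For every true (non-decoy) metabolite, finds the feature whose consensus
#' m/z is nearest its emitted adduct m/z (within `tol`).
#'
#' @param fm An [feature_matrix()] object.
#' @param truth Ground-truth table from [simulate_dataset()].
#' @param tol Matching tolerance (Da). Default 0.005.
#' @return `truth` with an added `feature_index` column (`NA` when no feature
#'   matched, e.g. the peak was filtered out).
#' @export
match_truth_features <- function(fm, truth, tol = 0.005) {
  truth$feature_index <- vapply(truth$adduct_mz, function(x) {
    d <- abs(fm$mz - x)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }, 0L)
  truth
}

#' Annotation-recovery summary against ground truth
#'
#' Fraction of planted features (true metabolites whose monoisotopic feature
#' survived preprocessing and received candidates) whose accepted annotation
#' set contains the true metabolite, together with the expected accuracy of a
#' uniform random pick among each feature's candidates (the random-pick
#' baseline).
#'
#' @param fm An [feature_matrix()] object.
#' @param ct Candidate table from [match_candidates()].
#' @param at Annotation table from [annotate_features()].
#' @param truth Ground-truth table from [simulate_dataset()].
#' @param tol Feature-matching tolerance (Da). Default 0.005.
#' @return A list: `recovery`, `baseline`, `n_planted`.
#' @export
evaluate_annotation <- function(fm, ct, at, truth, tol = 0.005) {
  truth <- match_truth_features(fm, truth, tol = tol)
  truth <- truth[!is.na(truth$feature_index), , drop = FALSE]
  # planted = feature has candidates at all
  n_cand <- table(ct$feature_index)
  planted <- truth[as.character(truth$feature_index) %in% names(n_cand), ,
                   drop = FALSE]
  if (nrow(planted) == 0L) {
    return(list(recovery = NA_real_, baseline = NA_real_, n_planted = 0L))
  }
  hit <- vapply(seq_len(nrow(planted)), function(r) {
    acc <- at$metabolite_id[at$accepted &
                              at$feature_index == planted$feature_index[r]]
    planted$metabolite_id[r] %in% acc
  }, TRUE)
  baseline <- mean(1 / as.numeric(n_cand[as.character(planted$feature_index)]))
  list(recovery = mean(hit), baseline = baseline, n_planted = nrow(planted))
}
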