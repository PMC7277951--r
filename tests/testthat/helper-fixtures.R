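# Shared fixture builders and independent oracles.

# write a small delimited file and return its path
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# feature matrix straight from a numeric matrix (features x samples)
fm_from_matrix <- function(m, mz = seq_len(nrow(m)) + 99,
                           sample_ids = paste0("s", seq_len(ncol(m)))) {
  feature_matrix(mz, m, sample_ids)
}

# brute-force candidate search: exhaustive scan over features x records x
# adducts, inclusive tolerance
brute_force_candidates <- function(fm, db, tol, adducts = c("M+H", "M+Na", "M+K")) {
  rows <- list()
  for (i in which(is.na(fm$isotope_parent))) {
    for (r in seq_len(nrow(db))) {
      for (a in adducts) {
        err <- fm$mz[i] - adduct_mz(db$neutral_mass[r], a)
        if (abs(err) <= tol) {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_index = i, metabolite_id = db$metabolite_id[r],
            adduct = a, mass_error = err, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(feature_index = integer(0), metabolite_id = character(0),
                      adduct = character(0), mass_error = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$feature_index, out$metabolite_id, out$adduct), , drop = FALSE]
}

# exact two-sided rank-sum p by enumeration of all rank assignments
enumerate_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  stopifnot(!anyDuplicated(all_v))
  n <- length(all_v); m <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- m * (n + 1) / 2
  # two-sided: as-or-more-extreme deviation of the rank sum from its mean
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# toy pathway database: 3 pathways over 9 metabolites
toy_pdb <- function() {
  pathway_db(c("pA", "pB", "pC"),
             c("Pathway A", "Pathway B", "Pathway C"),
             list(c("m1", "m2", "m3"), c("m4", "m5", "m6"),
                  c("m7", "m8", "m9")))
}

default_sim <- function(seed = 101L, ...) {
  simulate_dataset(sim_config(seed = seed, ...),
                   tempfile(paste0("sim", seed, "_")))
}

# run the front half of the pipeline on a simulation
run_pipeline <- function(sim, min_nonzero = 10L) {
  fm <- suppressMessages(build_feature_matrix(sim$manifest,
                                              min_nonzero = min_nonzero))
  ct <- match_candidates(fm, sim$db)
  at <- suppressMessages(annotate_features(fm, ct, sim$pdb))
  list(fm = fm, ct = ct, at = at)
}
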