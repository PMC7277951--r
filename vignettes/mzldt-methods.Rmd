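---
title: "Methods: models, parameters and design choices in mzldt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mzldt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind each pipeline stage, the
default parameter values and why they were chosen, the design of the
synthetic data generator (including what it deliberately does and does not
imitate), and the numerical choices that make the pipeline exact,
reproducible and fast on a single CPU.

## 1. Measurement model

The assay is direct-infusion (no chromatography) positive-mode
high-resolution mass spectrometry of plasma. Each sample yields one peak
list: pairs of *m/z* (Da) and intensity. The pipeline assumes:

- A spiked internal standard (losartan, monoisotopic [M+H]+ at *m/z*
  423.169) is present in every sample. Dividing every intensity by the
  standard's intensity removes per-sample global scale (injection volume,
  source efficiency); the standard itself becomes exactly 1
  (`recalibrate_intensities()`). The standard is located as the nearest
  peak within 0.005 Da; absence is an error, not a warning, because
  downstream intensities would be on arbitrary scales.
- Mass accuracy is a few mDa. One tolerance, **0.005 Da**, is used
  consistently for standard location, cross-sample alignment, isotopologue
  spacing and database search, so a feature matched at one stage cannot
  silently miss at another.
- Intensity 0 means "not detected", not "measured as zero". All
  correlation and filtering logic therefore treats zeros as missing.

## 2. Alignment and filtering

`align_spectra()` pools all peaks from all samples, sorts by *m/z*, and cuts
the pooled sequence wherever the gap between adjacent peaks exceeds the
tolerance (greedy single-linkage). This is O(N log N), deterministic, and
order-independent: the result does not depend on which sample is read
first. The consensus *m/z* of a cluster is the intensity-weighted mean of
its member peaks, so strong (better-measured) peaks dominate the position.
If one sample contributes several peaks to a cluster they are summed —
with direct infusion there is no retention time to separate them.

A caveat of gap-cutting is chaining: peaks spaced just under the tolerance
can merge into one wide feature. At 0.005 Da and realistic peak densities
this is rare, and the generator's 0.02 Da minimum spacing between true
analytes keeps the test-suite ground truth unambiguous while noise peaks
still exercise the cut logic.

Features are then kept only if detected in **at least 10 samples**
(`filter_features()`, i.e. in more than nine), which removes one-off noise
while retaining metabolites present in a quarter of a typical 40-sample
cohort.

## 3. Isotopologue linking

A feature is linked as an isotopologue of a lower-mass feature when their
spacing matches k × 1.00336 Da (k = 1, 2; the 13C–12C mass difference)
within tolerance **and** their across-sample intensities correlate at
Pearson r ≥ 0.7 over at least 5 pairwise nonzero samples. The correlation
requirement is what distinguishes a true isotopologue (whose intensity is
a fixed fraction of its parent in every sample) from a coincidental mass
spacing. Linked features stay in the matrix (they carry intensity
information) but are excluded from candidate search, since annotating a
13C peak as a separate metabolite would double-count its pathway.

## 4. Candidate search

`match_candidates()` matches consensus *m/z* against neutral masses under
three adducts (proton 1.007276, sodium 22.989218, potassium 38.963158 Da
— electron mass included) with an **inclusive** tolerance:
|observed − expected| ≤ 0.005 Da. Implementation: the database is kept
mass-sorted and each feature does two `findInterval()` lookups with a
±1e-9 Da slack, after which the exact inclusive comparison is applied to
the shortlisted rows. The slack guarantees no boundary case is lost to
floating-point rounding inside `findInterval`; the post-filter guarantees
the final decision is the same comparison a brute-force scan would make.
The test suite asserts exact agreement with a triple-loop oracle on 100
random databases, including values placed exactly at the boundary.

## 5. Biochemical-context annotation

At mDa accuracy most features match several isobaric candidates. The
annotation step scores each candidate by its biochemical context: a
feature's *neighbours* are the features whose log-intensities correlate at
Pearson r ≥ 0.7 (pairwise-complete over nonzero cells, at least 10 shared
observations); candidate c of feature i gets one context point per
neighbour that has at least one candidate sharing a pathway with c (each
neighbour counts at most once). The candidate with the highest context
score is accepted if it reaches **min_context_score = 2** — a single
co-correlated feature is too weak as evidence. Ties are accepted but
flagged `ambiguous`. Logs are taken before correlating because intensities
are approximately log-normal; Pearson on the log scale is then the natural
association measure. The union of accepted metabolite IDs is the
**annotated universe**, which doubles as the reference set for the
permutation null — selections are compared against what this cohort could
possibly have reported, not against the whole database.

## 6. Permutation scoring

For a subject with n selected metabolites, `permutation_null()` draws
**R = 30,000** random n-subsets of the annotated universe without
replacement and records, per pathway, the full frequency distribution of
overlap counts (a pathways × (n+1) table). From it come the null mean and
an exact empirical tail for any observed count, with the add-one rule
p = (1 + #{null ≥ observed}) / (R + 1), so p is never 0. The score is
observed / max(null mean, 1/R); flooring at 1/R keeps scores finite for
pathways the null essentially never hits. When the universe has no
structure beyond membership, this null is exactly hypergeometric, and the
tests verify the Monte-Carlo tail against `phyper()` within three
Monte-Carlo standard errors. We keep the permutation formulation (rather
than substituting `phyper`) because it remains correct if the selection
protocol ever becomes non-uniform.

Numerically, the draws are evaluated as one sparse matrix product
(pathway-membership indicator × draw indicator, `Matrix::crossprod`), so
30,000 draws over a ~40 × 320 universe take well under a second. Because
null statistics depend only on n, `diagnose_cohort()` caches them per
selection size, which in a 40-subject cohort saves most of the work.

## 7. Subject-level selection and the diagnostic score

Per subject, each feature's recalibrated intensity is converted to a
Z-score against the **control** group mean and sample standard deviation
(n − 1); a control subject is compared against the other controls
(leave-one-out), never against itself. Features with |z| > **1.64**
(two one-sided 5% tails under a Gaussian null) are selected; features with
zero control variance are skipped with a message. With 60 controls the
realised per-tail rate on pure Gaussian noise is within one percentage
point of 5% (verified by simulation in the tests); with very few controls
the heavier-than-Gaussian tails of the plug-in z would inflate selection,
which is why `zscore_select()` requires at least 3 and the documentation
recommends ≥ 20 controls.

The diagnostic score D is the plain sum of a 20-pathway panel's
representation scores. The shipped clinical panel (`pd_panel()`) and its
two decision thresholds — 12 for screening, 340 for high confidence, with
strictly-greater classification — are on the clinical assay's score scale.
On other cohorts the panel can be re-derived from the case-control
comparison (`derive_panel()`, top 20 by mean case score) and the threshold
chosen from the control distribution of D; `score_auc()` gives a
threshold-free summary.

Group contrasts (`compare_groups()`) report per-pathway mean scores, a
fold change rounded to one decimal (the unrounded value is kept as an
attribute), a Wilcoxon rank-sum p (exact when both groups are small and
untied, normal approximation with tie and continuity correction
otherwise — the standard `stats::wilcox.test` policy, verified against a
full enumeration oracle), and Benjamini–Hochberg q-values.

## 8. The synthetic generator: realism and limits

`simulate_dataset()` exists so that every claim the pipeline makes can be
checked against known ground truth. Defaults (all overridable via
`sim_config()`): 40 disjoint pathways × 8 metabolites, 20 cases and 20
controls, 2 pathways perturbed in cases with a ×3 intensity effect.

What it models, and why:

- **Log-normal intensities with pathway-level correlation.** Each pathway
  has a latent per-sample factor; member intensities share it with
  within-pathway correlation 0.8 on the log scale (the latent sd is
  `noise_sd * sqrt(r/(1-r))`). This correlation is what the annotation
  step's context scoring feeds on, so it must exist in the simulation for
  recovery numbers to mean anything.
- **Per-sample global scale, carried by the internal standard.** A random
  scale multiplies every peak including the losartan peak, so
  recalibration is genuinely exercised rather than being a no-op.
- **Adducts, isotopologues, noise.** Each metabolite is emitted under one
  adduct (M+H 70%, M+Na 20%, M+K 10%); 30% of metabolites get a 13C
  isotopologue at a fixed 8–35% relative intensity; 50 noise peaks per
  sample are placed at least 0.05 Da away from any true peak; all peak
  positions get Gaussian jitter (sd 0.5 mDa), comfortably inside the
  5 mDa tolerance.
- **Decoy database entries.** The database contains, per true metabolite,
  2 near-isobaric decoys (mass shifted by up to ±3 mDa, assigned to a
  random *other* pathway) that are never emitted in spectra. Without
  decoys almost every feature would have a unique candidate and the
  context-annotation step would be untested; with them the random-guess
  baseline accuracy is about 1/3, against which the measured recovery
  (> 0.95 at defaults) is a meaningful result. This emulates the isomer
  and isobar degeneracy of real metabolite databases at mDa accuracy.
- **Guaranteed spacing.** True masses are drawn in [80, 900] Da with at
  least 0.02 Da between any two (sorted uniforms plus a spacing ramp), so
  ground-truth feature matching at 5 mDa is unambiguous and recovery can
  be scored exactly.

Known departures from real data, accepted deliberately: pathways are
disjoint (real pathways overlap; the enrichment code handles overlap, the
generator just doesn't produce it so that ground truth stays crisp);
case-control effects are a uniform multiplicative shift on whole pathways;
there is no electrospray ionisation suppression, charge > 1, or in-source
fragmentation. The generator is a test instrument, not a simulator of
plasma.

## 9. Problem sizes and reproducibility

All randomness goes through explicit integer seeds; the generator and the
permutation null restore the caller's RNG state afterwards, so library
code never perturbs a user's session RNG. Sizes used by the shipped
tests and the acceptance script were chosen to give stable statistics
within a single-CPU minute-scale budget:

- 30,000 permutation draws wherever a tail probability is asserted
  (Monte-Carlo SE of a 3% tail ≈ 0.1%).
- 2,000 draws inside the 20-replicate end-to-end runs: the quantities
  checked there (pathway ranks, AUC) are rank-based and empirically
  identical at 2,000 and 30,000 draws, while the runtime differs by an
  order of magnitude.
- 10,000 simulations for rank-sum type-I calibration at cohort-sized
  groups (28 per arm), and 10,000 features × 60 controls for Z-tail
  calibration (binomial SE ≈ 0.2%).
- 20 simulated cohorts (seeds varied, defaults otherwise) for the
  end-to-end claims: perturbed pathways recovered in the top 5 in ≥ 90%
  of cases, mean diagnostic AUC > 0.8.

`scripts/acceptance.R --seed <int> --out <path>` recomputes all of the
above and writes them as JSON; the same seed reproduces the same file.
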