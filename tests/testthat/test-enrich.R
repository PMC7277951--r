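test_that("projection counts equal exhaustive set intersection", {
  pdb <- toy_pdb()
  expect_equal(unname(project_counts(character(0), pdb)), c(0L, 0L, 0L))
  expect_equal(project_counts(c("m1", "m2", "m3"), pdb)[["pA"]], 3L)

  set.seed(2)
  for (rep in 1:20) {
    sel <- sample(paste0("m", 1:9), 5)
    k <- project_counts(sel, pdb)
    want <- vapply(pdb$members, function(m) length(intersect(sel, m)), 0L)
    expect_equal(unname(k), unname(want))
  }
  # idempotent in the set sense: duplicates do not inflate counts
  expect_equal(project_counts(c("m1", "m1", "m2"), pdb)[["pA"]], 2L)
})

test_that("permutation null matches the hypergeometric expectation", {
  # toy universe N = 20, one pathway of K = 5, draws of n = 4
  universe <- paste0("u", 1:20)
  pdb <- pathway_db(c("p1", "p2"), c("P1", "P2"),
                    list(universe[1:5], c("x1", "x2")))  # p2 disjoint from universe
  R <- 30000L
  nul <- permutation_null(4L, universe, pdb, R = R, seed = 42L)
  expected <- 4 * 5 / 20
  hyper_sd <- sqrt(4 * (5 / 20) * (15 / 20) * (20 - 4) / (20 - 1))
  mc_se <- hyper_sd / sqrt(R)
  expect_lt(abs(nul$null_mean[["p1"]] - expected), 3 * mc_se)
  # pathway disjoint from the universe never scores
  expect_equal(nul$null_mean[["p2"]], 0)
  expect_equal(nul$null_sd[["p2"]], 0)
  # determinism under the same seed
  nul2 <- permutation_null(4L, universe, pdb, R = R, seed = 42L)
  expect_identical(nul$count_freq, nul2$count_freq)
  # null means scale linearly in n_sel (hypergeometric linearity)
  nul8 <- permutation_null(8L, universe, pdb, R = R, seed = 42L)
  expect_equal(nul8$null_mean[["p1"]] / nul$null_mean[["p1"]], 2,
               tolerance = 0.05)
  expect_error(permutation_null(25L, universe, pdb), "universe")
})

test_that("representation scores and empirical p follow the ratio/add-one rules", {
  universe <- paste0("u", 1:20)
  pdb <- pathway_db(c("p1", "p2"), c("P1", "P2"),
                    list(universe[1:5], universe[6:10]))
  R <- 30000L
  sel <- universe[c(1, 2, 3, 11)]  # k = 3 in p1, 0 in p2
  sp <- representation_scores(sel, universe, pdb, R = R, seed = 7L)
  expect_s3_class(sp, "ldt_scores")
  # k = 0 gives score 0
  expect_equal(sp$score[sp$pathway_id == "p2"], 0)
  # ratio definition
  expect_equal(sp$score[sp$pathway_id == "p1"],
               3 / max(sp$null_mean[sp$pathway_id == "p1"], 1 / R))
  # empirical tail within 3 MC standard errors of the exact hypergeometric tail
  p_exact <- stats::phyper(2, 5, 15, 4, lower.tail = FALSE)  # P(X >= 3)
  mc_se <- sqrt(p_exact * (1 - p_exact) / R)
  expect_lt(abs(sp$empirical_p[sp$pathway_id == "p1"] - p_exact), 3 * mc_se)
  # add-one rule: p never 0, never above 1
  expect_true(all(sp$empirical_p > 0 & sp$empirical_p <= 1))

  # monotonicity: adding a member of p1 never decreases k or score
  sp2 <- representation_scores(c(sel, universe[4]), universe, pdb,
                               R = R, seed = 7L)
  expect_gte(sp2$observed[sp2$pathway_id == "p1"],
             sp$observed[sp$pathway_id == "p1"])
  expect_gte(sp2$score[sp2$pathway_id == "p1"],
             sp$score[sp$pathway_id == "p1"])
})

test_that("fold change reproduces the published rounding arithmetic", {
  expect_equal(as.numeric(fold_change(27.8, 8.6)), 3.2)
  expect_equal(as.numeric(fold_change(21.4, 2.7)), 7.9)
  expect_equal(as.numeric(fold_change(5, 5)), 1.0)
  expect_true(is.na(as.numeric(fold_change(3, 0))))
  expect_equal(attr(fold_change(27.8, 8.6), "unrounded"), 27.8 / 8.6)
})

test_that("rank-sum p is exact for small untied samples", {
  # enumeration oracle over all 20 rank assignments
  expect_equal(enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # random untied small samples agree with enumeration
  set.seed(4)
  for (rep in 1:10) {
    x <- sample(100, 4); y <- setdiff(sample(100, 10), x)[1:5]
    expect_equal(ranksum_test(x, y), enumerate_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
  # degenerate input
  expect_equal(ranksum_test(rep(2, 5), rep(2, 6)), 1)
  expect_error(ranksum_test(1:2, 1:5), ">= 3")
})

test_that("rank-sum type-I error is calibrated at the 5% level", {
  set.seed(12)
  n_sim <- 10000
  # cohort-sized groups (28 per arm) where the test's discreteness is mild
  rej <- vapply(seq_len(n_sim), function(i) {
    ranksum_test(rnorm(28), rnorm(28)) < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("group comparison emits the published table shape", {
  universe <- paste0("u", 1:20)
  pdb <- pathway_db(c("p1", "p2"), c("P1", "P2"),
                    list(universe[1:5], universe[6:10]))
  set.seed(9)
  ids <- paste0("s", 1:8)
  profiles <- lapply(seq_along(ids), function(i) {
    sel <- sample(universe, 6)
    if (i <= 4) sel <- unique(c(sel, universe[1:3]))  # cases enriched in p1
    representation_scores(sel, universe, pdb, R = 2000L, seed = i)
  })
  names(profiles) <- ids
  groups <- stats::setNames(rep(c("case", "control"), each = 4), ids)
  cmp <- compare_groups(profiles, groups)
  expect_named(cmp, c("pathway_id", "name", "mean_case_score",
                      "mean_control_score", "fold", "fold_unrounded",
                      "ranksum_p", "bh_q"))
  expect_gt(cmp$mean_case_score[cmp$pathway_id == "p1"],
            cmp$mean_control_score[cmp$pathway_id == "p1"])
  expect_true(all(cmp$bh_q >= cmp$ranksum_p - 1e-12))
})
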