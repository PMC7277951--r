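make_at <- function(feature_index, metabolite_id) {
  n <- length(feature_index)
  data.frame(feature_index = feature_index, metabolite_id = metabolite_id,
             context_score = rep(5L, n), accepted = rep(TRUE, n),
             ambiguous = rep(FALSE, n), stringsAsFactors = FALSE)
}

test_that("Z-scores use control-only statistics with leave-one-out", {
  # controls {1,2,3}: mean 2, sample sd 1; subject value 10 gives z = 8
  m <- matrix(c(10, 1, 2, 3), 1, 4)
  fm <- fm_from_matrix(m, sample_ids = c("case1", "c1", "c2", "c3"))
  at <- make_at(1L, "metX")
  zs <- zscore_select(fm, "case1", c("c1", "c2", "c3"), at)
  expect_equal(zs$z, 8)
  expect_equal(zs$direction, "up")
  expect_equal(zs$selected_metabolites, "metX")

  # subject equal to the control mean is never selected
  m2 <- matrix(c(2, 1, 2, 3), 1, 4)
  fm2 <- fm_from_matrix(m2, sample_ids = c("case1", "c1", "c2", "c3"))
  zs2 <- zscore_select(fm2, "case1", c("c1", "c2", "c3"), at)
  expect_equal(zs2$z, 0)
  expect_equal(zs2$direction, "none")

  # leave-one-out: an outlier control is excluded from its own reference
  m3 <- matrix(c(100, 1, 2, 3), 1, 4)
  fm3 <- fm_from_matrix(m3, sample_ids = c("c0", "c1", "c2", "c3"))
  zs3 <- zscore_select(fm3, "c0", c("c0", "c1", "c2", "c3"), at)
  expect_equal(zs3$z, (100 - 2) / 1)  # hand-computed LOO statistics
  # ... and its presence does not contaminate another control's z
  zs4 <- zscore_select(fm3, "c1", c("c0", "c1", "c2", "c3"), at)
  loo_mean <- mean(c(100, 2, 3)); loo_sd <- sd(c(100, 2, 3))
  expect_equal(zs4$z, (1 - loo_mean) / loo_sd)

  # zero-variance features are skipped with a message
  m5 <- matrix(c(5, 1, 1, 1), 1, 4)
  fm5 <- fm_from_matrix(m5, sample_ids = c("case1", "c1", "c2", "c3"))
  expect_message(zs5 <- zscore_select(fm5, "case1", c("c1", "c2", "c3"), at),
                 "zero control sd")
  expect_true(is.na(zs5$z))

  expect_error(zscore_select(fm, "case1", c("c1", "c2"), at), ">= 3")
})

test_that("Gaussian-null selection rate per tail is about 5% at z_crit 1.64", {
  set.seed(33)
  n_feat <- 10000; n_ctrl <- 60
  m <- cbind(rnorm(n_feat), matrix(rnorm(n_feat * n_ctrl), n_feat, n_ctrl)) + 10
  fm <- fm_from_matrix(m, mz = seq_len(n_feat) + 99,
                       sample_ids = c("s0", paste0("c", 1:n_ctrl)))
  at <- make_at(integer(0), character(0))
  zs <- zscore_select(fm, "s0", paste0("c", 1:n_ctrl), at)
  up_rate <- mean(zs$direction == "up")
  down_rate <- mean(zs$direction == "down")
  expect_lt(abs(up_rate - 0.05), 0.01)   # 5% +- 1% absolute per tail
  expect_lt(abs(down_rate - 0.05), 0.01)
})

test_that("diagnostic score sums the panel and classification is strict", {
  prof <- data.frame(pathway_id = paste0("p", 1:25), name = paste0("P", 1:25),
                     score = c(1:20, rep(0, 5)), stringsAsFactors = FALSE)
  panel <- paste0("p", 1:20)
  expect_equal(diagnostic_score(prof, panel), 210)
  prof0 <- prof; prof0$score <- 0
  expect_equal(diagnostic_score(prof0, panel), 0)
  prof1 <- prof; prof1$score <- 1
  expect_equal(diagnostic_score(prof1, panel), 20)
  expect_error(diagnostic_score(prof, c(panel, "missing")), "missing")

  # strict inequality at the threshold
  expect_equal(classify(12, 12), "no-pattern")
  expect_equal(classify(13, 12), "PD-pattern")
  expect_equal(classify(350, 340), "PD-pattern")
  # monotone in D
  D <- sort(runif(50, 0, 30))
  lab <- classify(D, 12)
  expect_true(all(diff(lab == "PD-pattern") >= 0))
})

test_that("confusion metrics reproduce the published worked examples", {
  c1 <- confusion_metrics(18, 4, 24, 10)
  expect_equal(round(c1$accuracy), 75)
  expect_equal(round(c1$sensitivity), 64)   # 18/28 = 64.3
  expect_equal(round(c1$specificity), 86)   # 24/28 = 85.7
  c2 <- confusion_metrics(12, 1, 27, 16)
  expect_equal(round(c2$specificity), 96)   # 27/28 = 96.4
  expect_equal(round(c2$sensitivity), 43)
  expect_equal(round(c2$accuracy), 70)
  # perfect classifier
  c3 <- confusion_metrics(7, 0, 7, 0)
  expect_equal(c(c3$sensitivity, c3$specificity, c3$accuracy), c(100, 100, 100))
  # identities: sensitivity + FNR = specificity + FPR = 100
  fnr <- 100 * c1$fn / (c1$tp + c1$fn)
  fpr <- 100 * c1$fp / (c1$tn + c1$fp)
  expect_equal(c1$sensitivity + fnr, 100)
  expect_equal(c1$specificity + fpr, 100)
  expect_error(confusion_metrics(0, 1, 2, 0), "positive class")
})

test_that("panel utilities load and map the packaged panel", {
  panel <- pd_panel()
  expect_equal(nrow(panel), 20L)
  expect_true("Warburg effect" %in% panel$pathway_name)
  pdb <- pathway_db(c("x1", "x2"), c("Warburg effect", "Unrelated"),
                    list("m1", "m2"))
  expect_message(ids <- match_panel_names(panel$pathway_name, pdb), "unmatched")
  expect_equal(ids, "x1")
})

test_that("score AUC is the rank (Mann-Whitney) statistic", {
  D <- c(1, 2, 3, 4)
  expect_equal(score_auc(D, c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(score_auc(D, c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_equal(score_auc(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE)), 0.5)
})
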