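test_that("internal-standard recalibration divides by the standard peak", {
  s <- new_spectrum("x", c(180.0, 423.169), c(500, 2000))
  r <- recalibrate_intensities(s)
  expect_equal(r$intensity, c(0.25, 1.0))

  # standard already at 1 leaves the spectrum unchanged
  s1 <- new_spectrum("x", c(180.0, 423.169), c(0.25, 1))
  expect_equal(recalibrate_intensities(s1)$intensity, s1$intensity)

  # nearest peak within tol is used even if slightly off
  s2 <- new_spectrum("x", c(423.1693, 100), c(4, 2))
  expect_equal(recalibrate_intensities(s2)$intensity, c(0.5, 1))

  expect_error(recalibrate_intensities(new_spectrum("bad", c(100, 200), c(1, 1))),
               "bad")
})

test_that("alignment clusters pooled peaks by gap rule", {
  # single spectrum: identity
  s <- new_spectrum("a", c(100, 200, 300), c(1, 2, 3))
  fm <- align_spectra(list(s), tol = 0.005)
  expect_equal(fm$mz, c(100, 200, 300))
  expect_equal(as.numeric(fm$intensities), c(1, 2, 3))

  # gap 0.004 < tol: one shared feature
  a <- new_spectrum("a", 100.0000, 2)
  b <- new_spectrum("b", 100.0040, 6)
  fm1 <- align_spectra(list(a, b), tol = 0.005)
  expect_length(fm1$mz, 1L)
  expect_equal(as.numeric(fm1$intensities), c(2, 6))
  # consensus m/z is the intensity-weighted mean
  expect_equal(fm1$mz, (100 * 2 + 100.004 * 6) / 8)

  # gap 0.006 > tol: two features, each with one zero cell
  b2 <- new_spectrum("b", 100.0060, 6)
  fm2 <- align_spectra(list(a, b2), tol = 0.005)
  expect_length(fm2$mz, 2L)
  expect_equal(as.numeric(fm2$intensities), c(2, 0, 0, 6))

  # two peaks of one sample falling in one feature are summed
  c1 <- new_spectrum("a", c(100.000, 100.003), c(1, 4))
  c2 <- new_spectrum("b", 100.0015, 9)
  fm3 <- align_spectra(list(c1, c2), tol = 0.005)
  expect_length(fm3$mz, 1L)
  expect_equal(as.numeric(fm3$intensities), c(5, 9))

  expect_error(align_spectra(list(a), tol = 0), "positive")
})

test_that("alignment conserves peaks and is permutation-invariant", {
  set.seed(42)
  spectra <- lapply(1:6, function(i) {
    n <- sample(20:40, 1)
    new_spectrum(paste0("s", i), sort(runif(n, 50, 1000)), rexp(n))
  })
  fm <- align_spectra(spectra, tol = 0.005)
  # conservation: every input peak contributes somewhere
  expect_equal(sum(fm$intensities),
               sum(vapply(spectra, function(s) sum(s$intensity), 0)))
  # permutation invariance up to column order
  perm <- c(3, 1, 6, 2, 5, 4)
  fm2 <- align_spectra(spectra[perm], tol = 0.005)
  expect_equal(fm2$mz, fm$mz)
  expect_equal(fm2$intensities[, fm$sample_ids], fm$intensities)
  # within any feature no merged gap exceeds tol
  pooled <- sort(unlist(lapply(spectra, `[[`, "mz")))
  gaps <- diff(pooled)
  feat <- cumsum(c(1, as.integer(gaps > 0.005)))
  expect_true(all(tapply(pooled, feat, function(v) all(diff(v) <= 0.005))))
})

test_that("prevalence filter keeps features seen in >= min_nonzero samples", {
  m <- matrix(0, 3, 12)
  m[1, 1:9] <- 1   # 9 samples: dropped at default
  m[2, 1:10] <- 1  # 10 samples: kept
  m[3, 1:12] <- 1
  fm <- fm_from_matrix(m)
  f <- filter_features(fm)
  expect_equal(f$mz, fm$mz[2:3])
  # min_nonzero = 1 keeps everything that occurs somewhere
  expect_equal(filter_features(fm, 1L)$mz, fm$mz)
})

test_that("recalibration then alignment removes per-sample global scale", {
  set.seed(7)
  base_mz <- c(88.8, 150.15, 423.169, 500.5)
  base_int <- c(2, 5, 1, 0.3)
  scales <- c(900, 1500, 400)
  spectra <- lapply(seq_along(scales), function(i) {
    new_spectrum(paste0("s", i), base_mz, base_int * scales[i])
  })
  recal <- lapply(spectra, recalibrate_intensities)
  fm <- align_spectra(recal, tol = 0.005)
  std_row <- which.min(abs(fm$mz - 423.169))
  expect_equal(unname(fm$intensities[std_row, ]), rep(1, 3))
  expect_equal(unname(fm$intensities[1, ]), rep(2, 3))
})

test_that("isotopologues are linked by spacing and intensity correlation", {
  set.seed(1)
  n <- 12
  mono <- exp(rnorm(n, 0, 1))
  m <- rbind(mono, mono * 0.2, exp(rnorm(n)))
  fm <- feature_matrix(c(181.0707, 182.0741, 183.5), m, paste0("s", 1:n))
  lk <- link_isotopologues(fm)
  expect_equal(lk$isotope_parent, c(NA, 1L, NA))

  # same spacing, uncorrelated intensities: no link
  m2 <- rbind(mono, exp(rnorm(n)), exp(rnorm(n)))
  fm2 <- feature_matrix(c(181.0707, 182.0741, 183.5), m2, paste0("s", 1:n))
  expect_true(all(is.na(link_isotopologues(fm2)$isotope_parent)))

  # no pair within spacing tolerance: no links
  fm3 <- feature_matrix(c(100, 150, 200), m, paste0("s", 1:n))
  expect_true(all(is.na(link_isotopologues(fm3)$isotope_parent)))
})

test_that("feature matrices round-trip through TSV", {
  m <- matrix(c(1.5, 0, 2, 3, 0.25, 7), 3, 2)
  fm <- feature_matrix(c(100.123456, 101.126816, 200.2), m, c("a", "b"),
                       c(NA, 1L, NA))
  p <- tempfile()
  write_feature_matrix(fm, p)
  rt <- read_feature_matrix(p)
  expect_equal(rt$mz, fm$mz, tolerance = 1e-6)
  expect_equal(rt$intensities, fm$intensities)
  expect_equal(rt$isotope_parent, fm$isotope_parent)
})
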