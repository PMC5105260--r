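test_that("CSR curve points are cumulative fractions over sorted counts", {
  tab <- ChemotypeTable(c(a = 4, b = 3, c = 2, d = 1))
  p <- csrCurve(tab)@points
  expect_equal(p$x, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(p$y, c(0, 0.4, 0.7, 0.9, 1))
})

test_that("degenerate curves hit the analytic bounds", {
  singletons <- ChemotypeTable(stats::setNames(rep(1, 12),
                                               sprintf("s%02d", 1:12)))
  p <- csrCurve(singletons)@points
  expect_equal(p$y, p$x)  # exact diagonal
  expect_equal(csrAUC(singletons), 0.5)

  one <- ChemotypeTable(c(only = 8))
  p1 <- csrCurve(one)@points
  expect_equal(p1$x, c(0, 1))
  expect_equal(p1$y, c(0, 1))
  # N = 1 is the documented trapezoid degeneracy: the two-point polyline
  # is the diagonal; the staircase convention recovers the limit value 1
  expect_equal(csrAUC(one), 0.5)
  expect_equal(csrAUC(one, convention = "staircase"), 1)
  expect_equal(f50(one), 1)
})

test_that("trapezoid AUC matches the worked example and the limit", {
  tab <- ChemotypeTable(c(a = 4, b = 3, c = 2, d = 1))
  expect_equal(csrAUC(tab), 0.625)
  # one dominant chemotype among many singletons approaches area 1
  skew <- ChemotypeTable(stats::setNames(c(999001, rep(1, 999)),
                                         sprintf("k%04d", 1:1000)))
  expect_gt(csrAUC(skew), 0.99)
})

test_that("staircase convention sums right-edge rectangles", {
  tab <- ChemotypeTable(c(a = 4, b = 3, c = 2, d = 1))
  expect_equal(csrAUC(tab, convention = "staircase"),
               (0.4 + 0.7 + 0.9 + 1) / 4)
})

test_that("trapezoid AUC agrees with a midpoint-Riemann oracle", {
  set.seed(101)
  for (i in 1:200) {
    tab <- randomTable()
    cv <- csrCurve(tab)
    expect_equal(csrAUC(cv), riemannAUC(cv), tolerance = 1e-12)
  }
})

test_that("AUC never decreases when a compound moves to a richer chemotype", {
  # enumeration over small tables: move one compound from a smaller to a
  # larger chemotype and compare
  set.seed(7)
  for (i in 1:50) {
    cnt <- sort(sample(1:9, 4, replace = TRUE), decreasing = TRUE)
    if (cnt[4] < 2) cnt[4] <- 2
    before <- csrAUC(ChemotypeTable(stats::setNames(cnt, letters[1:4])))
    cnt2 <- cnt + c(1L, 0L, 0L, -1L)
    after <- csrAUC(ChemotypeTable(stats::setNames(cnt2, letters[1:4])))
    expect_gte(after, before - 1e-12)
  }
})

test_that("F50 uses the discrete smallest-k coverage rule", {
  expect_equal(f50(ChemotypeTable(c(a = 5, b = 3, c = 1, d = 1))), 0.25)
  even_singletons <- stats::setNames(rep(1, 10), sprintf("s%02d", 1:10))
  expect_equal(f50(ChemotypeTable(even_singletons)), 0.5)
  expect_equal(f50(c(4, 3, 2, 1)), 0.5)  # 4+3 = 7 >= 5 after two of four
})

test_that("Shannon entropy matches hand-computed and uniform cases", {
  expect_equal(shannonEntropy(8), 0)
  expect_equal(shannonEntropy(c(2, 2, 2, 2)), 2)
  expect_equal(shannonEntropy(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(shannonEntropy(numeric(0)), "nonempty")
})

test_that("entropy is permutation-invariant and maximal iff uniform", {
  set.seed(11)
  for (i in 1:50) {
    cnt <- sample(1:30, 6, replace = TRUE)
    expect_equal(shannonEntropy(cnt), shannonEntropy(sample(cnt)))
    if (stats::var(cnt) > 0)
      expect_lt(shannonEntropy(cnt), log2(length(cnt)))
  }
  expect_equal(shannonEntropy(rep(13, 9)), log2(9))
})

test_that("entropy agrees with an independent implementation", {
  set.seed(12)
  for (i in 1:100) {
    cnt <- sample(1:50, sample(2:20, 1), replace = TRUE)
    expect_equal(shannonEntropy(cnt),
                 vegan::diversity(cnt, index = "shannon") / log(2),
                 tolerance = 1e-12)
  }
})

test_that("scaled entropy selects top-n, clamps, and is bounded", {
  expect_equal(scaledShannonEntropy(ChemotypeTable(rep(10, 8)), 8)$sse, 1)
  expect_equal(scaledShannonEntropy(ChemotypeTable(c(a = 9)), 5)$sse, 0)
  r <- scaledShannonEntropy(ChemotypeTable(c(a = 5, b = 4, c = 3)), 70)
  expect_equal(r$n_selected, 3L)
  expect_equal(r$sse, r$se / log2(3))
  # renormalization: only the selected populations count
  r2 <- scaledShannonEntropy(ChemotypeTable(c(a = 6, b = 6, c = 1)), 2)
  expect_equal(r2$sse, 1)  # top two are uniform after renormalization
})

test_that("SSE profile covers the grid and flags skew", {
  tab <- ChemotypeTable(stats::setNames(c(50, rep(1, 9)),
                                        sprintf("k%02d", 1:10)))
  prof <- sseProfile(tab, n = c(5, 10, 15))
  expect_equal(prof$n_top, c(5L, 10L, 15L))
  expect_equal(prof$n_selected, c(5L, 10L, 10L))
  expect_true(all(prof$sse < 1))
  uni <- sseProfile(ChemotypeTable(rep(4, 20)))
  expect_true(all(abs(uni$sse - 1) < 1e-12))
})

test_that("scaffold summary reproduces published census ratios", {
  s1 <- summarizeScaffolds(tableFromCensus(70, 76, 65))
  expect_equal(round(s1$N_over_M, 3), 0.921)
  expect_equal(round(s1$Nsing_over_N, 3), 0.929)
  expect_equal(round(s1$Nsing_over_M, 3), 0.855)
  s2 <- summarizeScaffolds(tableFromCensus(238, 2249, 150))
  expect_equal(round(s2$N_over_M, 3), 0.106)
  expect_equal(round(s2$Nsing_over_N, 3), 0.630)
})

test_that("all-singleton summary hits every maximum-diversity bound", {
  tab <- ChemotypeTable(stats::setNames(rep(1, 24), sprintf("s%02d", 1:24)))
  s <- summarizeScaffolds(tab)
  expect_equal(s$N_over_M, 1)
  expect_equal(s$Nsing_over_M, 1)
  expect_equal(s$auc, 0.5)
  expect_equal(s$f50, 0.5)
})

test_that("AUC and F50 rank libraries in opposite directions", {
  set.seed(21)
  tabs <- replicate(40, randomTable(), simplify = FALSE)
  aucs <- vapply(tabs, csrAUC, numeric(1))
  f50s <- vapply(tabs, f50, numeric(1))
  expect_lte(suppressWarnings(
    stats::cor(aucs, f50s, method = "spearman")), 0)
})

test_that("summary TSV rounds ratios to 3 decimals and keeps counts", {
  tabs <- list(ChemotypeTable(c(a = 4, b = 3, c = 2, d = 1), "t1"),
               ChemotypeTable(stats::setNames(rep(1, 5), letters[1:5]),
                              "t2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- writeScaffoldSummary(tabs, f, sseGrid = c(5L, 10L))
  back <- read.delim(f)
  expect_equal(back$N, c(4L, 5L))
  expect_equal(back$auc, c(0.625, 0.5))
  expect_true(all(c("sse5", "sse10") %in% names(back)))
})
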