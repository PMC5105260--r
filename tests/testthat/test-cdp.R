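makeRecords <- function() {
  scaffold <- data.frame(set_name = c("A", "B", "C"),
                         N = c(10L, 20L, 30L), M = c(50L, 100L, 60L),
                         auc = c(0.60, 0.85, 0.90),
                         f50 = c(0.40, 0.10, 0.05))
  sim <- data.frame(set_name = c("A", "B", "C"),
                    median = c(0.30, 0.50, 0.30))
  prop <- c(A = 2.5, B = 1.0, C = 1.8)
  assembleCDP(scaffold, sim, prop, yMetric = "auc")
}

test_that("record assembly joins the three summaries per library", {
  rec <- makeRecords()
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$x_fp, c(0.30, 0.50, 0.30))
  expect_equal(rec$y_value, c(0.60, 0.85, 0.90))
  expect_equal(rec$prop_diversity, c(2.5, 1.0, 1.8))
  expect_true(all(is.na(rec$quadrant)))
})

test_that("a missing summary is an error naming the set", {
  scaffold <- data.frame(set_name = c("A", "B"), M = c(10L, 10L),
                         auc = c(0.6, 0.7), f50 = c(0.2, 0.3))
  sim <- data.frame(set_name = "A", median = 0.4)
  expect_error(assembleCDP(scaffold, sim, c(A = 1, B = 2)), "B")
  sim2 <- data.frame(set_name = c("A", "B"), median = c(0.4, 0.5))
  expect_error(assembleCDP(scaffold, sim2, c(A = 1)), "B")
})

test_that("median thresholds resolve by linear interpolation", {
  ex <- exampleLibrarySummaries()
  rec <- data.frame(set_name = ex$set_name, x_fp = ex$median_maccs,
                    y_metric = "f50", y_value = ex$f50,
                    prop_diversity = 1, size_M = ex$M)
  th <- resolveThresholds(rec, xThreshold = "median",
                          yThreshold = "median")
  # exact median of the printed F50 values is 0.1115; it agrees with the
  # published threshold 0.111 at the printed 3-decimal precision
  expect_equal(th$y_threshold, 0.1115)
  expect_lt(abs(th$y_threshold - 0.111), 5e-4 + 1e-12)
  expect_equal(th$x_threshold, stats::median(ex$median_maccs))
  expect_true(th$y_high_is_diverse)
})

test_that("fixed thresholds pass through and AUC direction flips", {
  rec <- makeRecords()
  th <- resolveThresholds(rec, xThreshold = 0.40, yThreshold = 0.75)
  expect_equal(th$x_threshold, 0.40)
  expect_equal(th$y_threshold, 0.75)
  expect_false(th$y_high_is_diverse)
})

test_that("quadrant classification follows the high/low semantics", {
  rec <- makeRecords()
  th <- resolveThresholds(rec, xThreshold = 0.40, yThreshold = 0.75)
  cl <- classifyQuadrants(rec, th)
  # A: fp 0.30 < 0.40 high; auc 0.60 < 0.75 high -> red
  # B: fp 0.50 low; auc 0.85 low -> white
  # C: fp 0.30 high; auc 0.90 low -> blue
  expect_equal(cl$quadrant, c("both_high", "both_low", "fp_only"))
  expect_equal(quadrantColor(cl$quadrant), c("red", "white", "blue"))
})

test_that("values on a threshold classify as low diversity", {
  rec <- makeRecords()
  th <- resolveThresholds(rec, xThreshold = 0.30, yThreshold = 0.60)
  cl <- classifyQuadrants(rec, th)
  expect_equal(cl$quadrant[1], "both_low")  # exactly on both lines
})

test_that("classification is invariant under record order", {
  rec <- makeRecords()
  th <- resolveThresholds(rec, xThreshold = 0.40, yThreshold = 0.75)
  shuffled <- rec[c(3, 1, 2), ]
  cl1 <- classifyQuadrants(rec, th)
  cl2 <- classifyQuadrants(shuffled, th)
  expect_equal(cl2$quadrant[match(cl1$set_name, cl2$set_name)],
               cl1$quadrant)
})

test_that("a maximally diverse library stays red under auc and f50", {
  scaffold <- data.frame(set_name = c("max", "mid", "low"),
                         M = c(60L, 60L, 60L),
                         auc = c(0.5, 0.75, 0.95),
                         f50 = c(0.5, 0.2, 0.02))
  sim <- data.frame(set_name = c("max", "mid", "low"),
                    median = c(0.1, 0.4, 0.8))
  prop <- c(max = 2, mid = 1.5, low = 1)
  for (ym in c("auc", "f50")) {
    rec <- assembleCDP(scaffold, sim, prop, yMetric = ym)
    th <- resolveThresholds(rec)
    cl <- classifyQuadrants(rec, th)
    expect_equal(cl$quadrant[cl$set_name == "max"], "both_high")
  }
})

test_that("single-record threshold resolution warns", {
  rec <- makeRecords()[1, ]
  expect_warning(th <- resolveThresholds(rec), "degenerate")
  expect_equal(th$x_threshold, rec$x_fp)
})

test_that("plot and companion table encode identical numbers", {
  rec <- makeRecords()
  th <- resolveThresholds(rec, xThreshold = 0.40, yThreshold = 0.75)
  cl <- classifyQuadrants(rec, th)
  g <- plotCDP(cl, th)
  expect_s3_class(g, "ggplot")
  png_f <- withr::local_tempfile(fileext = ".png")
  svg_f <- withr::local_tempfile(fileext = ".svg")
  tsv_f <- withr::local_tempfile(fileext = ".tsv")
  writeCDP(cl, th, plotFiles = c(png_f, svg_f), tableFile = tsv_f)
  expect_true(file.exists(png_f) && file.size(png_f) > 0)
  expect_true(file.exists(svg_f) && file.size(svg_f) > 0)
  back <- read.delim(tsv_f)
  expect_equal(back$x_fp, cl$x_fp)
  expect_equal(back$y_value, cl$y_value)
  expect_equal(back$quadrant, cl$quadrant)
  expect_equal(unique(back$x_threshold), th$x_threshold)
})
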