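test_that("pool scaffolds are fixed points of chemotype extraction", {
  pool <- scaffoldPool()
  expect_gte(length(pool), 100L)
  idx <- seq(1, length(pool), by = 6)  # systematic subsample
  keys <- extractChemotype(pool[idx])
  expect_identical(unname(keys), unname(extractChemotype(keys)))
  expect_false(any(keys == ACYCLIC_SENTINEL))
})

test_that("explicit specs recover their chemotype census exactly", {
  spec <- librarySpec(10, 100, "explicit", counts = rep(10L, 10),
                      seed = 42)
  lib <- generateLibrary(spec)
  expect_equal(length(lib$set), 100L)
  tab <- tabulateChemotypes(deduplicateLibrary(curateLibrary(lib$set)))
  got <- chemotypeCounts(tab)
  want <- lib$scaffoldCounts
  expect_setequal(names(got), names(want))
  expect_equal(as.integer(got[names(want)]), unname(want))
  # per-molecule agreement with ground truth
  keys <- extractChemotype(lib$set)
  expect_identical(unname(keys[lib$groundTruth$id]),
                   lib$groundTruth$chemotype_key)
})

test_that("all-singleton specs land on the diversity bounds end to end", {
  lib <- generateLibrary(librarySpec(60, 60, "uniform", seed = 7))
  tab <- tabulateChemotypes(deduplicateLibrary(curateLibrary(lib$set)))
  expect_equal(nChemotypes(tab), 60L)
  expect_equal(csrAUC(tab), 0.5)
  expect_equal(f50(tab), 0.5)
})

test_that("the same seed reproduces byte-identical output", {
  spec <- librarySpec(8, 40, "zipf", zipfExponent = 1.5,
                      acyclicFraction = 0.25, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".smi")
  f2 <- withr::local_tempfile(fileext = ".smi")
  writeGeneratedLibrary(generateLibrary(spec), f1)
  writeGeneratedLibrary(generateLibrary(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  other <- generateLibrary(librarySpec(8, 40, "zipf", zipfExponent = 1.5,
                                       acyclicFraction = 0.25, seed = 100))
  expect_false(identical(readLines(f1),
                         paste0(other$set@records$smiles_raw, "\t",
                                other$set@records$id)))
})

test_that("acyclic fraction maps exactly onto the sentinel chemotype", {
  lib <- generateLibrary(librarySpec(5, 40, "uniform",
                                     acyclicFraction = 0.5, seed = 3))
  expect_equal(sum(lib$groundTruth$chemotype_key == ACYCLIC_SENTINEL),
               20L)
  tab <- tabulateChemotypes(deduplicateLibrary(curateLibrary(lib$set)))
  expect_equal(unname(chemotypeCounts(tab)[[ACYCLIC_SENTINEL]]), 20L)
})

test_that("larger zipf exponents concentrate scaffolds (higher AUC, lower SSE)", {
  res <- vapply(c(0.2, 1, 2.5), function(s) {
    lib <- generateLibrary(librarySpec(20, 60, "zipf", zipfExponent = s,
                                       seed = 11))
    tab <- ChemotypeTable(lib$scaffoldCounts)
    c(auc = csrAUC(tab), sse = scaledShannonEntropy(tab, 20)$sse)
  }, numeric(2))
  expect_true(all(diff(res["auc", ]) > 0))
  expect_true(all(diff(res["sse", ]) < 0))
})

test_that("infeasible specs are rejected", {
  expect_error(librarySpec(10, 5, "uniform"), "fewer cyclic")
  expect_error(librarySpec(2, 10, "explicit", counts = c(4, 4)),
               "sum to the cyclic total")
  expect_error(generateLibrary(librarySpec(1, 200, "explicit",
                                           counts = 200L, seed = 1)),
               "infeasible")
  expect_error(generateLibrary(librarySpec(500, 500, "uniform")),
               "pool holds")
})
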