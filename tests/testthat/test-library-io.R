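test_that("SMILES files are read with the documented dialect", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# a comment", "CCO\tethanol", "c1ccccc1", "", "CC(=O)O"),
             f)
  set <- readLibrary(f)
  expect_s4_class(set, "CompoundSet")
  expect_equal(length(set), 3L)
  expect_equal(compoundData(set)$id, c("ethanol", "row2", "row3"))
  expect_equal(processingLog(set)$n_skipped, 0L)
})

test_that("malformed records are skipped and counted, order preserved", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "CCN", "not_a_smiles((", "CCC", "c1ccccc1"), f)
  set <- readLibrary(f)
  expect_equal(length(set), 4L)
  expect_equal(processingLog(set)$n_skipped, 1L)
  expect_equal(compoundData(set)$smiles_raw,
               c("CCO", "CCN", "CCC", "c1ccccc1"))
})

test_that("empty or unreadable input is fatal", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# only a comment", "junk((("), f)
  expect_error(readLibrary(f), "empty library")
  expect_error(readLibrary(file.path(tempdir(), "no_such_file.smi")),
               "cannot read")
})

test_that("SDF input round-trips through the reader", {
  sdf <- ChemmineR::smiles2sdf(c(benzene = "c1ccccc1", ethanol = "CCO"))
  f <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f, cid = TRUE)
  set <- readLibrary(f)
  expect_equal(length(set), 2L)
  expect_setequal(compoundData(set)$smiles_canonical,
                  c("c1ccccc1", "CCO"))
})

test_that("curation keeps the largest organic component and neutralizes", {
  set <- curateLibrary(librarySetFromSmiles(
    c(salt = "CC(=O)[O-].[Na+]", plain = "c1ccccc1",
      inorganic = "[Na+].[Cl-]")))
  d <- compoundData(set)
  expect_equal(d$smiles_canonical[d$id == "salt"], "CC(=O)O")
  expect_equal(d$smiles_canonical[d$id == "plain"], "c1ccccc1")
  expect_false("inorganic" %in% d$id)
  rej <- processingLog(set)$rejections
  expect_equal(rej$reason[rej$id == "inorganic"], "no_organic_component")
})

test_that("curation annotates heavy atoms and ring counts", {
  set <- curateLibrary(librarySetFromSmiles(
    c("CCO", "c1ccccc1", "C1CC1CC2CC2")))
  d <- compoundData(set)
  expect_equal(d$n_heavy_atoms, c(3L, 6L, 7L))
  expect_equal(d$n_rings, c(0L, 1L, 2L))
})

test_that("curation is idempotent", {
  raw <- c("CC(=O)[O-].[Na+]", "c1ccccc1", "CCO", "C[NH3+].[Cl-]",
           "O=C([O-])c1ccccc1.[K+]")
  once <- curateLibrary(librarySetFromSmiles(raw))
  twice <- curateLibrary(once)
  expect_identical(compoundData(once)$smiles_canonical,
                   compoundData(twice)$smiles_canonical)
})

test_that("deduplication keeps first occurrences and is order-insensitive", {
  set <- curateLibrary(librarySetFromSmiles(
    c(a = "CCO", b = "OCC", c = "CCN")))
  ded <- deduplicateLibrary(set)
  expect_equal(length(ded), 2L)
  expect_equal(compoundData(ded)$id, c("a", "c"))
  expect_equal(processingLog(ded)$n_duplicates, 1L)

  perm <- curateLibrary(librarySetFromSmiles(
    c(c = "CCN", b = "OCC", a = "CCO")))
  expect_setequal(compoundData(deduplicateLibrary(perm))$smiles_canonical,
                  compoundData(ded)$smiles_canonical)
})

test_that("pipeline size never exceeds the raw record count", {
  raw <- c("CCO", "OCC", "bad(((", "CC(=O)[O-].[Na+]", "[Na+].[Cl-]")
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(raw, f)
  set <- loadLibrary(f)
  expect_lte(length(set), length(raw))
  expect_equal(processingLog(set)$stage, "unique")
})

test_that("cyclic subsets drop exactly the ring-free molecules", {
  set <- curateLibrary(librarySetFromSmiles(
    c("CCO", "c1ccccc1", "CCCC", "Cc1ccncc1")))
  sub <- cyclicSubset(set)
  expect_equal(length(sub), 2L)
  expect_true(all(compoundData(sub)$n_rings > 0))
})
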