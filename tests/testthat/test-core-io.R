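test_that("SMILES lists read in file order with ids and parse reporting", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1"), f)
  mols <- readSmilesList(f)
  expect_s4_class(mols, "MoleculeSet")
  expect_identical(molIds(mols), c("mol_0001", "mol_0002"))
  expect_identical(molSmiles(mols), c("CCO", "c1ccccc1"))

  # explicit tab-separated ids are kept
  writeLines(c("CCO\tetoh", "C\tmeth"), f)
  expect_identical(molIds(readSmilesList(f)), c("etoh", "meth"))

  # an unparseable line is skipped with a warning and named in the report
  writeLines(c("CCO", "c1ccccc1", "notasmiles!!"), f)
  expect_warning(mols <- readSmilesList(f), "skipped 1")
  expect_length(mols, 2L)
  expect_equal(parseReport(mols)$rejected$line, 3L)

  # degenerate inputs are fatal
  writeLines(character(0), f)
  expect_error(readSmilesList(f), "no molecules")
  writeLines("totally *bogus*", f)
  expect_error(suppressWarnings(readSmilesList(f)), "no molecules")
  expect_error(readSmilesList(file.path(tempdir(), "absent.smi")),
               "cannot read")
})

test_that("vector matrices read under both orientations and reject bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4", "5,6"), f)           # 3 molecules, dim 2
  x <- readVectorMatrix(f, orientation = "rows")
  expect_identical(dim(vectorData(x)), c(2L, 3L))
  expect_false(isNormalized(x))
  expect_equal(vectorData(x)[, 3L], c(5, 6))

  xc <- readVectorMatrix(f, orientation = "columns")
  expect_identical(dim(vectorData(xc)), c(3L, 2L))

  # single-row file: one molecule; selecting k = 1 returns it
  writeLines("0.5,0.5", f)
  x1 <- readVectorMatrix(f, orientation = "rows")
  expect_identical(nCandidates(x1), 1L)
  expect_identical(selectedIndices(greedyLogdet(x1, 1L)), 1L)

  writeLines(c("1,2", "3,NaN"), f)
  expect_error(readVectorMatrix(f), "row 2, column 2")
  writeLines(c("1,2", "3"), f)
  expect_error(readVectorMatrix(f), "ragged")
})

test_that("vector matrix write/read round-trips at full precision", {
  x <- generateUnitVectors(7L, 5L, seed = 42L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeVectorMatrix(x, f)
  back <- readVectorMatrix(f, orientation = "rows")
  expect_equal(vectorData(back), vectorData(x), tolerance = 1e-12)
})

test_that("property tables compute ranges and flag degenerate columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mu,alpha", "0,1", "1,2", "2,3", "0.5,0"), f)
  tab <- readPropertyTable(f)
  expect_identical(propertyNames(tab), c("mu", "alpha"))
  expect_identical(nCandidates(tab), 4L)
  expect_equal(propertyRanges(tab)[, "mu"], c(min = 0, max = 2))

  writeLines(c("c", "5", "5", "5"), f)
  expect_warning(tab2 <- readPropertyTable(f), "degenerate")
  expect_equal(propertyRanges(tab2)[, "c"], c(min = 5, max = 5))
  expect_true(tab2@degenerate)

  writeLines(c("a,a", "1,2"), f)
  expect_error(readPropertyTable(f), "duplicate")
  writeLines(c("a,b", "1,x"), f)
  expect_error(readPropertyTable(f), "non-numeric")
})

test_that("selection JSON round-trips exactly, including the empty case", {
  mols <- toySmiles()
  sel <- Selection(c(3L, 17L), c(0.9, 0.4), "logdet")
  f <- withr::local_tempfile(fileext = ".json")
  writeSelection(sel, f, mols = mols, metadata = list(seed = 1L))
  doc <- jsonlite::read_json(f)
  expect_length(doc$selection, 2L)
  expect_identical(doc$selection[[1L]]$rank, 1L)
  expect_identical(doc$selection[[1L]]$id, molIds(mols)[3L])
  back <- readSelection(f)
  expect_identical(selectedIndices(back), selectedIndices(sel))
  expect_identical(stepGains(back), stepGains(sel))
  expect_identical(objectiveName(back), "logdet")

  empty <- Selection(integer(0), numeric(0), "logdet", k = 0L)
  writeSelection(empty, f)
  expect_length(jsonlite::read_json(f)$selection, 0L)
  expect_identical(selectedIndices(readSelection(f)), integer(0))

  expect_error(writeSelection(Selection(99L, 0, "x"), f, mols = mols),
               "exceed")
})

test_that("domain-type validity invariants are enforced", {
  expect_error(MoleculeSet(c("C", "O"), ids = c("a", "a")), "unique")
  expect_error(VectorMatrix(matrix(c(1, NA), 1), normalized = FALSE),
               "finite")
  expect_error(VectorMatrix(matrix(c(3, 4), 2), normalized = TRUE), "norm")
  # norm within 1e-6 of 1 is accepted as normalized, beyond is not
  v <- matrix(c(1 + 5e-7, 0), 2)
  expect_s4_class(VectorMatrix(v, normalized = TRUE), "VectorMatrix")
  expect_error(Selection(c(2L, 2L), c(1, 1), "x"), "distinct")
})
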