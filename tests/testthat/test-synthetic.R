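test_that("unit-vector generator yields seeded non-negative unit columns", {
  x <- generateUnitVectors(100L, 8L, seed = 1L)
  v <- vectorData(x)
  expect_true(all(v >= 0))
  expect_equal(sqrt(colSums(v^2)), rep(1, 100L), tolerance = 1e-12)
  expect_true(isNormalized(x))
  expect_identical(vectorData(generateUnitVectors(100L, 8L, seed = 1L)), v)
  expect_false(identical(vectorData(generateUnitVectors(100L, 8L, seed = 2L)),
                         v))
  # no column collisions at realistic sizes
  big <- vectorData(generateUnitVectors(1000L, 8L, seed = 9L))
  expect_identical(anyDuplicated(t(big)), 0L)
})

test_that("clustered instances respect noise scale and labels", {
  inst0 <- generateClusteredInstance(12L, 6L, 4L, noiseScale = 0, seed = 3L)
  v <- vectorData(inst0$vectors)
  expect_identical(inst0$labels, rep(1:4, 3L))
  # zero noise: members coincide with their cluster centers
  for (c in 1:4) {
    members <- which(inst0$labels == c)
    for (i in members[-1L])
      expect_equal(v[, i], v[, members[1L]], tolerance = 1e-12)
  }
  inst <- generateClusteredInstance(40L, 6L, 4L, noiseScale = 0.1, seed = 3L)
  vv <- vectorData(inst$vectors)
  expect_true(all(vv >= 0))
  expect_equal(sqrt(colSums(vv^2)), rep(1, 40L), tolerance = 1e-12)
  expect_error(generateClusteredInstance(3L, 6L, 4L, 0.1, 1L), "exceed")
  expect_error(generateClusteredInstance(8L, 6L, 2L, -1, 1L), "non-negative")
})

test_that("log-det greedy covers every well-separated cluster; random often misses", {
  inst <- generateClusteredInstance(40L, 8L, 4L, noiseScale = 0.05, seed = 5L)
  sel <- greedyLogdet(inst$vectors, 4L)
  expect_identical(sort(unique(inst$labels[selectedIndices(sel)])), 1:4)
  # MaxMin over Euclidean distance also covers all clusters (cross-selector)
  mm <- maxminSelect(EuclideanOracle(inst$vectors), 4L)
  expect_identical(sort(unique(inst$labels[selectedIndices(mm)])), 1:4)
  # random selection covers all 4 clusters strictly less often than greedy
  hits <- vapply(1:100, function(s) {
    r <- randomSelect(40L, 4L, seed = 7000L + s)
    length(unique(inst$labels[selectedIndices(r)])) == 4L
  }, logical(1L))
  expect_lt(mean(hits), 1)
})

test_that("generated properties are angle-linear with bounded values", {
  x <- generateUnitVectors(30L, 6L, seed = 13L)
  tab <- generateProperties(x, p = 2L, noiseScale = 0, seed = 13L)
  expect_identical(dim(propertyValues(tab)), c(30L, 2L))
  expect_identical(
    propertyValues(generateProperties(x, 2L, 0, seed = 13L)),
    propertyValues(tab))
  # identical columns get identical property rows at zero noise
  dup <- VectorMatrix(vectorData(x)[, c(1L, 1L, 2L)], normalized = TRUE)
  td <- propertyValues(generateProperties(dup, 2L, 0, seed = 4L))
  expect_equal(td[1L, ], td[2L, ], tolerance = 1e-12)
  # |w^T x| <= ||w|| for unit x (Cauchy-Schwarz); rebuild the generator's w
  set.seed(13)
  w <- matrix(rnorm(6 * 2), 6, 2)
  expect_true(all(abs(propertyValues(tab)) <=
                    rep(sqrt(colSums(w^2)), each = 30L) + 1e-9))
})

test_that("SubMo beats the average random selection on the property criterion", {
  inst <- generateClusteredInstance(60L, 8L, 4L, noiseScale = 0.05, seed = 11L)
  tab <- generateProperties(inst$vectors, p = 1L, noiseScale = 0, seed = 12L)
  k <- 8L
  submo <- wdudMeanNormalized(meanWdud(tab, greedyLogdet(inst$vectors, k)))
  rand <- vapply(1:100, function(s)
    wdudMeanNormalized(meanWdud(tab, randomSelect(60L, k, seed = 9000L + s))),
    numeric(1L))
  expect_lt(submo, mean(rand))
})

test_that("fixture writer emits matched, seed-stable files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- writeSyntheticFixtures(d1, n = 30L, m = 6L, nClusters = 3L, p = 2L,
                               noiseScale = 0.05, seed = 4L)
  writeSyntheticFixtures(d2, n = 30L, m = 6L, nClusters = 3L, p = 2L,
                         noiseScale = 0.05, seed = 4L)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]),
                     readLines(file.path(d2, basename(p1[[nm]]))))
  mols <- readSmilesList(p1$smiles)
  vec <- readVectorMatrix(p1$vectors)
  tab <- readPropertyTable(p1$properties)
  expect_identical(length(mols), 30L)
  expect_identical(nCandidates(vec), 30L)
  expect_identical(nCandidates(tab), 30L)
})

test_that("the toy molecule list parses and is fingerprint-diverse", {
  mols <- toySmiles()
  expect_length(mols, 20L)
  expect_true(all(c("O", "C") %in% molSmiles(mols)))
  fp <- computeFingerprints(mols, "MACCS")
  expect_gt(length(unique(fp@bits)), 2L)
})
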