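test_that("wdud reproduces hand-computed closed forms", {
  expect_equal(wdud(0.5, 0, 1), 0.25)          # two triangles of area 1/8
  expect_equal(wdud(c(0, 1), 0, 1), 0.25)      # integral of |x - 1/2|
  # quantile midpoints (2i-1)/(2k) achieve the optimal 1/(4k)
  for (k in 1:10) {
    mids <- (2 * seq_len(k) - 1) / (2 * k)
    expect_equal(wdud(mids, 0, 1), 1 / (4 * k), tolerance = 1e-12)
  }
  # linear scaling with the range width
  expect_equal(wdud(5, 0, 10), 2.5)
  expect_error(wdud(numeric(0), 0, 1), "nonempty")
  expect_error(wdud(0.5, 1, 0), "vmin <= vmax")
  expect_error(wdud(2, 0, 1), "outside")
  expect_warning(out <- wdud(2, 0, 1, clip = TRUE), "clipped")
  expect_equal(out, wdud(1, 0, 1))
  expect_identical(wdud(c(3, 3), 3, 3), 0)     # degenerate range
})

test_that("wdud agrees with a fine-grid quadrature oracle on random inputs", {
  set.seed(5)
  for (rep in 1:25) {
    k <- sample(1:12, 1L)
    vmin <- runif(1, -5, 0); vmax <- vmin + runif(1, 0.5, 5)
    vals <- runif(k, vmin, vmax)
    expect_lt(abs(wdud(vals, vmin, vmax) -
                    quadratureWdud(vals, vmin, vmax, npts = 2e5L)), 1e-3)
  }
})

test_that("wdud is permutation- and reflection-invariant but duplicate-sensitive", {
  vals <- c(0.1, 0.4, 0.9, 0.65)
  expect_identical(wdud(vals, 0, 1), wdud(rev(vals), 0, 1))
  expect_equal(wdud(vals, 0, 1), wdud(1 - vals, 0, 1), tolerance = 1e-12)
  refl <- wdud(0.3 + 0.8 - c(0.4, 0.7), 0.3, 0.8)
  expect_equal(wdud(c(0.4, 0.7), 0.3, 0.8), refl, tolerance = 1e-12)
  # duplicating an existing value changes the empirical CDF and the WDUD
  expect_false(isTRUE(all.equal(wdud(c(0.2, 0.8), 0, 1),
                                wdud(c(0.2, 0.2, 0.8), 0, 1))))
})

test_that("no k-subset of a random pool beats the quantile midpoints", {
  set.seed(17)
  pool <- runif(9)
  k <- 3L
  best <- 1 / (4 * k)
  sets <- utils::combn(9L, k)
  for (c in seq_len(ncol(sets)))
    expect_gte(wdud(pool[sets[, c]], 0, 1), best - 1e-12)
  # and a pool that contains the midpoints attains it exactly
  pool2 <- c(pool, (2 * seq_len(k) - 1) / (2 * k))
  sets2 <- utils::combn(length(pool2), k)
  attained <- min(apply(sets2, 2L, function(S) wdud(pool2[S], 0, 1)))
  expect_equal(attained, best, tolerance = 1e-12)
})

test_that("meanWdud scales properties by pool range and handles degenerates", {
  vals <- cbind(a = c(0, 0.25, 0.5, 0.75, 1),
                b = c(10, 15, 20, 25, 30),     # affine image of a
                c = rep(7, 5))                 # degenerate
  tab <- suppressWarnings(PropertyTable(vals))
  res <- meanWdud(tab, c(2L, 4L))              # scaled values {0.25, 0.75}
  pp <- res@perPropertyNormalized
  expect_equal(unname(pp[["a"]]), wdud(c(0.25, 0.75), 0, 1))
  # affine transforms leave the normalized WDUD unchanged
  expect_equal(pp[["a"]], pp[["b"]], tolerance = 1e-12)
  # original-units value scales by the range width
  expect_equal(unname(wdudPerProperty(res)[["b"]]), pp[["b"]] * 20)
  # degenerate property contributes 0 and is excluded from the mean
  expect_equal(unname(pp[["c"]]), 0)
  expect_identical(res@degenerate, "c")
  expect_equal(wdudMeanNormalized(res), mean(pp[c("a", "b")]))
  expect_error(meanWdud(tab, integer(0)), "nonempty")
})

test_that("wgSelect picks the 1-point optimum first and matches brute force", {
  tab <- PropertyTable(cbind(y = c(0.0, 0.1, 0.5, 0.9)))
  expect_identical(selectedIndices(wgSelect(tab, 1L)), 3L)  # midpoint wins

  # pool holding the exact k = 2 quantile midpoints {0.25, 0.75} plus decoys
  tab2 <- PropertyTable(cbind(y = c(0, 0.25, 0.05, 0.75, 1, 0.97)))
  sel2 <- wgSelect(tab2, 2L)
  expect_identical(sort(selectedIndices(sel2)), c(2L, 4L))
  expect_equal(wdudMeanNormalized(meanWdud(tab2, sel2)), 1 / 8,
               tolerance = 1e-12)

  # greedy final value vs exhaustive enumeration on small random pools
  set.seed(23)
  for (rep in 1:5) {
    tab3 <- PropertyTable(cbind(p = runif(8), q = runif(8)))
    k <- 3L
    greedyVal <- wdudMeanNormalized(meanWdud(tab3, wgSelect(tab3, k)))
    bf <- bruteForceWg(tab3, k)
    expect_gte(greedyVal, bf$value - 1e-12)       # cannot beat the optimum
    expect_lte(greedyVal, max(bf$all) + 1e-12)    # never worst either
  }

  # k = n reaches the same terminal set whatever the order
  full <- wgSelect(tab, 4L)
  expect_identical(sort(selectedIndices(full)), 1:4)
  expect_equal(wdudMeanNormalized(meanWdud(tab, selectedIndices(full))),
               wdudMeanNormalized(meanWdud(tab, 1:4)))
  expect_error(wgSelect(tab, 0L), "at least 1")

  # gains trace the achieved decreases in mean WDUD
  sel <- wgSelect(tab2, 3L)
  g <- stepGains(sel)
  m1 <- wdudMeanNormalized(meanWdud(tab2, sel@indices[1L]))
  m2 <- wdudMeanNormalized(meanWdud(tab2, sel@indices[1:2]))
  m3 <- wdudMeanNormalized(meanWdud(tab2, sel@indices[1:3]))
  expect_equal(g, c(-m1, m1 - m2, m2 - m3), tolerance = 1e-12)
})
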