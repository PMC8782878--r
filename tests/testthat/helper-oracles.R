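# Independent oracles the tests check the implementation against.

# greedy maximization by full refactorization at every step: at step t it
# recomputes f(S u {i}) - f(S) from scratch for every remaining candidate
naiveGreedyLogdet <- function(x, k) {
  n <- nCandidates(x)
  sel <- integer(0)
  gains <- numeric(0)
  for (t in seq_len(min(k, n))) {
    base <- logdetValue(x, sel)
    cand <- setdiff(seq_len(n), sel)
    g <- vapply(cand, function(i) logdetValue(x, c(sel, i)) - base,
                numeric(1L))
    j <- cand[which(g >= max(g) - 1e-12)[1L]]   # lowest index on ties
    sel <- c(sel, j)
    gains <- c(gains, g[which(g >= max(g) - 1e-12)[1L]])
  }
  list(indices = sel, gains = gains)
}

# trapezoid quadrature of the |U - V| integral on a fine grid
quadratureWdud <- function(values, vmin, vmax, npts = 1e5L) {
  xs <- seq(vmin, vmax, length.out = npts)
  U <- (xs - vmin) / (vmax - vmin)
  V <- stats::ecdf(values)(xs)
  h <- abs(U - V)
  sum((h[-1L] + h[-npts]) / 2) * (xs[2L] - xs[1L])
}

# brute-force minimum mean WDUD over all k-subsets of a property table
bruteForceWg <- function(table, k) {
  n <- nCandidates(table)
  sets <- utils::combn(n, k)
  vals <- apply(sets, 2L, function(S) wdudMeanNormalized(meanWdud(table, S)))
  list(value = min(vals), subset = sets[, which.min(vals)],
       all = vals)
}

# fingerprint set built directly from explicit on-bit lists
fpFromBits <- function(bits, nbits = 16L, kind = "ECFP") {
  new("FingerprintSet", kind = kind, bits = lapply(bits, as.integer),
      nbits = as.integer(nbits), ecfpRadius = 2L)
}
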