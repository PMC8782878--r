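#' MaxSum diversity selection
#'
#' The classical sum-dissimilarity picker: the first molecule is the one
#' with the largest total dissimilarity to all others
#' (\eqn{\sum_{j \ne i} d_{i,j}}), and each later step adds the candidate
#' maximizing \eqn{\sum_{j \in S} d_{i,j}} over the already-selected set.
#' Ties are broken toward the lowest candidate index. The per-step score is
#' recorded in the selection's gains.
#'
#' @param oracle a \code{\link{DissimilarityOracle}}.
#' @param k number of molecules to select, \code{1 <= k <= n}.
#' @return a \code{\link{Selection}}.
#' @export
maxsumSelect <- function(oracle, k) {
  .greedyDissim(oracle, k, "maxsum")
}

#' MaxMin diversity selection
#'
#' The classical nearest-neighbour picker: seeded like
#' \code{\link{maxsumSelect}} (largest total dissimilarity), then each step
#' adds the candidate maximizing its minimum dissimilarity to the selected
#' set, \eqn{\max_{i \notin S} \min_{j \in S} d_{i,j}}. Ties go to the
#' lowest index. The recorded min-distance scores are non-increasing along
#' the selection (the feasible minimum can only shrink).
#'
#' @inheritParams maxsumSelect
#' @return a \code{\link{Selection}}.
#' @export
maxminSelect <- function(oracle, k) {
  .greedyDissim(oracle, k, "maxmin")
}

.greedyDissim <- function(oracle, k, method) {
  n <- nCandidates(oracle)
  k <- as.integer(k)
  if (n < 1L) stop("empty candidate set")
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d candidates", k, n))

  # seed rule: largest total dissimilarity to all other candidates
  tot <- numeric(n)
  for (i in seq_len(n))
    tot[i] <- sum(.dissimRow(oracle, i, setdiff(seq_len(n), i)))
  first <- which(tot >= max(tot) - 1e-12)[1L]   # lowest index on ties

  sel <- integer(k)
  gains <- numeric(k)
  sel[1L] <- first
  gains[1L] <- tot[first]
  avail <- rep(TRUE, n)
  avail[first] <- FALSE
  # running score: cumulative sum (maxsum) or running min (maxmin) vs S
  score <- .dissimRow(oracle, first, seq_len(n))
  for (t in seq.int(2L, length.out = k - 1L)) {
    s <- score
    s[!avail] <- -Inf
    j <- which(s >= max(s) - 1e-12)[1L]   # lowest index on (near-)ties
    sel[t] <- j
    gains[t] <- score[j]
    avail[j] <- FALSE
    if (t < k) {
      dj <- .dissimRow(oracle, j, seq_len(n))
      score <- if (method == "maxsum") score + dj else pmin(score, dj)
    }
  }
  Selection(sel, gains, method, k = k)
}

#' Uniform random selection baseline
#'
#' Samples k distinct candidate indices uniformly without replacement —
#' i.e. from the empirical distribution of the candidate list itself.
#' Reproducible for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n number of candidates.
#' @param k number to select, \code{1 <= k <= n}.
#' @param seed integer RNG seed.
#' @return a \code{\link{Selection}} (gains are all \code{NA}: the method
#'   optimizes nothing).
#' @export
randomSelect <- function(n, k, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d candidates", k, n))
  idx <- .withSeed(seed, sample.int(n, k, replace = FALSE))
  Selection(idx, rep(NA_real_, k), "random", k = k)
}

# run expr under a fixed seed, restoring the global RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
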