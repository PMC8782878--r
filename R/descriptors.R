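#' Compute structural fingerprints
#'
#' Computes MACCS keys or ECFP circular fingerprints for every molecule,
#' through OpenBabel. MACCS uses the toolkit's 166-key dictionary. OpenBabel
#' emits ECFP of diameter \code{2 * radius} at a fixed 4096-bit length; when
#' \code{nbits < 4096} the fingerprint is OR-folded down to \code{nbits}
#' (bit b maps to \code{b mod nbits}), the conventional way to shorten hashed
#' fingerprints. Results are deterministic for a fixed toolkit version.
#'
#' @param mols a \code{\link{MoleculeSet}}; every record must have a SMILES.
#' @param kind `"MACCS"` or `"ECFP"`.
#' @param ecfpRadius circular-environment radius (default 2, i.e. ECFP4).
#' @param nbits bit length for ECFP (default 2048; a power of two at most
#'   4096). Ignored for MACCS.
#' @return a \code{\link{FingerprintSet}}.
#' @export
computeFingerprints <- function(mols, kind = c("MACCS", "ECFP"),
                                ecfpRadius = 2L, nbits = 2048L) {
  kind <- match.arg(kind)
  smi <- molSmiles(mols)
  if (anyNA(smi))
    stop("record(s) without SMILES: ",
         paste(molIds(mols)[is.na(smi)], collapse = ", "))
  if (kind == "MACCS") {
    obname <- "MACCS"
    nbits <- 166L
    ecfpRadius <- NA_integer_
  } else {
    if (!ecfpRadius %in% c(0L, 1L, 2L, 3L, 4L, 5L))
      stop("ecfpRadius must be an integer in 0..5")
    if (nbits < 1L || nbits > 4096L || bitwAnd(nbits, nbits - 1L) != 0L)
      stop("nbits must be a power of two in [1, 4096]")
    obname <- paste0("ECFP", 2L * ecfpRadius)
  }
  raw <- ChemmineOB::forEachMol("SMILES", paste(smi, collapse = "\n"),
    function(m) ChemmineOB::fingerprint_OB(list(m), obname))
  bits <- lapply(raw, function(row) {
    on <- which(as.numeric(row) != 0)
    if (kind == "MACCS") {
      on <- on[on <= 166L]               # drop OpenBabel's 256-bit padding
    } else if (nbits < length(row)) {
      on <- sort(unique((on - 1L) %% nbits + 1L))   # OR-fold
    }
    as.integer(on)
  })
  new("FingerprintSet", kind = kind, bits = bits, nbits = as.integer(nbits),
      ecfpRadius = as.integer(ecfpRadius))
}

#' ReLU then unit-norm refinement of descriptor vectors
#'
#' Clips every column to its non-negative part and scales it to Euclidean
#' norm 1 — the transform that makes the log-determinant function read
#' diversity off vector directions alone: non-negativity prevents nearly
#' origin-symmetric vectors from spanning a degenerate parallelotope, and
#' unit norms stop the objective from rewarding vector length instead of
#' angular spread. A column that is entirely non-positive becomes the zero
#' vector and is reported with a warning (its marginal log-determinant gain
#' is 0, so it is never picked ahead of any non-zero column).
#'
#' When vectors come from a network trained with these layers the transform
#' is a no-op; applying it post hoc to arbitrary exported embeddings is an
#' approximation of that training-time setup.
#'
#' @param x a \code{\link{VectorMatrix}}.
#' @return a \code{VectorMatrix} with the normalized flag set.
#' @export
reluNormalize <- function(x) {
  v <- pmax(vectorData(x), 0)
  nrm <- sqrt(colSums(v^2))
  zero <- nrm == 0
  if (any(zero))
    warning("column(s) entirely non-positive, mapped to the zero vector: ",
            paste(which(zero), collapse = ", "))
  nz <- !zero
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, nrm[nz], `/`)
  VectorMatrix(v, normalized = TRUE)
}

#' @describeIn dissimilarity Tanimoto dissimilarity
#'   \eqn{1 - |A \cap B|/|A \cup B|} of two fingerprints. Two empty
#'   fingerprints have, by the documented convention, similarity 0 and hence
#'   dissimilarity 1 (this matters for MaxMin/MaxSum on featureless
#'   molecules).
setMethod("dissimilarity", signature("TanimotoOracle"), function(oracle, i, j) {
  fp <- oracle@fingerprints
  n <- length(fp@bits)
  if (i < 1L || i > n || j < 1L || j > n) stop("index out of range")
  if (i == j) return(0)                        # d(i, i) = 0 always
  a <- fp@bits[[i]]; b <- fp@bits[[j]]
  u <- length(union(a, b))
  if (u == 0L) return(1)                       # empty vs empty convention
  1 - length(intersect(a, b)) / u
})

#' @describeIn dissimilarity Euclidean distance between descriptor-vector
#'   columns i and j.
setMethod("dissimilarity", signature("EuclideanOracle"), function(oracle, i, j) {
  v <- vectorData(oracle@vectors)
  if (i < 1L || i > ncol(v) || j < 1L || j > ncol(v))
    stop("index out of range")
  sqrt(sum((v[, i] - v[, j])^2))
})

setMethod(".dissimRow", signature("TanimotoOracle"), function(oracle, i, js) {
  vapply(js, function(j) dissimilarity(oracle, i, j), numeric(1L))
})

setMethod(".dissimRow", signature("EuclideanOracle"), function(oracle, i, js) {
  v <- vectorData(oracle@vectors)
  sqrt(colSums((v[, js, drop = FALSE] - v[, i])^2))
})

#' @rdname pairwiseMatrix
setMethod("pairwiseMatrix", "DissimilarityOracle", function(oracle, maxN) {
  n <- nCandidates(oracle)
  if (n > maxN)
    stop(sprintf(paste0("%d candidates exceed the materialization limit %d; ",
                        "use on-demand dissimilarity() calls instead"),
                 n, maxN))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) {
      js <- (i + 1L):n
      row <- .dissimRow(oracle, i, js)
      d[i, js] <- row
      d[js, i] <- row
    }
  }
  d
})
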