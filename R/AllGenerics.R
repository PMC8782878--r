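#' @import methods
NULL

#' Number of candidate molecules represented by an object
#'
#' @param x a \code{MoleculeSet}, \code{VectorMatrix}, \code{FingerprintSet},
#'   \code{PropertyTable} or \code{DissimilarityOracle}.
#' @return integer number of candidates.
#' @export
setGeneric("nCandidates", function(x) standardGeneric("nCandidates"))

#' Pairwise dissimilarity between two candidates
#'
#' Evaluates \eqn{d_{i,j}} under an oracle: Tanimoto dissimilarity of binary
#' fingerprints (\code{1 - |A
#' \cap B| / |A \cup B|}) or the Euclidean distance between descriptor
#' vectors. Dissimilarities are symmetric, non-negative and zero on the
#' diagonal; Tanimoto values lie in [0, 1].
#'
#' @param oracle a \code{DissimilarityOracle}.
#' @param i,j candidate indices (1-based).
#' @return a single non-negative numeric value.
#' @export
setGeneric("dissimilarity", function(oracle, i, j)
  standardGeneric("dissimilarity"))

# vectorized row d(i, js); internal fast path used by the selectors
setGeneric(".dissimRow", function(oracle, i, js) standardGeneric(".dissimRow"))

#' Materialize the full pairwise dissimilarity matrix
#'
#' Builds the symmetric n x n matrix of all pairwise dissimilarities under an
#' oracle. Guarded by an explicit size limit because the result is quadratic
#' in the number of candidates; beyond the limit callers should stick to
#' on-demand \code{\link{dissimilarity}} calls.
#'
#' @param oracle a \code{DissimilarityOracle}.
#' @param maxN refuse to materialize when more than \code{maxN} candidates
#'   (default 10000).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("pairwiseMatrix", function(oracle, maxN = 10000L)
  standardGeneric("pairwiseMatrix"))
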