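#' MoleculeSet: an ordered list of candidate molecules
#'
#' Holds candidate molecules in input order, each with a unique id and
#' (optionally) a SMILES string. SMILES validity is defined by the OpenBabel
#' toolkit's default sanitization; records whose SMILES the toolkit rejects
#' never enter a \code{MoleculeSet} (see \code{\link{readSmilesList}}).
#'
#' @slot ids character vector of unique identifiers.
#' @slot smiles character vector of SMILES (may contain \code{NA} when only
#'   descriptor vectors are supplied for those candidates).
#' @slot report list with parse diagnostics (e.g. rejected input lines).
#' @export
setClass("MoleculeSet",
  representation(ids = "character", smiles = "character", report = "list"),
  prototype(report = list()))

setValidity("MoleculeSet", function(object) {
  if (length(object@ids) != length(object@smiles))
    return("ids and smiles must have equal length")
  if (anyDuplicated(object@ids))
    return("molecule ids must be unique")
  if (anyNA(object@ids))
    return("molecule ids must not be NA")
  TRUE
})

#' VectorMatrix: molecular descriptor vectors as matrix columns
#'
#' An m x n numeric matrix whose n columns are m-dimensional descriptor
#' vectors, one per candidate molecule (for instance embeddings exported from
#' a trained graph neural network). The \code{normalized} flag asserts that
#' every column is entry-wise non-negative and has Euclidean norm 1 (or is
#' exactly zero); it is set by \code{\link{reluNormalize}} and by the
#' synthetic generators, and checked by the validity method with a 1e-6 norm
#' tolerance.
#'
#' @slot vectors numeric matrix, columns are candidates.
#' @slot normalized logical flag.
#' @export
setClass("VectorMatrix",
  representation(vectors = "matrix", normalized = "logical"),
  prototype(normalized = FALSE))

setValidity("VectorMatrix", function(object) {
  v <- object@vectors
  if (!is.numeric(v)) return("vectors must be a numeric matrix")
  if (any(!is.finite(v))) return("all entries must be finite")
  if (isTRUE(object@normalized)) {
    if (any(v < 0)) return("normalized matrix must be entry-wise non-negative")
    nrm <- sqrt(colSums(v^2))
    bad <- abs(nrm - 1) > 1e-6 & nrm > 0
    if (any(bad))
      return(sprintf("normalized flag set but column %d has norm %.8g",
                     which(bad)[1L], nrm[which(bad)[1L]]))
  }
  TRUE
})

#' FingerprintSet: binary structural keys per molecule
#'
#' Per-molecule binary fingerprints stored sparsely as sorted vectors of
#' "on" bit positions (1-based). Two kinds are supported: MACCS structural
#' keys (OpenBabel's 166-key dictionary) and ECFP circular fingerprints
#' hashed to \code{nbits} positions.
#'
#' @slot kind \code{"MACCS"} or \code{"ECFP"}.
#' @slot bits list of sorted integer vectors of on-bit positions.
#' @slot nbits total bit length.
#' @slot ecfpRadius circular-environment radius (ECFP only; \code{NA_integer_}
#'   for MACCS).
#' @export
setClass("FingerprintSet",
  representation(kind = "character", bits = "list", nbits = "integer",
                 ecfpRadius = "integer"),
  prototype(ecfpRadius = NA_integer_))

setValidity("FingerprintSet", function(object) {
  if (!object@kind %in% c("MACCS", "ECFP"))
    return("kind must be 'MACCS' or 'ECFP'")
  if (length(object@nbits) != 1L || is.na(object@nbits) || object@nbits < 1L)
    return("nbits must be a positive integer")
  for (b in object@bits) {
    if (length(b) && (min(b) < 1L || max(b) > object@nbits))
      return("every on-bit position must lie in [1, nbits]")
  }
  TRUE
})

#' Selection: an ordered subset of candidates with its gain trace
#'
#' The result of any selector: the chosen candidate indices in selection
#' order, the per-step objective increment (or score) recorded by the
#' selector, the name of the criterion and the requested subset size k.
#' Indices are 1-based, referring to the order of the input candidate list.
#' For the log-determinant objective the gains are non-increasing along the
#' greedy order (diminishing returns).
#'
#' @slot indices ordered integer vector of distinct candidate indices.
#' @slot gains numeric vector, one entry per selection step.
#' @slot objective label of the maximized/minimized criterion.
#' @slot k requested selection size.
#' @export
setClass("Selection",
  representation(indices = "integer", gains = "numeric",
                 objective = "character", k = "integer"))

setValidity("Selection", function(object) {
  if (anyDuplicated(object@indices)) return("indices must be distinct")
  if (length(object@indices) && min(object@indices) < 1L)
    return("indices must be >= 1")
  if (length(object@gains) != length(object@indices))
    return("gains must have one entry per selected index")
  TRUE
})

#' PropertyTable: named real-valued properties per molecule
#'
#' An n x p matrix of property values (candidates in rows, named properties
#' in columns) together with each property's \code{[v_min, v_max]} range.
#' Ranges default to the observed per-column min/max; a property whose range
#' collapses to a point is flagged degenerate (its WDUD is defined as 0 and
#' it is excluded from mean-WDUD aggregation).
#'
#' @slot values numeric matrix with column names.
#' @slot ranges 2 x p matrix with rows \code{min} and \code{max}.
#' @slot degenerate logical vector, one flag per property.
#' @export
setClass("PropertyTable",
  representation(values = "matrix", ranges = "matrix",
                 degenerate = "logical"))

setValidity("PropertyTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (any(!is.finite(v))) return("property values must be finite")
  if (is.null(colnames(v))) return("properties must be named")
  if (anyDuplicated(colnames(v))) return("property names must be unique")
  if (ncol(object@ranges) != ncol(v) || nrow(object@ranges) != 2L)
    return("ranges must be a 2 x p matrix")
  if (any(object@ranges[1L, ] > object@ranges[2L, ]))
    return("each property must satisfy v_min <= v_max")
  if (length(object@degenerate) != ncol(v))
    return("degenerate must have one flag per property")
  TRUE
})

#' DissimilarityOracle: contract yielding d(i, j) for any candidate pair
#'
#' Virtual parent of the two concrete oracles: \code{TanimotoOracle}
#' (Tanimoto dissimilarity over a \code{FingerprintSet}) and
#' \code{EuclideanOracle} (Euclidean distance over a \code{VectorMatrix}).
#' Selectors and the MPD criterion are written against this contract so any
#' descriptor source can drive them.
#'
#' @export
setClass("DissimilarityOracle", representation("VIRTUAL"))

#' @rdname DissimilarityOracle-class
#' @slot fingerprints a \code{FingerprintSet}.
#' @export
setClass("TanimotoOracle", contains = "DissimilarityOracle",
  representation(fingerprints = "FingerprintSet"))

#' @rdname DissimilarityOracle-class
#' @slot vectors a \code{VectorMatrix}.
#' @export
setClass("EuclideanOracle", contains = "DissimilarityOracle",
  representation(vectors = "VectorMatrix"))

#' WdudResult: property-based diversity evaluation of a selection
#'
#' Per-property Wasserstein distances to the uniform distribution (WDUD), in
#' the property's original units, plus the normalized per-property values
#' (properties min-max scaled to [0, 1]) and their arithmetic mean. Smaller
#' values mean property values more evenly spread over the pool's range,
#' i.e. a more diverse selection in the property-based sense.
#'
#' @slot perProperty named numeric vector, WDUD in original units.
#' @slot perPropertyNormalized named numeric vector, WDUD on [0,1]-scaled
#'   values.
#' @slot meanNormalized mean of the normalized values over non-degenerate
#'   properties.
#' @slot degenerate names of properties excluded as degenerate.
#' @export
setClass("WdudResult",
  representation(perProperty = "numeric", perPropertyNormalized = "numeric",
                 meanNormalized = "numeric", degenerate = "character"))

setValidity("WdudResult", function(object) {
  if (any(object@perProperty < 0) || any(object@perPropertyNormalized < 0))
    return("WDUD values must be non-negative")
  TRUE
})

## ---- constructors ----

#' Construct a MoleculeSet
#'
#' @param smiles character vector of SMILES strings (\code{NA} allowed).
#' @param ids optional ids; auto-generated as \code{mol_0001, ...} when
#'   missing.
#' @param report optional parse-report list.
#' @return a \code{MoleculeSet}.
#' @export
MoleculeSet <- function(smiles, ids = NULL, report = list()) {
  if (is.null(ids))
    ids <- sprintf("mol_%04d", seq_along(smiles))
  new("MoleculeSet", ids = as.character(ids), smiles = as.character(smiles),
      report = report)
}

#' Construct a VectorMatrix
#'
#' @param vectors numeric matrix with one descriptor vector per column.
#' @param normalized assert the non-negative unit-norm invariant.
#' @return a \code{VectorMatrix}.
#' @export
VectorMatrix <- function(vectors, normalized = FALSE) {
  storage.mode(vectors) <- "double"
  new("VectorMatrix", vectors = vectors, normalized = normalized)
}

#' Construct a PropertyTable
#'
#' @param values numeric matrix (candidates x properties) with column names.
#' @param ranges optional 2 x p range matrix; defaults to observed
#'   per-property min/max.
#' @return a \code{PropertyTable}.
#' @export
PropertyTable <- function(values, ranges = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ranges)) {
    ranges <- rbind(min = apply(values, 2L, min),
                    max = apply(values, 2L, max))
  } else {
    ranges <- as.matrix(ranges)
    rownames(ranges) <- c("min", "max")
  }
  degenerate <- ranges[1L, ] == ranges[2L, ]
  if (any(degenerate))
    warning("degenerate propert", if (sum(degenerate) > 1L) "ies: " else "y: ",
            paste(colnames(values)[degenerate], collapse = ", "),
            " (v_min = v_max)")
  new("PropertyTable", values = values, ranges = ranges,
      degenerate = unname(degenerate))
}

#' Construct a Selection
#'
#' @param indices ordered candidate indices (1-based).
#' @param gains per-step objective increments.
#' @param objective criterion label.
#' @param k requested size.
#' @return a \code{Selection}.
#' @export
Selection <- function(indices, gains, objective, k = length(indices)) {
  new("Selection", indices = as.integer(indices), gains = as.numeric(gains),
      objective = objective, k = as.integer(k))
}

#' Construct a Tanimoto dissimilarity oracle over fingerprints
#' @param fingerprints a \code{FingerprintSet}.
#' @return a \code{TanimotoOracle}.
#' @export
TanimotoOracle <- function(fingerprints) {
  new("TanimotoOracle", fingerprints = fingerprints)
}

#' Construct a Euclidean dissimilarity oracle over descriptor vectors
#' @param vectors a \code{VectorMatrix}.
#' @return a \code{EuclideanOracle}.
#' @export
EuclideanOracle <- function(vectors) {
  new("EuclideanOracle", vectors = vectors)
}

## ---- accessors ----

#' @describeIn MoleculeSet-class candidate ids in input order.
#' @param x object.
#' @export
molIds <- function(x) x@ids

#' @describeIn MoleculeSet-class SMILES strings in input order.
#' @export
molSmiles <- function(x) x@smiles

#' @describeIn MoleculeSet-class parse report recorded by the reader.
#' @export
parseReport <- function(x) x@report

#' @describeIn VectorMatrix-class the underlying m x n matrix.
#' @param x object.
#' @export
vectorData <- function(x) x@vectors

#' @describeIn VectorMatrix-class whether the non-negative unit-norm
#'   invariant is asserted.
#' @export
isNormalized <- function(x) x@normalized

#' @describeIn Selection-class selected candidate indices in order.
#' @param x object.
#' @export
selectedIndices <- function(x) x@indices

#' @describeIn Selection-class per-step gains/scores.
#' @export
stepGains <- function(x) x@gains

#' @describeIn Selection-class criterion label.
#' @export
objectiveName <- function(x) x@objective

#' @describeIn PropertyTable-class the n x p value matrix.
#' @param x object.
#' @export
propertyValues <- function(x) x@values

#' @describeIn PropertyTable-class property names.
#' @export
propertyNames <- function(x) colnames(x@values)

#' @describeIn PropertyTable-class the 2 x p range matrix.
#' @export
propertyRanges <- function(x) x@ranges

#' @describeIn WdudResult-class per-property WDUD in original units.
#' @param x object.
#' @export
wdudPerProperty <- function(x) x@perProperty

#' @describeIn WdudResult-class mean WDUD over [0,1]-normalized properties.
#' @export
wdudMeanNormalized <- function(x) x@meanNormalized

## ---- nCandidates methods ----

#' @rdname nCandidates
setMethod("nCandidates", "MoleculeSet", function(x) length(x@ids))
#' @rdname nCandidates
setMethod("nCandidates", "VectorMatrix", function(x) ncol(x@vectors))
#' @rdname nCandidates
setMethod("nCandidates", "FingerprintSet", function(x) length(x@bits))
#' @rdname nCandidates
setMethod("nCandidates", "PropertyTable", function(x) nrow(x@values))
#' @rdname nCandidates
setMethod("nCandidates", "TanimotoOracle",
          function(x) nCandidates(x@fingerprints))
#' @rdname nCandidates
setMethod("nCandidates", "EuclideanOracle",
          function(x) nCandidates(x@vectors))

#' @rdname MoleculeSet-class
setMethod("length", "MoleculeSet", function(x) length(x@ids))

## ---- show methods ----

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet with", length(object@ids), "molecules\n")
  n <- min(3L, length(object@ids))
  if (n > 0L)
    cat(paste0("  ", object@ids[seq_len(n)], ": ",
               object@smiles[seq_len(n)], collapse = "\n"), "\n")
  if (length(object@ids) > n) cat("  ...\n")
  if (length(object@report$rejected))
    cat("  (", length(object@report$rejected), "input line(s) rejected )\n")
})

setMethod("show", "VectorMatrix", function(object) {
  cat(sprintf("VectorMatrix: %d vectors of dimension %d%s\n",
              ncol(object@vectors), nrow(object@vectors),
              if (object@normalized) " (non-negative, unit-norm)" else ""))
})

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d x %s (%d bits%s)\n",
              length(object@bits), object@kind, object@nbits,
              if (!is.na(object@ecfpRadius))
                sprintf(", radius %d", object@ecfpRadius) else ""))
})

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection of %d candidate(s) by '%s'\n",
              length(object@indices), object@objective))
  n <- min(5L, length(object@indices))
  if (n > 0L)
    cat("  indices:", paste(object@indices[seq_len(n)], collapse = ", "),
        if (length(object@indices) > n) "..." else "", "\n")
})

setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable: %d molecules x %d properties (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
})

setMethod("show", "WdudResult", function(object) {
  cat("WDUD evaluation\n  per property (original units):\n")
  for (p in names(object@perProperty))
    cat(sprintf("    %-16s %.6g\n", p, object@perProperty[[p]]))
  cat(sprintf("  mean over [0,1]-normalized properties: %.6g\n",
              object@meanNormalized))
  if (length(object@degenerate))
    cat("  degenerate (excluded):",
        paste(object@degenerate, collapse = ", "), "\n")
})
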