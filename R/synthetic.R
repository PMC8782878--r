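#' Generate random non-negative unit descriptor vectors
#'
#' Draws n columns as the absolute value of standard Gaussians, scaled to
#' Euclidean norm 1 — points on the positive orthant of the unit sphere.
#' This emulates the statistical shape of embedding vectors produced by a
#' network whose final layers apply a ReLU and a unit-norm scaling, which is
#' the regime where the log-determinant objective reads diversity off
#' vector directions. Deterministic for a fixed seed.
#'
#' @param n number of candidates.
#' @param m vector dimension.
#' @param seed integer RNG seed.
#' @return a \code{\link{VectorMatrix}} with the normalized flag set.
#' @export
generateUnitVectors <- function(n, m, seed) {
  v <- .withSeed(seed, matrix(abs(stats::rnorm(m * n)), nrow = m))
  v <- sweep(v, 2L, sqrt(colSums(v^2)), `/`)
  VectorMatrix(v, normalized = TRUE)
}

#' Generate a clustered descriptor-vector instance
#'
#' Builds well-separated cluster centers on the positive orthant of the unit
#' sphere (each anchored, round-robin, on a coordinate axis with a small
#' positive jitter) and populates them with members: center plus Gaussian
#' noise, then ReLU + unit-norm. With \code{noiseScale = 0} members equal
#' their centers. Labels are returned so tests can assert cluster coverage
#' of a selector. Best separation is obtained with
#' \code{nClusters <= m} (one anchor axis per cluster).
#'
#' @param n number of candidates (assigned to clusters round-robin).
#' @param m vector dimension.
#' @param nClusters number of clusters, \code{<= n}.
#' @param noiseScale non-negative Gaussian noise scale around each center.
#' @param seed integer RNG seed.
#' @return list with \code{vectors} (a normalized \code{VectorMatrix}) and
#'   \code{labels} (integer cluster labels, one per candidate).
#' @export
generateClusteredInstance <- function(n, m, nClusters, noiseScale, seed) {
  if (nClusters > n) stop("nClusters must not exceed n")
  if (noiseScale < 0) stop("noiseScale must be non-negative")
  .withSeed(seed, {
    centers <- matrix(0, m, nClusters)
    for (c in seq_len(nClusters)) {
      axis <- (c - 1L) %% m + 1L
      v <- abs(stats::rnorm(m, 0, 0.15))
      v[axis] <- v[axis] + 3
      centers[, c] <- v / sqrt(sum(v^2))
    }
    labels <- rep(seq_len(nClusters), length.out = n)
    pts <- centers[, labels, drop = FALSE] +
      matrix(stats::rnorm(m * n, 0, noiseScale), m, n)
    pts <- pmax(pts, 0)
    nrm <- sqrt(colSums(pts^2))
    nrm[nrm == 0] <- 1
    pts <- sweep(pts, 2L, nrm, `/`)
    list(vectors = VectorMatrix(pts, normalized = TRUE), labels = labels)
  })
}

#' Generate properties linearly tied to vector direction
#'
#' Each property is a fixed random linear functional of the unit descriptor
#' vector plus Gaussian noise — the premise under which learned embeddings
#' predict properties through a final linear layer, so that property
#' information is carried by vector angles. Identical columns therefore get
#' identical property values at zero noise, and angularly spread selections
#' spread the property values.
#'
#' @param x a \code{\link{VectorMatrix}}.
#' @param p number of properties.
#' @param noiseScale Gaussian noise scale on each property value.
#' @param seed integer RNG seed.
#' @return a \code{\link{PropertyTable}} with ranges from the generated
#'   values, properties named \code{prop_1, ...}.
#' @export
generateProperties <- function(x, p, noiseScale, seed) {
  v <- vectorData(x)
  n <- ncol(v); m <- nrow(v)
  vals <- .withSeed(seed, {
    w <- matrix(stats::rnorm(m * p), m, p)
    crossprod(v, w) + matrix(stats::rnorm(n * p, 0, noiseScale), n, p)
  })
  colnames(vals) <- paste0("prop_", seq_len(p))
  PropertyTable(vals)
}

#' A small fixed list of molecules for fingerprint and counting tests
#'
#' Twenty small valid SMILES spanning alkanes, aromatics, alcohols, amines,
#' halides, a nitrile and carbonyl compounds; includes water and methane for
#' electron-count fixtures.
#'
#' @return a \code{\link{MoleculeSet}}.
#' @export
toySmiles <- function() {
  MoleculeSet(c(
    "O",            # water
    "C",            # methane
    "CC",           # ethane
    "CCC",          # propane
    "CCCC",         # butane
    "CCO",          # ethanol
    "CC(C)O",       # isopropanol
    "CO",           # methanol
    "c1ccccc1",     # benzene
    "Cc1ccccc1",    # toluene
    "c1ccncc1",     # pyridine
    "C1CCCCC1",     # cyclohexane
    "CCN",          # ethylamine
    "CN(C)C",       # trimethylamine
    "CCCl",         # chloroethane
    "CCBr",         # bromoethane
    "CC(=O)O",      # acetic acid
    "CC(=O)C",      # acetone
    "C=C",          # ethene
    "CC#N"          # acetonitrile
  ))
}

#' Write a synthetic fixture set to disk
#'
#' Emits a matched trio of files in the package's standard formats: a
#' `.smi` candidate list (the toy molecules, recycled to n), a
#' descriptor-vector CSV (one molecule per row) and a property CSV —
#' everything needed to exercise the selectors and criteria end to end
#' without any dataset download. Byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param n,m,nClusters,p,seed see the individual generators.
#' @param noiseScale noise for both the vectors and the properties.
#' @return invisibly, the list of written paths.
#' @export
writeSyntheticFixtures <- function(dir, n = 50L, m = 8L, nClusters = 4L,
                                   p = 2L, noiseScale = 0.05, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inst <- generateClusteredInstance(n, m, nClusters, noiseScale, seed)
  props <- generateProperties(inst$vectors, p, noiseScale, seed + 1L)
  toy <- molSmiles(toySmiles())
  smi <- rep(toy, length.out = n)
  ids <- sprintf("mol_%04d", seq_len(n))
  paths <- list(
    smiles = file.path(dir, "candidates.smi"),
    vectors = file.path(dir, "vectors.csv"),
    properties = file.path(dir, "properties.csv"),
    labels = file.path(dir, "cluster_labels.csv"))
  writeLines(paste(smi, ids, sep = "\t"), paths$smiles)
  writeVectorMatrix(inst$vectors, paths$vectors)
  pv <- propertyValues(props)
  writeLines(c(paste(colnames(pv), collapse = ","),
               apply(pv, 1L, function(r)
                 paste(formatC(r, digits = 17L, format = "g"),
                       collapse = ","))),
             paths$properties)
  writeLines(c("cluster", as.character(inst$labels)), paths$labels)
  invisible(paths)
}
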