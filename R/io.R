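#' Read a SMILES list
#'
#' Reads a `.smi`-style file with one molecule per non-empty line, either
#' `SMILES` alone or `SMILES<tab>ID`. Each SMILES is parsed with OpenBabel;
#' lines the toolkit rejects are skipped with a warning and recorded in the
#' parse report (note OpenBabel's sanitization is lenient, e.g. an unclosed
#' branch is auto-closed rather than rejected). Missing ids are auto-generated
#' as `mol_0001, ...` over the accepted records.
#'
#' @param path file path.
#' @return a \code{\link{MoleculeSet}} in file order; \code{parseReport()}
#'   lists rejected line numbers and their content.
#' @export
readSmilesList <- function(path) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (!length(lines)) stop("no molecules: ", path, " contains no data lines")

  parts <- strsplit(lines, "\t")
  smi <- vapply(parts, `[[`, character(1L), 1L)
  id <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else
    NA_character_, character(1L))

  ok <- vapply(smi, .smilesParses, logical(1L))
  if (!any(ok))
    stop("no molecules: every line of ", path, " failed to parse")
  rejected <- data.frame(line = lineno[!ok], smiles = smi[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("skipped %d unparseable SMILES line(s): %s",
                    nrow(rejected),
                    paste(rejected$line, collapse = ", ")))
  smi <- smi[ok]; id <- id[ok]
  if (all(is.na(id))) {
    id <- sprintf("mol_%04d", seq_along(smi))
  } else if (anyNA(id)) {
    id[is.na(id)] <- sprintf("mol_%04d", which(is.na(id)))
  }
  MoleculeSet(smiles = smi, ids = id,
              report = list(rejected = rejected, nInput = length(lineno)))
}

# TRUE when OpenBabel can read the SMILES string
.smilesParses <- function(smiles) {
  !inherits(tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) TRUE),
    error = function(e) e), "error")
}

#' Read a descriptor-vector matrix from delimited text
#'
#' Reads a CSV/TSV/whitespace-delimited numeric matrix. By the common export
#' convention each ROW is one molecule (`orientation = "rows"`); set
#' `orientation = "columns"` when vectors are stored column-wise. Either way
#' the result stores molecules as columns. A header line of non-numeric
#' labels is detected and skipped.
#'
#' @param path file path.
#' @param orientation `"rows"` (default) or `"columns"`.
#' @return a \code{\link{VectorMatrix}} with the normalized flag unset.
#' @export
readVectorMatrix <- function(path, orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  raw <- .readDelimMatrix(path)
  m <- if (orientation == "rows") t(raw) else raw
  VectorMatrix(unname(m), normalized = FALSE)
}

#' Write a descriptor-vector matrix
#'
#' Inverse of \code{\link{readVectorMatrix}}: one molecule per row, comma
#' separated, 17 significant digits so a read-back round-trip reproduces the
#' values exactly.
#'
#' @param x a \code{VectorMatrix}.
#' @param path output path.
#' @export
writeVectorMatrix <- function(x, path) {
  m <- t(vectorData(x))
  lines <- apply(m, 1L, function(r)
    paste(formatC(r, digits = 17L, format = "g"), collapse = ","))
  writeLines(lines, path)
}

.readDelimMatrix <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "[\t ]+"
  cells <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1L]])
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  startRow <- 1L
  if (anyNA(first) && length(cells) > 1L) startRow <- 2L  # header line
  cells <- cells[startRow:length(cells)]
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows: row %d has %d cells, expected %d",
                 which(ncols != ncols[1L])[1L] + startRow - 1L,
                 ncols[which(ncols != ncols[1L])[1L]], ncols[1L]))
  out <- matrix(NA_real_, nrow = length(cells), ncol = ncols[1L])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite cell at row %d, column %d: '%s'",
                   i + startRow - 1L, bad[1L], cells[[i]][bad[1L]]))
    out[i, ] <- v
  }
  out
}

#' Read a property table
#'
#' Reads delimited text with a header row of property names and a numeric
#' body, one molecule per row. Per-property ranges \code{[v_min, v_max]} are
#' computed as the observed column min/max; constant columns are flagged
#' degenerate (with a warning) since their uniform reference distribution
#' collapses to a point mass.
#'
#' @param path file path.
#' @return a \code{\link{PropertyTable}}.
#' @export
readPropertyTable <- function(path) {
  if (!file.exists(path)) stop("cannot read property table: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate property names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop(sprintf("non-numeric cell in property column '%s'", names(df)[j]))
  }
  PropertyTable(as.matrix(df))
}

#' Write a selection to JSON
#'
#' Serializes a \code{\link{Selection}} as a JSON document with one entry per
#' selected molecule (rank, 1-based candidate index, id, SMILES, per-step
#' gain) plus run metadata. Round-trips exactly through
#' \code{\link{readSelection}}.
#'
#' @param sel a \code{Selection}.
#' @param mols optional \code{MoleculeSet} aligned with the candidate list;
#'   supplies ids and SMILES.
#' @param path output path.
#' @param metadata named list of run metadata (seed, parameters, ...).
#' @export
writeSelection <- function(sel, path, mols = NULL, metadata = list()) {
  idx <- selectedIndices(sel)
  if (!is.null(mols) && length(idx) && max(idx) > length(mols))
    stop("selection indices exceed the molecule list")
  entries <- lapply(seq_along(idx), function(r) {
    e <- list(rank = r, index = idx[[r]], gain = stepGains(sel)[[r]])
    if (!is.null(mols)) {
      e$id <- molIds(mols)[[idx[[r]]]]
      e$smiles <- molSmiles(mols)[[idx[[r]]]]
    }
    e
  })
  doc <- c(list(objective = objectiveName(sel), k = sel@k), metadata,
           list(selection = entries))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a selection back from JSON
#'
#' @param path path written by \code{\link{writeSelection}}.
#' @return a \code{\link{Selection}}.
#' @export
readSelection <- function(path) {
  doc <- jsonlite::read_json(path)
  idx <- vapply(doc$selection, function(e) as.integer(e$index), integer(1L))
  gains <- vapply(doc$selection, function(e)
    if (is.null(e$gain)) NA_real_ else as.numeric(e$gain), numeric(1L))
  Selection(indices = idx, gains = gains, objective = doc$objective,
            k = as.integer(doc$k))
}
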