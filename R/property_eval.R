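#' Mean pairwise dissimilarity (MPD) of a selection
#'
#' The standard structure-based diversity criterion: the mean of
#' \eqn{d_{i,j}} over all unordered pairs within the selected set,
#' \deqn{\frac{1}{\binom{|S|}{2}} \sum_{i<j} d_{i,j}.}
#' Lies in [0, 1] for Tanimoto oracles. MPD is an evaluation criterion here,
#' never an optimization target (MaxSum greedily grows it; see
#' \code{\link{maxsumSelect}}).
#'
#' @param oracle a \code{\link{DissimilarityOracle}}.
#' @param S integer vector of at least two selected candidate indices, or a
#'   \code{\link{Selection}}.
#' @return the mean pairwise dissimilarity.
#' @export
mpd <- function(oracle, S) {
  if (is(S, "Selection")) S <- selectedIndices(S)
  S <- as.integer(S)
  if (length(S) < 2L)
    stop("MPD is undefined for fewer than 2 selected molecules")
  tot <- 0
  for (a in seq_len(length(S) - 1L))
    tot <- tot + sum(.dissimRow(oracle, S[a], S[(a + 1L):length(S)]))
  tot / choose(length(S), 2L)
}

# atomic numbers by element symbol
.ATOMIC_NUMBER <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58,
  Pr = 59, Nd = 60, Pm = 61, Sm = 62, Eu = 63, Gd = 64, Tb = 65, Dy = 66,
  Ho = 67, Er = 68, Tm = 69, Yb = 70, Lu = 71, Hf = 72, Ta = 73, W = 74,
  Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82,
  Bi = 83, Po = 84, At = 85, Rn = 86, Fr = 87, Ra = 88, Ac = 89, Th = 90,
  Pa = 91, U = 92, Np = 93, Pu = 94)

# molecular formulas (with implicit hydrogens and a trailing charge token)
# for each molecule, via OpenBabel
.obFormulas <- function(mols) {
  smi <- molSmiles(mols)
  if (anyNA(smi))
    stop("record(s) without SMILES: ",
         paste(molIds(mols)[is.na(smi)], collapse = ", "))
  props <- ChemmineOB::forEachMol("SMILES", paste(smi, collapse = "\n"),
    function(m) ChemmineOB::prop_OB(list(m)))
  vapply(props, function(p) p$formula, character(1L))
}

# parse "C2H6O", "HO-", "H4N+" ... -> list(atoms, nuclearCharge, charge)
.parseFormula <- function(f) {
  charge <- 0L
  m <- regmatches(f, regexec("([+-])([0-9]*)$", f))[[1L]]
  if (length(m)) {
    mag <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    charge <- if (m[2L] == "+") mag else -mag
    f <- sub("([+-])([0-9]*)$", "", f)
  }
  toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1L]]
  if (!length(toks) || paste(toks, collapse = "") != f)
    stop("cannot parse molecular formula: ", f)
  atoms <- 0L; z <- 0L
  for (tk in toks) {
    sym <- sub("[0-9]*$", "", tk)
    cnt <- sub("^[A-Za-z]+", "", tk)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(.ATOMIC_NUMBER))
      stop("unknown element '", sym, "' in formula ", f)
    atoms <- atoms + cnt
    z <- z + cnt * .ATOMIC_NUMBER[[sym]]
  }
  list(atoms = atoms, nuclearCharge = z, charge = charge)
}

#' Count electrons per molecule
#'
#' The electron count is the sum of atomic numbers over all atoms (implicit
#' hydrogens included) minus the net formal charge — water and methane both
#' have 10, hydroxide has 9 - (-1) = 10. Isotopes do not change the count,
#' and radicals are counted by electrons present, not by pairing. Used as
#' the \eqn{N_{elec}} divisor that weakens the system-size dependence of
#' energetic properties (U0, U, H, G) before diversity evaluation.
#'
#' @param mols a \code{\link{MoleculeSet}} with valid SMILES.
#' @return integer vector, one count per molecule.
#' @export
countElectrons <- function(mols) {
  parsed <- lapply(.obFormulas(mols), .parseFormula)
  out <- vapply(parsed, function(p)
    as.integer(p$nuclearCharge - p$charge), integer(1L))
  if (any(out < 1L)) stop("non-positive electron count")
  names(out) <- molIds(mols)
  out
}

#' Count vibrational modes per molecule
#'
#' Returns \eqn{N_{mode} = 3 N_{atom} - 6} with \eqn{N_{atom}} the total
#' atom count including implicit hydrogens. The 3N - 6 formula is applied
#' uniformly — including to linear molecules, where 3N - 5 would be the
#' physically correct mode count; the uniform rule is the documented
#' convention of this divisor. Molecules with fewer than 3 atoms would get a
#' non-positive count and are refused: pick a different divisor for
#' diatomics.
#'
#' @param mols a \code{\link{MoleculeSet}} with valid SMILES.
#' @return integer vector, one count per molecule.
#' @export
countModes <- function(mols) {
  parsed <- lapply(.obFormulas(mols), .parseFormula)
  atoms <- vapply(parsed, function(p) as.integer(p$atoms), integer(1L))
  bad <- atoms < 3L
  if (any(bad))
    stop("3N - 6 is non-positive for molecule(s) with fewer than 3 atoms: ",
         paste(molIds(mols)[bad], collapse = ", "))
  out <- 3L * atoms - 6L
  names(out) <- molIds(mols)
  out
}

#' Derive system-size-corrected property columns
#'
#' Adds columns obtained by dividing a base property by a per-molecule
#' divisor: the electron count (\code{"nelec"}), the 3N - 6 vibrational mode
#' count (\code{"nmode"}), or nothing (\code{"none"}, a plain copy). Typical
#' use: energies U0, U, H, G divided by N_elec and ZPVE, Cv divided by
#' N_mode, so that diversity evaluation reflects chemistry rather than
#' molecule size. Ranges of the derived columns are recomputed from the new
#' values, never inherited.
#'
#' @param table a \code{\link{PropertyTable}}.
#' @param mols a \code{\link{MoleculeSet}} aligned row-for-row with the
#'   table.
#' @param specs data frame (or list coercible to one) with columns
#'   \code{base} and \code{divisor} (\code{"nelec"}, \code{"nmode"} or
#'   \code{"none"}).
#' @return a new \code{\link{PropertyTable}} containing the original columns
#'   plus the derived ones, named \code{<base>/N_elec}, \code{<base>/N_mode}
#'   or \code{<base>} (for \code{"none"}, replacing nothing — the copy keeps
#'   its base name only if absent, otherwise it is skipped).
#' @export
deriveProperties <- function(table, mols, specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  stopifnot(all(c("base", "divisor") %in% names(specs)))
  vals <- propertyValues(table)
  if (length(mols) != nrow(vals))
    stop("molecule list and property table sizes differ")
  need <- setdiff(specs$base, colnames(vals))
  if (length(need))
    stop("unknown base propert", if (length(need) > 1) "ies: " else "y: ",
         paste(need, collapse = ", "))
  nelec <- NULL; nmode <- NULL
  newCols <- list()
  for (r in seq_len(nrow(specs))) {
    base <- specs$base[r]
    div <- match.arg(specs$divisor[r], c("nelec", "nmode", "none"))
    col <- vals[, base]
    if (div == "nelec") {
      if (is.null(nelec)) nelec <- countElectrons(mols)
      newCols[[paste0(base, "/N_elec")]] <- col / nelec
    } else if (div == "nmode") {
      if (is.null(nmode)) nmode <- countModes(mols)
      newCols[[paste0(base, "/N_mode")]] <- col / nmode
    } else {
      if (!base %in% names(newCols)) newCols[[base]] <- col
    }
  }
  newCols <- newCols[setdiff(names(newCols), colnames(vals))]
  out <- cbind(vals, do.call(cbind, newCols))
  rownames(out) <- NULL
  PropertyTable(out)
}
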