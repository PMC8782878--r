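#' Wasserstein distance to the uniform distribution (WDUD)
#'
#' Measures how evenly k property values spread over the pool's property
#' range: assign mass 1/k to each value \eqn{y_i} and compute the
#' 1-Wasserstein distance between this empirical distribution and the
#' uniform distribution on \eqn{[v_{min}, v_{max}]},
#' \deqn{\int_{v_{min}}^{v_{max}} |U(x) - V(x)| \, dx,}
#' with U the uniform CDF and V the empirical CDF. Smaller values mean more
#' evenly distributed (more property-diverse) selections; the minimum over
#' all k-point sets is \eqn{(v_{max}-v_{min})/(4k)}, attained at the
#' quantile midpoints \eqn{v_{min} + (2i-1)(v_{max}-v_{min})/(2k)}.
#'
#' The integral is evaluated exactly: \eqn{[v_{min}, v_{max}]} is split at
#' the sorted values, and within each piece (where V is constant and U
#' linear) the area of \eqn{|U - V|} is the trapezoid/two-triangle closed
#' form, splitting additionally at the U-V crossing point. No numerical
#' quadrature is involved, so results are bit-reproducible.
#'
#' @param values numeric vector of k >= 1 selected property values.
#' @param vmin,vmax the pool's property range, \code{vmin <= vmax}.
#' @param clip values outside \code{[vmin, vmax]} are fatal by default
#'   (they cannot arise when the range comes from the same pool); with
#'   \code{clip = TRUE} they are clipped with a warning, for user-supplied
#'   narrower ranges.
#' @return a non-negative numeric value, in the property's units.
#' @export
wdud <- function(values, vmin, vmax, clip = FALSE) {
  k <- length(values)
  if (k < 1L) stop("values must be nonempty")
  if (!is.finite(vmin) || !is.finite(vmax) || vmin > vmax)
    stop("invalid range: need finite vmin <= vmax")
  if (vmin == vmax) return(0)  # degenerate range: point-mass target
  out <- values < vmin | values > vmax
  if (any(out)) {
    if (!clip)
      stop("property value(s) outside [vmin, vmax]; pass clip = TRUE ",
           "if the supplied range is intentionally narrower")
    warning(sprintf("clipped %d value(s) into [%g, %g]", sum(out), vmin, vmax))
    values <- pmin(pmax(values, vmin), vmax)
  }
  R <- vmax - vmin
  breaks <- c(vmin, sort(values), vmax)
  total <- 0
  for (t in seq_len(k + 1L)) {
    a <- breaks[t]; b <- breaks[t + 1L]
    if (b <= a) next
    cc <- (t - 1) / k                        # V level on (a, b)
    ga <- (a - vmin) / R - cc                # U - V at the endpoints
    gb <- (b - vmin) / R - cc
    if (ga * gb < 0) {
      x0 <- vmin + cc * R                    # crossing point
      total <- total + abs(ga) * (x0 - a) / 2 + abs(gb) * (b - x0) / 2
    } else {
      total <- total + (abs(ga) + abs(gb)) * (b - a) / 2
    }
  }
  total
}

#' Mean WDUD of a selection over a property table
#'
#' Evaluates WDUD for every property of a \code{\link{PropertyTable}}
#' restricted to the selected candidates. Each property is min-max scaled to
#' [0, 1] by its stored range before the dimensionless mean is taken;
#' per-property values are also reported in original units (WDUD scales
#' linearly under affine maps of the property axis). Degenerate properties
#' (v_min = v_max) contribute 0, are excluded from the mean, and are listed
#' in the result.
#'
#' @param table a \code{\link{PropertyTable}} over the full candidate pool.
#' @param S nonempty integer vector of selected candidate indices, or a
#'   \code{\link{Selection}}.
#' @return a \code{\link{WdudResult}}.
#' @export
meanWdud <- function(table, S) {
  if (is(S, "Selection")) S <- selectedIndices(S)
  S <- as.integer(S)
  if (!length(S)) stop("S must be nonempty")
  vals <- propertyValues(table)
  if (min(S) < 1L || max(S) > nrow(vals)) stop("index out of range")
  rng <- propertyRanges(table)
  p <- ncol(vals)
  perNorm <- numeric(p)
  perOrig <- numeric(p)
  for (j in seq_len(p)) {
    lo <- rng[1L, j]; hi <- rng[2L, j]
    if (table@degenerate[j]) { perNorm[j] <- 0; perOrig[j] <- 0; next }
    scaled <- (vals[S, j] - lo) / (hi - lo)
    perNorm[j] <- wdud(scaled, 0, 1)
    perOrig[j] <- perNorm[j] * (hi - lo)
  }
  names(perNorm) <- names(perOrig) <- colnames(vals)
  keep <- !table@degenerate
  new("WdudResult", perProperty = perOrig, perPropertyNormalized = perNorm,
      meanNormalized = if (any(keep)) mean(perNorm[keep]) else 0,
      degenerate = colnames(vals)[!keep])
}

#' Wasserstein-greedy (WG) selection
#'
#' Property-based benchmark selector that greedily drives down the mean
#' WDUD over [0,1]-normalized properties: step t adds the candidate whose
#' inclusion yields the smallest mean WDUD of the enlarged set. The first
#' step — where no decrease from the empty set is defined — picks the
#' candidate minimizing the 1-point mean WDUD. Ties go to the lowest index.
#' Gains record the achieved decrease in mean WDUD (previous minus new); the
#' first gain is the negated 1-point value.
#'
#' @param table a \code{\link{PropertyTable}} over the candidate pool;
#'   normalization uses the table's stored (pool-wide) ranges.
#' @param k number of molecules to select, \code{1 <= k <= n}.
#' @return a \code{\link{Selection}}.
#' @export
wgSelect <- function(table, k) {
  vals <- propertyValues(table)
  n <- nrow(vals)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d candidates", k, n))
  rng <- propertyRanges(table)
  keep <- which(!table@degenerate)
  if (!length(keep))
    stop("every property is degenerate; mean WDUD is undefined")
  scaled <- vapply(keep, function(j)
    (vals[, j] - rng[1L, j]) / (rng[2L, j] - rng[1L, j]), numeric(n))
  scaled <- matrix(scaled, nrow = n)

  sel <- integer(k)
  gains <- numeric(k)
  avail <- rep(TRUE, n)
  prev <- NA_real_
  for (t in seq_len(k)) {
    best <- Inf; bestJ <- NA_integer_
    for (i in which(avail)) {
      idx <- c(sel[seq_len(t - 1L)], i)
      m <- mean(vapply(seq_len(ncol(scaled)),
                       function(j) wdud(scaled[idx, j], 0, 1), numeric(1L)))
      if (m < best - 1e-15) { best <- m; bestJ <- i }
    }
    sel[t] <- bestJ
    gains[t] <- if (t == 1L) -best else prev - best
    prev <- best
    avail[bestJ] <- FALSE
  }
  Selection(sel, gains, "wg", k = k)
}
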