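---
title: "Diverse molecule selection with the log-determinant objective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diverse molecule selection with the log-determinant objective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divpick)
```

## The problem

Compound acquisition, reaction screening and library design all start from
the same question: given a long list of candidate molecules, which small
subset covers the most chemical ground? Classical pickers answer it
structurally — maximize pairwise fingerprint dissimilarity — but a set of
molecules can be structurally varied yet hug a narrow band of property
values. `divpick` implements a selection method and an evaluation criterion
that take the property view seriously, alongside the structural standards,
so both views can be computed and compared on the same candidate list.

## The log-determinant objective and its greedy maximizer

Each candidate $i$ carries an $m$-dimensional descriptor vector $x_i$
(typically an embedding exported from a property-prediction network);
$X = [x_1\ \dots\ x_n]$ collects them as columns. For a subset
$S \subseteq \{1,\dots,n\}$ the diversity objective is

$$f(S) = \log\det\!\big(X[S]^\top X[S] + I_{|S|}\big),$$

where $X[S]$ keeps the columns in $S$. Adding the identity makes the matrix
positive definite regardless of rank, so $f(\emptyset) = 0$ and $f \ge 0$
always. The function equals the log of the squared volume of the
parallelotope spanned by the identity-augmented vectors
$\tilde{x}_i = (x_i, e_i)$ — `augmentedGramLogdet()` verifies this identity
and the test suite asserts it on random instances — so $f$ rewards sets of
vectors pointing in genuinely different directions and penalizes
near-duplicates: two orthonormal columns score $2\log 2$, a duplicated unit
column only $\log 3$.

$f$ is monotone and submodular (adding a molecule to a smaller set helps at
least as much as adding it to a larger one). `greedyLogdet()` therefore
starts from the empty set and repeatedly adds the candidate with the
largest marginal gain; for monotone submodular objectives with
$f(\emptyset)=0$ this greedy selection is guaranteed at least a
$1 - 1/e \approx 63\%$ fraction of the optimal $k$-subset value, and on
random instances it is typically far closer (the acceptance checks
enumerate all $\binom{12}{4}$ subsets on 50 instances and observe worst
cases above 90%).

### Why ReLU + unit normalization

The volume reading of $f$ behaves badly on raw embeddings for two reasons.
Nearly origin-symmetric vectors ($x$ and $-x$) are directionally opposite
yet span a thin parallelotope, so sign structure corrupts the diversity
signal; clipping at zero (ReLU) removes it. And if norms vary, $f$ can
prefer a few long vectors over many well-spread short ones; scaling every
column to unit norm makes the objective purely angular.
`reluNormalize()` applies both steps to supplied vectors. When the
embedding network was itself trained with these output layers the transform
is the identity; applied post hoc to arbitrary exported vectors it is an
approximation of that training-time setup, which is the honest reading of
what this package can do for vectors it did not train. A column that is
entirely non-positive collapses to the zero vector; it is reported rather
than rejected, and since its marginal gain is $\log(1+0)=0$ it is never
picked ahead of any non-zero column.

### The fast greedy implementation

Re-evaluating $f(S \cup \{i\})$ from scratch for every candidate at every
step costs a Cholesky factorization per evaluation. Instead the selector
maintains the Cholesky factor $L$ of $X[S]^\top X[S] + I$ and, for every
candidate, the squared residual $r_i = 1 + \|x_i\|^2 - \|L^{-1}X[S]^\top
x_i\|^2$, updated by one rank-one step per iteration; the marginal gain is
exactly $\log r_i$ by the bordering (Schur-complement) determinant
identity. The contract is behavioural: the test suite replays the fast
selector against a full-refactorization greedy on over a hundred random
instances and requires identical index sequences and gains agreeing to
1e-8 relative.

Numerical choices worth stating:

* **Tie rule.** Gains within 1e-12 (absolute) of the step maximum are
  treated as tied and the lowest candidate index wins. This matters on
  unit-norm instances, where the first step is an exact $\log 2$ tie across
  all candidates and floating-point noise would otherwise pick an
  effectively random index. A consequence: selection is permutation
  equivariant exactly on tie-free instances, and only up to the tie rule
  otherwise.
* **Conditioning guard.** Gains are mathematically non-negative; values in
  $[-10^{-9}, 0)$ are clamped to zero, anything lower aborts with a
  conditioning error rather than silently continuing.
* **No regularization knob.** The identity offset is part of the
  objective's definition, not a tunable parameter.
* **k > n** selects all n with a warning, so pipelines compose without
  special-casing short candidate lists.

## WDUD: the property-based diversity criterion

For one property with pool range $[v_{\min}, v_{\max}]$ and selected values
$y_1,\dots,y_k$, place mass $1/k$ on each $y_i$ and measure the
1-Wasserstein distance to the uniform distribution on the range:

$$\mathrm{WDUD} = \int_{v_{\min}}^{v_{\max}} |U(x) - V(x)|\,dx,$$

with $U$ the uniform CDF and $V$ the empirical CDF. Small WDUD means the
selected property values are evenly spread over the pool's range — the
property-based notion of a diverse selection. Unlike variance (maximized by
piling onto the two extremes) or KL divergence (blind to *where* mass is
missing), the Wasserstein distance rewards even coverage.

`wdud()` evaluates the integral exactly: the range is split at the sorted
values, and each piece — $V$ constant, $U$ linear — contributes a
trapezoid, split once more at the $U$–$V$ crossing point when the sign
changes. The closed form is bit-reproducible; a fine-grid trapezoid
quadrature is kept in the test helpers purely as an independent oracle.
Useful exact facts, all asserted in the tests: a single value at the
midpoint gives $1/4$ of the range width; the quantile midpoints
$(2i-1)/(2k)$ achieve the optimum $1/(4k)$; WDUD scales linearly under
affine maps of the property axis.

`meanWdud()` aggregates across properties by min-max scaling each to
$[0,1]$ with the *pool-wide* range (the reading most consistent with
normalizing "the property values": ranges describe the candidate list, not
the selection) and averaging. Degenerate properties ($v_{\min} = v_{\max}$)
have a point-mass target; their WDUD is defined as 0 and they are excluded
from the mean with a warning. Values outside a stored range are fatal by
default — impossible when ranges come from the same table — and clipped
with a warning only when the caller passes deliberately narrower ranges.

### The Wasserstein-greedy benchmark

`wgSelect()` greedily minimizes mean WDUD: step $t$ adds the candidate
whose inclusion yields the smallest mean WDUD of the enlarged set. Exact
minimization reduces to mixed-integer programming and is out of scope;
greedy is the benchmark. The first step has no defined "decrease from the
empty set", so the selector picks the candidate minimizing the 1-point
WDUD — the natural reading, flagged as an interpretation. Ties again go to
the lowest index; in tie-heavy pools a different ordering convention would
give different (equally valid) selections.

## Structural baselines and criteria

`maxminSelect()` and `maxsumSelect()` implement the classical pickers over
any `DissimilarityOracle`: both seed at the candidate with the largest
total dissimilarity $\sum_{j \ne i} d_{i,j}$, then add
$\arg\max_i \min_{j \in S} d_{i,j}$ (MaxMin) or
$\arg\max_i \sum_{j \in S} d_{i,j}$ (MaxSum). At $k=2$ the two coincide.
`randomSelect()` samples uniformly without replacement — sampling the
candidate list uniformly *is* sampling its empirical distribution.

Dissimilarities come either from Euclidean distance between descriptor
vectors or from Tanimoto dissimilarity $1 - |A \cap B|/|A \cup B|$ of
MACCS keys or ECFP. Fingerprints are computed with OpenBabel: MACCS is the
toolkit's 166-key dictionary; ECFP is emitted at diameter $2r$ and 4096
bits and OR-folded to the requested length (default radius 2, 2048 bits —
the conventional ECFP4 setting; both are overridable). Two empty
fingerprints are given dissimilarity 1 (similarity 0, the common toolkit
convention) — documented prominently because it affects MaxMin/MaxSum
ordering on featureless molecules — while $d(i,i) = 0$ always holds.

`mpd()` is the structural evaluation criterion: the mean of $d_{i,j}$ over
all unordered pairs of the selection. It is never an optimization target
here (MaxSum greedily grows it).

## Derived properties against system-size dependence

Total energies scale with molecule size, so their raw WDUD mostly measures
size diversity. `deriveProperties()` divides energetic properties by the
electron count $N_{\mathrm{elec}}$ (sum of atomic numbers including
implicit hydrogens, minus net formal charge — counting electrons present,
so isotopes and radical pairing are irrelevant) and vibrational properties
by $N_{\mathrm{mode}} = 3N_{\mathrm{atom}} - 6$. The $3N-6$ formula is
applied uniformly, including to linear molecules where $3N-5$ is the
physically correct count — the divisor is a documented convention, not a
spectroscopic claim — and molecules with fewer than three atoms are
refused rather than given a non-positive divisor. Hydrogens are included
in the atom count, matching how quantum-chemistry datasets store
geometries. Derived columns get freshly computed ranges.

## What the synthetic generators emulate — and what they do not

The test bed never downloads a dataset. `generateUnitVectors()` draws
columns as $|\mathcal{N}(0,1)|$ scaled to unit norm — the statistical shape
of ReLU-then-normalized embeddings (non-negative, unit-length, spread over
the positive orthant). The Gaussian-absolute-value construction was chosen
over a Dirichlet-square-root alternative as the simpler, parameter-free
option. `generateClusteredInstance()` anchors well-separated centers on
coordinate axes (round-robin, with a small positive jitter; separation is
best with no more clusters than dimensions) and perturbs members with
Gaussian noise before re-applying ReLU + normalization.
`generateProperties()` makes each property a fixed random linear functional
of the unit vector plus noise — properties carried by vector *angles*,
which is precisely the premise under which embeddings trained through a
final linear layer encode properties.

What passing tests on these fixtures shows: the selectors, criteria and
their interplay behave as the mathematics says they must (greedy
guarantee, cluster coverage, lower WDUD than random on angle-linear
properties). What they do not show: that any particular trained network
produces embeddings whose angles track real chemical properties — that is
a property of the upstream model, not of this package.

### Problem sizes in the shipped checks

The acceptance checks solve 50 instances with $n=12$, $m=8$, $k=4$
exhaustively ($\binom{12}{4} = 495$ subsets each), replay fast-vs-naive
greedy on 100 instances with $n \le 12$, run the quadrature cross-check at
$10^6$ grid points on 100 random inputs, and use a 60-candidate,
4-cluster pool for the selector comparison. These sizes were chosen so
that the exhaustive oracles stay exact; the implementation itself handles
thousands of candidates comfortably (the greedy step is linear in $n$ at
fixed $|S|$, and the pairwise-matrix materialization is guarded by an
explicit size limit).

## Conventions and known limitations

* Indices are 1-based everywhere, including the JSON artifacts — the
  native convention of this language and its ecosystem.
* SMILES validity is whatever OpenBabel's default sanitization accepts,
  which is lenient (an unclosed branch is auto-closed, not rejected).
  Rejected lines are skipped with a warning and recorded in the parse
  report; when that happens, vector and property rows must be re-aligned
  by id — a size mismatch between inputs is fatal, never silently
  re-indexed by position.
* MACCS here is OpenBabel's 166-key set; other toolkits number 167 keys
  with an unused key 0. Fingerprints are reproducible bit-for-bit only
  within a toolkit version.
* The WG selector's first step and all tie rules are repository
  conventions where the method definitions are silent; tie-heavy pools may
  legitimately differ between implementations.
* `wdud()` with user-supplied ranges narrower than the data clips values
  (with a warning); that path never arises when ranges come from the pool
  itself.
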