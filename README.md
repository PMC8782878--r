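# divpick

Diverse molecule selection by log-determinant submodular maximization,
with property-based (WDUD) and structure-based (MPD) diversity evaluation.

## The problem

Screening campaigns, compound acquisition and reaction discovery all need a
small subset of molecules that covers as much chemical ground as possible.
The classical pickers (MaxMin, MaxSum over fingerprint Tanimoto
dissimilarity) optimize structural spread, but structurally varied sets can
still cluster in a narrow band of property values. `divpick` is for
cheminformaticians who want both views on the same candidate list: a
selector that works on learned descriptor vectors, the classical
structural baselines, and criteria that score a selection from either
side.

## The method

Each candidate `i` carries a descriptor vector `x_i` (e.g. an embedding
from a property-prediction network), collected as the columns of an
`m x n` matrix `X`. A subset `S` is scored by the monotone submodular
log-determinant function

    f(S) = log det( X[S]' X[S] + I )

which equals the log squared volume of the parallelotope spanned by the
identity-augmented vectors: near-duplicate directions add almost nothing,
orthogonal directions add the most. `greedyLogdet()` maximizes it greedily
with incremental Cholesky updates; the greedy value is guaranteed at least
`1 - 1/e ≈ 63%` of the optimal k-subset value and is typically much
closer. Vectors are first passed through ReLU + unit normalization
(`reluNormalize()`) so the objective reads diversity purely off vector
directions.

A selection is evaluated with:

* **WDUD** (`wdud()`, `meanWdud()`) — the Wasserstein distance between the
  empirical distribution of selected property values and the uniform
  distribution over the pool's property range, `∫|U − V| dx`, computed in
  exact closed form. Smaller = property values more evenly spread.
* **MPD** (`mpd()`) — mean pairwise Tanimoto dissimilarity of MACCS keys
  or ECFP (via OpenBabel), the standard structural criterion.

Baselines: `maxminSelect()`, `maxsumSelect()`, `randomSelect()`, and the
Wasserstein-greedy benchmark `wgSelect()` that greedily minimizes mean
WDUD directly. `deriveProperties()` divides energetic properties by the
electron count and vibrational ones by `3·N_atom − 6` to weaken
system-size dependence before evaluation.

## Worked example

Select 8 molecules from a synthetic pool of 60 clustered unit vectors with
angle-linear properties (no downloads; everything is generated in code):

```r
library(divpick)

inst <- generateClusteredInstance(60, 8, 4, noiseScale = 0.05, seed = 11)
tab  <- generateProperties(inst$vectors, p = 2, noiseScale = 0, seed = 12)

sel <- greedyLogdet(inst$vectors, 8)
selectedIndices(sel)
#> [1]  1 58 39 60  4 37 10  7
round(stepGains(sel), 4)
#> [1] 0.6931 0.6931 0.6919 0.6907 0.4156 0.4128 0.4121 0.4096
inst$labels[selectedIndices(sel)]
#> [1] 1 2 3 4 4 1 2 3
```

The gain trace is non-increasing (diminishing returns); the first four
picks each open a new cluster at close to the maximum possible gain
`log 2 ≈ 0.6931`, after which the objective drops to within-cluster
refinement — and the selection cycles through all four clusters again.

```r
wdudMeanNormalized(meanWdud(tab, sel))
#> [1] 0.1036
mean(sapply(1:100, function(s)
  wdudMeanNormalized(meanWdud(tab, randomSelect(60, 8, seed = s)))))
#> [1] 0.1475
```

The log-determinant selection spreads the (angle-linear) property values
more evenly than random selection: mean WDUD 0.104 against a random
average of 0.147, while covering all 4 clusters versus the random average
of 3.69.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/scripts/divpick.R synth  --n 60 --m 8 --clusters 4 --out fixtures/
Rscript inst/scripts/divpick.R select --method submo --vectors fixtures/vectors.csv \
        --k 8 --out selection.json
Rscript inst/scripts/divpick.R evaluate --criterion wdud \
        --properties fixtures/properties.csv --selection selection.json --out eval.json
```

Subcommands: `select` (submo, wg, maxmin, maxsum, random), `evaluate`
(wdud, mpd-mk, mpd-ef), `derive`, `synth`. Flags override a YAML config
(`--config`), which overrides built-in defaults; the effective
configuration and seed are echoed into every JSON artifact.

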