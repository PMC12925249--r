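---
title: "Rank-based signature scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based signature scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uscore)
library(Matrix)
```

## The scoring model

Given a genes-by-cells expression matrix $M$ and a signature $s$ of $n$
genes, each cell $j$ is scored independently of every other cell. Within the
cell's full expression profile $M_{:,j}$ all genes are ranked by descending
expression (rank 1 = highest); tied values receive their midrank. The ranks
$r_i$ of the signature genes are capped at a ceiling $r_\max$,

$$ r_i \leftarrow \min(r_i,\, r_\max), $$

and summarized by the Mann–Whitney U statistic

$$ U \;=\; \sum_{i=1}^{n} r_i \;-\; \frac{n(n+1)}{2}, $$

which counts (with ties as $\tfrac12$) the pairs in which a non-signature
gene outranks a signature gene. The score is

$$ \mathrm{score} \;=\; 1 - \frac{U}{U_\max}, \qquad
   U_\max \;=\; n\,r_\max - \frac{n(n+1)}{2}. $$

A score of 1 means the signature occupies the top $n$ ranks of the cell; a
score of 0 means every signature gene sits at or beyond the rank cap. Because
only within-cell rank order enters, the score is invariant to any per-cell
monotone transform — raw counts and log-normalized values give identical
results — and to dataset composition: adding or removing *other cells* never
changes a cell's score.

An earlier normalization used $U_\max = n\,r_\max$. That constant exceeds the
attainable maximum of $U$ (it ignores the $n(n+1)/2$ offset), so a fully
capped signature could never reach score 0 and all scores were compressed
upward. The corrected constant is the default; the inflated one remains
available as `legacy_norm = TRUE` purely for comparison, and corrected scores
are never above legacy scores on the same input.

### Positive and negative gene sets

A signature may state genes expected to be *absent* from the cell state as
well as genes expected to be present: tokens suffixed `-` (ASCII hyphen or
typographic minus) form the negative set, all others the positive set. Each
set is scored separately and combined as

$$ \mathrm{score} = \max\!\big(0,\; \mathrm{score}^{+} - w\,\mathrm{score}^{-}\big), $$

clipped at zero so the combined score stays in $[0,1]$ ($w = 1$ by default).
A gene appearing in both sets is rejected as a curation error rather than
resolved by precedence. With the `skip` policy (below), a signature whose
positive set vanishes is *undefined* (`NA`), never 0 — an unscorable
signature is not the same as absent signal; a surviving positive set with a
fully-missing negative set is scored positive-only with a warning, since
nothing is known about the unmeasured negative genes.

## Parameters that matter

**`r_max`** (default 1500, unitless rank). Single-cell matrices are mostly
zeros, and those tied zeros would otherwise occupy a huge midrank that
drowns the informative part of the profile. The cap bounds the contribution
of undetected genes. A good setting is the median number of detected
(non-zero) genes per cell — about right for 10X Chromium at the default; for
targeted panels (Xenium, CosMx, a few hundred genes) or antibody-tag data it
must be lowered accordingly, and comparisons across samples should use one
common value. When a set is larger than the cap ($r_\max < n$), $U_\max$ can
be non-positive and the score is reported undefined rather than guessed.

**Missing-gene policy** (`impute_zero`, default, vs `skip`). Public
repositories often ship matrices with lowly-detected genes filtered out;
`impute_zero` assumes such genes are genuinely unexpressed and appends them
to the matrix as all-zero rows before ranking — exactly equivalent to having
measured them as zeros, including the (tiny) shift this induces in the zero
tail's midrank. When several signatures are scored together the union of
their unobserved genes is appended once, so all signatures see one
consistent gene universe. `skip` instead assumes absent genes were never
measured (targeted panels) and removes them from the set.

**`chunk_size`** (default 500 cells). Ranking requires densifying columns,
so cells are processed in mini-batches; the chunk size trades memory for
call overhead and *never* affects values — the score table is bitwise
identical for any chunk size and any `workers` count, which the test suite
asserts.

**Tie handling** is midrank (average rank), the standard Mann–Whitney
convention, applied before capping; both choices make scores independent of
the order genes happen to appear in the input file. These two conventions
are design decisions of this package — the underlying method statement fixes
neither.

## kNN smoothing of scores

Sparsity makes single-cell scores noisy; an optional post-hoc step replaces
each cell's score by a decay-weighted average over its $k$ nearest
neighbours in an embedding (by default the package's own PCA: per-cell
scaling to 10,000 total counts, `log1p`, gene centering, 20 components with
a deterministic sign convention; any cells-by-dimensions table can be
supplied instead). With neighbours ordered by increasing distance,

$$ \mathrm{score}_{\mathrm{kNN}} = \frac{\sum_i w_i\, \mathrm{score}_i}{\sum_i w_i},
   \qquad w_i = (1-\lambda)^i, $$

where the sum runs over the sequence (self, neighbour 1, …, neighbour $k$)
with the cell itself at $i = 0$ (weight 1). Self-inclusion is a deliberate
choice: with weights only over neighbours, $\lambda = 1$ would zero every
weight and leave the score undefined, whereas including the self reproduces
the intended limits exactly — $\lambda = 1$ applies no smoothing and
$\lambda = 0$ is the unweighted mean of self plus neighbours. Defaults
$k = 10$, $\lambda = 0.1$ and 20 components follow common single-cell
practice; decay is rank-ordered (by neighbour position, not distance).
Smoothed scores are convex combinations, so they remain in $[0,1]$; smoothing
operates on score tables only and never alters the expression matrix.
Undefined neighbour scores are dropped from numerator and denominator alike.

Neighbour search is exact (full pairwise Euclidean distances) with ties
broken by ascending cell index; approximate search is out of scope at the
scales this package targets.

## Aggregation and inference

Cells from one sample are not independent replicates; testing score
differences across conditions at the single-cell level inflates
significance (pseudo-replication). `aggregate_scores()` therefore reduces
the table to mean defined scores per group — intended to be the *sample* —
for use as the unit of downstream tests, reporting group sizes and how many
cells actually contributed. The tests themselves are left to the user. A
related caveat the package cannot enforce: signatures derived from a dataset
(say, by differential expression) should not be re-tested on the same
dataset ("double dipping").

## The synthetic benchmark

`simulate_counts()` draws counts from a gamma–Poisson (negative binomial)
model: lognormal per-gene baseline rates (sdlog 1), lognormal per-cell depth
factors (sdlog 0.35), NB size 0.5, and a global scale calibrated by
root-finding so the expected zero fraction matches the requested sparsity
(realized sparsity lands within a few percentage points; the suite asserts
±5). Planted populations multiply their signature's positive-gene rates by a
fold factor and divide negative-gene rates by it. Defaults emulate a
droplet-style experiment: 2000 genes × 1000 cells at 90% sparsity; the
standard benchmark plants a 30-gene population in 30% of cells at fold 8.
Everything is reproducible from one integer seed.

This generator emulates overdispersed sparse counts with depth variation; it
does **not** emulate batch effects, doublets, ambient RNA, correlated gene
programs beyond the planted signature, or realistic library-size/gene-rate
joint structure. Passing the planted-recovery check therefore demonstrates
that the scoring pipeline recovers a known rank-level signal through the
full stack (simulation → ranking → scoring → smoothing), not that any
particular biological signature will separate cell states in real data.

## Numerical choices and degenerate inputs

* Scores are mathematically confined to $[0,1]$; the implementation still
  clamps against floating-point drift.
* Undefined scores are `NA` everywhere and empty fields in TSV output —
  never silently 0.
* Correctness is checked against an independently coded naive oracle (full
  per-column sort with a hand-written midrank walk, direct formulas) to
  within 1e-12 on hundreds of random sparse fixtures; in practice the two
  agree exactly.
* An all-zero cell ranks every gene at the same midrank $(G+1)/2$, capped;
  any signature then scores 0 once fully capped, or a well-defined constant
  otherwise.
* A constant expression matrix has no principal components and raises a
  degenerate-embedding error rather than returning noise.
* `find_knn` truncates $k \ge n_\text{cells}$ with a warning; a single-cell
  dataset yields an empty graph and smoothing degenerates to the identity.
* Problem sizes in the shipped tests (matrices up to 100×50 for oracle
  equivalence, a 2000×1000 planted benchmark end-to-end) were chosen as the
  smallest scales at which every property is informative.

## Worked example

```{r example}
set.seed(1)
genes <- synthetic_genes(500)
sig <- parse_signature("planted", c(sample(genes, 12),
                                    paste0(sample(genes, 3), "-")))
sim <- simulate_counts(simulation_spec(
  n_genes = 500, n_cells = 300, sparsity = 0.9, seed = 1L,
  populations = list(list(signature = sig, fraction = 0.3, fold = 8))))

r_max <- median(colSums(sim$matrix > 0))
tab <- score_signatures(sim$matrix, sig, scoring_params(r_max = r_max))
aggregate_scores(tab, setNames(sim$cells$population, sim$cells$cell_id))
```

The planted population's mean score sits well above background. Smoothing
sharpens the picture without touching the counts:

```{r smooth}
emb <- compute_embedding(sim$matrix, n_components = 15)
smoothed <- smooth_scores(tab, find_knn(emb, 10), lambda = 0.1)
c(raw_sd = sd(tab$scores[, 1]), smoothed_sd = sd(smoothed$scores[, 1]))
```

## Known limitations

* Gene matching is exact and case-sensitive; no alias or identifier mapping.
* `.h5ad` input requires an HDF5 reader this installation does not provide;
  convert to a Matrix Market triplet directory or dense table first.
* No statistical testing machinery; `aggregate_scores()` prepares the
  sample-level table and stops there.
* Scores compare signature genes against the rest of the *measured*
  transcriptome; with very small panels the U statistic loses resolution
  regardless of `r_max`.
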