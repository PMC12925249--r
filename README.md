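# uscore

Rank-based gene signature scoring for single-cell expression data.

A recurring task in single-cell analysis is quantifying, cell by cell, the
activity of a predefined gene set — a marker panel, a pathway, a
transcriptional program. `uscore` scores each cell with a Mann–Whitney
U statistic on the ranks of the signature genes within that cell's own
expression profile, which makes the score robust to normalization (only
within-cell rank order matters), independent of every other cell in the
dataset, and bounded in [0, 1].

## The score

For a signature of $n$ genes in a cell, genes are ranked by descending
expression (midranks for ties) and ranks are capped at $r_\max$ so the long
tail of undetected genes cannot dominate:

$$ r_i \leftarrow \min(r_i, r_\max), \quad
   U = \sum_{i=1}^n r_i - \frac{n(n+1)}{2}, \quad
   \mathrm{score} = 1 - \frac{U}{U_\max}, \quad
   U_\max = n\,r_\max - \frac{n(n+1)}{2}. $$

Score 1 = signature genes occupy the cell's top $n$ ranks; score 0 = all at
or beyond the cap. Signatures may mix positive and negative genes
(`"CD8A"`, `"CD4-"`): each set is scored separately and combined as
$\max(0, \mathrm{score}^+ - w\,\mathrm{score}^-)$. Genes absent from the
matrix are either imputed as zero counts (whole-transcriptome data) or
skipped (targeted panels). Scores can be smoothed over each cell's $k$
nearest neighbours in PCA space with decay weights $(1-\lambda)^i$, and
aggregated to per-sample means for sample-level statistics.

## Worked example

Simulate a sparse 500-gene × 300-cell count matrix with a planted
signature-positive population (30% of cells, 8-fold elevation of 12
positive genes, 8-fold suppression of 3 negative genes), then score it:

```r
library(uscore)
library(Matrix)

set.seed(1)
genes <- synthetic_genes(500)
sig <- parse_signature("planted", c(sample(genes, 12),
                                    paste0(sample(genes, 3), "-")))
sim <- simulate_counts(simulation_spec(
  n_genes = 500, n_cells = 300, sparsity = 0.9, seed = 1L,
  populations = list(list(signature = sig, fraction = 0.3, fold = 8))))

# cap ranks at the median number of detected genes per cell
r_max <- median(colSums(sim$matrix > 0))   # 49
tab <- score_signatures(sim$matrix, sig, scoring_params(r_max = r_max))
tab
#> <score_table> 300 cells x 1 signatures
#>              planted
#> cell00001 0.02745098
#> cell00002 0.07843137
#> cell00003 0.00000000
#> cell00004 0.10686275
#>   ... 296 more cells

aggregate_scores(tab, setNames(sim$cells$population, sim$cells$cell_id))
#>        group signature mean_score n_cells n_defined
#> 1 background   planted 0.02585096     210       210
#> 2    planted   planted 0.19932045      90        90
```

Planted cells average a score of 0.199 against a 0.026 background — the
planted rank signal is recovered nearly an order of magnitude above noise.
Smoothing scores over 10 PCA neighbours tightens the distributions without
touching the expression matrix:

```r
emb <- compute_embedding(sim$matrix, n_components = 15)
smoothed <- smooth_scores(tab, find_knn(emb, 10), lambda = 0.1)
c(raw_sd = sd(tab$scores[, 1]), smoothed_sd = sd(smoothed$scores[, 1]))
#>      raw_sd smoothed_sd
#>  0.09805361  0.05085162
```

## Command line

```sh
Rscript inst/scripts/uscore.R \
  --input counts_mtx_dir/ --signatures sets.gmt --output scores.tsv \
  --rmax 1500 --missing impute_zero --groupby samples.tsv \
  --smooth --k 10 --lambda 0.1
```

Inputs: Matrix Market triplet directories (`matrix.mtx` + `genes.tsv` +
`barcodes.tsv`), dense TSV/CSV tables, GMT signature files or inline token
lists. Outputs: a per-cell score TSV plus optional `_groups.tsv`
(per-group means) and `_smoothed.tsv` companions. CLI output is
byte-identical to the equivalent library calls.

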