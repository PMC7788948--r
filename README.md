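# sccimpute

Dropout imputation for single-cell RNA-seq count matrices, one cell at
a time.

scRNA-seq captures only ~5–15% of the mRNA molecules in a cell, so
lowly expressed genes frequently read out as zero even when active.
`sccimpute` decides, for every zero in the matrix, whether it is a
*dropout* (and restores a value) or a *true biological zero* (and keeps
it), without ever pooling cells into clusters — preserving
cell-to-cell heterogeneity that cluster-then-impute methods smooth
away.

## Method

For a genes × cells count matrix `X`:

1. **Filter outlier cells**: embed cells on the first two principal
   components of `log(1+X)`; a cell whose nearest-neighbor distance
   `dis_c` exceeds `q1 + 1.5 (q3 − q1)` is removed.
2. **Find each cell's neighbors**: select up to 500 informative genes
   (largest residuals of `log2(100·dropout rate)` regressed on mean
   `log2(x+1)` expression), rank the other cells by cosine similarity
   on that subspace, keep the top 20, then drop any neighbor more than
   0.1 below the best similarity.
3. **Model each (cell, gene)**: fit, on the gene's values in the
   neighbor cells and by EM,

   `f(x) = λ₁·Normal(x; μ, σ) + λ₂·Binomial(x; N, p) + λ₃·1{x = 0}`,  `λ₁+λ₂+λ₃ = 1`

   — high expression, low expression seen through a per-molecule
   detection probability `p` (initialized at 0.1) on a small transcript
   count `N ≤ 9`, and true silence. The largest fitted weight decides:
   `λ₁` → keep the observed value, `λ₂` → replace a zero with the
   Binomial mean `N·p`, `λ₃` → confirm a true zero. Nonzero entries are
   never modified in the default mode.

The package also ships a calibrated synthetic-data simulator (cell
types, cell-volume size factors, logistic expression-dependent
dropout), evaluation utilities (adjusted Rand index, the
intra/inter-class squared-distance ratio `Dis = Dis_intra/Dis_inter`,
zero accounting, PCA scatter plots), and a command-line interface.

## Worked example

```r
library(sccimpute)

set.seed(1)
sim <- simulate_cells(sim_config(seed = 1))   # 3 types, 150 cells, 8180 genes
res <- impute_all(sim$observed_matrix)
print(res)
#> SCC imputation result
#>   genes x cells: 8180 x 127 (of 150 input cells)
#>   zeros: 810763 -> 810492 (78.04% -> 78.02%), 271 dropouts resolved
#>   true zeros retained: 329204

kept <- colnames(res$matrix)
cluster_and_score(sim$observed_matrix, sim$labels, k = 3, seed = 1)$ari
#> [1] 0.4705312
cluster_and_score(res$matrix, sim$labels[kept], k = 3, seed = 1)$ari
#> [1] 0.5312221
intra_inter_distance(sim$observed_matrix, sim$labels)$dis_ratio
#> [1] 0.1407364
intra_inter_distance(res$matrix, sim$labels[kept])$dis_ratio
#> [1] 0.132402
```

Reading the output: 23 of 150 cells were flagged as outliers and
removed; of the ~811k zeros among the kept cells, 271 were judged
dropouts and replaced by their fitted Binomial means while 329,204
were positively classified as true zeros (the rest sit under
Normal-dominant models and are kept as observed). K-means clustering
of the cells against the simulated ground-truth types improves from
ARI 0.47 to 0.53, and the intra/inter-class distance ratio (smaller =
tighter types) drops from 0.141 to 0.132.

Per-entry provenance is in `res$provenance` (labels `kept_nonzero`,
`kept_high`, `imputed_dropout`, `true_zero`, `no_neighbors`) and the
run report in `res$report`.

## Command line

```sh
Rscript inst/cli/scc simulate --out sim/ --seed 1
Rscript inst/cli/scc impute -i sim/observed.tsv -o imputed.tsv --report report.json
Rscript inst/cli/scc evaluate --raw sim/observed.tsv --modified imputed.tsv \
    --labels sim/labels.tsv
```

Input matrices may be dense TSV/CSV (cells in the header row, genes in
the first column) or Matrix Market `.mtx` with companion
`*_genes.txt` / `*_cells.txt` label files.

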