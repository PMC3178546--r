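# getem — gene expression templates for tissue classification

`getem` answers a simple question about transcriptomes: *given the
expression of a small panel of genes, which normal human tissue does this
sample look like — and how far has it drifted from that normal state?*

It is aimed at computational biologists working with bulk expression
compendia (microarray or RNA-seq on a log2 scale) who want a compact,
interpretable nearest-centroid classifier rather than a black-box model:

1. **Signature selection.** For each training compendium, rank every gene by
   its coefficient of variation across samples, CV = σ/μ, and keep the top
   fraction *q* (default 2.5%). Intersect the per-dataset candidate sets so
   only genes that are reproducibly variable across independent data sources
   survive — this is what removes batch-driven false positives. Finally,
   collapse redundant genes by average-linkage hierarchical clustering under
   the correlation distance *d* = 1 − *r*, cutting the tree at height
   1 − `corr_cut` and keeping one representative per cluster.
2. **Template building.** For every tissue *t*, the gene expression template
   (GET) is the vector of expected signature-gene expression:
   per-dataset tissue means averaged with equal weight across datasets, so no
   single large compendium dominates.
3. **Nearest-template prediction.** A sample **x** is assigned
   `argmax_t cor(x, GET_t)` (1-nearest-neighbour over templates), with
   Pearson correlation by default or Spearman for robustness to monotone
   distortions. The correlation to the sample's own tissue template — the
   *deviation score* — doubles as a measure of departure from the normal
   physiological state (development, cancer, engineered tissue).
4. **Downstream analyses.** Per-tissue accuracy tables, 2×2
   sensitivity/specificity, mean ± sd correlation summaries, and
   developmental-trajectory regression (OLS of correlation on time with a
   slope t-test, plus ranking of all templates by slope).

A seeded synthetic-compendium generator reproduces the statistical structure
this method assumes (shared tissue profiles, per-dataset batch offsets,
Gaussian noise, planted high-variance signature genes), so the entire
pipeline is testable without any external downloads.

## Worked example

```r
library(getem)

sim <- generate_compendium(sim_config(n_tissues = 6, n_genes = 1000,
                                      n_signature = 20,
                                      samples_per_tissue_per_dataset = 3,
                                      seed = 11))
sig <- select_signature(sim$matrices, sim$meta, q = 0.025, corr_cut = 0.85)
#> [getem INFO] select_signature: 20 candidates after intersecting 3 datasets
#> [getem INFO] remove_redundancy: corr_cut=0.85, 20 candidates -> 16 representatives (max mean-CV rule)

ts <- build_templates(sim$matrices, sim$meta, sig)
ts
#> Template set: 6 tissues x 16 signature genes

set.seed(1)
test <- t(sim$truth$expected[, sig$gene_ids]) +
  rnorm(6 * length(sig$gene_ids), 0, 0.2)
colnames(test) <- paste0("new_", rownames(sim$truth$expected))
preds <- predict_matrix(test, ts)
prediction_report(preds)[, 1:3]
#>      sample_id predicted_tissue best_correlation
#> 1 new_tissue01         tissue01        0.9945727
#> 2 new_tissue02         tissue02        0.9916582
#> ...
```

Interpretation: the derived signature (16 of the 20 planted high-variance
genes; 4 merged as redundant) classifies every held-out noisy sample to its
true tissue, with correlations near 1 because the noise sd (0.2) is a tenth
of the planted tissue-effect sd (2). Evaluation mirrors published-table
arithmetic exactly:

```r
st <- confusion_stats(tp = 24, fp = 5, fn = 1, tn = 40)
sprintf("sensitivity %d%%, specificity %d%%", st$sensitivity_pct, st$specificity_pct)
#> "sensitivity 96%, specificity 89%"
```

## Command line

The installed package ships a `getem` executable (under the package's
`exec/` directory) with subcommands `simulate`, `select`, `build`,
`predict`, `evaluate` and `trajectory`; every command accepts `--config
cfg.json` with explicit flags taking precedence, logs a JSON run manifest
to stderr, and writes data only to files/stdout:

```sh
getem simulate --out-dir work --seed 42
getem select   --matrices work/ds1.tsv,work/ds2.tsv,work/ds3.tsv \
               --meta work/meta.tsv --out work/sig.txt
getem build    --matrices work/ds1.tsv,work/ds2.tsv,work/ds3.tsv \
               --meta work/meta.tsv --signature work/sig.txt --out work/templates.tsv
getem predict  --matrix work/ds1.tsv --templates work/templates.tsv --out work/pred.tsv
getem evaluate --confusion 24,5,1,40
```

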