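# concordia

Bias correction and integration of paired high-dimensional genomic
matrices by concordant-information enhancement.

## The problem

High-throughput genomics routinely produces several feature-by-sample
matrices on the same samples: gene expression next to copy number,
chromatin accessibility next to transcriptomes, or the same assay run
independently by two labs. Each platform carries its own technical biases
(batches, hybridization, GC content, coverage), and a subset of samples is
often affected much more strongly than the rest. Within-platform
batch-correction methods cannot use the one piece of information that
identifies such biases most directly: a second measurement of the same
samples on an independent platform.

`concordia` adjusts one matrix (the *main* matrix `M`, n₁ features × n
samples) using a column-matched *associated* matrix `C` (n₂ × n), under the
assumption that pairwise sample distances should agree across platforms and
that disagreement is mostly technical. It is aimed at computational
biologists integrating consortium-style data (expression + CNV, DHS +
expression, cross-lab replicate cohorts).

## The method

If the two matrices are not row-matched (e.g. genes vs peaks), `C` is first
summarized into `M`'s feature space: for each main feature, up to
`max_neighbors` associated features whose genomic anchors (strand-aware TSS
for genes, interval midpoint for peaks) lie within `max_distance` of the
main feature's anchor are collected, and the sub-matrix is reduced to its
first principal component score on the correlation matrix (each row
standardized, leading eigenvector of their Pearson correlation matrix),
sign-flipped if needed so it correlates non-negatively with the main row.
Defaults follow common practice for gene/peak integration: 50 neighbors
within 100 kb when summarizing peaks around genes, 20 when summarizing
genes around peaks.

Each main row `mᵢ` with summarized partner `cᵢ` is then updated through a
three-scenario rule gated by ρ = cor(cᵢ, mᵢ):

| gate | update |
|---|---|
| ρ ≤ cutoff1 (default 0) | `mᵢ` kept unchanged |
| cutoff1 < ρ ≤ cutoff2 (default 0.5) | `scale(mᵢ) + ρ·scale(cᵢ)` |
| ρ > cutoff2 | first PC of the 2 × 2 correlation-matrix PCA of `{mᵢ, cᵢ}` |

where `scale(x)` standardizes to mean 0, s.d. 1 (n − 1 denominator). Every
updated row is rescaled to the mean and s.d. of the original row, so the
adjustment changes only the *pattern* across samples, never a row's scale.
`cutoff2` can instead be chosen empirically as the quantile of the realized
row correlations that sends roughly one third of rows through the
principal-component update (`auto_cutoff2 = TRUE`).

The package also ships a synthetic paired-data generator (shared
cluster-structured latent signal, independent per-platform noise, a strong
column-wise bias on a subset of main-matrix samples) and the evaluation
metrics used to assess adjustment quality: the adjusted Rand index under
repeated K-means, and per-feature Spearman-correlation deltas against a
partner platform.

## Worked example

```r
library(concordia)

sim <- generate_paired_dataset(seed = 1)
fit <- concordia(sim$main, sim$assoc, sim$main_annot, sim$assoc_annot)
fit
#> Concordance-adjustment run
#>   300 features x 60 samples; rows summarized by genomic neighborhood
#>   cutoff1 = 0, cutoff2 = 0.5 (fixed)
#>   scenario1       0
#>   scenario2      74
#>   scenario3     226
#>   skipped         0
```

226 of 300 rows correlated with their summarized partner above 0.5 and took
the principal-component update; the remaining 74 took the
correlation-weighted sum. Does the adjustment recover the planted sample
clusters better than the raw, biased matrix?

```r
kmeans_ari_distribution(sim$main, sim$true_labels, k = 4, n_reps = 100, seed = 1)
#> K-means cluster recovery: k = 4, 100 repetitions (seed 1)
#>   adjusted Rand index: mean 0.6870, range [0.2204, 1.0000]
kmeans_ari_distribution(fit$result$adjusted, sim$true_labels, k = 4, n_reps = 100, seed = 1)
#> K-means cluster recovery: k = 4, 100 repetitions (seed 1)
#>   adjusted Rand index: mean 0.7565, range [0.2177, 1.0000]
```

The mean adjusted Rand index (1 = perfect recovery of the 4 planted
clusters, 0 = chance) rises from 0.687 to 0.757 after adjustment: borrowing
the associated platform's concordant signal pulls the 10 bias-displaced
samples back toward their clusters. Per-row diagnostics are in
`fit$result$row_correlation` and `fit$result$scenario`.

A command-line front end is installed at `exec/concordia` with `adjust`,
`simulate` and `evaluate` subcommands over TSV matrices and BED-like
annotations; see `vignettes/concordia-methods.Rmd` for the full model
description and design choices.

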