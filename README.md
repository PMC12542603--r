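# chromastrat

Stratification of cardiac single-nucleus RNA-seq cohorts into
disease-associated cell subpopulations, using a curated panel of chromatin
structural genes (remodellers, histone modifiers, genome-topology factors)
as the feature space.

In dilated cardiomyopathy (DCM), each cardiac cell type harbours
subpopulations whose prevalence shifts with disease — most prominently a
cardiomyocyte population that expands from a few percent of nuclei in
healthy hearts to a dominant fraction in DCM. `chromastrat` makes these
shifts measurable with a two-stage pipeline:

1. **Stage 1 — global typing.** Rare-gene filtering (genes expressed in
   fewer than 1% of cells are temporarily removed), median-library + log1p
   normalisation, a three-layer autoencoder (input → 10-dimensional
   embedded layer → reconstructed output, trained full-batch to minimise
   reconstruction MSE), UMAP projection, DBSCAN density clustering, and
   cell-type assignment from lineage markers (*ACTC1/MYH7/TNNT2/RYR2* for
   cardiomyocytes, *PECAM1* for endothelium, etc.). Sex-biased genes
   (*XIST*, *UTY*, *KDM5D*) are excluded throughout.
2. **Stage 2 — panel-restricted subclustering.** Within each cell type the
   same embed–project–cluster recipe runs on the chromatin-panel genes
   only, yielding subclusters CM1, CM2, … (largest first).

Downstream, upregulated subcluster markers are selected by three joint
criteria — Wilcoxon rank-sum p < 10⁻⁶, expression in ≥ 20% of in-cluster
cells, and mean abundance ≥ 2-fold the other subclusters — and marker
lists can be scored for over-representation against GMT gene sets with a
hypergeometric test, Benjamini–Hochberg adjustment, the `p < 0.01` OR
`adjusted p < 0.05` filter, and enrichment score `−log10(adjusted p)`.
Per-condition composition tables report each subcluster as a percentage of
its condition's cells of that type.

A negative-binomial synthetic cohort generator (`generate_cohort()`)
plants a chromatin-panel-restricted cardiomyocyte subpopulation at 3%
(healthy) vs 18% (disease) prevalence, with known affected genes, so the
whole pipeline is testable end-to-end against ground truth without any
downloads.

## Worked example

```r
library(chromastrat)

cohort <- generate_cohort(default_config(seed = 1))
cohort
#> <synthetic_cohort> 1000 genes x 24000 cells
#> # A tibble: 12 x 3
#>    condition cell_type         n
#>  1 disease   cardiomyocyte  5424
#>  2 disease   endothelial    1845
#>  ...

sub <- subcluster_by_type(cohort$counts, cohort$annotation,
                          types = "cardiomyocyte", seed = 1)
sub
#> <subclustering>
#>   cell_type     subcluster_label     n
#> 1 cardiomyocyte CM1               9600
#> 2 cardiomyocyte CM2                982
#> 3 cardiomyocyte <NA>               272

comp <- composition(sub, cohort$annotation)
disease_enriched_subcluster(comp)
#> # A tibble: 1 x 6
#>   cell_type     subcluster subcluster_label pct_disease pct_healthy delta
#> 1 cardiomyocyte          2 CM2                     15.5        3.09  12.4
```

The 10,854 cardiomyocyte nuclei split into a large baseline subcluster
(CM1), a disease-enriched subcluster (CM2) and 272 DBSCAN noise cells
(excluded from percentage denominators, always reported). CM2 holds 15.5%
of disease-condition cardiomyocytes versus 3.1% of healthy ones — the
planted 18%-vs-3% shift, recovered up to the cells whose sampled
expression carries too little signal to assign (see the methods vignette
for the detectability analysis). Markers and enrichment follow the same
grammar:

```r
norm <- normalize_counts(exclude_genes(cohort$counts))
markers <- select_markers(norm[, sub$cells$cell_id], sub$cells$subcluster)
sets <- read_gmt("pathways.gmt")
enrich(markers$gene[markers$cluster == 2], sets,
       universe = rownames(filter_rare_genes(cohort$counts)))
```

`autoplot()` methods cover composition tables, subclusterings and
autoencoder training curves; `tidy()`/`glance()` summarise fitted
autoencoders. `run_pipeline(run_config(...))` orchestrates every stage
from files on disk and writes TSV results plus a deterministic
`manifest.json` from which `run_config_from_manifest()` reproduces the run
byte-for-byte. `scripts/run_pipeline.R` wraps simulate / run-all for shell
use.

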