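# pancanstrat

Stratifying tumours across anatomical primary sites from bulk RNA-seq.

Cancer expression programmes — immune evasion, proliferative signalling,
angiogenesis, invasion — cut across primary sites, but site-specific
baseline expression usually swamps them. `pancanstrat` implements a
pan-cancer stratification pipeline for gene-by-sample expression
matrices in the Xena/Toil dialect (log2(TPM+1) TSV) with matched
tumour/normal phenotype sheets:

1. **Ingest & filter** — convert to TPM+1, keep protein-coding genes,
   restrict to primary sites with at least 20 tumours *and* 20 normals.
2. **Normalize** — two log-ratio corrections against normal tissue:
   tissue-corrected
   `L_tissue[i,j,l] = ln( X[i,j,l] / mean_normal[i,l] )`
   and grand-mean-corrected
   `L_grand[i,j] = ln( C[i,j] / mean_l(mean_normal[i,l]) )`
   (an unweighted mean of per-site means, not a pooled mean).
3. **Modules** — weighted correlation network with soft power chosen by
   the scale-free criterion, topological overlap similarity
   `TOM[i,j] = (Σ_u a[i,u]a[u,j] + a[i,j]) / (min(k_i,k_j) + 1 − a[i,j])`,
   average-linkage tree cut statically; module expression is the member
   mean.
4. **Clustering** — cosine distance over module-member genes, Ward.D2
   agglomeration, k chosen by maximal mean silhouette width.
5. **Annotation** — hypergeometric over-representation of modules
   against GMT pathway sets, Benjamini–Hochberg corrected per module.
6. **Stratification** — Kruskal–Wallis + Dunn across clusters, Tukey HSD
   across sites, and a per-(site, cluster) hypergeometric test: a site is
   *stratified* when over-represented (p ≤ 0.05) in ≥ 2 clusters.

A synthetic-cohort generator plants co-expression modules, latent tumour
clusters and stratified sites with written ground truth, so the whole
pipeline is testable offline.

## Worked example

The `analysis/` scripts run the study end to end on a simulated cohort
(4 sites × 24 tumours + 24 normals, 3 planted modules, 4 latent
clusters, two ground-truth stratified sites):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_modules.R
Rscript analysis/04_cluster.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_stratification.R
```

which prints, among other lines:

```
tissue-corrected values span [-2.80, 2.32] ln units
uncorrected power  6 (fallback) | 68 genes in 2 modules | ARI vs planted 0.598
tissue      power  6 (fallback) | 106 genes in 3 modules | ARI vs planted 0.982
grand       power  6 (fallback) | 112 genes in 3 modules | ARI vs planted 0.880
uncorrected k = 2 (mean silhouette 0.592) | ARI vs latent clusters 0.326
tissue      k = 4 (mean silhouette 0.745) | ARI vs latent clusters 1.000
grand       k = 4 (mean silhouette 0.749) | ARI vs latent clusters 1.000
enriched-cluster counts (sites x modes):
  site1    1  2  2
  site2    1  2  2
  site3    1  1  1
  site4    1  1  1
tissue-corrected stratification calls match planted truth: TRUE
```

Reading: on uncorrected data the tissue signature dominates — module
detection is blurred (ARI 0.60) and tumours collapse into 2 clusters
that track nothing planted. After either normal-tissue correction the
three planted modules are recovered almost exactly, the silhouette sweep
picks the planted k = 4, clustering matches the latent clusters (ARI
1.0), and exactly the two planted stratified sites are called stratified
(over-represented in 2 clusters each; the columns of the count matrix are
uncorrected, tissue, grand). All tables land under `results/`.

The same machinery is available programmatically:

```r
library(pancanstrat)
co  <- generate_cohort(generator_config(seed = 1))
res <- run_pipeline(co$tumour, co$normal, co$sheet, modes = "tissue")
res$tissue$k                      # 4
res$tissue$stratification$sites   # per-site enriched-cluster counts
```

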