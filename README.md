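# omicfuse

Integrative multi-omic subtyping of tumor cohorts, built around similarity
network fusion (SNF) of matched bulk transcriptome and proteome profiles.
The package targets the analysis pattern used in pediatric low-grade glioma
studies — most prominently pilocytic astrocytoma, where two molecular groups
emerge only when mRNA and protein layers are integrated — but every module
is generic.

## What it does

Given feature-by-sample omic matrices and a clinical table, the package:

1. **Integrates layers.** Per-layer patient affinity graphs use a locally
   scaled Gaussian kernel on Euclidean distances over z-scored features,
   `W_ij = exp(−d_ij² / (μ·ε_ij))` with
   `ε_ij = (d̄_K(i) + d̄_K(j) + d_ij)/3`, and are merged by iterative
   cross-network diffusion (`P⁽ᵛ⁾ ← S⁽ᵛ⁾ P̄⁽⁻ᵛ⁾ S⁽ᵛ⁾ᵀ`, T rounds, defaults
   K = 10, μ = 0.5, T = 10). The number of groups is selected by the
   eigengap of the normalized Laplacian and samples are assigned by spectral
   clustering.
2. **Derives signatures and extends groups.** Welch t-tests with p ≤ 0.05
   and |fold change| ≥ 2 yield ranked up/down marker signatures (top-N per
   direction); semi-supervised hierarchical clustering (Pearson
   dissimilarity, average linkage) extends core group labels to additional
   samples, and a submap procedure (mutual marker enrichment with a
   permutation null, Fisher-combined and FDR-adjusted) maps subclasses
   across cohorts.
3. **Quantifies posttranscriptional regulation.** Per matched
   transcript–protein pair, Pearson correlation across samples; per group,
   the protein/mRNA log-ratio `median(log2 protein) − median(log2 mRNA)`;
   group shifts tested by Mann–Whitney (exact by enumeration for small
   samples).
4. **Scores pathways and cell types.** Preranked GSEA on t statistics
   (weighted Kolmogorov–Smirnov running sum, gene-label permutation null),
   enrichment-map edges by overlap coefficient, ssGSEA-like single-sample
   scores, and cell-type fractions by non-negative least squares against a
   signature matrix, with rank-sum group contrasts.
5. **Tests clinical associations.** Chi-square / Fisher exact contingency
   tests, Mann–Whitney age contrasts, Kaplan–Meier curves and the log-rank
   test for progression-free survival.

A seeded synthetic cohort generator (`simulate_cohort()`) reproduces the
statistical structure this analysis assumes — two latent groups of 14 + 14
samples, planted differential features, weak transcript–protein coupling
(median pairwise r ≈ 0.168), an opposite group-specific protein/mRNA ratio
shift, a group-uninformative methylation layer, immune cell-type mixing and
group-dependent clinical covariates — with full ground truth, so every
downstream claim is testable.

## Worked example

```r
library(omicfuse)

cohort  <- simulate_cohort(cohort_config(seed = 1))
aligned <- align_cohort(list(mrna = cohort$mrna, protein = cohort$protein))

params     <- snf_params(K = 10, mu = 0.5, T = 10)
affinities <- lapply(aligned$matrices, build_affinity, params = params)
fusion     <- fuse_networks(affinities, params)
summary(fusion)
#> Fused similarity network over 28 samples (2 layers)
#> Eigengap-selected number of clusters: 2
#> Eigengaps: k=2: 0.1715, k=3: 0.0558, k=4: 0.0420, k=5: 0.0659, k=6: 0.0019

fusion$labels <- spectral_cluster(fusion$fused, 2, seed = 1)
print(fusion)
#> snf_fusion: 28 samples, 2 layer(s), K=10 mu=0.50 T=10
#>   cluster sizes: 14 / 14
```

The two spectral groups coincide exactly with the planted ones (adjusted
Rand index 1). Posttranscriptional analysis on the 2000 matched pairs:

```r
pairs <- match_pairs(aligned$matrices$mrna, aligned$matrices$protein)
pair_correlations(pairs)$median_r
#> [1] 0.1767  — the weak global mRNA–protein coupling

ratios <- group_ratio(pairs, cohort$true_labels)
sapply(ratios$per_pair[c("group1", "group2")], median)
#>  group1  group2
#>  -0.51    0.49   — mRNA-dominant group 1, protein-dominant group 2
```

Cell-type deconvolution recovers the planted immune contrast:

```r
dec <- estimate_fractions(cohort$mrna, cohort$signature)
compare_fractions(dec, cohort$true_labels)
#>    cell_type mean1  mean2   U        p        q
#> 1      tumor 0.593 0.7507   8 3.92e-05 7.83e-05
#> 2      tcell 0.209 0.0479 196 7.47e-06 2.99e-05
#> 3  microglia 0.110 0.0922 127 1.90e-01 1.90e-01
#> 4 macrophage 0.089 0.1092  63 1.13e-01 1.51e-01
```

T cells are enriched in group 1 while microglia and macrophages do not
differ. `run_pipeline(pipeline_config(out_dir = "run"))` executes the whole
chain — alignment, fusion, clustering, signatures, extension, ratios,
enrichment, deconvolution, clinical tests — writing tab-separated artifacts
and a `manifest.json` run record.

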