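# methAgeNet

Integrative analysis of age-associated DNA-methylation drift and
cancer-differential methylation, for epigenomics researchers who want to
ask: *which genes whose promoter methylation drifts with age are the same
genes that go wrong in tumours, and do they carry prognostic information?*

The package re-implements, as a tested and reusable R pipeline, an
analysis strategy that links an aging methylation cohort (Illumina
27K-style beta values, one value per CpG in [0, 1]) with tumour/normal
methylation, a protein–protein interaction (PPI) network, gene
expression and survival outcomes. Because the original cohorts are not
redistributable, the package ships a synthetic-data generator that
emulates their statistical structure with ground-truth labels, so every
stage is testable end to end.

## The method

1. **Gene-level methylation.** CpGs with missing values are dropped. For
   each gene, the *consistency ratio* is the fraction of samples in which
   all member CpGs lie on the same side of β = 0.5; genes below 0.8 are
   excluded, the rest get the per-sample mean of their CpGs.
2. **Age-associated DMGs (aDMGs).** Per gene, OLS of β on age; the
   two-sided permutation p-value is
   p = (1 + #{|r_perm| ≥ |r_obs|}) / (n_perm + 1) over 1000 age
   permutations; Benjamini–Hochberg at FDR ≤ 0.01. Genes are classed
   hyper/hypo (slope sign) × high/low (mean β ≥ 0.5), and the
   drift-vs-level association is summarised by the odds ratio
   (b/a)/(d/c) with a Wald 95% CI and Fisher's exact test.
3. **Cancer DMGs (cDMGs).** Per gene and cancer, the Shannon entropy of
   the normalised tumour/normal group means, H = −Σ p_i log₂ p_i
   (p_i = m_i / (m_T + m_N)), adjusted by mirroring (min of H on the
   means and on their complements); low entropy = strong differential
   methylation. Per-cancer sets are unioned; hypergeometric tests give
   gene-set enrichment.
4. **Co-methylation network.** The PPI restricted to aDMGs, each edge
   weighted by the Pearson correlation of the two methylation profiles
   and kept only if it beats the empirical [0.005, 0.995] quantiles of
   1000 label-shuffled correlations (ASWN). The ACWN is its restriction
   to cDMGs and their direct neighbours. Degree, clustering coefficient
   C_i = 2 n_i / (k_i (k_i − 1)) and random induced-subnetwork nulls
   quantify its structure.
5. **Modules.** Greedy overlapping-module detection by cohesiveness
   f(V) = w_in / (w_in + w_bound + p·|V|), with overlap-based merging and
   size/density filters (ClusterONE-style, authored here).
6. **Markers.** Module genes that are both aDMG and cDMG are mapped to
   HH/LL/HL/LH patterns (age direction × cancer direction); a gene is a
   marker where the pattern is HH with expression down or LL with
   expression up (methylation silencing / activation concordance).
7. **Prognostic index.** Candidate markers are z-scored with training-set
   parameters, entered into Cox regressions (Efron ties) with clinical
   covariates; genes at multivariate p < 0.05 form
   PI = Σ coef_g · z_g. Patients split at the training-median PI;
   Kaplan–Meier curves and the log-rank test compare the risk groups, and
   a 10000-draw random-gene-set permutation test checks that the pipeline
   beats chance.

## Worked example

```r
library(methAgeNet)
cfg <- simConfig(n_genes = 300, n_aging_samples = 150, n_tumor = 25,
                 n_normal = 15, n_cancers = 3, ppi_n_extra_genes = 80,
                 seed = 7)
res <- runPipeline(cfg, nPerm = 1000, netPerm = 500, subnetReps = 200,
                   genesetReps = 2000, k = 10)

length(res$age$admgs)          # 52 age-associated genes called
res$network$topology$mean_degree   # 4.92 in the ACWN
res$modules                    # ModuleSet with 4 modules covering 21 genes
length(res$markers$called)     # 10 candidate markers
res$survival$selected          # 4 genes enter the prognostic index
signif(res$survival$km_train$p, 3)  # 1.85e-06 (training log-rank)
res$survival$random_set$p      # 0 (no random 10-gene set does as well)
str(res$recovery)
```

The recovery block compares every caller with the generator's planted
truth; on this run the aDMG caller reaches sensitivity 1.00 at observed
FDR 0, the entropy caller sensitivity 1.00 / specificity 1.00, the best
module overlaps the planted community at Jaccard 0.91, and all planted
concordant markers that survive preprocessing are recovered
(sensitivity 1.00) with no discordant HL/LH gene called.

Stage outputs (gene-level betas, aDMG table, cDMG union, ACWN edge list,
modules, pattern map, marker table, Cox tables, KM summary, provenance
manifest) are written as TSV/JSON when `outdir` is given.

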