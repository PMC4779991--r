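---
title: "Methods: linking age-associated methylation drift to cancer through weighted co-methylation networks"
author: "methAgeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation drift, networks and markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methAgeNet)
```

# Scope and model

Promoter methylation (the beta value, the methylated fraction of a CpG,
in [0, 1]) drifts with chronological age at many genes, and a subset of
those genes is also differentially methylated between tumours and
matched normal tissue. This package implements a full analysis chain
that identifies the overlap, organises it on a protein-interaction
scaffold weighted by co-methylation, extracts cohesive modules, calls
candidate markers by methylation/expression concordance, and evaluates
prognostic value. The assumptions, stage by stage:

* **Linearity of drift.** Age effects on gene-level beta are modelled
  as ordinary least squares on age (beta units per year). This follows
  the broad empirical finding that age-related promoter methylation
  change is approximately linear over adult life; non-linear or
  plateauing trajectories are deliberately out of scope.
* **Two-group differential methylation as low entropy.** For each gene
  the tumour and normal group means (m_T, m_N) are normalised to
  p_i = m_i / (m_T + m_N) and scored by Shannon entropy in bits;
  1 bit means the groups are indistinguishable, 0 a maximal contrast.
  Because entropy of raw means is insensitive to contrasts between two
  *low* means' complements, the adjusted score takes the minimum of the
  entropy on the means and on (1 − m_T, 1 − m_N), which makes the score
  invariant under beta → 1 − beta. This is a deliberately transparent,
  two-category re-implementation of the entropy idea behind
  quantitative differential-methylation callers; it does not reproduce
  any particular software's multi-group machinery.
* **Interactions constrain co-methylation.** Only gene pairs that
  interact in the background PPI are candidate edges; the edge weight is
  the Pearson correlation of the two genes' methylation profiles across
  the aging samples, and an edge survives only a two-sided per-edge
  permutation test. Co-methylation of interacting genes is read as
  shared regulation.
* **Proportional hazards.** Prognostic evaluation uses Cox partial
  likelihood (Efron tie handling) and a linear prognostic index on
  z-scored methylation.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| consistency threshold | 0.8 | fraction of samples | keeps genes whose CpGs agree on the side of beta = 0.5 in ≥ 80% of samples; trades retained genes against gene-level interpretability |
| permutations (age test) | 1000 | draws | floor of the permutation p is 1/1001; with BH at FDR 0.01 this limits resolution for very large gene sets (see below) |
| FDR threshold | 0.01 | q | aDMG calling; a `useRawP` switch applies unadjusted p ≤ threshold instead |
| entropy threshold | 0.95 | bits | calls group-mean contrasts of ~0.3 beta units at realistic noise; exposed because no canonical value exists |
| edge retention tail | 0.005 | quantile | two-sided per-edge permutation test at p < 0.01 |
| cohesiveness penalty | 2 | per node | models unobserved boundary edges; standard for cohesiveness-based module growth |
| min module size / density | 3 / 0.5 | — | filters trivial or sparse modules |
| overlap-merge threshold | 0.8 | ω score | merges near-duplicate modules, ω(A,B) = \|A∩B\|² / (\|A\|·\|B\|) |
| hub fraction | 0.15 | of nodes | top of the degree ranking, ties at the cutoff included |
| random gene sets | k = 25, 10000 reps | — | chance level for the count of age- and survival-associated genes |

# The synthetic generator

`simConfig()` fixes the study conditions; `simAgingCohort()`,
`simTumorNormal()`, `simPPI()`, `simExpression()`, `simSurvival()` and
`simClinicalCohort()` draw from one master seed plus fixed per-operation
offsets, so each generator is independently reproducible and a fixed
seed fixes every output.

What it emulates: integer ages uniform on 16–88 with 394 samples (the
size and range of the aging cohort the method targets); multi-CpG gene
promoters (1–4 CpGs per gene); linear drift of magnitude 0.003/yr in a
20% subset with shared slope sign across a gene's CpGs; genes planted
to fail the consistency filter (CpGs straddling 0.5); seven
tumour/normal datasets with ±0.3 group-mean shifts, most of them
direction-concordant with the age drift; a preferential-attachment
(scale-free) PPI with a planted community among concordant genes plus a
few discordant (HL/LH) exceptions; expression negatively coupled to
promoter methylation of regulated genes (slope −2, noise 0.5); and a
218-patient clinical cohort whose exponential event times have hazard
baseline_hazard·exp(PI) with planted coefficients 0.5 on three
community genes, censored uniformly on (0, 120] months.

The default gene count is 2000 rather than the ~14500 genes of a real
27K array: it preserves every statistical feature that the callers see
(effect sizes, noise, network sparsity, multiplicity for BH) while
keeping a full pipeline run around a minute; the array scale is a
configuration choice away.

What it does **not** emulate: Infinium probe chemistry and detection
p-values, batch effects, cell-composition mixtures in whole blood,
age-dependent variance, non-linear drift, and correlated noise between
genes outside the planted community. Passing recovery tests therefore
demonstrates the correctness and calibration of the computational
chain — not robustness to those real-data artefacts; on real arrays
batch correction and cell-composition deconvolution remain the user's
responsibility upstream of this package.

One structural simplification: tumour/normal matrices are generated at
gene level. The CpG-to-gene aggregation path (and its consistency
filter) is exercised on the aging cohort, where the age-trajectory ×
boundary interaction makes it interesting; repeating probe-level
simulation for fourteen cancer matrices would add runtime without
adding tested behaviour.

A consequence worth knowing: a planted drift gene whose trajectory
crosses beta = 0.5 mid-cohort will often fail the consistency filter
with multi-CpG promoters — the filter is doing its job. Recovery
metrics for modules and markers are therefore computed over planted
genes that survive preprocessing, and the number retained is reported
alongside.

# Numerical choices and conventions

* **Boundary of "side of 0.5".** A CpG with beta exactly 0.5 counts as
  the high side ({≥ 0.5} vs {< 0.5}), matching the level rule "high if
  mean beta ≥ 0.5".
* **Permutation p smoothing.** Age-test p-values use the
  (1 + count)/(n_perm + 1) convention so p can never be 0. The
  random-gene-set test deliberately uses the *unsmoothed* count/reps
  fraction — that is the convention its reported chance levels assume.
* **Which p enters FDR.** Calling applies BH to the permutation
  p-values; permutation-FDR hybrids are a defensible alternative, and
  the raw-p switch covers the stricter reading where the unadjusted
  permutation p is thresholded directly. With 1000 permutations the
  smallest attainable q is n_genes/(1001·rank), so on very large gene
  sets BH at 0.01 needs more permutations — the limit is intentional
  and documented rather than silently worked around.
* **Per-gene vs shared permutations.** Each gene (and each network
  edge) draws its own permutations from one seeded stream, genes in row
  order and edges in sorted node-pair order. This keeps results
  order-independent and keeps null p-values independent across genes,
  so their calibration can be checked against binomial error.
* **ACWN edge rule.** The cancer-related network keeps the cDMGs and
  their direct neighbours; edges must touch at least one cDMG, so every
  included neighbour is justified by its cDMG link. The plain induced
  subgraph is available via `induced = TRUE`; which of the two the
  original analysis used is not determinable from its description.
* **Negative edge weights in modules.** The per-edge test is two-sided,
  so strong negative co-methylation is as informative as positive;
  cohesiveness requires non-negative weights, hence module detection
  uses |r|.
* **Greedy growth determinism.** Single best move per step (additions
  preferred, then lexicographic node id), strict improvement with an
  epsilon of 1e-12; module merging unions connected components of the
  overlap graph to a fixed point, which makes the merge order
  irrelevant.
* **Hub ties.** All nodes tied at the cutoff degree are hubs (a star
  graph's leaves are all included once one leaf is).
* **Median survival.** The earliest time at which the product-limit
  estimate drops to 0.5 or below; "not reached" (NA) when it never
  does. Patients exactly at the PI threshold go to the low-risk group;
  the threshold is always the *training* median.
* **Degenerate inputs.** Zero-variance profiles get r = 0 and p = 1;
  both group means zero sends the entropy to the complements; zero
  contingency cells flag the CI as undefined (no Haldane correction);
  tied expression means go to "down" with a warning; clipping of
  planted shifts outside [0, 1] warns and records the clipped mean.

# Design decisions that were genuinely open

* The entropy threshold (0.95 bits) and all module-detection parameters
  are not derivable from the method description; they are defaults
  calibrated once against the generator's planted effect sizes and
  exposed as arguments.
* Marker calling requires methylation/expression concordance in each
  cancer separately and reports the per-cancer marker assignments; the
  alternative (concordance in at least one cancer for a global call) is
  recoverable from the pattern map output.
* Gene entry into the prognostic index requires multivariate Cox
  p < 0.05 alongside age, sex and stage — candidates are not
  pre-screened univariately, since the clinical covariates are exactly
  what the multivariate model is there to adjust for.
* Expression direction uses the group-mean comparison only; a rank-sum
  filter would be easy to add but the marker definition is a direction,
  not a significance statement.

# Problem sizes used in the shipped checks

The test suite runs the full pipeline at 200 genes / 100 aging samples
/ 2 cancers / 218 patients with 1000 permutations, plus targeted
configurations per property (e.g. 500 genes × 200 samples for
aDMG-recovery calibration, 1000 null edges for retention calibration).
The acceptance script runs the default conditions: 2000 genes, 394
aging samples, 7 cancers, 218 patients, 1000 permutations per gene and
edge, 1000 random subnetworks and 10000 random gene sets. The
random-set draw size scales with the gene universe in the small test
configurations (k = 10 at 200 genes) so the chance level stays in the
regime the full design implies.

# Known limitations

* Entropy on group means ignores within-group variance; a mean shift of
  0.2 centred near beta = 0.5 scores ≈ 0.97 bits and is missed at the
  default threshold. The threshold is a dial, not a discovery.
* The greedy cohesiveness optimiser finds local optima; the test suite
  verifies it never beats (and on planted cliques matches) exhaustive
  enumeration on small graphs, not global optimality in general.
* Permutation resolution bounds the smallest q; see above.
* The generator's truth labels make sensitivity/precision measurable,
  but real cohorts add artefacts the generator excludes by design
  (batch, cellular heterogeneity); numbers obtained here bound the
  method's behaviour under its own assumptions only.
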