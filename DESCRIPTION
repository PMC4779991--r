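Package: methAgeNet
Title: Age-Associated DNA Methylation Drift, Co-Methylation Networks and
    Cancer Marker Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis linking age-associated DNA methylation
    drift to cancer-differential methylation. Collapses CpG-level beta
    values to gene level with a cross-CpG consistency filter, calls
    age-associated differentially methylated genes by permutation-tested
    linear regression, scores tumour-versus-normal differential
    methylation with a group-entropy statistic, builds a
    permutation-weighted co-methylation protein-interaction network,
    detects overlapping modules by greedy cohesiveness optimisation, maps
    HH/LL methylation patterns with expression concordance to call
    candidate markers, and evaluates prognostic value with Cox
    regression, a prognostic index and Kaplan-Meier analysis. Ships a
    synthetic-data generator emulating an aging methylation cohort,
    tumour/normal pairs, a scale-free interaction network, coupled
    expression and survival outcomes, with ground-truth labels for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    survival,
    ape,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
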