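# Shared small simulation configs and a memoised pipeline run reused by
# several test files.

tinyCfg <- function(...) {
    defaults <- list(n_genes = 200, n_aging_samples = 100, n_tumor = 20,
                     n_normal = 10, n_cancers = 2, ppi_n_extra_genes = 50,
                     n_patients = 218, seed = 11)
    args <- utils::modifyList(defaults, list(...))
    do.call(simConfig, args)
}

.pipeline_cache <- new.env(parent = emptyenv())

smallPipeline <- function() {
    if (is.null(.pipeline_cache$res)) {
        .pipeline_cache$res <- suppressWarnings(suppressMessages(
            runPipeline(tinyCfg(), nPerm = 1000, netPerm = 300,
                        subnetReps = 100, genesetReps = 1000, k = 10)))
    }
    .pipeline_cache$res
}
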