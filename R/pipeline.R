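#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates every stage on data from the synthetic generator: simulate
#' the aging cohort, collapse CpGs to genes with the consistency filter,
#' call age-associated DMGs (permutation-tested linear models, BH FDR),
#' call per-cancer entropy-based DMGs and their union, build the
#' permutation-weighted co-methylation network (ASWN) and its
#' cancer-related restriction (ACWN), detect cohesive modules, map HH/LL
#' patterns with expression concordance to call markers, and run the
#' prognostic-index survival analysis with the random-gene-set test.
#' Stages execute in dependency order
#' (simulate, preprocess, age, cancer, network, modules, markers,
#' survival); excluding a stage also skips everything downstream of it.
#' Every source of randomness derives from \code{seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSV/JSON plus a provenance manifest.
#' @param stages character vector of stages to run.
#' @param consistencyThreshold cross-CpG consistency threshold (0.8).
#' @param nPerm age-model permutations (1000).
#' @param fdr aDMG FDR threshold (0.01).
#' @param hThreshold entropy threshold in bits (0.95).
#' @param netPerm per-edge permutations (1000) and \code{tail} the
#'   retention tail (0.005).
#' @param tail per-edge retention tail.
#' @param clusterParams a \code{\link{cohesivenessParams}}.
#' @param hubFraction top-degree fraction defining hubs (0.15).
#' @param subnetReps random-subnetwork repetitions (1000).
#' @param k,genesetReps random gene-set test draw size (25) and
#'   repetitions (10000).
#' @param seed integer master seed (defaults to \code{cfg$seed}).
#' @return a list with one element per executed stage plus \code{truth},
#'   \code{recovery} (sensitivity/precision against the planted labels)
#'   and \code{manifest}.
#' @export
runPipeline <- function(cfg = simConfig(), outdir = NULL,
                        stages = c("simulate", "preprocess", "age",
                                   "cancer", "network", "modules",
                                   "markers", "survival"),
                        consistencyThreshold = 0.8, nPerm = 1000L,
                        fdr = 0.01, hThreshold = 0.95, netPerm = 1000L,
                        tail = 0.005,
                        clusterParams = cohesivenessParams(),
                        hubFraction = 0.15, subnetReps = 1000L,
                        k = 25L, genesetReps = 10000L, seed = cfg$seed) {
    all_stages <- c("simulate", "preprocess", "age", "cancer", "network",
                    "modules", "markers", "survival")
    run_until <- match(FALSE, all_stages %in% stages,
                       nomatch = length(all_stages) + 1L) - 1L
    active <- all_stages[seq_len(run_until)]
    res <- list()

    # simulate
    sim <- simAgingCohort(cfg)
    res$truth <- sim$truth
    res$simulate <- sim
    if (!"preprocess" %in% active) return(finishPipeline(res, cfg, outdir))

    # preprocess
    cpg <- dropMissingProbes(sim$betas)
    agg <- aggregateGenes(cpg, sim$annotation,
                          threshold = consistencyThreshold)
    res$preprocess <- agg
    genes <- agg$genes
    ages <- sampleAges(genes)
    if (!"age" %in% active) return(finishPipeline(res, cfg, outdir))

    # age-associated DMGs
    rec <- fitAgeModels(genes)
    rec$p_perm <- unname(permutationPValues(genes, nPerm = nPerm,
                                            seed = seed + 11L))
    rec <- callADMGs(rec, fdr = fdr)
    rec <- classifyCategory(rec, genes)
    cc <- categoryCounts(rec)
    assoc <- if (all(cc > 0))
        categoryAssociation(cc["a"], cc["b"], cc["c"], cc["d"]) else NULL
    admg_set <- rec$gene[rec$called]
    clust <- if (length(admg_set) >= 2)
        clusterAgeMeans(betaValues(genes)[admg_set, , drop = FALSE], ages)
        else NULL
    res$age <- list(records = rec, counts = cc, association = assoc,
                    admgs = admg_set, clustering = clust)
    if (!"cancer" %in% active) return(finishPipeline(res, cfg, outdir))

    # cancer DMGs
    tn_list <- lapply(seq_len(cfg$n_cancers), simTumorNormal, cfg = cfg)
    names(tn_list) <- names(sim$truth$cancer_dm_genes)
    keep <- rownames(betaValues(genes))
    cdmg_list <- lapply(tn_list, function(tn)
        callCDMGs(betaValues(tn$tumor)[keep, , drop = FALSE],
                  betaValues(tn$normal)[keep, , drop = FALSE],
                  hThreshold = hThreshold))
    age_p <- vapply(tn_list, function(tn)
        suppressWarnings(ageConfoundingCheck(
            sampleAges(tn$tumor), sampleAges(tn$normal))), numeric(1))
    cdmg_union <- unionCDMGs(cdmg_list)
    enrich <- genesetEnrichment(unique(cdmg_union$gene),
                                names(sim$truth$age_assoc_genes),
                                cfg$n_genes)
    res$cancer <- list(per_cancer = cdmg_list, union = cdmg_union,
                       age_check_p = age_p, enrichment = enrich)
    if (!"network" %in% active) return(finishPipeline(res, cfg, outdir))

    # co-methylation network
    ppi <- simPPI(cfg)
    aswn <- buildASWN(admg_set, ppi, genes, nPerm = netPerm, tail = tail,
                      seed = seed + 12L)
    cdmg_set <- unique(cdmg_union$gene)
    acwn <- extractACWN(aswn, cdmg_set)
    topo <- if (igraph::vcount(acwn) > 0) networkTopology(acwn) else NULL
    rand <- if (igraph::vcount(acwn) > 0)
        randomSubnetworks(ppi, igraph::vcount(acwn), reps = subnetReps,
                          seed = seed + 13L) else NULL
    hubs <- if (igraph::vcount(acwn) > 0) hubGenes(acwn, hubFraction)
        else character()
    res$network <- list(ppi = ppi, aswn = aswn, acwn = acwn,
                        topology = topo, random = rand, hubs = hubs)
    if (!"modules" %in% active) return(finishPipeline(res, cfg, outdir))

    # modules
    mods <- if (igraph::vcount(acwn) > 0) detectModules(acwn, clusterParams)
        else new("ModuleSet", modules = list(),
                 stats = data.frame(f = numeric(), density = numeric(),
                                    size = integer()),
                 params = unclass(clusterParams))
    res$modules <- mods
    if (!"markers" %in% active) return(finishPipeline(res, cfg, outdir))

    # markers: per-cancer expression coupled to the tumour/normal betas
    exprT <- exprN <- list()
    for (ci in seq_len(cfg$n_cancers)) {
        cn <- names(tn_list)[ci]
        cfg_i <- cfg
        cfg_i$seed <- cfg$seed + 1000L + ci  # distinct noise per cancer
        # one call per cancer so tumour and normal share per-gene baselines
        comb <- cbind(betaValues(tn_list[[ci]]$tumor),
                      betaValues(tn_list[[ci]]$normal))
        expr <- simExpression(comb, sim$truth$regulated_genes, cfg_i)
        n_t <- ncol(betaValues(tn_list[[ci]]$tumor))
        exprT[[cn]] <- expr[, seq_len(n_t), drop = FALSE]
        exprN[[cn]] <- expr[, -seq_len(n_t), drop = FALSE]
    }
    module_genes <- unique(unlist(moduleMembers(mods)))
    pmap <- buildPatternMap(module_genes, rec, cdmg_union, exprT, exprN)
    markers <- callMarkers(pmap)
    res$markers <- list(pattern_map = pmap, table = markers,
                        called = markers$gene[markers$is_marker])
    if (!"survival" %in% active) return(finishPipeline(res, cfg, outdir))

    # survival / prognostic index
    res$survival <- runSurvivalStage(cfg, res, keep, k, genesetReps, seed)
    finishPipeline(res, cfg, outdir)
}

runSurvivalStage <- function(cfg, res, keep, k, genesetReps, seed) {
    clin <- simClinicalCohort(cfg)
    b <- betaValues(clin$betas)[keep, , drop = FALSE]
    cd <- as.data.frame(colData(clin$betas))
    candidates <- res$markers$called
    if (!length(candidates)) {
        warning("no marker called; survival stage limited to the ",
                "random gene-set test")
    }
    idx <- withSeed(seed + 14L, sample.int(ncol(b)))
    n_train <- floor(ncol(b) / 2)
    train_i <- sort(idx[seq_len(n_train)])
    test_i <- sort(idx[-seq_len(n_train)])

    # gene-wise univariate screening over all genes (for the random-set
    # test's qualifying set)
    uni_p <- vapply(seq_len(nrow(b)), function(i) {
        d <- data.frame(time = cd$time[train_i], event = cd$event[train_i],
                        x = as.vector(scale(b[i, train_i])))
        if (stats::var(d$x) == 0) return(1)
        f <- tryCatch(survival::coxph(survival::Surv(time, event) ~ x,
                                      data = d, ties = "efron"),
                      error = function(e) NULL, warning = function(w) NULL)
        if (is.null(f)) 1 else summary(f)$coefficients[1, "Pr(>|z|)"]
    }, numeric(1))
    surv_assoc <- rownames(b)[uni_p < 0.05]
    qualifying <- intersect(res$age$admgs, surv_assoc)
    out <- list(surv_assoc = surv_assoc, qualifying = qualifying,
                pi_true = clin$pi_true, train = train_i, test = test_i)

    if (length(candidates)) {
        zs <- zscoreGenes(b[candidates, train_i, drop = FALSE],
                          b[candidates, test_i, drop = FALSE])
        dtr <- data.frame(time = cd$time[train_i],
                          event = cd$event[train_i],
                          age = cd$age[train_i], sex = cd$sex[train_i],
                          stage = cd$stage[train_i],
                          t(zs$train), check.names = FALSE)
        uni <- coxFit(dtr, c(candidates, "age", "sex", "stage"),
                      mode = "univariate")
        multi <- coxFit(dtr, c(candidates, "age", "sex", "stage"),
                        mode = "multivariate")
        sel <- multi$variable[multi$variable %in% candidates &
                              multi$p < 0.05]
        out$univariate <- uni
        out$multivariate <- multi
        out$selected <- sel
        if (length(sel)) {
            coefs <- stats::setNames(
                multi$coef[match(sel, multi$variable)], sel)
            pi_tr <- prognosticIndex(zs$train[sel, , drop = FALSE], coefs)
            pi_te <- prognosticIndex(zs$apply[sel, , drop = FALSE], coefs)
            thr <- stats::median(pi_tr)
            g_tr <- riskSplit(pi_tr, thr)
            g_te <- riskSplit(pi_te, thr)
            out$coefs <- coefs
            out$threshold <- thr
            out$km_train <- kmLogrank(g_tr, cd$time[train_i],
                                      cd$event[train_i])
            out$km_test <- tryCatch(
                kmLogrank(g_te, cd$time[test_i], cd$event[test_i]),
                error = function(e) NULL)
            out$observed <- length(intersect(sel, res$age$admgs))
        }
    }
    observed <- if (is.null(out$observed)) 0L else out$observed
    out$random_set <- randomGenesetTest(rownames(b), qualifying,
                                        observed = observed, k = k,
                                        reps = genesetReps,
                                        seed = seed + 15L)
    out
}

# Recovery metrics against the planted truth, provenance manifest, and
# optional TSV/JSON output.
finishPipeline <- function(res, cfg, outdir) {
    truth <- res$truth
    rec <- list()
    if (!is.null(res$preprocess)) {
        rep <- res$preprocess$report
        planted <- truth$inconsistent_genes
        rec$inconsistent_recovered <- if (length(planted))
            mean(!rep$retained[match(planted, rep$gene)]) else NA_real_
    }
    if (!is.null(res$age)) {
        called <- res$age$admgs
        pos <- intersect(names(truth$age_assoc_genes),
                         res$age$records$gene)
        rec$admg_sensitivity <- if (length(pos))
            length(intersect(called, pos)) / length(pos) else NA_real_
        rec$admg_fdr <- if (length(called))
            length(setdiff(called, pos)) / length(called) else NA_real_
    }
    if (!is.null(res$cancer)) {
        sens <- spec <- numeric(0)
        for (cn in names(res$cancer$per_cancer)) {
            d <- res$cancer$per_cancer[[cn]]
            pos <- intersect(names(truth$cancer_dm_genes[[cn]]), d$gene)
            neg <- setdiff(d$gene, pos)
            if (length(pos))
                sens <- c(sens, mean(d$is_dmg[match(pos, d$gene)]))
            if (length(neg))
                spec <- c(spec, mean(!d$is_dmg[match(neg, d$gene)]))
        }
        rec$cdmg_sensitivity <- if (length(sens)) mean(sens) else NA_real_
        rec$cdmg_specificity <- if (length(spec)) mean(spec) else NA_real_
    }
    # planted genes whose trajectories hover at the 0.5 boundary are
    # excluded by the consistency filter, so module- and marker-recovery
    # are measured over the planted genes still in the analysis universe
    analyzed <- if (!is.null(res$preprocess))
        res$preprocess$report$gene[res$preprocess$report$retained] else
        names(truth$age_assoc_genes)
    if (!is.null(res$modules) && length(res$modules) > 0 &&
        length(truth$community_members)) {
        comm <- intersect(truth$community_members, analyzed)
        jac <- vapply(moduleMembers(res$modules), function(m) {
            length(intersect(m, comm)) / length(union(m, comm))
        }, numeric(1))
        rec$module_community_jaccard <- max(jac)
    }
    if (!is.null(res$markers) && length(truth$marker_genes)) {
        called <- res$markers$called
        planted <- intersect(truth$marker_genes, analyzed)
        rec$marker_sensitivity <- if (length(planted))
            length(intersect(called, planted)) / length(planted) else
            NA_real_
        rec$n_planted_markers_retained <- length(planted)
        rec$discordant_called <-
            length(intersect(called, truth$discordant_genes))
    }
    res$recovery <- rec
    res$manifest <- list(
        package = "methAgeNet",
        version = as.character(utils::packageVersion("methAgeNet")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = cfg$seed,
        config = unclass(cfg),
        stages_run = setdiff(names(res), c("truth", "recovery",
                                           "manifest")),
        timestamp = NULL)
    if (!is.null(outdir)) writePipelineOutputs(res, outdir)
    res
}

writePipelineOutputs <- function(res, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(x, f) utils::write.table(
        x, file.path(outdir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(res$preprocess)) {
        b <- betaValues(res$preprocess$genes)
        tsv(data.frame(gene = rownames(b), b, check.names = FALSE),
            "gene_betas.tsv")
        tsv(res$preprocess$report, "consistency_report.tsv")
    }
    if (!is.null(res$age)) {
        tsv(res$age$records, "admg_table.tsv")
        if (!is.null(res$age$association))
            jsonlite::write_json(res$age$association,
                                 file.path(outdir, "category_association.json"),
                                 auto_unbox = TRUE, digits = NA)
        if (!is.null(res$age$clustering))
            ape::write.tree(res$age$clustering$tree,
                            file.path(outdir, "age_dendrogram.nwk"))
    }
    if (!is.null(res$cancer)) {
        tsv(res$cancer$union, "cdmg_union.tsv")
        jsonlite::write_json(res$cancer$enrichment,
                             file.path(outdir, "enrichment.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(res$network) && igraph::vcount(res$network$acwn) > 0) {
        el <- igraph::as_edgelist(res$network$acwn)
        tsv(data.frame(gene_a = el[, 1], gene_b = el[, 2],
                       weight = igraph::E(res$network$acwn)$weight),
            "acwn_edges.tsv")
    }
    if (!is.null(res$modules) && length(res$modules) > 0) {
        st <- moduleStats(res$modules)
        st$members <- vapply(moduleMembers(res$modules), paste,
                             character(1), collapse = ",")
        st$module_id <- seq_len(nrow(st))
        tsv(st[, c("module_id", "members", "f", "density", "size")],
            "modules.tsv")
    }
    if (!is.null(res$markers)) {
        tsv(res$markers$pattern_map, "pattern_map.tsv")
        tsv(res$markers$table, "markers.tsv")
    }
    if (!is.null(res$survival)) {
        s <- res$survival
        if (!is.null(s$multivariate)) tsv(s$multivariate, "cox_multi.tsv")
        if (!is.null(s$univariate)) tsv(s$univariate, "cox_uni.tsv")
        km <- list(random_set_p = s$random_set$p)
        if (!is.null(s$km_train))
            km$train <- list(p = s$km_train$p,
                             median = as.list(s$km_train$median_survival))
        if (!is.null(s$km_test))
            km$test <- list(p = s$km_test$p,
                            median = as.list(s$km_test$median_survival))
        jsonlite::write_json(km, file.path(outdir, "km_summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outdir)
}
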