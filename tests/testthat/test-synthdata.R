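test_that("generators are deterministic under a fixed seed", {
    cfg <- tinyCfg()
    a1 <- suppressMessages(simAgingCohort(cfg))
    a2 <- suppressMessages(simAgingCohort(cfg))
    expect_identical(betaValues(a1$betas), betaValues(a2$betas))
    expect_identical(a1$truth, a2$truth)
    t1 <- suppressWarnings(simTumorNormal(cfg, 1))
    t2 <- suppressWarnings(simTumorNormal(cfg, 1))
    expect_identical(betaValues(t1$tumor), betaValues(t2$tumor))
    expect_identical(simPPI(cfg), simPPI(cfg))
    s1 <- simSurvival(rep(0, 50), cfg)
    expect_identical(s1, simSurvival(rep(0, 50), cfg))
})

test_that("zero-noise aging cohort is exactly linear in age", {
    cfg <- tinyCfg(noise_sd = 0, slope_magnitude = 0.005,
                   frac_inconsistent_genes = 0)
    sim <- simAgingCohort(cfg)
    b <- betaValues(sim$betas)
    ages <- sampleAges(sim$betas)
    ann <- sim$annotation
    g <- names(sim$truth$age_assoc_genes)[1]
    slope <- sim$truth$age_assoc_genes[[g]]
    row <- ann$cpg_id[ann$gene_symbol == g][1]
    # any two samples differ by exactly slope * (age difference)
    i <- which(ages == min(ages))[1]; j <- which(ages == max(ages))[1]
    expect_equal(b[row, j] - b[row, i], slope * (ages[j] - ages[i]),
                 tolerance = 1e-12)
    # fitted OLS slope recovers the planted slope exactly
    fit <- fitAgeModels(b[row, , drop = FALSE], ages)
    expect_equal(fit$slope, slope, tolerance = 1e-12)
    expect_equal(abs(fit$r), 1, tolerance = 1e-12)
})

test_that("with no planted age effect, per-gene slopes are null", {
    cfg <- tinyCfg(frac_age_assoc = 0, planted_community_size = 0,
                   n_discordant = 0, n_risky = 0,
                   frac_inconsistent_genes = 0)
    sim <- simAgingCohort(cfg)
    expect_length(sim$truth$age_assoc_genes, 0)
    b <- betaValues(sim$betas)
    ages <- sampleAges(sim$betas)
    fit <- fitAgeModels(b, ages)
    se <- cfg$noise_sd / sqrt(sum((ages - mean(ages))^2))
    expect_lt(mean(abs(fit$slope)), 3 * se)
})

test_that("tumour/normal shifts equal the planted effect", {
    cfg <- tinyCfg(noise_sd = 0)
    tn <- suppressWarnings(simTumorNormal(cfg, 1))
    dm <- tn$truth$cancer_dm_genes[[1]]
    bt <- rowMeans(betaValues(tn$tumor))
    bn <- rowMeans(betaValues(tn$normal))
    diffs <- bt[names(dm)] - bn[names(dm)]
    # unclipped genes shift by exactly +/- dm_effect in the planted
    # direction
    unclipped <- abs(abs(diffs) - cfg$dm_effect) < 1e-12
    expect_gte(mean(unclipped), 0.8)
    expect_true(all(sign(diffs[dm == "hyper"]) > 0))
    expect_true(all(sign(diffs[dm == "hypo"]) < 0))
    # non-DM genes do not move
    others <- setdiff(names(bt), names(dm))
    expect_equal(unname(bt[others]), unname(bn[others]), tolerance = 1e-12)
})

test_that("dm_effect = 0 plants no cancer DM gene", {
    cfg <- tinyCfg(dm_effect = 0)
    tn <- simTumorNormal(cfg, 1)
    expect_length(tn$truth$cancer_dm_genes[[1]], 0)
})

test_that("simulated interaction network is simple, clique-planted and heavy-tailed", {
    cfg <- tinyCfg(planted_community_size = 5, n_discordant = 0)
    ppi <- simPPI(cfg)
    expect_true(all(ppi$gene_a != ppi$gene_b))
    expect_false(any(duplicated(paste(ppi$gene_a, ppi$gene_b))))
    comm <- sort(c(simTruth(cfg)$community_members))
    key <- paste(ppi$gene_a, ppi$gene_b)
    pairs <- utils::combn(comm, 2)
    expect_true(all(paste(pairs[1, ], pairs[2, ]) %in% key))
    expect_identical(sum(paste(pairs[1, ], pairs[2, ]) %in% key), 10L)
    # heavy tail of the degree distribution at n >= 500, m = 2
    big <- simPPI(simConfig(n_genes = 400, ppi_n_extra_genes = 150,
                            ppi_attachment = 2, seed = 5))
    deg <- table(c(big$gene_a, big$gene_b))
    expect_gt(max(deg), 3 * stats::median(deg))
})

test_that("expression is negatively coupled to methylation of regulated genes", {
    cfg <- tinyCfg(expr_noise_sd = 0, expr_slope = -2)
    b <- matrix(c(0.1, 0.6), 1, 2, dimnames = list("G1", c("s1", "s2")))
    e <- simExpression(b, "G1", cfg)
    expect_equal(e[1, 1] - e[1, 2], 1.0, tolerance = 1e-12)

    cfg2 <- tinyCfg(expr_noise_sd = 0.01)
    sim <- suppressMessages(simAgingCohort(cfg2))
    agg <- suppressMessages(aggregateGenes(sim$betas, sim$annotation))
    gb <- betaValues(agg$genes)[, 1:100]
    reg <- intersect(sim$truth$regulated_genes, rownames(gb))
    ex <- simExpression(gb, reg, cfg2)
    rs <- vapply(reg, function(g) stats::cor(gb[g, ], ex[g, ]), numeric(1))
    expect_true(all(rs < -0.9))
    unreg <- setdiff(rownames(gb), reg)[1:50]
    ru <- vapply(unreg, function(g) stats::cor(gb[g, ], ex[g, ]),
                 numeric(1))
    expect_true(all(abs(ru) < 0.3))
})

test_that("survival times follow the planted hazard model", {
    cfg <- tinyCfg(baseline_hazard = 0.02, censor_time_max = 1e7)
    s <- simSurvival(rep(0, 10000), cfg)
    mu <- 1 / cfg$baseline_hazard
    expect_lt(abs(mean(s$time) - mu), 3 * mu / sqrt(10000))
    expect_true(all(s$time > 0))

    cfg2 <- tinyCfg(censor_time_max = 1e6)
    s2 <- simSurvival(c(rep(1, 500), rep(-1, 500)), cfg2)
    w <- stats::wilcox.test(s2$time[1:500], s2$time[501:1000],
                            alternative = "less")
    expect_lt(w$p.value, 1e-10)

    s3 <- simSurvival(rep(0, 100), tinyCfg(censor_time_max = 1e-4))
    expect_true(all(s3$event == 0))
    expect_error(simSurvival(rep(0, 5), tinyCfg(baseline_hazard = 0)),
                 "baseline_hazard")
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(frac_age_assoc = 1.2), "fractions")
    expect_error(simConfig(age_range = c(50, 30)), "age_range")
    expect_error(simConfig(n_genes = 10, frac_age_assoc = 0.9,
                           frac_inconsistent_genes = 0.5), "planted")
    expect_error(simConfig(n_genes = 20, frac_age_assoc = 0.2,
                           planted_community_size = 8), "community")
})
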