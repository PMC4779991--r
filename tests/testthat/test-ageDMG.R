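test_that("OLS age models match hand computation", {
    fit <- fitAgeModels(rbind(g = c(0.2, 0.3, 0.4, 0.5)), c(20, 40, 60, 80))
    expect_equal(fit$slope, 0.005, tolerance = 1e-12)
    expect_equal(fit$r, 1, tolerance = 1e-12)
    expect_equal(fit$intercept, 0.1, tolerance = 1e-12)

    fit2 <- fitAgeModels(rbind(g = rep(0.4, 5)), c(20, 30, 40, 50, 60))
    expect_equal(fit2$slope, 0)
    expect_equal(fit2$r, 0)

    ages <- c(25, 35, 50, 72)
    fit3 <- fitAgeModels(rbind(g = -0.001 * ages + 0.5), ages)
    expect_equal(fit3$slope, -0.001, tolerance = 1e-12)
    expect_equal(fit3$r, -1, tolerance = 1e-12)

    expect_error(fitAgeModels(rbind(g = c(0.1, 0.2, 0.3)), c(50, 50, 50)),
                 "ages")
})

test_that("permutation p-values hit the smoothing floor and are reproducible", {
    ages <- seq_len(100)
    b <- rbind(lin = 0.002 * ages + 0.2)
    p <- permutationPValues(b, ages, nPerm = 1000, seed = 7)
    expect_equal(unname(p), 1 / 1001)
    expect_identical(p, permutationPValues(b, ages, nPerm = 1000, seed = 7))
    expect_error(permutationPValues(b, ages, nPerm = 0), "nPerm")
    # p is bounded below by 1/(nPerm+1) and above by 1
    expect_true(all(p >= 1 / 1001 & p <= 1))
})

test_that("BH calling matches hand-applied Benjamini-Hochberg", {
    rec <- data.frame(gene = sprintf("g%03d", 1:100), slope = 0.001,
                      intercept = 0.2, r = 0.5)
    rec$p_perm <- c(1 / 1001, rep(1, 99))
    out <- callADMGs(rec, fdr = 0.01)
    # q = 100 * (1/1001) / 1 = 0.0999 -> NOT called at 0.01
    expect_equal(out$q[1], 100 / 1001, tolerance = 1e-12)
    expect_false(out$called[1])
    out10 <- callADMGs(rec[1:10, ], fdr = 0.01)
    # q = 10/1001 = 0.00999 -> called
    expect_true(out10$called[1])
    expect_identical(out10$direction[1], "hyper")
    # all p = 1 -> no calls; q non-decreasing in p
    allone <- callADMGs(transform(rec, p_perm = 1))
    expect_false(any(allone$called))
    expect_true(all(diff(out$q[order(out$p_perm)]) >= -1e-12))
    expect_error(callADMGs(rec[0, ]), "empty")
})

test_that("level and category classification follow the beta >= 0.5 rule", {
    b <- rbind(gHi = rep(0.5, 4), gLo = rep(0.3, 4), gHyp = rep(0.8, 4))
    rec <- data.frame(gene = c("gHi", "gLo", "gHyp"),
                      slope = c(0.001, 0.001, -0.001),
                      direction = c("hyper", "hyper", "hypo"))
    out <- classifyCategory(rec, b)
    expect_identical(out$level, c("high", "low", "high"))
    expect_identical(out$category,
                     c("hyper-high", "hyper-low", "hypo-high"))
    rec$direction <- "none"
    expect_true(all(classifyCategory(rec, b)$category == "none"))
})

test_that("category association reproduces the odds ratio arithmetic", {
    res <- categoryAssociation(1, 1, 1, 1)
    expect_equal(res$odds_ratio, 1)
    res2 <- categoryAssociation(10, 20, 20, 10)
    expect_equal(res2$odds_ratio, 4)
    expect_true(res2$ci_low <= res2$odds_ratio &
                res2$odds_ratio <= res2$ci_high)
    expect_warning(categoryAssociation(0, 5, 5, 5), "zero cell")
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
    tabs <- list(c(3, 7, 12, 2), c(1, 9, 5, 5), c(10, 10, 10, 10),
                 c(2, 25, 18, 4), c(30, 1, 6, 22))
    for (t in tabs) {
        got <- categoryAssociation(t[1], t[2], t[3], t[4])$p
        want <- fisherEnumOracle(t[1], t[2], t[3], t[4])
        expect_equal(got, want, tolerance = 1e-8)
    }
})

test_that("favoured-category proportion counts hyper-low and hypo-high genes", {
    cats <- c(rep("hyper-low", 3), rep("hypo-high", 1),
              rep("hyper-high", 2), rep("none", 5))
    expect_equal(favoredCategoryProportion(cats), 4 / 6)
    expect_true(is.na(favoredCategoryProportion(rep("none", 3))))
})

test_that("age-mean clustering merges identical profiles first and is order invariant", {
    set.seed(1)
    prof <- matrix(runif(40), 10, 4)
    prof[, 2] <- prof[, 1]  # ages 1 and 2 share a profile
    ages <- c(30, 40, 50, 60)
    b <- prof[, c(1, 2, 3, 4)]
    rownames(b) <- paste0("g", 1:10); colnames(b) <- paste0("s", 1:4)
    cl <- clusterAgeMeans(b, ages)
    expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
    first <- sort(abs(cl$hclust$merge[1, ]))
    expect_identical(cl$ages[first], c(30, 40))
    # permuting sample columns does not change the 2-way partition
    perm <- c(3, 1, 4, 2)
    cl2 <- clusterAgeMeans(b[, perm], ages[perm])
    expect_identical(cl$partition, cl2$partition)
    expect_error(clusterAgeMeans(b[, 1, drop = FALSE], 30), "unique ages")
})

test_that("a planted regime change at age 50 splits the age dendrogram", {
    cfg <- simConfig(n_genes = 150, n_aging_samples = 200,
                     frac_age_assoc = 0.3, slope_magnitude = 0.0005,
                     age_step_effect = 0.15, age_step_at = 50,
                     frac_inconsistent_genes = 0, seed = 21)
    sim <- suppressMessages(simAgingCohort(cfg))
    agg <- suppressMessages(aggregateGenes(sim$betas, sim$annotation))
    admg <- intersect(names(sim$truth$age_assoc_genes),
                      rownames(betaValues(agg$genes)))
    cl <- clusterAgeMeans(betaValues(agg$genes)[admg, ],
                          sampleAges(agg$genes))
    split_lab <- ifelse(cl$ages >= 50, 1, 2)
    mis <- min(sum(cl$partition != split_lab),
               sum(cl$partition != 3 - split_lab))
    expect_lte(mis, 1)
})
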