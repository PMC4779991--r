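test_that("z-scoring uses training parameters on both sets", {
    z <- zscoreTrainApply(c(1, 2, 3), c(4))
    expect_equal(z$apply, 2)  # sample sd of train = 1
    expect_equal(mean(z$train), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z$train), 1, tolerance = 1e-12)
    # a constant shift of the apply set moves z by shift/sd_train
    z2 <- zscoreTrainApply(c(1, 2, 3), c(4) + 5)
    expect_equal(z2$apply - z$apply, 5)
    expect_error(zscoreTrainApply(c(2, 2, 2)), "zero training variance")
})

test_that("Cox fits report hr = exp(coef) and recover planted effects", {
    set.seed(31)
    cfg <- tinyCfg(baseline_hazard = 0.02, censor_time_max = 120)
    x <- rnorm(500)
    d <- cbind(simSurvival(0.5 * x, cfg), x = x)
    fit <- coxFit(d, "x", mode = "univariate")
    expect_equal(fit$hr, exp(fit$coef), tolerance = 1e-12)
    expect_true(fit$risky)
    expect_lt(abs(fit$coef - 0.5), 0.15)
    expect_error(coxFit(transform(d, event = 0), "x"), "2 events")
    expect_error(coxFit(transform(d, x = 1), "x"), "constant")
})

test_that("a covariate independent of the hazard has nominal CI coverage", {
    cfg <- tinyCfg()
    cover <- logical(50)
    set.seed(77)
    for (i in 1:50) {
        x <- rnorm(100); noisevar <- rnorm(100)
        cfg$seed <- 500L + i
        d <- cbind(simSurvival(0.5 * x, cfg), x = x, z = noisevar)
        fit <- coxFit(d, c("x", "z"), mode = "multivariate")
        zi <- fit[fit$variable == "z", ]
        cover[i] <- zi$ci_low <= 1 && 1 <= zi$ci_high  # HR CI covers 1
    }
    expect_gte(mean(cover), 0.9)
})

test_that("the prognostic index is the coefficient-weighted z sum", {
    z <- matrix(0, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
    expect_equal(prognosticIndex(z, c(g1 = 1, g2 = 2, g3 = 3)),
                 rep(0, 4))
    z1 <- matrix(1, 1, 1, dimnames = list("g1", "p"))
    expect_equal(prognosticIndex(z1, c(g1 = 0.45)), 0.45)
    z3 <- matrix(c(1, -1, 0), 3, 1,
                 dimnames = list(c("g1", "g2", "g3"), "p"))
    expect_equal(prognosticIndex(z3, c(g1 = 0.450, g2 = 0.522, g3 = 0.467)),
                 -0.072, tolerance = 1e-12)
    expect_error(prognosticIndex(z3, c(g1 = 1)), "do not match")
})

test_that("risk split is threshold-inclusive to low and uses the training median", {
    pi <- c(-2, -1, 0, 1, 2)
    g <- riskSplit(pi)
    expect_identical(as.character(g), c("low", "low", "low", "high", "high"))
    expect_warning(g2 <- riskSplit(rep(1, 4)), "low-risk")
    expect_true(all(g2 == "low"))
    # a test set is split at the training threshold, not its own median
    test_pi <- c(10, 11, 12)
    expect_true(all(riskSplit(test_pi, threshold = 0) == "high"))
})

test_that("Kaplan-Meier matches the empirical survival without censoring", {
    time <- c(1, 2, 3, 4, 1, 2, 3, 4)
    event <- rep(1, 8)
    group <- factor(rep(c("low", "high"), each = 4))
    km <- kmLogrank(group, time, event)
    # identical groups: log-rank statistic 0, p = 1
    expect_equal(km$chisq, 0, tolerance = 1e-9)
    expect_equal(km$p, 1, tolerance = 1e-6)
    # no censoring: S steps through the empirical survival; median is the
    # earliest time with S <= 0.5
    s <- km$fit$surv[1:4]
    expect_equal(s, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
    expect_equal(unname(km$median_survival), c(2, 2))
    # a group with no events has an undefined (not reached) median
    km2 <- kmLogrank(factor(c("a", "a", "b", "b")),
                     c(5, 6, 7, 8), c(1, 1, 0, 0))
    expect_true(is.na(km2$median_survival["b"]))
    expect_error(kmLogrank(factor(rep("a", 3)), 1:3, rep(1, 3)),
                 "two non-empty groups")
})

test_that("risk groups separate survival when the hazard depends on the score", {
    cfg <- tinyCfg(censor_time_max = 240)
    pi <- rep(c(0.5, -0.5), each = 200)  # hazard ratio e between groups
    s <- simSurvival(pi, cfg)
    g <- riskSplit(pi, threshold = 0)
    km <- kmLogrank(g, s$time, s$event)
    expect_lt(km$p, 0.01)
    expect_lt(km$median_survival["high"], km$median_survival["low"])
})

test_that("the random gene-set test uses the plain count convention", {
    genes <- paste0("g", 1:200)
    qual <- genes[1:40]
    r <- randomGenesetTest(genes, qual, observed = 0, k = 10, reps = 500,
                           seed = 3)
    expect_equal(r$p, 1)
    r2 <- randomGenesetTest(genes, genes, observed = 10, k = 10,
                            reps = 200, seed = 3)
    expect_equal(r2$p, 1)
    # p is exactly the unsmoothed fraction of qualifying repetitions
    r3 <- randomGenesetTest(genes, qual, observed = 4, k = 10, reps = 1000,
                            seed = 9)
    expect_equal(r3$p, sum(r3$counts >= 4) / 1000)
    expect_identical(r3$counts,
                     randomGenesetTest(genes, qual, observed = 4, k = 10,
                                       reps = 1000, seed = 9)$counts)
    expect_error(randomGenesetTest(genes, qual, 1, k = 300), "exceeds")
})

test_that("the empirical random-set p matches the exact tail probability", {
    genes <- paste0("g", 1:10000)
    qual <- genes[1:1000]  # per-gene qualifying probability 0.1
    obs <- 5
    r <- randomGenesetTest(genes, qual, observed = obs, k = 25,
                           reps = 10000, seed = 13)
    exact <- stats::phyper(obs - 1, 1000, 9000, 25, lower.tail = FALSE)
    expect_lt(abs(r$p - exact), 0.015)
    # binomial approximation agrees at this scale
    expect_lt(abs(exact - stats::pbinom(obs - 1, 25, 0.1,
                                        lower.tail = FALSE)), 0.005)
})
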