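#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: an aging whole-blood
#' methylation cohort of 394 individuals aged 16 to 88 (27K-array-style
#' multi-CpG gene promoters), seven tumour/normal cancer datasets, a
#' scale-free protein-interaction network with a planted dense community
#' among true positives, expression negatively coupled to promoter
#' methylation of regulated genes, and survival times whose hazard depends
#' on a linear risk score. Gene count defaults to 2000 (desk scale; the
#' full 27K array annotates ~14500 genes and can be requested explicitly).
#'
#' @param n_aging_samples number of healthy aging samples.
#' @param age_range integer years, \code{c(min, max)} with min < max.
#' @param n_genes number of simulated genes.
#' @param cpgs_per_gene_range \code{c(min, max)} CpG probes per gene.
#' @param frac_age_assoc fraction of genes with a planted linear age drift.
#' @param slope_magnitude planted |slope| in beta units per year.
#' @param noise_sd Gaussian noise sd in beta units (values clipped to [0,1]).
#' @param frac_inconsistent_genes fraction of genes planted to fail the
#'   cross-CpG consistency filter (their CpGs straddle 0.5).
#' @param n_tumor,n_normal samples per cancer dataset.
#' @param n_cancers number of cancer types.
#' @param frac_cancer_dm fraction of genes differentially methylated per
#'   cancer.
#' @param frac_dm_concordant fraction of each cancer's DM genes drawn from
#'   age-associated genes with the cancer shift in the same direction as the
#'   age drift (the HH/LL mechanism).
#' @param dm_effect tumour-vs-normal group mean shift in beta units.
#' @param ppi_n_extra_genes interaction-network genes beyond the simulated
#'   methylation universe.
#' @param ppi_attachment preferential-attachment edges per added node.
#' @param planted_community_size size of the planted near-clique of
#'   concordant age+cancer genes.
#' @param n_discordant number of planted genes whose cancer shift opposes
#'   their age drift (HL/LH exceptions), added to the planted community.
#' @param expr_slope expression units per beta unit for regulated genes
#'   (negative: methylation represses expression).
#' @param expr_noise_sd expression noise sd for regulated genes.
#' @param baseline_hazard per-month exponential event rate at risk score 0.
#' @param censor_time_max months; censoring uniform on (0, max].
#' @param n_patients clinical-cohort size for survival analysis.
#' @param n_risky number of planted survival-associated genes (drawn from
#'   the community) and \code{risk_coef} their log-hazard per z unit.
#' @param risk_coef planted Cox coefficient of risky genes.
#' @param age_step_effect optional extra mean shift (beta units) applied to
#'   age-associated genes at ages >= \code{age_step_at}; 0 disables it.
#' @param age_step_at years.
#' @param seed integer master seed; each generator draws from
#'   \code{seed + op offset} so individual generators are independently
#'   reproducible.
#' @return a list of class \code{"simConfig"}.
#' @examples
#' cfg <- simConfig(n_genes = 100, n_aging_samples = 40, seed = 7)
#' sim <- simAgingCohort(cfg)
#' dim(betaValues(sim$betas))
#' @export
simConfig <- function(n_aging_samples = 394L,
                      age_range = c(16L, 88L),
                      n_genes = 2000L,
                      cpgs_per_gene_range = c(1L, 4L),
                      frac_age_assoc = 0.2,
                      slope_magnitude = 0.003,
                      noise_sd = 0.05,
                      frac_inconsistent_genes = 0.05,
                      n_tumor = 50L,
                      n_normal = 25L,
                      n_cancers = 7L,
                      frac_cancer_dm = 0.10,
                      frac_dm_concordant = 0.8,
                      dm_effect = 0.3,
                      ppi_n_extra_genes = 300L,
                      ppi_attachment = 2L,
                      planted_community_size = 8L,
                      n_discordant = 2L,
                      expr_slope = -2,
                      expr_noise_sd = 0.5,
                      baseline_hazard = 0.02,
                      censor_time_max = 120,
                      n_patients = 218L,
                      n_risky = 3L,
                      risk_coef = 0.5,
                      age_step_effect = 0,
                      age_step_at = 50,
                      seed = 1L) {
    cfg <- as.list(environment())
    fracs <- c(frac_age_assoc, frac_inconsistent_genes, frac_cancer_dm,
               frac_dm_concordant)
    if (any(fracs < 0 | fracs > 1))
        stop("all fractions must lie in [0, 1]")
    counts <- c(n_aging_samples, n_genes, n_tumor, n_normal, n_cancers,
                n_patients)
    if (any(counts < 1))
        stop("all counts must be >= 1")
    if (length(age_range) != 2L || age_range[1] >= age_range[2])
        stop("age_range must be c(min, max) with min < max")
    if (cpgs_per_gene_range[1] < 1 ||
        cpgs_per_gene_range[1] > cpgs_per_gene_range[2])
        stop("invalid cpgs_per_gene_range")
    n_age <- round(frac_age_assoc * n_genes)
    n_inc <- round(frac_inconsistent_genes * n_genes)
    if (n_age + n_inc > n_genes)
        stop("n_genes is smaller than the planted fractions imply")
    if (n_age > 0 && planted_community_size + n_discordant > n_age)
        stop("planted community exceeds the number of age-associated genes")
    class(cfg) <- "simConfig"
    cfg
}

#' @export
print.simConfig <- function(x, ...) {
    cat("simConfig:", x$n_genes, "genes,", x$n_aging_samples,
        "aging samples (ages", x$age_range[1], "-", x$age_range[2], "),",
        x$n_cancers, "cancers, seed", x$seed, "\n")
    invisible(x)
}

# Deterministic per-gene ground truth shared by all generator ops: gene ids,
# CpG counts, planted age slopes and baselines, per-cancer DM assignments,
# the planted community, risky genes. Drawn from the master seed (offset 0)
# so every generator sees the same labels.
geneParams <- function(cfg) {
    withSeed(cfg$seed, {
        n <- cfg$n_genes
        ids <- sprintf("G%05d", seq_len(n))
        rng <- cfg$cpgs_per_gene_range
        n_cpgs <- if (rng[1] == rng[2]) rep(rng[1], n) else
            sample(seq(rng[1], rng[2]), n, replace = TRUE)

        n_age <- round(cfg$frac_age_assoc * n)
        age_genes <- if (n_age > 0) sort(sample(ids, n_age)) else character()
        sign_age <- stats::setNames(
            sample(c(-1, 1), n_age, replace = TRUE), age_genes)
        slopes <- sign_age * cfg$slope_magnitude
        span <- cfg$slope_magnitude * diff(cfg$age_range)

        # baseline beta at the youngest age, kept clear of [0,1] so the
        # zero-noise trajectory never clips
        base <- stats::setNames(stats::runif(n, 0.05, 0.95), ids)
        if (n_age > 0) {
            hyper <- age_genes[sign_age > 0]
            hypo <- age_genes[sign_age < 0]
            base[hyper] <- stats::runif(length(hyper), 0.05,
                                        max(0.95 - span, 0.06))
            base[hypo] <- stats::runif(length(hypo),
                                       min(0.05 + span, 0.94), 0.95)
        }
        gene_mean <- base
        gene_mean[age_genes] <- base[age_genes] + slopes[age_genes] *
            diff(cfg$age_range) / 2

        n_inc <- round(cfg$frac_inconsistent_genes * n)
        pool <- setdiff(ids, age_genes)
        inconsistent <- if (n_inc > 0) sort(sample(pool, n_inc)) else
            character()
        n_cpgs[match(inconsistent, ids)] <-
            pmax(n_cpgs[match(inconsistent, ids)], 2L)

        # planted community: concordant age+cancer genes plus a few
        # discordant (HL/LH) exceptions
        community <- character(); discordant <- character()
        if (n_age >= cfg$planted_community_size + cfg$n_discordant &&
            cfg$planted_community_size > 0) {
            community <- sort(sample(age_genes, cfg$planted_community_size))
            if (cfg$n_discordant > 0)
                discordant <- sort(sample(setdiff(age_genes, community),
                                          cfg$n_discordant))
        }

        cancer_dm <- vector("list", cfg$n_cancers)
        names(cancer_dm) <- sprintf("cancer%02d", seq_len(cfg$n_cancers))
        if (cfg$dm_effect > 0) {
            n_dm <- round(cfg$frac_cancer_dm * n)
            for (ci in seq_len(cfg$n_cancers)) {
                dirs <- c(stats::setNames(ifelse(sign_age[community] > 0,
                                                 "hyper", "hypo"), community),
                          stats::setNames(ifelse(sign_age[discordant] > 0,
                                                 "hypo", "hyper"), discordant))
                remaining <- max(n_dm - length(dirs), 0)
                n_conc <- round(cfg$frac_dm_concordant * remaining)
                free_age <- setdiff(age_genes, c(community, discordant))
                conc <- sample(free_age, min(n_conc, length(free_age)))
                dirs <- c(dirs, stats::setNames(
                    ifelse(sign_age[conc] > 0, "hyper", "hypo"), conc))
                free <- setdiff(ids, names(dirs))
                rand <- sample(free, min(remaining - length(conc),
                                         length(free)))
                dirs <- c(dirs, stats::setNames(
                    sample(c("hyper", "hypo"), length(rand), replace = TRUE),
                    rand))
                cancer_dm[[ci]] <- dirs
            }
        } else {
            cancer_dm <- lapply(cancer_dm, function(z) stats::setNames(
                character(), character()))
        }

        risky <- character()
        if (length(community) >= cfg$n_risky && cfg$n_risky > 0)
            risky <- sort(sample(community, cfg$n_risky))
        risky_coefs <- stats::setNames(rep(cfg$risk_coef, length(risky)),
                                       risky)

        list(ids = ids, n_cpgs = n_cpgs, age_genes = age_genes,
             slopes = slopes, base = base, gene_mean = gene_mean,
             inconsistent = inconsistent, community = community,
             discordant = discordant, cancer_dm = cancer_dm,
             risky_coefs = risky_coefs,
             regulated = c(community, discordant))
    })
}

# Assemble the user-facing truth labels from geneParams output.
truthFromParams <- function(gp) {
    list(age_assoc_genes = gp$slopes,
         cancer_dm_genes = gp$cancer_dm,
         community_members = c(gp$community, gp$discordant),
         marker_genes = gp$community,
         discordant_genes = gp$discordant,
         risky_genes = gp$risky_coefs,
         inconsistent_genes = gp$inconsistent,
         regulated_genes = gp$regulated)
}

#' Ground-truth labels for a simulation configuration
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with planted gene sets: signed age slopes, per-cancer DM
#'   directions, community members, marker (concordant community) genes,
#'   discordant (HL/LH) genes, risky genes with hazard coefficients,
#'   inconsistent genes and expression-regulated genes.
#' @export
simTruth <- function(cfg) truthFromParams(geneParams(cfg))

#' Simulate the aging methylation cohort at CpG level
#'
#' Ages are drawn uniformly (integer years) on \code{age_range}. CpGs of an
#' age-associated gene follow
#' \eqn{\beta = clip(base + slope (age - age_{min}) + N(0, \sigma), 0, 1)}
#' with a shared slope sign across the gene's CpGs; other genes have
#' age-constant means. Genes planted as inconsistent get CpGs on opposite
#' sides of 0.5 so the consistency filter removes them.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{betas} (CpG-level \linkS4class{BetaSet}),
#'   \code{annotation} (data.frame \code{cpg_id}, \code{gene_symbol}) and
#'   \code{truth} (see \code{\link{simTruth}}).
#' @export
simAgingCohort <- function(cfg) {
    gp <- geneParams(cfg)
    withSeed(cfg$seed + 1L, {
        n <- cfg$n_aging_samples
        ages <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n,
                       replace = TRUE)
        sample_ids <- sprintf("A%04d", seq_len(n))

        gene_means <- matrix(rep(gp$base, n), nrow = cfg$n_genes,
                             dimnames = list(gp$ids, sample_ids))
        if (length(gp$age_genes)) {
            drift <- outer(gp$slopes[gp$age_genes],
                           ages - cfg$age_range[1])
            gene_means[gp$age_genes, ] <-
                gene_means[gp$age_genes, , drop = FALSE] + drift
            if (cfg$age_step_effect != 0) {
                step <- outer(sign(gp$slopes[gp$age_genes]) *
                              cfg$age_step_effect,
                              as.numeric(ages >= cfg$age_step_at))
                gene_means[gp$age_genes, ] <-
                    gene_means[gp$age_genes, , drop = FALSE] + step
            }
        }

        cpg_gene <- rep(gp$ids, gp$n_cpgs)
        cpg_ids <- paste0(cpg_gene, "_cg",
                          unlist(lapply(gp$n_cpgs, seq_len)))
        mu <- gene_means[cpg_gene, , drop = FALSE]
        rownames(mu) <- cpg_ids

        # inconsistent genes: CpGs alternate around 0.5 in every sample
        for (g in gp$inconsistent) {
            rows <- which(cpg_gene == g)
            lev <- rep(c(0.72, 0.28), length.out = length(rows))
            mu[rows, ] <- matrix(rep(lev, ncol(mu)), nrow = length(rows))
        }

        raw <- mu + matrix(stats::rnorm(length(mu), sd = cfg$noise_sd),
                           nrow = nrow(mu))
        clipped <- mean(raw < 0 | raw > 1)
        if (clipped > 0)
            message(sprintf("simAgingCohort: clipped %.2f%% of beta values",
                            100 * clipped))
        beta <- clip01(raw)

        meta <- DataFrame(age = ages, group = "healthy",
                          sex = sample(c("M", "F"), n, replace = TRUE),
                          row.names = sample_ids)
        list(betas = BetaSet(beta, meta),
             annotation = data.frame(cpg_id = cpg_ids,
                                     gene_symbol = cpg_gene,
                                     stringsAsFactors = FALSE),
             truth = truthFromParams(gp))
    })
}

#' Simulate one tumour/normal gene-level methylation dataset
#'
#' Differentially methylated genes have their tumour group mean shifted by
#' \code{dm_effect} in the planted direction (clipped to [0,1] with a
#' warning when the shift leaves the unit interval).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param cancerIndex which cancer (1..\code{n_cancers}).
#' @return list with \code{tumor} and \code{normal} gene-level
#'   \linkS4class{BetaSet}s and \code{truth}.
#' @export
simTumorNormal <- function(cfg, cancerIndex = 1L) {
    if (cancerIndex < 1 || cancerIndex > cfg$n_cancers)
        stop("cancerIndex out of range")
    gp <- geneParams(cfg)
    withSeed(cfg$seed + 100L + cancerIndex, {
        dm <- gp$cancer_dm[[cancerIndex]]
        mu_n <- gp$gene_mean
        mu_t <- mu_n
        if (length(dm)) {
            shift <- ifelse(dm == "hyper", cfg$dm_effect, -cfg$dm_effect)
            tgt <- mu_t[names(dm)] + shift
            if (any(tgt < 0 | tgt > 1))
                warning(sprintf(
                    "simTumorNormal: %d tumour group means clipped to [0,1]",
                    sum(tgt < 0 | tgt > 1)))
            mu_t[names(dm)] <- clip01(tgt)
        }
        mk <- function(mu, m, prefix, grp) {
            b <- clip01(matrix(rep(mu, m), ncol = m) +
                        stats::rnorm(length(mu) * m, sd = cfg$noise_sd))
            dimnames(b) <- list(gp$ids, sprintf("%s%03d", prefix, seq_len(m)))
            age <- pmin(pmax(round(stats::rnorm(m, 62, 10)), 30),
                        cfg$age_range[2])
            BetaSet(b, DataFrame(age = age, group = grp,
                                 sex = sample(c("M", "F"), m, replace = TRUE),
                                 row.names = colnames(b)))
        }
        tn <- mk(mu_t, cfg$n_tumor, sprintf("T%02d_", cancerIndex), "tumor")
        nn <- mk(mu_n, cfg$n_normal, sprintf("N%02d_", cancerIndex), "normal")
        list(tumor = tn, normal = nn, truth = truthFromParams(gp))
    })
}

#' Simulate the background protein-interaction network
#'
#' A preferential-attachment (scale-free) graph over the gene universe with
#' a planted clique over the community members; simple (no self-loops, no
#' duplicate edges).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param geneUniverse optional character vector of node names; defaults to
#'   the simulated genes plus \code{ppi_n_extra_genes} extra genes.
#' @param community optional planted-clique members; defaults to the
#'   configuration's planted community (including discordant genes).
#' @return data.frame with columns \code{gene_a}, \code{gene_b}.
#' @export
simPPI <- function(cfg, geneUniverse = NULL, community = NULL) {
    gp <- geneParams(cfg)
    if (is.null(geneUniverse))
        geneUniverse <- c(gp$ids,
                          sprintf("X%04d", seq_len(cfg$ppi_n_extra_genes)))
    if (is.null(community))
        community <- c(gp$community, gp$discordant)
    if (!all(gp$ids %in% geneUniverse))
        stop("geneUniverse must cover all simulated genes")
    if (length(community) > length(geneUniverse))
        stop("planted community larger than the gene universe")
    withSeed(cfg$seed + 2L, {
        g <- igraph::sample_pa(length(geneUniverse), power = 1,
                               m = cfg$ppi_attachment, directed = FALSE)
        igraph::V(g)$name <- sample(geneUniverse)
        if (length(community) >= 2) {
            pairs <- utils::combn(community, 2)
            g <- igraph::add_edges(g, as.vector(pairs))
        }
        g <- igraph::simplify(g)
        el <- igraph::as_edgelist(g)
        data.frame(gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
    })
}

#' Simulate gene expression coupled to promoter methylation
#'
#' Regulated genes follow \code{expr = a + expr_slope * beta + noise} with a
#' negative slope (methylation silences expression); other genes vary
#' independently of methylation (unit-sd baseline variation).
#'
#' @param geneBetas gene-level \linkS4class{BetaSet} or matrix.
#' @param regulated character vector of regulated genes (subset of rows).
#' @param cfg a \code{\link{simConfig}}.
#' @return expression matrix with the dimnames of \code{geneBetas}.
#' @export
simExpression <- function(geneBetas, regulated, cfg) {
    b <- if (is(geneBetas, "BetaSet")) betaValues(geneBetas) else
        as.matrix(geneBetas)
    if (!all(regulated %in% rownames(b)))
        stop("regulated genes must be rows of geneBetas")
    withSeed(cfg$seed + 3L, {
        a <- stats::runif(nrow(b), 5, 10)
        expr <- matrix(a, nrow(b), ncol(b)) +
            matrix(stats::rnorm(length(b)), nrow(b))
        dimnames(expr) <- dimnames(b)
        if (length(regulated)) {
            noise <- matrix(stats::rnorm(length(regulated) * ncol(b),
                                         sd = cfg$expr_noise_sd),
                            length(regulated))
            expr[regulated, ] <- a[match(regulated, rownames(b))] +
                cfg$expr_slope * b[regulated, , drop = FALSE] + noise
        }
        expr
    })
}

#' Simulate survival outcomes from a linear risk score
#'
#' Event times are exponential with rate
#' \code{baseline_hazard * exp(pi)}; censoring is uniform on
#' (0, \code{censor_time_max}] and \code{event = 0} when censored.
#'
#' @param pi numeric per-patient risk scores.
#' @param cfg a \code{\link{simConfig}} (needs \code{baseline_hazard > 0}).
#' @return data.frame with \code{time} (months) and \code{event} (0/1).
#' @export
simSurvival <- function(pi, cfg) {
    if (!all(is.finite(pi))) stop("risk scores must be finite")
    if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
    if (cfg$censor_time_max <= 0) stop("censor_time_max must be > 0")
    withSeed(cfg$seed + 4L, {
        tt <- stats::rexp(length(pi),
                          rate = cfg$baseline_hazard * exp(pi))
        cc <- stats::runif(length(pi), 0, cfg$censor_time_max)
        data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
    })
}

#' Simulate a clinical methylation cohort with survival outcomes
#'
#' Gene-level beta values for \code{n_patients} tumour patients around the
#' per-gene baseline means; the planted risky genes contribute
#' \code{risk_coef} per z-scored beta unit to the true log hazard, from
#' which times and events are drawn via \code{\link{simSurvival}}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{betas} (\linkS4class{BetaSet} carrying
#'   \code{time}, \code{event}, \code{age}, \code{sex}, \code{stage} in
#'   colData), \code{pi_true} and \code{truth}.
#' @export
simClinicalCohort <- function(cfg) {
    gp <- geneParams(cfg)
    withSeed(cfg$seed + 5L, {
        m <- cfg$n_patients
        b <- clip01(matrix(rep(gp$gene_mean, m), ncol = m) +
                    stats::rnorm(cfg$n_genes * m, sd = cfg$noise_sd))
        dimnames(b) <- list(gp$ids, sprintf("P%04d", seq_len(m)))
        pi_true <- rep(0, m)
        if (length(gp$risky_coefs)) {
            z <- t(scale(t(b[names(gp$risky_coefs), , drop = FALSE])))
            pi_true <- as.vector(gp$risky_coefs %*% z)
        }
        surv <- simSurvival(pi_true, cfg)
        meta <- DataFrame(age = pmin(pmax(round(stats::rnorm(m, 62, 10)), 30),
                                     95),
                          sex = sample(c(0L, 1L), m, replace = TRUE),
                          stage = sample(1:4, m, replace = TRUE),
                          group = "tumor",
                          time = surv$time, event = surv$event,
                          row.names = colnames(b))
        list(betas = BetaSet(b, meta), pi_true = pi_true,
             truth = truthFromParams(gp))
    })
}
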