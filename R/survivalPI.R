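#' Z-score transformation with training-set parameters
#'
#' Standardises with the training mean and (sample) standard deviation and
#' applies the same transform to a second set, so test-set values are on
#' the training scale.
#'
#' @param train numeric training values.
#' @param apply numeric values to transform with the training parameters
#'   (defaults to \code{train}).
#' @return list with \code{train}, \code{apply} (both standardised),
#'   \code{mean}, \code{sd}.
#' @export
zscoreTrainApply <- function(train, apply = train) {
    m <- mean(train); s <- stats::sd(train)
    if (is.na(s) || s == 0) stop("zero training variance")
    list(train = (train - m) / s, apply = (apply - m) / s,
         mean = m, sd = s)
}

# Gene-wise z-scoring of beta matrices (genes x patients) with training
# parameters.
zscoreGenes <- function(trainMat, applyMat = trainMat) {
    m <- rowMeans(trainMat)
    s <- apply(trainMat, 1, stats::sd)
    if (any(s == 0)) stop("zero training variance for some genes")
    list(train = (trainMat - m) / s, apply = (applyMat - m) / s)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fits with Efron tie handling. In univariate mode each
#' covariate is fit alone; in multivariate mode all covariates enter one
#' model. Wald confidence intervals and p-values are reported; a gene is
#' "risky" when its hazard ratio exceeds 1.
#'
#' @param data data.frame containing \code{time}, \code{event} and the
#'   covariate columns (numeric).
#' @param covariates character vector of covariate column names.
#' @param mode "univariate" or "multivariate".
#' @param time,event column names for follow-up time (months) and event
#'   indicator (0/1).
#' @return data.frame with \code{variable}, \code{coef}, \code{hr},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{risky}.
#' @export
coxFit <- function(data, covariates,
                   mode = c("univariate", "multivariate"),
                   time = "time", event = "event") {
    mode <- match.arg(mode)
    if (sum(data[[event]]) < 2) stop("need at least 2 events")
    const <- vapply(covariates, function(v) stats::var(data[[v]]) == 0,
                    logical(1))
    if (any(const))
        stop("constant covariates: ", paste(covariates[const],
                                            collapse = ", "))
    fit_one <- function(vars) {
        fml <- stats::as.formula(paste0(
            "survival::Surv(", time, ", ", event, ") ~ ",
            paste(sprintf("`%s`", vars), collapse = " + ")))
        fit <- survival::coxph(fml, data = data, ties = "efron")
        if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
            stop("Cox fit did not converge")
        s <- summary(fit)
        data.frame(variable = rownames(s$coefficients),
                   coef = s$coefficients[, "coef"],
                   hr = s$coefficients[, "exp(coef)"],
                   ci_low = s$conf.int[, "lower .95"],
                   ci_high = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
    }
    out <- if (mode == "univariate")
        do.call(rbind, lapply(covariates, fit_one))
    else fit_one(covariates)
    out$variable <- gsub("`", "", out$variable)
    out$risky <- out$hr > 1
    out
}

#' Hazard ratio from a Cox regression coefficient
#'
#' @param coef log-hazard regression coefficient(s).
#' @return \code{exp(coef)}.
#' @export
coefToHR <- function(coef) exp(coef)

#' Prognostic index
#'
#' Per-patient linear risk score: the sum over genes of the Cox regression
#' coefficient times the z-scored methylation level.
#'
#' @param z matrix of z-scored methylation, genes x patients.
#' @param coefs named numeric Cox coefficients; names must match
#'   \code{rownames(z)}.
#' @return numeric PI per patient.
#' @export
prognosticIndex <- function(z, coefs) {
    z <- as.matrix(z)
    if (!setequal(rownames(z), names(coefs)))
        stop("gene sets of z and coefs do not match")
    as.vector(coefs[rownames(z)] %*% z)
}

#' Split patients into high- and low-risk groups
#'
#' High risk when PI exceeds the threshold (by default the training-set
#' median); patients exactly at the threshold go to the low-risk group.
#'
#' @param pi numeric prognostic indices.
#' @param threshold cut point; defaults to \code{median(pi)} (pass the
#'   training median when splitting a test set).
#' @return factor with levels \code{low}, \code{high}.
#' @export
riskSplit <- function(pi, threshold = stats::median(pi)) {
    grp <- factor(ifelse(pi > threshold, "high", "low"),
                  levels = c("low", "high"))
    if (all(grp == "low"))
        warning("all patients fall in the low-risk group")
    grp
}

#' Kaplan-Meier curves and log-rank test for two risk groups
#'
#' Product-limit survival estimate per group, the median survival (the
#' earliest time at which the estimated survival drops to 0.5 or below;
#' not reached when it never does) and the two-group log-rank chi-square
#' p-value.
#'
#' @param group factor of group labels.
#' @param time,event follow-up times and event indicators.
#' @return list with \code{fit} (a \code{survfit} object),
#'   \code{median_survival} (named per group, NA when not reached),
#'   \code{chisq}, \code{p}.
#' @export
kmLogrank <- function(group, time, event) {
    if (nlevels(droplevels(factor(group))) < 2)
        stop("need two non-empty groups")
    d <- data.frame(time = time, event = event, group = group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
    strata <- rep(names(fit$strata), fit$strata)
    med <- vapply(names(fit$strata), function(s) {
        tt <- fit$time[strata == s]; ss <- fit$surv[strata == s]
        hit <- which(ss <= 0.5)
        if (length(hit)) tt[min(hit)] else NA_real_
    }, numeric(1))
    names(med) <- sub("^group=", "", names(med))
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
    list(fit = fit, median_survival = med, chisq = unname(sd$chisq), p = p)
}

#' Random gene-set survival permutation test
#'
#' Repeatedly draws \code{k} genes uniformly without replacement and counts
#' how many are in the qualifying set (genes both age-associated and
#' survival-associated per the pipeline's callers); the empirical p-value
#' is the plain fraction of repetitions whose count reaches the observed
#' one (no +1 smoothing).
#'
#' @param allGenes character vector to sample from.
#' @param qualifying character subset of \code{allGenes}.
#' @param observed observed count of qualifying genes.
#' @param k genes per draw (default 25).
#' @param reps repetitions (default 10000).
#' @param seed integer seed.
#' @return list with \code{p}, \code{counts} (per-repetition statistics).
#' @export
randomGenesetTest <- function(allGenes, qualifying, observed, k = 25L,
                              reps = 10000L, seed = 1L) {
    if (reps < 1) stop("reps must be >= 1")
    if (k > length(allGenes)) stop("k exceeds the gene universe")
    isq <- allGenes %in% qualifying
    counts <- withSeed(seed, {
        n <- length(allGenes)
        vapply(seq_len(reps),
               function(i) sum(isq[sample.int(n, k)]), integer(1))
    })
    list(p = mean(counts >= observed), counts = counts)
}
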