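#' Per-gene linear age models
#'
#' Ordinary least-squares fit of gene methylation on age for every row of
#' the matrix, plus the Pearson correlation of methylation with age.
#' Vectorised across genes.
#'
#' @param x gene-level \linkS4class{BetaSet} or numeric matrix
#'   (genes x samples).
#' @param ages numeric years, aligned to columns; defaults to
#'   \code{sampleAges(x)}.
#' @return data.frame with \code{gene}, \code{slope} (beta units / year),
#'   \code{intercept}, \code{r}.
#' @examples
#' fitAgeModels(rbind(g1 = c(0.2, 0.3, 0.4, 0.5)), c(20, 40, 60, 80))
#' @export
fitAgeModels <- function(x, ages = NULL) {
    b <- if (is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    if (is.null(ages) && is(x, "BetaSet")) ages <- sampleAges(x)
    if (length(ages) != ncol(b))
        stop("ages must align with the sample columns")
    if (ncol(b) < 3) stop("need at least 3 samples")
    if (stats::var(ages) == 0) stop("ages must not all be equal")
    xc <- ages - mean(ages)
    sxx <- sum(xc^2)
    slope <- as.vector((b %*% xc) / sxx)
    intercept <- rowMeans(b) - slope * mean(ages)
    data.frame(gene = rownames(b), slope = slope, intercept = intercept,
               r = rowPearson(b, ages),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation p-values for the age association
#'
#' For each gene the ages are permuted \code{nPerm} times and the two-sided
#' p-value is \code{(1 + #\{|r_perm| >= |r_obs|\}) / (nPerm + 1)} (the +1
#' smoothing keeps p >= 1/(nPerm+1)). Each gene draws its own permutations
#' from one seeded stream, genes processed in row order, so the result is
#' deterministic and gene-level null p-values are independent.
#'
#' @inheritParams fitAgeModels
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return numeric vector of p-values named by gene.
#' @export
permutationPValues <- function(x, ages = NULL, nPerm = 1000L, seed = 1L) {
    if (nPerm < 1) stop("nPerm must be >= 1")
    b <- if (is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    if (is.null(ages) && is(x, "BetaSet")) ages <- sampleAges(x)
    if (length(ages) != ncol(b))
        stop("ages must align with the sample columns")
    n <- ncol(b)
    r_obs <- abs(rowPearson(b, ages))
    ys <- as.vector(scale(ages))
    withSeed(seed, {
        p <- vapply(seq_len(nrow(b)), function(i) {
            v <- b[i, ]
            s <- stats::sd(v)
            if (s == 0) return(1)
            xs <- (v - mean(v)) / s
            idx <- vapply(seq_len(nPerm), function(j) sample.int(n),
                          integer(n))
            rperm <- abs(colSums(matrix(xs[idx], n) * ys) / (n - 1))
            (1 + sum(rperm >= r_obs[i])) / (nPerm + 1)
        }, numeric(1))
        stats::setNames(p, rownames(b))
    })
}

#' Call age-associated differentially methylated genes
#'
#' Benjamini-Hochberg adjustment of the permutation p-values; genes with
#' q <= \code{fdr} are called and directed by the slope sign (hyper:
#' methylation rises with age; hypo: falls). \code{useRawP = TRUE} switches
#' to unadjusted p <= \code{fdr}.
#'
#' @param records data.frame from \code{\link{fitAgeModels}} with a
#'   \code{p_perm} column (see \code{\link{permutationPValues}}).
#' @param fdr significance threshold (default 0.01).
#' @param useRawP use unadjusted permutation p-values instead of BH q.
#' @return the records with added \code{q}, \code{called},
#'   \code{direction} (hyper/hypo/none).
#' @export
callADMGs <- function(records, fdr = 0.01, useRawP = FALSE) {
    if (nrow(records) == 0) stop("empty record list")
    if (!"p_perm" %in% names(records))
        stop("records need a p_perm column")
    records$q <- stats::p.adjust(records$p_perm, method = "BH")
    records$called <- if (useRawP) records$p_perm <= fdr else
        records$q <= fdr
    records$direction <- ifelse(!records$called, "none",
                                ifelse(records$slope > 0, "hyper", "hypo"))
    records
}

#' Classify methylation level and the four aDMG categories
#'
#' A gene is "high" when its mean beta across all samples is at least 0.5,
#' else "low"; called genes fall into hyper-high / hyper-low / hypo-high /
#' hypo-low, uncalled genes into "none".
#'
#' @param records output of \code{\link{callADMGs}}.
#' @param x the gene-level \linkS4class{BetaSet} or matrix the records were
#'   fit on.
#' @return the records with added \code{level} and \code{category}.
#' @export
classifyCategory <- function(records, x) {
    b <- if (is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    mb <- rowMeans(b)[records$gene]
    records$mean_beta <- unname(mb)
    records$level <- ifelse(mb >= 0.5, "high", "low")
    records$category <- ifelse(records$direction == "none", "none",
                               paste(records$direction, records$level,
                                     sep = "-"))
    records
}

#' 2x2 contingency counts of the aDMG categories
#'
#' @param records output of \code{\link{classifyCategory}}.
#' @return named vector \code{c(a, b, c, d)} = counts of hyper-high,
#'   hyper-low, hypo-high, hypo-low genes.
#' @export
categoryCounts <- function(records) {
    c(a = sum(records$category == "hyper-high"),
      b = sum(records$category == "hyper-low"),
      c = sum(records$category == "hypo-high"),
      d = sum(records$category == "hypo-low"))
}

#' Association between drift direction and methylation level
#'
#' Sample odds ratio \code{(b/a)/(d/c)} for the 2x2 table of hyper/hypo
#' aDMGs by high/low level, with a Wald 95\% CI on the log odds ratio and a
#' two-sided Fisher exact p-value. With a zero cell the CI is undefined and
#' flagged (no Haldane correction is applied).
#'
#' @param a,b,c,d counts: hyper-high, hyper-low, hypo-high, hypo-low.
#' @return list with \code{odds_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{counts}, \code{zero_cell}.
#' @examples
#' categoryAssociation(275, 1339, 1066, 1597)$odds_ratio  # 3.25
#' @export
categoryAssociation <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                  dimnames = list(c("hyper", "hypo"), c("high", "low")))
    zero <- any(tab == 0)
    if (zero) {
        warning("zero cell: odds ratio CI undefined")
        or <- NA_real_
    } else {
        or <- (b / a) / (d / c)
        se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
        ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
    }
    p <- stats::fisher.test(tab)$p.value
    list(odds_ratio = or,
         ci_low = if (zero) NA_real_ else ci[1],
         ci_high = if (zero) NA_real_ else ci[2],
         p = p, counts = c(a = a, b = b, c = c, d = d), zero_cell = zero)
}

#' Proportion of genes in the favoured drift-level classes
#'
#' The fraction of categorised genes falling in the hyper-low or hypo-high
#' class (drift away from the gene's resting level), as reported for module
#' genes versus all aDMGs.
#'
#' @param categories character vector of categories (as produced by
#'   \code{\link{classifyCategory}}); "none" entries are ignored.
#' @return fraction in [0, 1].
#' @export
favoredCategoryProportion <- function(categories) {
    categories <- categories[categories != "none"]
    if (!length(categories)) return(NA_real_)
    mean(categories %in% c("hyper-low", "hypo-high"))
}

#' Hierarchical clustering of age-averaged methylation profiles
#'
#' Samples are averaged per unique age; the age profiles are clustered
#' agglomeratively with distance 1 - Pearson correlation and average
#' linkage, and the tree is cut into two groups.
#'
#' @param x aDMG sub-matrix (genes x samples), \linkS4class{BetaSet} or
#'   matrix.
#' @param ages numeric years per sample.
#' @return list with \code{ages} (sorted unique ages), \code{hclust},
#'   \code{partition} (named 1/2 per unique age) and \code{tree}
#'   (\code{ape::phylo}, writable as newick).
#' @export
clusterAgeMeans <- function(x, ages = NULL) {
    b <- if (is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    if (is.null(ages) && is(x, "BetaSet")) ages <- sampleAges(x)
    ua <- sort(unique(ages))
    if (length(ua) < 2) stop("need at least 2 unique ages")
    am <- vapply(ua, function(a)
        rowMeans(b[, ages == a, drop = FALSE]), numeric(nrow(b)))
    colnames(am) <- as.character(ua)
    d <- 1 - stats::cor(am)
    d[is.na(d)] <- 1
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    part <- stats::cutree(hc, k = 2)
    list(ages = ua, hclust = hc, partition = part,
         tree = ape::as.phylo(hc))
}
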