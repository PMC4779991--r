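#' Group-entropy differential methylation score
#'
#' Shannon entropy (bits) of the normalised tumour/normal group means
#' \eqn{p_i = m_i / (m_T + m_N)}, with \eqn{0\log 0 = 0}: 1 bit means no
#' group difference, 0 bits a maximal one. Because the entropy of the raw
#' means is insensitive to shared hypomethylation, the adjusted score
#' \code{H_adj} is the minimum of the entropy on the means and on their
#' complements \code{(1 - m_T, 1 - m_N)}, making the score invariant under
#' the global transform beta -> 1 - beta.
#'
#' @param meanTumor,meanNormal group mean beta values in [0, 1]
#'   (vectorised).
#' @return list with \code{H} and \code{H_adj} (bits).
#' @examples
#' groupEntropy(0.8, 0.2)$H  # 0.7219...
#' @export
groupEntropy <- function(meanTumor, meanNormal) {
    if (any(meanTumor < 0 | meanTumor > 1 | meanNormal < 0 | meanNormal > 1))
        stop("group means must lie in [0, 1]")
    h2 <- function(x, y) {
        s <- x + y
        p <- ifelse(s > 0, x / s, NA_real_)
        plgp <- function(q) ifelse(q > 0, q * log2(q), 0)
        ifelse(is.na(p), NA_real_, -(plgp(p) + plgp(1 - p)))
    }
    H <- h2(meanTumor, meanNormal)
    Hm <- h2(1 - meanTumor, 1 - meanNormal)
    H_adj <- pmin(H, Hm, na.rm = TRUE)
    # both means 0: H undefined on the means, taken from the complements
    H <- ifelse(is.na(H), Hm, H)
    list(H = H, H_adj = H_adj)
}

#' Call cancer differentially methylated genes
#'
#' Per-gene tumour and normal group means are scored with
#' \code{\link{groupEntropy}}; genes with \code{H_adj <= hThreshold} are
#' called, directed hyper-in-cancer when the tumour mean exceeds the normal
#' mean. The default threshold 0.95 bits is calibrated so that group-mean
#' differences of ~0.3 beta units are called at realistic noise.
#'
#' @param tumor,normal gene-level \linkS4class{BetaSet}s (or matrices)
#'   sharing a gene universe.
#' @param hThreshold entropy threshold in bits (default 0.95).
#' @return data.frame with \code{gene}, \code{mean_tumor},
#'   \code{mean_normal}, \code{H}, \code{H_adj}, \code{direction},
#'   \code{is_dmg}.
#' @export
callCDMGs <- function(tumor, normal, hThreshold = 0.95) {
    bt <- if (is(tumor, "BetaSet")) betaValues(tumor) else as.matrix(tumor)
    bn <- if (is(normal, "BetaSet")) betaValues(normal) else
        as.matrix(normal)
    shared <- intersect(rownames(bt), rownames(bn))
    if (!length(shared)) stop("tumor and normal share no genes")
    if (ncol(bt) < 1 || ncol(bn) < 1) stop("need >= 1 sample per group")
    mt <- rowMeans(bt[shared, , drop = FALSE])
    mn <- rowMeans(bn[shared, , drop = FALSE])
    e <- groupEntropy(mt, mn)
    data.frame(gene = shared, mean_tumor = unname(mt),
               mean_normal = unname(mn), H = e$H, H_adj = e$H_adj,
               direction = ifelse(mt > mn, "hyper", "hypo"),
               is_dmg = e$H_adj <= hThreshold,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Union of per-cancer cDMG sets
#'
#' @param perCancer named list of \code{\link{callCDMGs}} outputs (or of
#'   data.frames with \code{gene}, \code{direction}, \code{is_dmg}).
#' @return data.frame with one row per gene x cancer in which the gene is a
#'   cDMG: \code{gene}, \code{cancer}, \code{direction}.
#' @export
unionCDMGs <- function(perCancer) {
    if (!length(perCancer)) stop("need at least one cDMG set")
    if (is.null(names(perCancer)))
        names(perCancer) <- sprintf("cancer%02d", seq_along(perCancer))
    rows <- lapply(names(perCancer), function(cn) {
        d <- perCancer[[cn]]
        d <- d[d$is_dmg, , drop = FALSE]
        if (!nrow(d)) return(NULL)
        data.frame(gene = d$gene, cancer = cn, direction = d$direction,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(), cancer = character(),
                          direction = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Check tumour/normal age balance
#'
#' Two-sided Wilcoxon rank-sum test of the age distributions; a warning is
#' emitted when the groups differ at p < 0.05 (age imbalance can confound
#' tumour/normal differential methylation).
#'
#' @param tumorAges,normalAges numeric years.
#' @return the p-value.
#' @export
ageConfoundingCheck <- function(tumorAges, normalAges) {
    if (!length(tumorAges) || !length(normalAges))
        stop("both groups need at least one age")
    p <- stats::wilcox.test(tumorAges, normalAges, exact = NULL)$p.value
    if (is.finite(p) && p < 0.05)
        warning(sprintf(
            "tumour/normal age distributions differ (Wilcoxon p = %.3g)", p))
    p
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test P(X >= overlap) of a query set against a
#' target set drawn from a universe of \code{universeSize} genes.
#'
#' @param query,target character gene sets (assumed subsets of the
#'   universe).
#' @param universeSize number of genes in the background universe.
#' @return list with \code{overlap}, \code{query_size}, \code{target_size},
#'   \code{universe_size}, \code{overlap_pct_of_target} (percentage of the
#'   target set covered) and \code{p}.
#' @export
genesetEnrichment <- function(query, target, universeSize) {
    query <- unique(query); target <- unique(target)
    if (length(query) > universeSize || length(target) > universeSize)
        stop("set sizes exceed the universe")
    ov <- length(intersect(query, target))
    p <- stats::phyper(ov - 1, length(target),
                       universeSize - length(target), length(query),
                       lower.tail = FALSE)
    list(overlap = ov, query_size = length(query),
         target_size = length(target), universe_size = universeSize,
         overlap_pct_of_target = 100 * ov / length(target),
         p = p)
}
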