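#' Drop CpG probes with missing values
#'
#' Probes carrying one or more missing beta values are discarded before
#' gene aggregation; no imputation is attempted.
#'
#' @param x a CpG-level \linkS4class{BetaSet}.
#' @return a \linkS4class{BetaSet} restricted to complete probes.
#' @export
dropMissingProbes <- function(x) {
    b <- betaValues(x)
    keep <- rowSums(is.na(b)) == 0
    if (!any(keep))
        stop("all probes carry missing values")
    dropped <- sum(!keep)
    if (dropped > 0)
        message(sprintf("dropMissingProbes: discarded %d of %d probes",
                        dropped, nrow(b)))
    x[keep, ]
}

#' Cross-CpG consistency ratio of one gene
#'
#' The fraction of samples in which all of the gene's CpGs lie on the same
#' side of 0.5 (sides defined as beta >= 0.5 versus beta < 0.5). A
#' single-CpG gene is consistent in every sample.
#'
#' @param cpgBetas numeric matrix, rows = the gene's CpGs, columns =
#'   samples; no missing values.
#' @return fraction in [0, 1].
#' @examples
#' m <- rbind(c(0.6, 0.6), c(0.7, 0.3))
#' consistencyRatio(m)  # 0.5
#' @export
consistencyRatio <- function(cpgBetas) {
    cpgBetas <- as.matrix(cpgBetas)
    if (nrow(cpgBetas) == 0 || ncol(cpgBetas) == 0)
        stop("empty input")
    if (anyNA(cpgBetas))
        stop("missing values must be removed first")
    hi <- colSums(cpgBetas >= 0.5)
    mean(hi == 0 | hi == nrow(cpgBetas))
}

#' Collapse CpG-level beta values to gene level
#'
#' For each annotated gene the consistency ratio is computed; genes at or
#' above \code{threshold} are retained and their methylation level is the
#' per-sample mean over member CpGs. Probes absent from the matrix are
#' skipped; probes mapping to several genes contribute to each.
#'
#' @param x a complete CpG-level \linkS4class{BetaSet} (run
#'   \code{\link{dropMissingProbes}} first).
#' @param annotation data.frame with columns \code{cpg_id},
#'   \code{gene_symbol}.
#' @param threshold minimum consistency ratio for a gene to be retained
#'   (default 0.8).
#' @return list with \code{genes} (gene-level \linkS4class{BetaSet}) and
#'   \code{report} (data.frame \code{gene}, \code{n_cpgs},
#'   \code{consistency_ratio}, \code{retained} for every gene).
#' @export
aggregateGenes <- function(x, annotation, threshold = 0.8) {
    b <- betaValues(x)
    if (anyNA(b))
        stop("missing values present; run dropMissingProbes() first")
    ann <- annotation[annotation$cpg_id %in% rownames(b), , drop = FALSE]
    skipped <- sum(!annotation$cpg_id %in% rownames(b))
    if (skipped > 0)
        message(sprintf("aggregateGenes: %d annotated probes absent, skipped",
                        skipped))
    if (nrow(ann) == 0)
        stop("annotation maps no probes in the matrix")
    by_gene <- split(ann$cpg_id, ann$gene_symbol)
    genes <- names(by_gene)
    ratio <- numeric(length(genes))
    means <- matrix(NA_real_, length(genes), ncol(b),
                    dimnames = list(genes, colnames(b)))
    for (i in seq_along(genes)) {
        sub <- b[by_gene[[i]], , drop = FALSE]
        ratio[i] <- consistencyRatio(sub)
        means[i, ] <- colMeans(sub)
    }
    report <- data.frame(gene = genes,
                         n_cpgs = lengths(by_gene),
                         consistency_ratio = ratio,
                         retained = ratio >= threshold,
                         row.names = NULL, stringsAsFactors = FALSE)
    keep <- report$retained
    if (!any(keep))
        stop("no gene passes the consistency threshold")
    list(genes = BetaSet(means[report$gene[keep], , drop = FALSE],
                         colData(x)),
         report = report)
}
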