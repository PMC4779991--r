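#' Classify the age/cancer methylation pattern
#'
#' HH: methylation rises with age and is higher in tumour than normal; LL:
#' falls with age and is lower in tumour. HL and LH are the discordant
#' patterns (hyper with age but hypo in cancer, and vice versa).
#'
#' @param ageDirection "hyper" or "hypo" (drift with age).
#' @param methDirection "hyper" or "hypo" (tumour versus normal).
#' @return "HH", "LL", "HL" or "LH" (vectorised); NA when a direction is
#'   undefined.
#' @export
classifyPattern <- function(ageDirection, methDirection) {
    a <- ifelse(ageDirection == "hyper", "H",
                ifelse(ageDirection == "hypo", "L", NA))
    m <- ifelse(methDirection == "hyper", "H",
                ifelse(methDirection == "hypo", "L", NA))
    ifelse(is.na(a) | is.na(m), NA_character_, paste0(a, m))
}

#' Tumour-versus-normal expression direction
#'
#' "up" when the tumour group mean exceeds the normal group mean, "down"
#' otherwise; an exact tie goes to "down" with a warning.
#'
#' @param exprTumor,exprNormal numeric expression values per group.
#' @return "up" or "down".
#' @export
expressionDirection <- function(exprTumor, exprNormal) {
    if (!length(exprTumor) || !length(exprNormal))
        stop("both groups need at least one value")
    mt <- mean(exprTumor); mn <- mean(exprNormal)
    if (mt == mn) warning("tied expression means; direction set to 'down'")
    if (mt > mn) "up" else "down"
}

#' Build the gene x cancer pattern map
#'
#' For every module gene that is an acDMG (age-associated and
#' cancer-differential) in a cancer, records the age direction, resting
#' methylation level (carried from the aging cohort), the cancer
#' methylation direction, the HH/LL/HL/LH pattern, the expression
#' direction, and whether methylation and expression are concordant (HH
#' with expression down, or LL with expression up). All four pattern
#' classes are reported; discordant HL/LH genes are kept, not dropped.
#'
#' @param moduleGenes character vector (typically the union of detected
#'   module members).
#' @param admgRecords output of \code{\link{classifyCategory}} (needs
#'   \code{gene}, \code{direction}, \code{level}).
#' @param cdmgUnion output of \code{\link{unionCDMGs}} (\code{gene},
#'   \code{cancer}, \code{direction}).
#' @param exprTumor,exprNormal named lists (per cancer) of expression
#'   matrices (genes x samples); optional — when absent the expression
#'   columns are NA.
#' @return data.frame with one row per gene x cancer: \code{gene},
#'   \code{cancer}, \code{age_direction}, \code{level},
#'   \code{meth_direction}, \code{pattern}, \code{expr_direction},
#'   \code{concordant}.
#' @export
buildPatternMap <- function(moduleGenes, admgRecords, cdmgUnion,
                            exprTumor = NULL, exprNormal = NULL) {
    adm <- admgRecords[admgRecords$direction %in% c("hyper", "hypo"), ]
    rows <- cdmgUnion[cdmgUnion$gene %in% intersect(moduleGenes, adm$gene), ,
                      drop = FALSE]
    if (!nrow(rows))
        return(data.frame(gene = character(), cancer = character(),
                          age_direction = character(), level = character(),
                          meth_direction = character(),
                          pattern = character(),
                          expr_direction = character(),
                          concordant = logical(),
                          stringsAsFactors = FALSE))
    i <- match(rows$gene, adm$gene)
    out <- data.frame(gene = rows$gene, cancer = rows$cancer,
                      age_direction = adm$direction[i],
                      level = adm$level[i],
                      meth_direction = rows$direction,
                      stringsAsFactors = FALSE)
    out$pattern <- classifyPattern(out$age_direction, out$meth_direction)
    out$expr_direction <- NA_character_
    for (j in seq_len(nrow(out))) {
        cn <- out$cancer[j]; gn <- out$gene[j]
        if (!is.null(exprTumor) && cn %in% names(exprTumor) &&
            gn %in% rownames(exprTumor[[cn]]))
            out$expr_direction[j] <- expressionDirection(
                exprTumor[[cn]][gn, ], exprNormal[[cn]][gn, ])
    }
    out$concordant <- (out$pattern == "HH" & out$expr_direction == "down") |
        (out$pattern == "LL" & out$expr_direction == "up")
    out
}

#' Call age-associated cancer markers
#'
#' A gene is a marker in a cancer when its pattern there is HH with
#' expression down (promoter hypermethylation with transcriptional
#' silencing) or LL with expression up (hypomethylation with activation);
#' \code{is_marker} is true when the gene is a marker in at least one
#' cancer.
#'
#' @param patternMap output of \code{\link{buildPatternMap}}.
#' @return data.frame with one row per gene: \code{gene}, \code{pattern}
#'   (pattern in its marker cancers, or the gene's modal pattern),
#'   \code{marker_cancers} (comma-separated), \code{is_marker}.
#' @export
callMarkers <- function(patternMap) {
    genes <- unique(patternMap$gene)
    rows <- lapply(genes, function(g) {
        sub <- patternMap[patternMap$gene == g, , drop = FALSE]
        mk <- sub[!is.na(sub$concordant) & sub$concordant, , drop = FALSE]
        pat <- if (nrow(mk)) unique(mk$pattern)[1] else
            names(sort(table(sub$pattern), decreasing = TRUE))[1]
        data.frame(gene = g, pattern = pat,
                   marker_cancers = paste(mk$cancer, collapse = ","),
                   is_marker = nrow(mk) > 0, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Overlap between experiment and validation marker sets
#'
#' @param experimentMarkers,validationMarkers character gene sets.
#' @return list with \code{shared}, \code{experiment_only},
#'   \code{validation_only}, \code{shared_fraction} (of the experiment
#'   set).
#' @export
validateMarkers <- function(experimentMarkers, validationMarkers) {
    shared <- intersect(experimentMarkers, validationMarkers)
    if (!length(shared) && length(experimentMarkers))
        warning("no marker shared between the two sets")
    list(shared = shared,
         experiment_only = setdiff(experimentMarkers, validationMarkers),
         validation_only = setdiff(validationMarkers, experimentMarkers),
         shared_fraction = if (length(experimentMarkers))
             length(shared) / length(experimentMarkers) else NA_real_)
}
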