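#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' BetaSet: a methylation beta-value matrix with sample metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay named
#' \code{"beta"} (rows = CpG probes or genes, columns = samples, values in
#' \eqn{[0,1]}) and per-sample metadata in \code{colData} (typically
#' \code{age} in years, \code{group} in \{tumor, normal, healthy\},
#' \code{time} in months, \code{event} in \{0,1\}, \code{stage}, \code{sex}).
#' Missing values are permitted at the CpG level and are removed by
#' \code{\link{dropMissingProbes}} before gene aggregation.
#'
#' @slot . inherits all slots from SummarizedExperiment.
#' @seealso \code{\link{BetaSet}} (constructor), \code{\link{betaValues}},
#'   \code{\link{sampleAges}}
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    if (!"beta" %in% assayNames(object))
        return("assay 'beta' is required")
    b <- assay(object, "beta")
    v <- b[!is.na(b)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
        return("beta values must lie in [0, 1]")
    if (anyDuplicated(rownames(b)))
        return("feature ids must be unique")
    if (anyDuplicated(colnames(b)))
        return("sample ids must be unique")
    TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta values in \eqn{[0,1]}; rows are
#'   features (CpG probes or genes), columns are samples. Dimnames are
#'   required.
#' @param sampleData a \code{data.frame} or \code{DataFrame} of per-sample
#'   metadata aligned to \code{colnames(beta)} (columns such as \code{age},
#'   \code{group}, \code{time}, \code{event}, \code{stage}, \code{sex}).
#' @return a \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' bs <- BetaSet(b, data.frame(age = c(20, 40, 60), row.names = colnames(b)))
#' sampleAges(bs)
#' @export
BetaSet <- function(beta, sampleData = NULL) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("'beta' must have row and column names")
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(beta))
    sampleData <- as(sampleData, "DataFrame")
    se <- SummarizedExperiment(assays = list(beta = beta),
                               colData = sampleData)
    new("BetaSet", se)
}

#' @describeIn BetaSet the beta-value matrix.
#' @param x a BetaSet.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname BetaSet
#' @export
setMethod("betaValues", "BetaSet", function(x) assay(x, "beta"))

#' @describeIn BetaSet per-sample ages (years), or NULL when absent.
#' @export
setGeneric("sampleAges", function(x) standardGeneric("sampleAges"))

#' @rdname BetaSet
#' @export
setMethod("sampleAges", "BetaSet", function(x) colData(x)$age)

#' @describeIn BetaSet per-sample group labels, or NULL when absent.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname BetaSet
#' @export
setMethod("sampleGroups", "BetaSet", function(x) colData(x)$group)

setMethod("show", "BetaSet", function(object) {
    cat("BetaSet with", nrow(object), "features and", ncol(object),
        "samples\n")
    callNextMethod()
})

#' ModuleSet: overlapping network modules with cohesiveness scores
#'
#' Result container for \code{\link{detectModules}}: a list of (possibly
#' overlapping) gene sets together with their cohesiveness, density and size.
#'
#' @slot modules list of character vectors (member genes per module).
#' @slot stats data.frame with one row per module: \code{f} (cohesiveness),
#'   \code{density}, \code{size}.
#' @slot params the \code{\link{cohesivenessParams}} used.
#' @seealso \code{\link{detectModules}}, \code{\link{moduleMembers}}
#' @export
setClass("ModuleSet",
         representation(modules = "list", stats = "data.frame",
                        params = "list"))

setValidity("ModuleSet", function(object) {
    if (length(object@modules) != nrow(object@stats))
        return("stats must have one row per module")
    TRUE
})

#' @describeIn ModuleSet list of member-gene vectors.
#' @param x a ModuleSet.
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @rdname ModuleSet
#' @export
setMethod("moduleMembers", "ModuleSet", function(x) x@modules)

#' @describeIn ModuleSet per-module statistics (f, density, size).
#' @export
setGeneric("moduleStats", function(x) standardGeneric("moduleStats"))

#' @rdname ModuleSet
#' @export
setMethod("moduleStats", "ModuleSet", function(x) x@stats)

#' @rdname ModuleSet
#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

setMethod("show", "ModuleSet", function(object) {
    n <- length(object@modules)
    cat("ModuleSet with", n, "modules covering",
        length(unique(unlist(object@modules))), "genes\n")
    if (n) {
        s <- object@stats
        cat("  sizes:", paste(range(s$size), collapse = "-"),
            " cohesiveness:", sprintf("%.3f-%.3f", min(s$f), max(s$f)), "\n")
    }
})
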