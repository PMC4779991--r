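# Per-edge permutation retention: is the observed Pearson r of x and y
# outside the empirical [tail, 1-tail] quantiles of r under label shuffling
# of x? Returns c(r, retained). Draws nPerm permutations from the current
# RNG stream.
edgeRetention <- function(x, y, nPerm = 1000L, tail = 0.005) {
    n <- length(x)
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 || sy == 0) return(c(r = NA_real_, retained = 0))
    xs <- (x - mean(x)) / sx
    ys <- (y - mean(y)) / sy
    r <- sum(xs * ys) / (n - 1)
    idx <- vapply(seq_len(nPerm), function(j) sample.int(n), integer(n))
    rperm <- colSums(matrix(xs[idx], n) * ys) / (n - 1)
    lo <- stats::quantile(rperm, tail, names = FALSE)
    hi <- stats::quantile(rperm, 1 - tail, names = FALSE)
    c(r = r, retained = as.numeric(r > hi || r < lo))
}

#' Build the age-associated weighted co-methylation network (ASWN)
#'
#' The protein-interaction network is restricted to the aDMGs; each
#' remaining edge is weighted by the Pearson correlation of the two genes'
#' methylation profiles across the aging samples. Per edge, one profile's
#' sample labels are shuffled \code{nPerm} times and the edge is retained
#' only when the observed correlation falls outside the empirical
#' [\code{tail}, 1 - \code{tail}] quantiles of the permuted correlations
#' (two-sided permutation test at p < 2 * tail). Non-retained edges and
#' then isolated nodes are removed. Edges are processed in sorted node-pair
#' order from a single seeded stream, so the result does not depend on the
#' input edge order.
#'
#' @param admgs character vector of aDMG symbols.
#' @param ppiEdges data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param x gene-level \linkS4class{BetaSet} (or matrix) of the aging
#'   cohort.
#' @param nPerm permutations per edge (default 1000).
#' @param tail one-sided retention tail (default 0.005, i.e. p < 0.01
#'   two-sided).
#' @param seed integer seed.
#' @return an \code{igraph} graph with edge attributes \code{weight}
#'   (Pearson r) and vertex attribute \code{is_admg}.
#' @export
buildASWN <- function(admgs, ppiEdges, x, nPerm = 1000L, tail = 0.005,
                      seed = 1L) {
    b <- if (is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    nodes <- intersect(intersect(admgs, rownames(b)),
                       unique(c(ppiEdges$gene_a, ppiEdges$gene_b)))
    if (!length(nodes))
        stop("no aDMG maps to the interaction network")
    keep <- ppiEdges$gene_a %in% nodes & ppiEdges$gene_b %in% nodes
    el <- ppiEdges[keep, c("gene_a", "gene_b"), drop = FALSE]
    a <- pmin(el$gene_a, el$gene_b)
    bb <- pmax(el$gene_a, el$gene_b)
    ord <- order(a, bb)
    a <- a[ord]; bb <- bb[ord]
    dup <- duplicated(paste(a, bb)) | a == bb
    a <- a[!dup]; bb <- bb[!dup]
    if (!length(a)) {
        warning("no interaction among the aDMGs")
        return(igraph::make_empty_graph(directed = FALSE))
    }
    res <- withSeed(seed, {
        t(vapply(seq_along(a), function(i)
            edgeRetention(b[a[i], ], b[bb[i], ], nPerm, tail),
            numeric(2)))
    })
    retained <- res[, 2] == 1 & !is.na(res[, 1])
    g <- igraph::graph_from_data_frame(
        data.frame(from = a[retained], to = bb[retained],
                   weight = res[retained, 1]),
        directed = FALSE, vertices = data.frame(name = nodes))
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    igraph::V(g)$is_admg <- TRUE
    g
}

#' Extract the age-associated cancer-related network (ACWN)
#'
#' Nodes are the cDMGs present in the ASWN plus their direct ASWN
#' neighbours. By default edges must touch at least one cDMG (so every
#' included non-cDMG gene is justified by its cDMG link);
#' \code{induced = TRUE} keeps the full induced subgraph instead. The
#' vertex attribute \code{is_cdmg} distinguishes acDMGs (aDMG and cDMG)
#' from aDMG-only neighbours.
#'
#' @param aswn ASWN graph from \code{\link{buildASWN}}.
#' @param cdmgs character vector of cDMG symbols.
#' @param induced keep all edges among the selected nodes.
#' @return an \code{igraph} graph (empty, with a warning, when no cDMG is
#'   in the ASWN).
#' @export
extractACWN <- function(aswn, cdmgs, induced = FALSE) {
    core <- intersect(cdmgs, igraph::V(aswn)$name)
    if (!length(core)) {
        warning("no cDMG present in the ASWN; returning an empty graph")
        return(igraph::make_empty_graph(directed = FALSE))
    }
    adj <- igraph::adjacent_vertices(aswn, core)
    nb <- unique(unlist(lapply(adj, function(v)
        igraph::V(aswn)$name[as.integer(v)])))
    nodes <- union(core, nb)
    g <- igraph::induced_subgraph(aswn, nodes)
    if (!induced) {
        el <- igraph::as_edgelist(g)
        drop <- !(el[, 1] %in% core | el[, 2] %in% core)
        g <- igraph::delete_edges(g, which(drop))
        g <- igraph::delete_vertices(g,
                                     igraph::V(g)[igraph::degree(g) == 0 &
                                                  !igraph::V(g)$name %in% core])
    }
    igraph::V(g)$is_cdmg <- igraph::V(g)$name %in% cdmgs
    g
}

#' Network topology: degree and clustering coefficient
#'
#' Per-node degree \eqn{k_i}, number of edges among neighbours \eqn{n_i}
#' and local clustering coefficient
#' \eqn{C_i = 2 n_i / (k_i (k_i - 1))} (0 when \eqn{k_i < 2}), with network
#' means and the degree histogram for log-log plotting.
#'
#' @param g an \code{igraph} graph (simple, undirected).
#' @return list with \code{degree}, \code{n_neighbor_edges},
#'   \code{clustering}, \code{mean_degree}, \code{mean_clustering},
#'   \code{degree_histogram} (data.frame \code{degree}, \code{count}).
#' @export
networkTopology <- function(g) {
    if (igraph::vcount(g) == 0) stop("empty graph")
    k <- igraph::degree(g)
    tri <- igraph::count_triangles(g)
    ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
    names(ci) <- names(k)
    hist <- as.data.frame(table(degree = k), stringsAsFactors = FALSE)
    hist$degree <- as.integer(hist$degree)
    names(hist)[2] <- "count"
    list(degree = k, n_neighbor_edges = stats::setNames(tri, names(k)),
         clustering = ci,
         mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
         mean_clustering = mean(ci),
         degree_histogram = hist)
}

#' Random induced-subnetwork null distribution
#'
#' Repeatedly samples \code{nNodes} nodes uniformly without replacement
#' from the background network, induces the subgraph and records its mean
#' degree and mean clustering coefficient; the empirical comparison p-value
#' for an observed statistic is the fraction of repetitions at or above it
#' (see \code{\link{empiricalP}}).
#'
#' @param ppi background network: \code{igraph} graph or edge data.frame
#'   (\code{gene_a}, \code{gene_b}).
#' @param nNodes nodes per sample (the observed network's node count).
#' @param reps repetitions (default 1000).
#' @param seed integer seed.
#' @return data.frame with \code{mean_degree}, \code{mean_clustering}, one
#'   row per repetition.
#' @export
randomSubnetworks <- function(ppi, nNodes, reps = 1000L, seed = 1L) {
    g <- if (igraph::is_igraph(ppi)) ppi else
        igraph::graph_from_data_frame(ppi[, c("gene_a", "gene_b")],
                                      directed = FALSE)
    if (nNodes > igraph::vcount(g))
        stop("nNodes exceeds the background network size")
    withSeed(seed, {
        out <- t(vapply(seq_len(reps), function(i) {
            vs <- sample(igraph::V(g), nNodes)
            sg <- igraph::induced_subgraph(g, vs)
            k <- igraph::degree(sg)
            tri <- igraph::count_triangles(sg)
            ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
            c(2 * igraph::ecount(sg) / igraph::vcount(sg), mean(ci))
        }, numeric(2)))
        data.frame(mean_degree = out[, 1], mean_clustering = out[, 2])
    })
}

#' Empirical upper-tail comparison p-value
#'
#' @param dist numeric null distribution.
#' @param observed observed statistic.
#' @return fraction of the null at or above the observed value.
#' @export
empiricalP <- function(dist, observed) mean(dist >= observed)

#' Hub genes by degree
#'
#' Nodes in the top \code{fraction} of the degree ranking; all nodes tied
#' at the cutoff degree are included.
#'
#' @param g an \code{igraph} graph.
#' @param fraction top fraction by degree (default 0.15).
#' @return character vector of hub gene names.
#' @export
hubGenes <- function(g, fraction = 0.15) {
    if (igraph::vcount(g) == 0) stop("empty graph")
    k <- igraph::degree(g)
    ncut <- max(1L, ceiling(fraction * length(k)))
    cutoff <- sort(k, decreasing = TRUE)[ncut]
    names(k)[k >= cutoff]
}
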