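#' Parameters for greedy cohesiveness module detection
#'
#' Defaults follow the published conventions for cohesiveness-based
#' overlapping module detection: node penalty 2, minimum size 3, minimum
#' density 0.5, overlap-merge threshold 0.8.
#'
#' @param penalty non-negative per-node penalty in the cohesiveness
#'   denominator (models unobserved boundary interactions).
#' @param min_size smallest reported module.
#' @param min_density minimum internal edge density
#'   \eqn{2 m / (s (s - 1))}.
#' @param overlap_threshold modules with overlap score
#'   \eqn{\omega(A,B) = |A \cap B|^2 / (|A| |B|)} at or above this are
#'   merged.
#' @return list of class \code{"cohesivenessParams"}.
#' @export
cohesivenessParams <- function(penalty = 2, min_size = 3L,
                               min_density = 0.5,
                               overlap_threshold = 0.8) {
    if (penalty < 0) stop("penalty must be >= 0")
    if (overlap_threshold <= 0 || overlap_threshold > 1)
        stop("overlap_threshold must lie in (0, 1]")
    if (min_size < 1) stop("min_size must be >= 1")
    structure(list(penalty = penalty, min_size = as.integer(min_size),
                   min_density = min_density,
                   overlap_threshold = overlap_threshold),
              class = "cohesivenessParams")
}

# Adjacency list with non-negative weights: list of named numeric vectors.
# Negative co-methylation weights enter by absolute value (the permutation
# retention test is two-sided, so a strong negative correlation is as
# cohesive as a positive one).
adjacencyList <- function(g) {
    if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
    el <- igraph::as_edgelist(g)
    w <- abs(igraph::E(g)$weight)
    nodes <- igraph::V(g)$name
    adj <- stats::setNames(
        rep(list(stats::setNames(numeric(0), character(0))), length(nodes)),
        nodes)
    for (i in seq_along(w)) {
        adj[[el[i, 1]]][el[i, 2]] <- w[i]
        adj[[el[i, 2]]][el[i, 1]] <- w[i]
    }
    adj
}

#' Cohesiveness of a node set
#'
#' \eqn{f(V) = w_{in} / (w_{in} + w_{bound} + p |V|)}: total internal edge
#' weight over internal plus boundary weight plus a per-node penalty. Edge
#' weights are taken as absolute values.
#'
#' @param g an \code{igraph} graph with (possibly signed) edge weights.
#' @param members character vector of member nodes.
#' @param penalty per-node penalty (default 0).
#' @return list with \code{f}, \code{w_in}, \code{w_bound}.
#' @export
cohesiveness <- function(g, members, penalty = 0) {
    if (!length(members)) stop("empty member set")
    if (!all(members %in% igraph::V(g)$name))
        stop("members must be graph nodes")
    adj <- adjacencyList(g)
    st <- setCohesion(adj, members, penalty)
    list(f = st$f, w_in = st$w_in, w_bound = st$w_bound)
}

setCohesion <- function(adj, members, penalty) {
    w_in <- 0; w_bound <- 0
    inset <- stats::setNames(rep(TRUE, length(members)), members)
    for (v in members) {
        nb <- adj[[v]]
        ins <- names(nb) %in% members
        w_in <- w_in + sum(nb[ins])
        w_bound <- w_bound + sum(nb[!ins])
    }
    w_in <- w_in / 2
    denom <- w_in + w_bound + penalty * length(members)
    list(f = if (denom > 0) w_in / denom else 0,
         w_in = w_in, w_bound = w_bound)
}

#' Grow one cohesive module from a seed node
#'
#' Starting from the singleton seed, repeatedly applies the single best
#' addition of a boundary node or removal of an internal node that strictly
#' increases cohesiveness, until a local optimum is reached. Ties are
#' broken deterministically (additions before removals, then lexicographic
#' node id).
#'
#' @param g an \code{igraph} graph.
#' @param seedNode seed vertex name.
#' @param params a \code{\link{cohesivenessParams}}.
#' @return list with \code{members}, \code{f}, \code{w_in},
#'   \code{w_bound}.
#' @export
growCluster <- function(g, seedNode, params = cohesivenessParams()) {
    if (!seedNode %in% igraph::V(g)$name)
        stop("seed node not in the graph")
    adj <- adjacencyList(g)
    growClusterAdj(adj, seedNode, params$penalty)
}

growClusterAdj <- function(adj, seedNode, penalty) {
    members <- seedNode
    st <- setCohesion(adj, members, penalty)
    repeat {
        inside <- function(v) names(adj[[v]]) %in% members
        boundary <- setdiff(unique(unlist(lapply(members, function(v)
            names(adj[[v]])))), members)
        cand <- list()
        for (v in sort(boundary)) {
            nb <- adj[[v]]
            s_in <- sum(nb[inside(v)])
            s_out <- sum(nb) - s_in
            w_in2 <- st$w_in + s_in
            w_b2 <- st$w_bound - s_in + s_out
            d2 <- w_in2 + w_b2 + penalty * (length(members) + 1)
            cand[[length(cand) + 1]] <- list(
                type = "add", node = v,
                f = if (d2 > 0) w_in2 / d2 else 0,
                w_in = w_in2, w_bound = w_b2)
        }
        if (length(members) > 1) {
            for (v in sort(members)) {
                nb <- adj[[v]]
                ins <- names(nb) %in% setdiff(members, v)
                s_in <- sum(nb[ins])
                s_out <- sum(nb) - s_in
                w_in2 <- st$w_in - s_in
                w_b2 <- st$w_bound - s_out + s_in
                d2 <- w_in2 + w_b2 + penalty * (length(members) - 1)
                cand[[length(cand) + 1]] <- list(
                    type = "remove", node = v,
                    f = if (d2 > 0) w_in2 / d2 else 0,
                    w_in = w_in2, w_bound = w_b2)
            }
        }
        if (!length(cand)) break
        fs <- vapply(cand, `[[`, numeric(1), "f")
        best <- cand[[which.max(fs)]]
        if (best$f <= st$f + 1e-12) break
        if (best$type == "add")
            members <- c(members, best$node)
        else
            members <- setdiff(members, best$node)
        st <- list(f = best$f, w_in = best$w_in, w_bound = best$w_bound)
    }
    list(members = sort(members), f = st$f, w_in = st$w_in,
         w_bound = st$w_bound)
}

overlapScore <- function(a, b)
    length(intersect(a, b))^2 / (length(a) * length(b))

# Merge modules whose pairwise overlap score reaches the threshold:
# connected components of the overlap graph are unioned, repeated to a
# fixed point. Component-wise merging makes the result independent of the
# processing order.
mergeModules <- function(mods, threshold) {
    mods <- unique(lapply(mods, sort))
    repeat {
        n <- length(mods)
        if (n < 2) return(mods)
        comp <- seq_len(n)
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            if (overlapScore(mods[[i]], mods[[j]]) >= threshold) {
                old <- comp[j]; comp[comp == old] <- comp[i]
            }
        }
        merged <- lapply(split(seq_len(n), comp), function(ix)
            sort(unique(unlist(mods[ix]))))
        merged <- unique(unname(merged))
        if (length(merged) == length(mods)) return(merged)
        mods <- merged
    }
}

#' Detect overlapping cohesive modules
#'
#' Greedy cohesiveness optimisation over the whole graph: nodes are used as
#' seeds in decreasing order of weighted degree (skipping nodes already
#' covered by a grown module), each seed is grown with
#' \code{\link{growCluster}}, modules with overlap score at or above
#' \code{overlap_threshold} are merged (to a fixed point), and modules
#' smaller than \code{min_size} or sparser than \code{min_density} are
#' discarded. Modules may overlap.
#'
#' @param g an \code{igraph} graph with edge weights (absolute values are
#'   used).
#' @param params a \code{\link{cohesivenessParams}}.
#' @return a \linkS4class{ModuleSet}.
#' @export
detectModules <- function(g, params = cohesivenessParams()) {
    if (igraph::vcount(g) == 0) stop("empty graph")
    adj <- adjacencyList(g)
    strength <- vapply(adj, sum, numeric(1))
    seeds <- names(sort(strength, decreasing = TRUE))
    # stable ordering: strength desc, then node id
    seeds <- seeds[order(-strength[seeds], seeds)]
    covered <- character(0)
    mods <- list()
    for (s in seeds) {
        if (s %in% covered) next
        m <- growClusterAdj(adj, s, params$penalty)
        mods[[length(mods) + 1]] <- m$members
        covered <- union(covered, m$members)
    }
    mods <- mergeModules(mods, params$overlap_threshold)
    stats_rows <- lapply(mods, function(members) {
        st <- setCohesion(adj, members, params$penalty)
        s <- length(members)
        m_in <- 0
        for (v in members)
            m_in <- m_in + sum(names(adj[[v]]) %in% members)
        m_in <- m_in / 2
        dens <- if (s > 1) 2 * m_in / (s * (s - 1)) else 0
        data.frame(f = st$f, density = dens, size = s)
    })
    stats <- do.call(rbind, stats_rows)
    rownames(stats) <- NULL
    keep <- stats$size >= params$min_size &
        stats$density >= params$min_density
    new("ModuleSet", modules = mods[keep],
        stats = stats[keep, , drop = FALSE],
        params = unclass(params))
}
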