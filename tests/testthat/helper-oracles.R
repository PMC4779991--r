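# Independent brute-force oracles used to validate the closed-form /
# library-backed implementations.

# Two-sided Fisher exact p by enumerating the hypergeometric support of a
# 2x2 table with fixed margins.
fisherEnumOracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- vapply(support, function(x)
        exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)),
        numeric(1))
    p_obs <- probs[match(a, support)]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by summing the pmf over all overlaps.
hyperEnumOracle <- function(overlap, targetSize, universeSize, querySize) {
    support <- 0:min(targetSize, querySize)
    probs <- vapply(support, function(x)
        exp(lchoose(targetSize, x) +
            lchoose(universeSize - targetSize, querySize - x) -
            lchoose(universeSize, querySize)), numeric(1))
    sum(probs[support >= overlap])
}

# Local clustering coefficient by enumerating neighbour pairs.
clusteringBruteForce <- function(g) {
    vs <- igraph::V(g)$name
    adj <- lapply(vs, function(v)
        igraph::V(g)$name[as.integer(igraph::neighbors(g, v))])
    names(adj) <- vs
    vapply(vs, function(v) {
        nb <- adj[[v]]
        k <- length(nb)
        if (k < 2) return(0)
        m <- 0
        for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
            if (nb[j] %in% adj[[nb[i]]]) m <- m + 1
        2 * m / (k * (k - 1))
    }, numeric(1))
}

# Exhaustive best-cohesiveness subset of a small graph.
bestSubsetCohesiveness <- function(g, penalty = 0) {
    vs <- igraph::V(g)$name
    best <- 0
    for (sz in seq_along(vs)) {
        combs <- utils::combn(vs, sz, simplify = FALSE)
        for (s in combs) {
            f <- cohesiveness(g, s, penalty)$f
            if (f > best) best <- f
        }
    }
    best
}
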