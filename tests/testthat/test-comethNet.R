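test_that("perfectly correlated and anti-correlated edges are always retained", {
    n <- 60
    x <- seq(0.1, 0.9, length.out = n)
    b <- rbind(gA = x, gB = x, gC = 1 - x)
    colnames(b) <- paste0("s", seq_len(n))
    ppi <- data.frame(gene_a = c("gA", "gA"), gene_b = c("gB", "gC"))
    g <- buildASWN(c("gA", "gB", "gC"), ppi, b, nPerm = 200, tail = 0.01,
                   seed = 2)
    expect_equal(igraph::ecount(g), 2)
    w <- igraph::E(g)$weight
    expect_equal(sort(w), c(-1, 1), tolerance = 1e-12)
    expect_error(buildASWN("gZ", ppi, b), "no aDMG")
})

test_that("ASWN edge filtering drops null edges and isolated nodes", {
    set.seed(8)
    n <- 80
    b <- matrix(runif(5 * n), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    b["g2", ] <- b["g1", ] + rnorm(n, sd = 0.01)  # strong co-methylation
    ppi <- data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"))
    g <- buildASWN(paste0("g", 1:5), ppi, b, nPerm = 500, tail = 0.005,
                   seed = 4)
    expect_true(all(c("g1", "g2") %in% igraph::V(g)$name))
    # the independent pair is filtered and its endpoints dropped
    expect_false("g3" %in% igraph::V(g)$name)
    # determinism
    g2 <- buildASWN(paste0("g", 1:5), ppi, b, nPerm = 500, tail = 0.005,
                    seed = 4)
    expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
})

test_that("ACWN keeps cDMGs, their neighbours and cDMG-touching edges", {
    g <- igraph::graph_from_data_frame(
        data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1),
        directed = FALSE)
    acwn <- extractACWN(g, "b")
    expect_setequal(igraph::V(acwn)$name, c("a", "b", "c"))
    expect_equal(igraph::ecount(acwn), 2)

    tri <- igraph::graph_from_data_frame(
        data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                   weight = 1), directed = FALSE)
    acwn2 <- extractACWN(tri, c("a", "b"))
    expect_equal(igraph::ecount(acwn2), 3)  # bc touches b, a cDMG
    expect_warning(out <- extractACWN(tri, "zzz"), "no cDMG")
    expect_equal(igraph::vcount(out), 0)
    # the neighbour-neighbour edge bc between two non-cDMGs is excluded by
    # default but kept under the induced-subgraph rule
    acwn3 <- extractACWN(tri, "a")
    expect_equal(igraph::ecount(acwn3), 2)
    acwn4 <- extractACWN(tri, "a", induced = TRUE)
    expect_equal(igraph::ecount(acwn4), 3)
})

test_that("the ACWN is a subgraph of the ASWN", {
    res <- smallPipeline()
    aswn <- res$network$aswn; acwn <- res$network$acwn
    expect_true(all(igraph::V(acwn)$name %in% igraph::V(aswn)$name))
    ek <- function(g) {
        el <- igraph::as_edgelist(g)
        paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
    expect_true(all(ek(acwn) %in% ek(aswn)))
})

test_that("topology matches closed forms and brute-force triangle counting", {
    tri <- igraph::make_full_graph(3)
    igraph::V(tri)$name <- c("a", "b", "c")
    t1 <- networkTopology(tri)
    expect_true(all(t1$clustering == 1))
    expect_equal(t1$mean_degree, 2)
    path <- igraph::graph_from_data_frame(
        data.frame(from = c("a", "b"), to = c("b", "c")), directed = FALSE)
    t2 <- networkTopology(path)
    expect_equal(unname(t2$clustering["b"]), 0)
    expect_equal(t2$mean_degree, 4 / 3)
    expect_equal(t2$mean_degree,
                 2 * igraph::ecount(path) / igraph::vcount(path))
    # oracle equivalence on random graphs up to 50 nodes
    set.seed(12)
    for (i in 1:3) {
        g <- igraph::sample_gnp(sample(10:50, 1), 0.2)
        igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
        tp <- networkTopology(g)
        expect_equal(unname(tp$clustering), unname(clusteringBruteForce(g)),
                     tolerance = 1e-12)
        expect_equal(tp$mean_degree,
                     2 * igraph::ecount(g) / igraph::vcount(g))
    }
    expect_error(networkTopology(igraph::make_empty_graph(directed = FALSE)),
                 "empty")
})

test_that("random subnetworks reproduce the full network when sampling all nodes", {
    set.seed(3)
    g <- igraph::sample_gnp(30, 0.2)
    igraph::V(g)$name <- paste0("n", 1:30)
    full <- networkTopology(g)
    rs <- randomSubnetworks(g, 30, reps = 5, seed = 1)
    expect_true(all(abs(rs$mean_degree - full$mean_degree) < 1e-12))
    expect_true(all(abs(rs$mean_clustering - full$mean_clustering) < 1e-12))
    expect_identical(randomSubnetworks(g, 10, reps = 20, seed = 9),
                     randomSubnetworks(g, 10, reps = 20, seed = 9))
    expect_error(randomSubnetworks(g, 31, reps = 2), "exceeds")
    expect_equal(empiricalP(c(1, 2, 3, 4), 3), 0.5)
})

test_that("a planted-community network out-clusters random subnetworks", {
    res <- smallPipeline()
    obs <- res$network$topology$mean_clustering
    expect_gt(obs, stats::quantile(res$network$random$mean_clustering, 0.95))
})

test_that("hub selection keeps all ties at the cutoff degree", {
    star <- igraph::make_star(20, mode = "undirected")
    igraph::V(star)$name <- c("hub", paste0("leaf", 1:19))
    # top 15% of 20 nodes = 3, but all 19 leaves tie at degree 1
    expect_identical(length(hubGenes(star, 0.15)), 20L)
    ring <- igraph::make_ring(10)
    igraph::V(ring)$name <- paste0("r", 1:10)
    expect_identical(length(hubGenes(ring, 0.15)), 10L)  # all tied
    g <- igraph::graph_from_data_frame(
        data.frame(from = c("a", "a", "a", "b"), to = c("b", "c", "d", "c")),
        directed = FALSE)
    expect_identical(sort(hubGenes(g, 1.0)),
                     sort(igraph::V(g)$name))
    expect_identical(hubGenes(g, 0.25), "a")
})
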