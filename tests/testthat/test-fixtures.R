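test_that("the simulated tree has the documented role structure", {
    tree <- makeSimTree()
    expect_equal(length(genes(tree)), 31L)
    expect_equal(unname(signedDegree(tree, "S9")), c(0L, 1L))
    expect_equal(unname(signedDegree(tree, "S15")), c(0L, 1L))
    # the two negative leaves see identical 1-hop rings
    expect_equal(degreeRings(tree, "S9", 1)[[2]],
                 degreeRings(tree, "S15", 1)[[2]], ignore_attr = TRUE)
    # positive backbone: connected tree over the positively linked genes
    gp <- igraph::graph_from_edgelist(posEdges(tree), directed = FALSE)
    expect_true(igraph::is_connected(gp))
    expect_equal(igraph::ecount(gp), igraph::vcount(gp) - 1) # acyclic
    # matches the packaged edge list
    shipped <- readEdgeList(system.file("extdata", "sim_tree_edges.tsv",
                                        package = "signedRoles"))
    expect_identical(posEdges(shipped), posEdges(tree))
    expect_identical(negEdges(shipped), negEdges(tree))
})

test_that("preferential attachment yields the exact edge count", {
    net <- makeScaleFree(200, mAttach = 2, negFraction = 0, seed = 1)
    expect_equal(nrow(posEdges(net)) + nrow(negEdges(net)), 396L) # 2(n - m)
    expect_equal(nrow(negEdges(net)), 0L)
    expect_equal(length(genes(net)), 200L)

    # negative fraction concentrates around its nominal value
    n <- 500
    net2 <- makeScaleFree(n, mAttach = 2, negFraction = 0.3, seed = 2)
    e <- nrow(posEdges(net2)) + nrow(negEdges(net2))
    phat <- nrow(negEdges(net2)) / e
    expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / e))

    expect_error(makeScaleFree(2, mAttach = 2, seed = 1), "n > mAttach")
    expect_error(makeScaleFree(10, 2, negFraction = 1.5, seed = 1),
                 "negFraction")
    expect_error(makeScaleFree(10, 2), "seed")
})

test_that("generators are pure functions of spec and seed", {
    a <- makeScaleFree(80, 2, 0.4, seed = 5)
    b <- makeScaleFree(80, 2, 0.4, seed = 5)
    expect_identical(posEdges(a), posEdges(b))
    expect_identical(negEdges(a), negEdges(b))
    c <- makeScaleFree(80, 2, 0.4, seed = 6)
    expect_false(identical(posEdges(a), posEdges(c)))

    base <- makeScaleFree(100, 2, 0.3, seed = 7)
    p1 <- makePerturbedPair(base, 10, seed = 8)
    p2 <- makePerturbedPair(base, 10, seed = 8)
    expect_identical(posEdges(p1$netB), posEdges(p2$netB))
    expect_identical(p1$perturbed, p2$perturbed)
})

test_that("generated networks always satisfy the signed-network invariants", {
    set.seed(123)
    for (i in 1:100) {
        n <- sample(10:60, 1)
        net <- makeScaleFree(n, sample(1:3, 1), runif(1), seed = i)
        expect_true(validObject(net))
        deg <- signedDegree(net)
        expect_true(all(rowSums(deg) >= 1))
    }
})

test_that("perturbed pairs change the planted genes and little else", {
    base <- makeScaleFree(150, 2, 0.3, seed = 17)

    # no perturbation: identical copies
    p0 <- makePerturbedPair(base, 0, seed = 18)
    expect_identical(posEdges(p0$netA), posEdges(p0$netB))

    pp <- makePerturbedPair(base, 15, seed = 19)
    expect_equal(networkContext(pp$netA), "c1")
    expect_equal(networkContext(pp$netB), "c2")
    dA <- signedDegree(pp$netA); dB <- signedDegree(pp$netB)
    common <- intersect(rownames(dA), rownames(dB))
    delta <- rowSums(abs(dB[common, ] - dA[common, ]))
    # every planted gene moved by >= 2 in L1 signed degree
    expect_true(all(delta[intersect(pp$perturbed, common)] >= 2))
    # total edge count preserved
    expect_equal(nrow(posEdges(pp$netB)) + nrow(negEdges(pp$netB)),
                 nrow(posEdges(pp$netA)) + nrow(negEdges(pp$netA)))
    # collateral stays within the documented bound
    expect_lte(length(pp$collateral), 2 * 15)
    expect_error(makePerturbedPair(base, 40, seed = 1), "kGenes")
})

test_that("twin fixtures plant automorphic pairs", {
    tw <- makeTwinPairs(n = 80, nTwinPairs = 6, seed = 21)
    expect_equal(length(genes(tw$net)), 80L)
    neigh <- function(net, v, sgn) {
        e <- if (sgn > 0) posEdges(net) else negEdges(net)
        sort(c(e[e[, 1] == v, 2], e[e[, 2] == v, 1]))
    }
    for (i in seq_len(nrow(tw$twins))) {
        a <- tw$twins$a[i]; b <- tw$twins$b[i]
        expect_identical(neigh(tw$net, a, 1), neigh(tw$net, b, 1))
        expect_identical(neigh(tw$net, a, -1), neigh(tw$net, b, -1))
        expect_false(b %in% c(neigh(tw$net, a, 1), neigh(tw$net, a, -1)))
    }
})

test_that("multi-context cohorts separate the two planted patterns", {
    base <- makeScaleFree(80, 2, 0.3, seed = 31)
    mc <- makeMultiContext(base, C = 3, kGenesPerClass = 5, seed = 32)
    expect_equal(length(contexts(mc$merged)), 3L)
    expect_equal(sum(mc$truth$class == "all"), 5L)
    expect_equal(sum(mc$truth$class == "one"), 5L)
    # genes perturbed everywhere list every context
    expect_true(all(mc$truth$perturbedIn[mc$truth$class == "all"] ==
                    "c1,c2,c3"))
    # an unperturbed cohort leaves all copies identical
    mc0 <- makeMultiContext(base, C = 3, kGenesPerClass = 0, seed = 33)
    nets <- mc0$merged@networks
    expect_identical(posEdges(nets[[1]]), posEdges(nets[[2]]))
    expect_identical(negEdges(nets[[2]]), negEdges(nets[[3]]))
})

test_that("multi-context embeddings rank planted classes as designed", {
    base <- makeScaleFree(80, 2, 0.3, seed = 41)
    mc <- makeMultiContext(base, C = 3, kGenesPerClass = 6, seed = 42)
    emb <- embedNetworks(mc$merged, kMax = 2, dim = 16, walksPerNode = 6,
                         walkLength = 40, seed = 43)
    rep <- classifyDTGs(emb, sdAuto = TRUE)
    allG <- mc$truth$gene[mc$truth$class == "all"]
    oneG <- mc$truth$gene[mc$truth$class == "one"]
    nullG <- setdiff(rep$gene, mc$truth$gene)
    # consistently rewired genes drift more on average than null genes
    expect_gt(mean(rep$meanDist[rep$gene %in% allG]),
              mean(rep$meanDist[rep$gene %in% nullG]))
    # single-context rewiring shows up more in SD rank than mean rank
    sdRank <- rank(rep$sdDist); meanRank <- rank(rep$meanDist)
    oneRows <- rep$gene %in% oneG
    expect_gt(mean(sdRank[oneRows]), mean(sdRank[rep$gene %in% nullG]))
})
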