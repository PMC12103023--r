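twoCtxEmb <- function(vecs1, vecs2, genes) {
    m <- rbind(vecs1, vecs2)
    rownames(m) <- c(paste0(genes, "::c1"), paste0(genes, "::c2"))
    embFromMatrix(m)
}

test_that("centroid distances follow the midpoint geometry", {
    emb <- twoCtxEmb(rbind(c(0, 0)), rbind(c(2, 0)), "g")
    gd <- geneDistances(emb, "g")
    expect_equal(gd$center, c(1, 0), ignore_attr = TRUE)
    expect_equal(unname(gd$distances), c(1, 1))
    expect_equal(gd$mean, 1)

    # identical vectors in every context: all distances zero
    emb0 <- twoCtxEmb(rbind(c(3, 4)), rbind(c(3, 4)), "g")
    expect_equal(unname(geneDistances(emb0, "g")$distances), c(0, 0))

    # three contexts, hand-computed centroid and distances
    m <- rbind("g::c1" = c(0, 0), "g::c2" = c(3, 0), "g::c3" = c(0, 4))
    gd3 <- geneDistances(embFromMatrix(m), "g")
    expect_equal(gd3$center, c(1, 4 / 3), ignore_attr = TRUE)
    expected <- c(sqrt(1 + 16 / 9), sqrt(4 + 16 / 9), sqrt(1 + 64 / 9))
    expect_equal(unname(gd3$distances), expected, tolerance = 1e-9)
    expect_equal(gd3$mean, mean(expected), tolerance = 1e-9)

    # missing context is refused with the reason
    m2 <- rbind("g::c1" = c(0, 0), "g::c2" = c(3, 0), "h::c1" = c(1, 1),
                "h::c2" = c(0, 0), "h::c3" = c(2, 2))
    expect_error(geneDistances(embFromMatrix(m2), "g"), "missing from")
})

test_that("for two contexts both distances equal half the pair distance", {
    set.seed(12)
    n <- 40
    emb <- twoCtxEmb(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4), n),
                     paste0("g", 1:n))
    for (g in paste0("g", sample(n, 10))) {
        gd <- geneDistances(emb, g)
        pair <- sqrt(sum((embeddingMatrix(emb)[paste0(g, "::c1"), ] -
                          embeddingMatrix(emb)[paste0(g, "::c2"), ])^2))
        expect_equal(unname(gd$distances[1]), pair / 2)
        expect_equal(unname(gd$distances[2]), pair / 2)
    }
})

test_that("the distance SD is the population form", {
    expect_equal(distanceSD(c(5, 5, 5)), 0)
    expect_equal(distanceSD(c(0, 2)), 1)
    expect_equal(distanceSD(c(1, 2, 3)), sqrt(2 / 3), tolerance = 1e-9)
})

test_that("pairwise DTG selection flags exactly the top decile", {
    set.seed(77)
    n <- 200
    emb <- twoCtxEmb(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4), n),
                     paste0("g", 1:n))
    rep <- classifyDTGs(emb)
    expect_equal(nrow(rep), n)
    expect_equal(sum(rep$flag == "dtg_mean"), 20L)
    expect_equal(rep$meanDist, sort(rep$meanDist, decreasing = TRUE))
    # flagged genes are exactly the largest distances
    expect_true(min(rep$meanDist[rep$flag == "dtg_mean"]) >=
                max(rep$meanDist[rep$flag == "not_dtg"]))

    # degenerate case: identical embeddings still flag 10% by rank
    m0 <- matrix(1, n, 4)
    embDeg <- twoCtxEmb(m0, m0, paste0("g", 1:n))
    repDeg <- classifyDTGs(embDeg)
    expect_equal(sum(repDeg$flag == "dtg_mean"), 20L)
    expect_true(all(repDeg$meanDist == 0))
})

test_that("multi-context DTG selection uses the 5% mean and SD rules", {
    set.seed(99)
    n <- 100; C <- 4
    mats <- lapply(1:C, function(i) matrix(rnorm(n * 3, sd = 0.1), n))
    # gene 1 drifts in every context; gene 2 jumps in exactly one
    for (i in 1:C) mats[[i]][1, ] <- rnorm(3, mean = 3 * i)
    mats[[2]][2, ] <- mats[[1]][2, ] + 20
    m <- do.call(rbind, mats)
    rownames(m) <- unlist(lapply(1:C, function(i) paste0("g", 1:n, "::c", i)))
    rep <- classifyDTGs(embFromMatrix(m), sdThreshold = 0.4)
    expect_equal(sum(rep$flag == "dtg_mean"), ceiling(0.05 * n))
    expect_true("g1" %in% rep$gene[rep$flag == "dtg_mean"])
    expect_true("g2" %in% rep$gene[rep$flag != "not_dtg"])
    expect_true(all(rep$sdDist >= 0))

    # the automatic threshold flags the top-5% SD tail
    repAuto <- classifyDTGs(embFromMatrix(m), sdAuto = TRUE)
    thr <- attr(repAuto, "params")$sdThreshold
    expect_equal(sum(repAuto$sdDist > thr & repAuto$flag == "dtg_sd") +
                 sum(repAuto$sdDist > thr & repAuto$flag == "dtg_mean"),
                 sum(repAuto$sdDist > thr))
})

test_that("genes missing from a context are excluded but reported", {
    m <- rbind("a::c1" = c(0, 0), "a::c2" = c(1, 0),
               "b::c1" = c(0, 0), "b::c2" = c(2, 0),
               "only1::c1" = c(5, 5))
    rep <- classifyDTGs(embFromMatrix(m))
    expect_setequal(rep$gene, c("a", "b"))
    expect_equal(attr(rep, "excluded"), "only1")
})

test_that("Louvain modules recover the dumbbell partition and size filter", {
    c1 <- paste0("a", 1:15); c2 <- paste0("b", 1:15)
    dumbbell <- SignedNetwork(pos = rbind(cliqueEdges(c1), cliqueEdges(c2),
                                          c("a1", "b1")))
    mods <- louvainModules(dumbbell, minSize = 10, seed = 1)
    expect_equal(length(mods$modules), 2L)
    expect_setequal(lapply(unname(mods$modules), sort),
                    list(sort(c1), sort(c2)))

    # an extra 5-clique falls below the size threshold
    c3 <- paste0("s", 1:5)
    withSmall <- SignedNetwork(pos = rbind(cliqueEdges(c1), cliqueEdges(c2),
                                           cliqueEdges(c3), c("a1", "b1"),
                                           c("b1", "s1")))
    mods2 <- louvainModules(withSmall, minSize = 10, seed = 1)
    expect_equal(length(mods2$modules), 2L)
    expect_equal(unname(lengths(mods2$dropped)), 5L)

    # everything small: empty report plus warning
    tiny <- SignedNetwork(pos = rbind(c("x", "y"), c("y", "z")))
    expect_warning(mods3 <- louvainModules(tiny, minSize = 10), "minimum size")
    expect_equal(length(mods3$modules), 0L)
})

test_that("module stability reports mean shift and NA%", {
    gs <- paste0("g", 1:10)
    v1 <- matrix(0, 10, 2); v2 <- matrix(0, 10, 2)
    emb <- twoCtxEmb(v1, v2, gs)
    st <- moduleStability(list(m1 = gs), emb, "c1", "c2")
    expect_equal(st$meanDistance, 0)
    expect_equal(st$naPct, 0)

    # half the module absent from c2
    m <- rbind(matrix(0, 10, 2), matrix(0, 5, 2))
    rownames(m) <- c(paste0(gs, "::c1"), paste0(gs[1:5], "::c2"))
    st2 <- moduleStability(list(m1 = gs), embFromMatrix(m), "c1", "c2")
    expect_equal(st2$naPct, 0.5)
    expect_equal(st2$shared, 5L)

    # hand-computed mean over pair distances {1, 1, 2, 4}
    g4 <- paste0("g", 1:4)
    v1 <- matrix(0, 4, 2)
    v2 <- rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 4))
    st3 <- moduleStability(list(m1 = g4), twoCtxEmb(v1, v2, g4), "c1", "c2")
    expect_equal(st3$meanDistance, 2, tolerance = 1e-9)

    # order of members and of modules is irrelevant
    st4 <- moduleStability(list(m1 = rev(g4)), twoCtxEmb(v1, v2, g4),
                           "c1", "c2")
    expect_equal(st4$meanDistance, st3$meanDistance)

    # empty intersection: NA mean, NA% = 1
    mOnly <- rbind("h1::c1" = c(0, 0), "h2::c1" = c(1, 1),
                   "z::c2" = c(0, 0))
    st5 <- moduleStability(list(m1 = c("h1", "h2")), embFromMatrix(mOnly),
                           "c1", "c2")
    expect_true(is.na(st5$meanDistance))
    expect_equal(st5$naPct, 1)
})

test_that("topology metrics match closed forms on canonical graphs", {
    # 4-node positive clique: local clustering 1 everywhere
    k4 <- SignedNetwork(pos = cliqueEdges(paste0("v", 1:4)))
    tm <- topologyMetrics(k4)
    expect_equal(tm$clusteringPos, rep(1, 4))
    expect_equal(tm$clusteringNeg, rep(0, 4))
    expect_equal(tm$degreeCentralityPos, rep(1, 4))

    # positive star with n = 5: center degree centrality 4/(5-1) = 1
    star <- SignedNetwork(pos = cbind("hub", paste0("s", 1:4)))
    tms <- topologyMetrics(star)
    expect_equal(tms$degreeCentralityPos[tms$gene == "hub"], 1)

    # middle of a 3-path carries all shortest paths: betweenness 1
    p3 <- SignedNetwork(pos = rbind(c("a", "m"), c("m", "b")))
    tmp <- topologyMetrics(p3)
    expect_equal(tmp$betweenness[tmp$gene == "m"], 1)
    expect_equal(tmp$betweenness[tmp$gene == "a"], 0)
})

test_that("topology metrics agree with brute-force recomputation", {
    nets <- list(
        makeSimTree(),
        makeScaleFree(12, 2, 0.4, seed = 3),
        makeScaleFree(10, 3, 0.5, seed = 4),
        starNet(),
        SignedNetwork(pos = cliqueEdges(paste0("p", 1:5)),
                      neg = rbind(c("p1", "q"), c("p2", "q"))))
    for (net in nets) {
        if (length(genes(net)) > 12L) next
        expectMetricsEqual(topologyMetrics(net), bruteMetrics(net),
                           tol = 1e-5)
    }
})

test_that("cluster profiles average metrics per embedding cluster", {
    tree <- makeSimTree()
    set.seed(4)
    # planted duplicate embeddings for two structural groups
    m <- matrix(0, 31, 3, dimnames = list(genes(tree), NULL))
    grpA <- genes(tree)[1:15]
    m[grpA, ] <- matrix(rep(c(5, 5, 5), each = 15), 15)
    emb <- embFromMatrix(m)
    pr <- clusterProfile(emb, tree, K = 2, seed = 1)
    expect_equal(length(unique(pr$assignments[grpA])), 1L)
    expect_equal(length(unique(pr$assignments[setdiff(genes(tree), grpA)])),
                 1L)

    # K = 1: single row of global means
    pr1 <- clusterProfile(emb, tree, K = 1, seed = 1)
    tm <- topologyMetrics(tree)
    expect_equal(unname(unlist(pr1$means["cluster1", ])),
                 unname(colMeans(tm[, -1], na.rm = TRUE)))

    # per-metric min-max scaling spans [0, 1] for non-constant rows
    pr10 <- clusterProfile(embFromMatrix(matrix(rnorm(31 * 4), 31,
                               dimnames = list(genes(tree), NULL))),
                           tree, K = 10, seed = 2)
    sc <- pr10$scaled
    for (r in seq_len(nrow(sc))) {
        rng <- diff(range(pr10$means[[r]]))
        if (!is.finite(rng) || rng == 0) next
        expect_equal(min(sc[r, ]), 0)
        expect_equal(max(sc[r, ]), 1)
    }
    expect_error(clusterProfile(emb, tree, K = 40), "exceeds")
})
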