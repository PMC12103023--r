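test_that("signed degrees count incident edges by sign", {
    net <- starNet()
    expect_equal(unname(signedDegree(net, "hub")), c(3L, 1L))
    expect_equal(unname(signedDegree(net, "n1")), c(0L, 1L))
    expect_error(signedDegree(net, "nope"), "unknown")

    # sign-flipped copy swaps the components for every node
    flipped <- SignedNetwork(pos = negEdges(net), neg = posEdges(net))
    d <- signedDegree(net); f <- signedDegree(flipped)
    expect_equal(unname(f[, "pos"]), unname(d[genes(net), "neg"]))
    expect_equal(unname(f[, "neg"]), unname(d[genes(net), "pos"]))
})

test_that("ebed matches its closed forms and symmetries", {
    expect_equal(ebed(c(2, 5), c(2, 5)), 1)
    expect_equal(ebed(c(1, 0), c(3, 0)), 2) # exp(|ln(2/4)|) under natural log
    expect_equal(ebed(c(3, 1), c(1, 3)), ebed(c(1, 3), c(3, 1)))
    expect_equal(ebed(c(1, 0), c(3, 0), minusOne = TRUE), 1)

    set.seed(2)
    a <- matrix(sample(0:8, 2000, TRUE), ncol = 2)
    b <- matrix(sample(0:8, 2000, TRUE), ncol = 2)
    expect_equal(ebed(a, b), ebed(b, a))
    # simultaneous swap of (d+, d-) in both arguments changes nothing
    expect_equal(ebed(a, b), ebed(a[, 2:1], b[, 2:1]))
    expect_true(all(ebed(a, b) >= 1))
    same <- a
    expect_equal(ebed(a, same), rep(1, nrow(a)))
    # closed form against the independent reference
    expect_equal(ebed(a, b), refCost(a[, 1], a[, 2], b[, 1], b[, 2]))
})

test_that("DTW on degree sequences matches hand-computable cases", {
    # 1x1 alignment is just the local cost
    expect_equal(dtwDistance(rbind(c(2, 1)), rbind(c(0, 3))),
                 ebed(c(2, 1), c(0, 3)))
    # identical constant sequences of length n cost exactly n (diagonal)
    for (n in c(1, 3, 6)) {
        s <- matrix(rep(c(2, 1), each = n), ncol = 2)
        expect_equal(dtwDistance(s, s), n)
    }
    # one element against two copies of itself: both map at cost 1
    expect_equal(dtwDistance(rbind(c(1, 0)), rbind(c(1, 0), c(1, 0))), 2)
    expect_error(dtwDistance(matrix(numeric(0), ncol = 2), rbind(c(1, 0))),
                 "empty")
    # symmetry on random sequences
    set.seed(3)
    for (i in 1:20) {
        s <- matrix(sample(0:2, 2 * sample(1:4, 1), TRUE), ncol = 2)
        t <- matrix(sample(0:2, 2 * sample(1:4, 1), TRUE), ncol = 2)
        expect_equal(dtwDistance(s, t), dtwDistance(t, s))
    }
})

test_that("degree rings partition the component by hop distance", {
    net <- pathNet()
    r <- degreeRings(net, "A", 2)
    expect_equal(nrow(r[[1]]), 1L)                     # ring 0: A itself
    expect_equal(r[[2]], signedDegree(net)["B", , drop = FALSE],
                 ignore_attr = TRUE)                   # ring 1 = {deg(B)}
    expect_equal(r[[3]], signedDegree(net)["C", , drop = FALSE],
                 ignore_attr = TRUE)

    # isolated pair in a larger network: ring 2 of u is empty
    net2 <- SignedNetwork(pos = rbind(c("u", "v"), c("x", "y"), c("y", "z")))
    expect_equal(nrow(degreeRings(net2, "u", 2)[[3]]), 0L)
    expect_error(degreeRings(net2, "u", -1), "kMax")

    # ring sizes over all k sum to the component size
    sf <- makeScaleFree(60, 2, 0.3, seed = 9)
    sizes <- vapply(degreeRings(sf, "g1", 60), nrow, integer(1))
    comp <- igraph::components(signedRoles:::.unionGraph(sf))
    expect_equal(sum(sizes), unname(comp$csize[comp$membership["g1"]]))

    # rings come out sorted under the canonical order
    r3 <- degreeRings(sf, "g2", 3)
    for (ring in r3) {
        if (nrow(ring) < 2) next
        key <- order(ring[, 1] + ring[, 2], ring[, 1], ring[, 2])
        expect_equal(key, seq_len(nrow(ring)))
    }
})

test_that("f_k accumulates DTW distances with self-comparison identities", {
    tree <- makeSimTree()
    dt <- dissimilarityTable(tree, kMax = 3)
    expect_equal(kMax(dt), 3L)

    # f_0(u,u) = 1; f_k(u,u) grows by exactly |R_k(u)| while rings last
    for (u in c("S0", "S9", "S6")) {
        rings <- degreeRings(tree, u, 3)
        expect_equal(fLayer(dt, 0)[u, u], 1)
        for (k in 1:3) {
            if (nrow(rings[[k + 1]]) == 0) break
            expect_equal(fLayer(dt, k)[u, u],
                         fLayer(dt, k - 1)[u, u] + nrow(rings[[k + 1]]))
        }
    }

    # automorphic twins: identical rings at every hop, so f grows at the
    # minimum possible rate f_k = f_0 + sum |R_j|
    rings <- degreeRings(tree, "S9", 3)
    expect_equal(fLayer(dt, 0)["S9", "S15"], 1)
    for (k in 1:3) {
        if (nrow(rings[[k + 1]]) == 0) break
        expect_equal(fLayer(dt, k)["S9", "S15"],
                     1 + sum(vapply(rings[2:(k + 1)], nrow, integer(1))))
    }
})

test_that("f_k is symmetric, monotone in k, and truncates on empty rings", {
    sf <- makeScaleFree(80, 2, 0.3, seed = 13)
    dt <- dissimilarityTable(sf, kMax = 3)
    set.seed(14)
    ids <- nodeIds(dt)
    for (i in 1:100) {
        uv <- sample(ids, 2)
        vals <- vapply(0:kMax(dt), function(k) fLayer(dt, k)[uv[1], uv[2]],
                       numeric(1))
        expect_equal(vals, vapply(0:kMax(dt),
                                  function(k) fLayer(dt, k)[uv[2], uv[1]],
                                  numeric(1)))
        def <- which(!is.na(vals))
        if (length(def) > 1)
            expect_true(all(diff(vals[def]) >= 0))
        # truncation: once NA, deeper layers stay NA
        if (anyNA(vals))
            expect_true(all(is.na(vals[seq(min(which(is.na(vals))),
                                           length(vals))])))
    }

    # two disconnected dyads: rings beyond hop 1 are empty, so pair
    # comparison truncates after k = 1
    net <- SignedNetwork(pos = rbind(c("a", "b"), c("c", "d")))
    dt2 <- dissimilarityTable(net, kMax = 3)
    expect_equal(kMax(dt2), 1L) # no node has a 2-hop ring at all
    expect_false(anyNA(fLayer(dt2, 1)))
})

test_that("relabeling a network leaves the f_k multiset invariant", {
    sf <- makeScaleFree(40, 2, 0.4, seed = 21)
    rl <- relabelNet(sf, seed = 22)
    d1 <- dissimilarityTable(sf, kMax = 2)
    d2 <- dissimilarityTable(rl$net, kMax = 2)
    for (k in 0:2) {
        a <- fLayer(d1, k); b <- fLayer(d2, k)
        expect_equal(sort(a[upper.tri(a)]), sort(b[upper.tri(b)]))
        # and cell-wise under the relabeling map
        expect_equal(a, b[rl$map[rownames(a)], rl$map[colnames(a)]],
                     ignore_attr = TRUE)
    }
})

test_that("cross-context f is minimal between isomorphic partners", {
    sf <- makeScaleFree(30, 2, 0.3, seed = 33, context = "c1")
    rl <- relabelNet(sf, seed = 34, context = "c2")
    m <- mergeNetworks(list(sf, rl$net))
    dt <- dissimilarityTable(m, kMax = 2)
    f <- fLayer(dt, 0)
    for (u in genes(sf)) {
        row <- f[paste0(u, "::c1"), paste0(genes(rl$net), "::c2")]
        expect_lte(row[paste0(rl$map[u], "::c2")], min(row) + 1e-12)
    }
    # deepest common layer: partner still minimal for a few probes
    f2 <- fLayer(dt, 2)
    set.seed(1)
    for (u in sample(genes(sf), 5)) {
        row <- f2[paste0(u, "::c1"), paste0(genes(rl$net), "::c2")]
        if (all(is.na(row))) next
        expect_lte(row[paste0(rl$map[u], "::c2")], min(row, na.rm = TRUE) + 1e-12)
    }
})

test_that("the dissimilarity table survives its triplet file format", {
    sf <- makeScaleFree(25, 2, 0.3, seed = 5)
    dt <- dissimilarityTable(sf, kMax = 2)
    f <- tempfile(fileext = ".tsv.gz")
    writeDissimilarityTable(dt, f)
    back <- readDissimilarityTable(f)
    expect_equal(kMax(back), kMax(dt))
    expect_equal(nodeIds(back), nodeIds(dt))
    for (k in 0:kMax(dt))
        expect_equal(fLayer(back, k), fLayer(dt, k), tolerance = 1e-12)
})

test_that("the node-count guard aborts oversized all-pairs runs", {
    sf <- makeScaleFree(50, 2, 0.3, seed = 2)
    expect_error(dissimilarityTable(sf, kMax = 2, maxNodes = 40), "guard")
})
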