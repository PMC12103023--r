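# independent reference implementations used to cross-check the package

# closed-form local cost between two signed degrees (computed directly,
# independent of the package's ebed)
refCost <- function(dp1, dn1, dp2, dn2)
    exp(sqrt(log((dp1 + 1) / (dp2 + 1))^2 + log((dn1 + 1) / (dn2 + 1))^2))

# ---- DTW oracle: explicit enumeration of all warping paths --------------

.pathCache <- new.env(parent = emptyenv())

# all monotone warping paths from cell (1,1) to (m,n) with steps
# {(1,0),(0,1),(1,1)}; each path is a 2-column index matrix
warpPaths <- function(m, n) {
    key <- paste0(m, "x", n)
    got <- .pathCache[[key]]
    if (!is.null(got)) return(got)
    res <- if (m == 1L && n == 1L) list(matrix(c(1L, 1L), ncol = 2)) else {
        acc <- list()
        ext <- function(pm, pn) lapply(warpPaths(pm, pn),
                                       function(p) rbind(p, c(m, n)))
        if (m > 1L) acc <- c(acc, ext(m - 1L, n))
        if (n > 1L) acc <- c(acc, ext(m, n - 1L))
        if (m > 1L && n > 1L) acc <- c(acc, ext(m - 1L, n - 1L))
        acc
    }
    .pathCache[[key]] <- res
    res
}

# minimal path cost for many sequence pairs of one shape at once.
# SA: nPairs x m matrix of alphabet indices, SB: nPairs x n; CM: cost matrix
enumDTW <- function(SA, SB, CM) {
    best <- rep(Inf, nrow(SA))
    for (p in warpPaths(ncol(SA), ncol(SB))) {
        cost <- 0
        for (r in seq_len(nrow(p)))
            cost <- cost + CM[cbind(SA[, p[r, 1L]], SB[, p[r, 2L]])]
        best <- pmin(best, cost)
    }
    best
}

# all canonically sorted sequences of length l over an ordered alphabet of
# size a (non-decreasing index tuples), as a matrix of index rows
sortedSequences <- function(l, a) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(a)), l)))
    if (l == 1L) return(grid)
    keep <- rowSums(grid[, -1L, drop = FALSE] >=
                    grid[, -l, drop = FALSE]) == l - 1L
    grid[keep, , drop = FALSE]
}

# ---- brute-force signed topology metrics --------------------------------

.bruteAdj <- function(edges, nodes) {
    A <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(NROW(edges))) {
        A[edges[i, 1L], edges[i, 2L]] <- 1L
        A[edges[i, 2L], edges[i, 1L]] <- 1L
    }
    A
}

.bruteClustering <- function(A) {
    vapply(seq_len(nrow(A)), function(v) {
        nb <- which(A[v, ] > 0L)
        k <- length(nb)
        if (k < 2L) return(0)
        sum(A[nb, nb]) / 2 / choose(k, 2)
    }, numeric(1))
}

.bruteAssortativity <- function(A) {
    idx <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
    if (nrow(idx) < 2L) return(NA_real_)
    deg <- rowSums(A)
    x <- c(deg[idx[, 1L]], deg[idx[, 2L]])
    y <- c(deg[idx[, 2L]], deg[idx[, 1L]])
    r <- suppressWarnings(stats::cor(x, y))
    if (is.na(r) || is.nan(r)) NA_real_ else r
}

.bruteBetweenness <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n); diag(D) <- 0
    S <- matrix(0, n, n)
    for (s in seq_len(n)) {
        dist <- rep(Inf, n); dist[s] <- 0
        sigma <- rep(0, n); sigma[s] <- 1
        frontier <- s; d <- 0
        while (length(frontier)) {
            nxt <- integer(0)
            for (v in frontier) for (w in which(A[v, ] > 0L)) {
                if (is.infinite(dist[w])) { dist[w] <- d + 1; nxt <- c(nxt, w) }
                if (dist[w] == d + 1) sigma[w] <- sigma[w] + sigma[v]
            }
            frontier <- unique(nxt); d <- d + 1
        }
        D[s, ] <- dist; S[s, ] <- sigma
    }
    btw <- vapply(seq_len(n), function(v) {
        tot <- 0
        for (s in seq_len(n)) for (t in seq_len(n)) {
            if (s >= t || s == v || t == v) next
            if (!is.finite(D[s, t])) next
            if (D[s, v] + D[v, t] == D[s, t])
                tot <- tot + S[s, v] * S[v, t] / S[s, t]
        }
        tot
    }, numeric(1))
    if (n > 2L) btw / ((n - 1) * (n - 2) / 2) else btw
}

.bruteEigenvector <- function(A) {
    ev <- eigen(A, symmetric = TRUE)$vectors[, 1L]
    ev <- abs(ev)
    ev / max(ev)
}

bruteMetrics <- function(net) {
    ns <- genes(net)
    n <- length(ns)
    Ap <- .bruteAdj(posEdges(net), ns)
    An <- .bruteAdj(negEdges(net), ns)
    A <- pmax(Ap, An)
    data.frame(
        gene = ns,
        degreeCentralityPos = rowSums(Ap) / (n - 1),
        degreeCentralityNeg = rowSums(An) / (n - 1),
        betweenness = .bruteBetweenness(A),
        eigenvector = .bruteEigenvector(A),
        assortativityPos = ifelse(rowSums(Ap) > 0, .bruteAssortativity(Ap),
                                  NA_real_),
        assortativityNeg = ifelse(rowSums(An) > 0, .bruteAssortativity(An),
                                  NA_real_),
        clusteringPos = .bruteClustering(Ap),
        clusteringNeg = .bruteClustering(An),
        row.names = NULL, stringsAsFactors = FALSE)
}

# compare metric frames column-wise with NA agreement
expectMetricsEqual <- function(got, ref, tol = 1e-6) {
    for (cl in setdiff(colnames(ref), "gene")) {
        g <- got[[cl]]; r <- ref[[cl]]
        expect_equal(is.na(g), is.na(r), info = cl)
        ok <- !is.na(r)
        expect_equal(g[ok], r[ok], tolerance = tol, info = cl,
                     ignore_attr = TRUE)
    }
}
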