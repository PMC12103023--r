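#' Exponential Biased Euclidean Distance (EBED) between signed degrees
#'
#' GRNs are scale-free, so raw degree differences are dominated by hubs.
#' EBED takes the natural log of the (+1 shifted) degree ratio in each sign
#' component, measures the Euclidean distance of the two log-ratios, and
#' exponentiates to restore the original scale:
#' \deqn{\mathrm{EBED}(a,b) = \exp\sqrt{\ln^2\frac{a^+ + 1}{b^+ + 1} +
#'   \ln^2\frac{a^- + 1}{b^- + 1}}}
#' It is symmetric, at least 1, and equals 1 exactly when the degrees agree.
#' With \code{minusOne = TRUE} the distance is shifted down by 1 so that
#' identical degrees score 0 (a sensitivity variant).
#'
#' @param a,b length-2 integer vectors \code{[d+, d-]}, or matrices with two
#'   columns for vectorised evaluation.
#' @param minusOne logical, use the shifted variant.
#' @return numeric distance(s).
#' @examples
#' ebed(c(2, 5), c(2, 5)) # 1
#' ebed(c(1, 0), c(3, 0)) # 2: exp(|ln(2/4)|)
#' @export
ebed <- function(a, b, minusOne = FALSE) {
    a <- rbind(a); b <- rbind(b)
    stopifnot(ncol(a) == 2L, ncol(b) == 2L)
    x <- log((a[, 1L] + 1) / (b[, 1L] + 1))
    y <- log((a[, 2L] + 1) / (b[, 2L] + 1))
    d <- exp(sqrt(x^2 + y^2))
    unname(if (minusOne) d - 1 else d)
}

#' Dynamic time warping between signed-degree sequences
#'
#' Classic DTW with sum aggregation over steps \{(1,0), (0,1), (1,1)\} and
#' [ebed()] as local cost, used to compare the (differently sized) k-hop
#' degree rings of two genes.
#'
#' @param s,t non-empty signed-degree sequences: two-column integer matrices,
#'   one row per element.
#' @param minusOne passed to the local cost, see [ebed()].
#' @return the DTW distance (numeric scalar).
#' @examples
#' dtwDistance(rbind(c(1, 0)), rbind(c(1, 0), c(1, 0))) # 2
#' @export
dtwDistance <- function(s, t, minusOne = FALSE) {
    s <- rbind(s); t <- rbind(t)
    if (!nrow(s) || !nrow(t)) stop("DTW is undefined for empty sequences")
    storage.mode(s) <- "integer"; storage.mode(t) <- "integer"
    .cppDTW(s, t, isTRUE(minusOne))
}

# canonical ring order: ascending (total degree, d+, d-)
.canonicalOrder <- function(deg) order(deg[, 1L] + deg[, 2L], deg[, 1L], deg[, 2L])

.degreeAndDist <- function(x) {
    if (is(x, "MergedNetwork")) {
        deg <- signedDegree(x)
        g <- .mergedUnionGraph(x)
    } else {
        deg <- signedDegree(x)
        g <- .unionGraph(x)
    }
    D <- igraph::distances(g, algorithm = "unweighted")
    D <- D[rownames(deg), rownames(deg), drop = FALSE]
    list(deg = deg, dist = D)
}

#' Degree rings around a gene
#'
#' Ring k holds the signed degrees of all genes at shortest-path distance
#' exactly k from \code{u} (hops counted on the unsigned union of positive
#' and negative edges), sorted in the canonical order (ascending total
#' degree, then \code{d+}, then \code{d-}). Ring 0 is the gene's own degree.
#'
#' @param net a [SignedNetwork] or [MergedNetwork].
#' @param u node identifier (\code{"gene::context"} for merged input).
#' @param kMax non-negative integer, deepest ring.
#' @return list of \code{kMax + 1} two-column integer matrices; rings beyond
#'   the component radius are zero-row.
#' @export
degreeRings <- function(net, u, kMax) {
    if (kMax < 0) stop("kMax must be >= 0")
    dd <- .degreeAndDist(net)
    if (!u %in% rownames(dd$deg)) stop("unknown node: ", u)
    ord <- .canonicalOrder(dd$deg)
    ids <- rownames(dd$deg)[ord]
    d2u <- dd$dist[u, ids]
    lapply(0:kMax, function(k) {
        ring <- ids[!is.infinite(d2u) & d2u == k]
        m <- dd$deg[ring, , drop = FALSE]
        storage.mode(m) <- "integer"
        m
    })
}

#' All-pairs cumulative structural dissimilarity
#'
#' Computes \code{f_0(u, v) = EBED(d_u, d_v)} and
#' \code{f_k = f_{k-1} + DTW(R_k(u), R_k(v))} for every unordered node pair,
#' across the full merged node set when given a [MergedNetwork] --
#' structural similarity deliberately crosses contexts. A pair stops
#' accumulating at the first k where either ring is empty (its deeper
#' entries are \code{NA}).
#'
#' @param x a [SignedNetwork] or [MergedNetwork].
#' @param kMax requested hop depth (default 3); the effective depth is
#'   capped at the deepest k for which at least two nodes still have a
#'   non-empty ring.
#' @param ebedMinusOne see [ebed()].
#' @param maxNodes guard: abort (with guidance) beyond this node count,
#'   since the computation is quadratic in nodes.
#' @return a [DissimilarityTable].
#' @export
dissimilarityTable <- function(x, kMax = 3L, ebedMinusOne = FALSE,
                               maxNodes = 3000L) {
    if (kMax < 0) stop("kMax must be >= 0")
    dd <- .degreeAndDist(x)
    n <- nrow(dd$deg)
    if (n > maxNodes)
        stop("network has ", n, " nodes, above the all-pairs guard (",
             maxNodes, "); raise maxNodes explicitly or reduce the network")
    ecc <- apply(dd$dist, 1L, function(r) max(r[is.finite(r)]))
    kEff <- as.integer(min(kMax, if (n >= 2L) sort(ecc, decreasing = TRUE)[2L] else 0L))
    D <- dd$dist
    D[!is.finite(D)] <- -1
    storage.mode(D) <- "integer"
    deg <- dd$deg
    storage.mode(deg) <- "integer"
    f <- .cppDissimilarity(deg, D, .canonicalOrder(deg), kEff,
                           isTRUE(ebedMinusOne))
    f <- lapply(f, function(m) { dimnames(m) <- list(rownames(deg), rownames(deg)); m })
    new("DissimilarityTable", kMax = kEff, nodeIds = rownames(deg), f = f,
        ebedMinusOne = isTRUE(ebedMinusOne))
}

#' @rdname DissimilarityTable-class
#' @aliases kMax,DissimilarityTable-method
setMethod("kMax", "DissimilarityTable", function(x) x@kMax)

#' @rdname DissimilarityTable-class
setMethod("nodeIds", "DissimilarityTable", function(x) x@nodeIds)

#' @rdname DissimilarityTable-class
#' @param k layer index (0-based).
#' @export
fLayer <- function(x, k) {
    stopifnot(is(x, "DissimilarityTable"), k >= 0, k <= x@kMax)
    x@f[[k + 1L]]
}

setMethod("show", "DissimilarityTable", function(object) {
    cat("DissimilarityTable:", length(object@nodeIds), "nodes, kMax =",
        object@kMax, "\n")
})

#' Persist / restore a dissimilarity table
#'
#' Triplet text format (k, u, v, f) with a two-line header, reusable across
#' runs.
#'
#' @param x a [DissimilarityTable]; \code{path} a file path.
#' @param path file path.
#' @return \code{readDissimilarityTable} returns a [DissimilarityTable].
#' @export
writeDissimilarityTable <- function(x, path) {
    stopifnot(is(x, "DissimilarityTable"))
    con <- gzfile(path, "wt")
    on.exit(close(con))
    writeLines(c(paste("#kMax", x@kMax, as.integer(x@ebedMinusOne)),
                 paste0("#nodes\t", paste(x@nodeIds, collapse = "\t"))), con)
    n <- length(x@nodeIds)
    for (k in 0:x@kMax) {
        m <- x@f[[k + 1L]]
        ut <- which(upper.tri(m, diag = TRUE) & !is.na(m), arr.ind = TRUE)
        if (nrow(ut))
            writeLines(sprintf("%d\t%d\t%d\t%.17g", k, ut[, 1L], ut[, 2L],
                               m[ut]), con)
    }
    invisible(path)
}

#' @rdname writeDissimilarityTable
#' @export
readDissimilarityTable <- function(path) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    h1 <- strsplit(readLines(con, 1L), " ")[[1L]]
    kM <- as.integer(h1[[2L]])
    minusOne <- as.logical(as.integer(h1[[3L]]))
    ids <- strsplit(readLines(con, 1L), "\t")[[1L]][-1L]
    dat <- utils::read.table(con, sep = "\t",
                             col.names = c("k", "i", "j", "f"))
    n <- length(ids)
    f <- lapply(0:kM, function(k) {
        m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
        d <- dat[dat$k == k, , drop = FALSE]
        m[cbind(d$i, d$j)] <- d$f
        m[cbind(d$j, d$i)] <- d$f
        m
    })
    new("DissimilarityTable", kMax = kM, nodeIds = ids, f = f,
        ebedMinusOne = minusOne)
}
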