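#' Intra-layer link weight
#'
#' Layer k of the multilayer graph links genes with weight
#' \code{exp(-f_k)}: the more similar two genes' multi-hop topology, the
#' heavier their link.
#'
#' @param f cumulative dissimilarity value(s), \code{>= 0}.
#' @return numeric weight(s) in (0, 1].
#' @export
layerWeight <- function(f) {
    stopifnot(all(f >= 0, na.rm = TRUE))
    exp(-f)
}

#' Build the multilayer context graph
#'
#' Assembles intra-layer weights \code{w_k = exp(-f_k)} from a
#' [DissimilarityTable], counts for each gene and layer the number of links
#' whose weight strictly exceeds the mean link weight of that layer
#' (\code{Gamma_k(u)}), and derives the directed inter-layer weights:
#' upward \code{ln(Gamma_k(u) + e)} (at least 1), downward constant 1. The
#' upward bias pushes random walks toward deeper layers, where similarity
#' judgements integrate wider neighbourhoods.
#'
#' @param table a [DissimilarityTable].
#' @return a [ContextGraph].
#' @export
buildContextGraph <- function(table) {
    stopifnot(is(table, "DissimilarityTable"))
    kM <- table@kMax
    n <- length(table@nodeIds)
    intra <- vector("list", kM + 1L)
    gam <- matrix(0L, n, kM + 1L, dimnames = list(table@nodeIds, NULL))
    lmean <- numeric(kM + 1L)
    for (k in 0:kM) {
        W <- layerWeight(table@f[[k + 1L]])
        diag(W) <- NA_real_
        ut <- W[upper.tri(W)]
        if (!any(!is.na(ut))) stop("layer ", k, " has no intra links")
        lmean[k + 1L] <- mean(ut, na.rm = TRUE)
        gam[, k + 1L] <- as.integer(rowSums(W > lmean[k + 1L], na.rm = TRUE))
        intra[[k + 1L]] <- W
    }
    up <- matrix(numeric(0), n, 0L)
    if (kM >= 1L)
        up <- log(gam[, 1:kM, drop = FALSE] + exp(1))
    rownames(up) <- table@nodeIds
    new("ContextGraph", kMax = kM, nodeIds = table@nodeIds, intra = intra,
        gamma = gam, up = up, layerMean = lmean)
}

#' @rdname ContextGraph-class
#' @aliases kMax,ContextGraph-method
setMethod("kMax", "ContextGraph", function(x) x@kMax)

#' @rdname ContextGraph-class
setMethod("nodeIds", "ContextGraph", function(x) x@nodeIds)

setMethod("show", "ContextGraph", function(object) {
    cat("ContextGraph:", length(object@nodeIds), "nodes x",
        object@kMax + 1L, "layers\n")
})

#' Gamma: similar-gene count per layer
#'
#' Number of layer-k links of gene \code{u} whose weight strictly exceeds
#' the mean weight of all links in layer k.
#'
#' @param g a [ContextGraph].
#' @param u node identifier.
#' @param k layer, 0-based.
#' @return integer count.
#' @export
gammaCount <- function(g, u, k) {
    stopifnot(is(g, "ContextGraph"), k >= 0, k <= g@kMax)
    if (!u %in% g@nodeIds) stop("unknown node: ", u)
    unname(g@gamma[u, k + 1L])
}

#' Inter-layer weights at a node
#'
#' @param g a [ContextGraph].
#' @param u node identifier.
#' @param k layer, 0-based.
#' @return list with \code{up} (\code{ln(Gamma_k(u) + e)}, \code{NA} at the
#'   top layer) and \code{down} (1, \code{NA} at layer 0).
#' @export
interlayerWeights <- function(g, u, k) {
    stopifnot(is(g, "ContextGraph"), k >= 0, k <= g@kMax)
    if (!u %in% g@nodeIds) stop("unknown node: ", u)
    list(up = if (k < g@kMax) unname(log(g@gamma[u, k + 1L] + exp(1))) else NA_real_,
         down = if (k > 0) 1 else NA_real_)
}

#' Random-walk transition distribution at (node, layer)
#'
#' Intra-layer moves jointly receive probability \code{q} (default 0.8),
#' split across the layer's links in proportion to their weights; the
#' remaining \code{1 - q} goes to the inter-layer moves in proportion to the
#' upward/downward weights. At layer 0 all inter-layer mass goes up, at the
#' top layer all of it goes down; with a single layer the intra moves take
#' all the mass. A node with no intra links at a layer sends all mass to the
#' inter-layer moves (with a warning).
#'
#' @param g a [ContextGraph].
#' @param u node identifier.
#' @param k layer, 0-based.
#' @param q intra-layer transition probability.
#' @return list with components \code{intra} (named probability vector),
#'   \code{up} and \code{down} (scalars; 0 where the move does not exist).
#' @export
transitionDistribution <- function(g, u, k, q = 0.8) {
    stopifnot(is(g, "ContextGraph"), k >= 0, k <= g@kMax, q > 0, q < 1)
    if (!u %in% g@nodeIds) stop("unknown node: ", u)
    w <- g@intra[[k + 1L]][u, ]
    w <- w[!is.na(w)]
    wUp <- if (k < g@kMax) unname(log(g@gamma[u, k + 1L] + exp(1))) else 0
    wDown <- if (k > 0) 1 else 0
    interW <- wUp + wDown
    if (length(w)) {
        intraMass <- if (interW > 0) q else 1
        intra <- intraMass * w / sum(w)
    } else {
        warning("node ", u, " has no intra links at layer ", k,
                "; all mass to inter-layer moves")
        if (interW == 0) stop("node ", u, " has no moves at layer ", k)
        intraMass <- 0
        intra <- stats::setNames(numeric(0), character(0))
    }
    rest <- 1 - intraMass
    list(intra = intra,
         up = if (interW > 0) rest * wUp / interW else 0,
         down = if (interW > 0) rest * wDown / interW else 0)
}

# precompute per-(node, layer) move tables for the C++ walker
.walkTables <- function(g, q) {
    n <- length(g@nodeIds)
    kM <- g@kMax
    nbr <- cum <- vector("list", kM + 1L)
    pIntra <- pUp <- matrix(0, n, kM + 1L)
    for (k in 0:kM) {
        W <- g@intra[[k + 1L]]
        nbr[[k + 1L]] <- vector("list", n)
        cum[[k + 1L]] <- vector("list", n)
        wUp <- if (k < kM) log(g@gamma[, k + 1L] + exp(1)) else rep(0, n)
        wDown <- if (k > 0) 1 else 0
        interW <- wUp + wDown
        for (u in seq_len(n)) {
            w <- W[u, ]
            j <- which(!is.na(w))
            if (length(j)) {
                im <- if (interW[u] > 0) q else 1
                cw <- cumsum(w[j]); cw <- cw / cw[length(cw)]
                nbr[[k + 1L]][[u]] <- j
                cum[[k + 1L]][[u]] <- cw
                pIntra[u, k + 1L] <- im
            } else {
                nbr[[k + 1L]][[u]] <- integer(0)
                cum[[k + 1L]][[u]] <- numeric(0)
                pIntra[u, k + 1L] <- 0
            }
            rest <- 1 - pIntra[u, k + 1L]
            pUp[u, k + 1L] <- if (interW[u] > 0) rest * wUp[u] / interW[u] else 0
        }
    }
    list(nbr = nbr, cum = cum, pIntra = pIntra, pUp = pUp)
}
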