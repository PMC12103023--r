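# split merged ids "gene::context" -> data.frame(gene, context)
.splitIds <- function(ids) {
    pos <- regexpr("::", ids, fixed = TRUE)
    if (any(pos < 0))
        stop("embedding ids are not in 'gene::context' form; ",
             "this analysis needs a merged (multi-context) embedding")
    data.frame(gene = substr(ids, 1L, pos - 1L),
               context = substr(ids, pos + 2L, nchar(ids)),
               stringsAsFactors = FALSE)
}

#' Per-gene embedding distances across contexts
#'
#' For a gene present in all \code{C} contexts of a merged embedding:
#' centroid of its per-context vectors, Euclidean distance of each context
#' vector to that centroid, and their mean -- the quantities differentially
#' topological genes are ranked by.
#'
#' @param emb a merged [EmbeddingTable] (ids \code{"gene::context"}).
#' @param gene gene identifier.
#' @return list with \code{center} (numeric vector), \code{distances}
#'   (named by context) and \code{mean}.
#' @export
geneDistances <- function(emb, gene) {
    stopifnot(is(emb, "EmbeddingTable"))
    ids <- .splitIds(nodeIds(emb))
    ctx <- sort(unique(ids$context))
    rows <- which(ids$gene == gene)
    if (!length(rows)) stop("gene not present in the embedding: ", gene)
    if (!setequal(ids$context[rows], ctx))
        stop("gene ", gene, " is missing from context(s): ",
             paste(setdiff(ctx, ids$context[rows]), collapse = ", "))
    V <- emb@vectors[rows, , drop = FALSE]
    cen <- colMeans(V)
    d <- sqrt(rowSums(sweep(V, 2L, cen)^2))
    names(d) <- ids$context[rows]
    d <- d[ctx]
    list(center = cen, distances = d, mean = mean(d))
}

#' Population standard deviation of per-context distances
#'
#' Dividing by \code{C} (not \code{C - 1}); used to spot genes whose role
#' changes only in a few contexts.
#'
#' @param d numeric vector of per-context centroid distances (length >= 2).
#' @return non-negative scalar.
#' @examples
#' distanceSD(c(1, 2, 3)) # sqrt(2/3)
#' @export
distanceSD <- function(d) {
    stopifnot(length(d) >= 2L)
    sqrt(mean((d - mean(d))^2))
}

# distances for all genes present in every context; excluded genes recorded
.allGeneDistances <- function(emb) {
    ids <- .splitIds(nodeIds(emb))
    ctx <- sort(unique(ids$context))
    C <- length(ctx)
    tab <- table(ids$gene)
    full <- names(tab)[tab == C]
    excluded <- setdiff(unique(ids$gene), full)
    V <- emb@vectors
    dmat <- matrix(NA_real_, length(full), C,
                   dimnames = list(full, ctx))
    for (ci in seq_along(ctx)) {
        rows <- paste(full, ctx[ci], sep = "::")
        dmat[, ci] <- 0
        dmat[, ci] <- rowSums(V[rows, , drop = FALSE]^2)
    }
    # centroid per gene
    cen <- 0
    for (ci in seq_along(ctx))
        cen <- cen + V[paste(full, ctx[ci], sep = "::"), , drop = FALSE]
    cen <- cen / C
    for (ci in seq_along(ctx)) {
        diff <- V[paste(full, ctx[ci], sep = "::"), , drop = FALSE] - cen
        dmat[, ci] <- sqrt(rowSums(diff^2))
    }
    list(contexts = ctx, C = C, dist = dmat, excluded = excluded)
}

#' Identify differentially topological genes (DTGs)
#'
#' Ranks genes shared by all contexts by the mean centroid distance of
#' their per-context embeddings. For two contexts, the top 10% (by rank,
#' \code{ceiling(topFracPair * N)}) are flagged \code{dtg_mean}. For more
#' than two contexts, the top 5th percentile of mean distances are flagged
#' \code{dtg_mean} (consistent role change across contexts), and genes whose
#' population SD of distances exceeds \code{sdThreshold} are additionally
#' flagged \code{dtg_sd} (role change confined to some contexts). Genes
#' missing from at least one context are excluded and listed in the
#' \code{"excluded"} attribute.
#'
#' @param emb a merged [EmbeddingTable].
#' @param topFracPair flagged fraction for C = 2 (default 0.10).
#' @param topFracMulti flagged fraction for C > 2 (default 0.05).
#' @param sdThreshold empirical SD threshold for C > 2 (default 0.4).
#' @param sdAuto when \code{TRUE}, replace \code{sdThreshold} with the 95th
#'   percentile of the observed SDs.
#' @return data.frame with one row per eligible gene: per-context distances
#'   (\code{dist.<context>}), \code{meanDist}, \code{sdDist}, \code{flag}
#'   in \{\code{dtg_mean}, \code{dtg_sd}, \code{not_dtg}\}; rows ordered by
#'   descending mean distance with ties broken by gene id. Attributes:
#'   \code{excluded} (genes absent somewhere), \code{params}.
#' @export
classifyDTGs <- function(emb, topFracPair = 0.10, topFracMulti = 0.05,
                         sdThreshold = 0.4, sdAuto = FALSE) {
    ag <- .allGeneDistances(emb)
    N <- nrow(ag$dist)
    if (N == 0L) stop("no gene is present in every context")
    meanDist <- rowMeans(ag$dist)
    sdDist <- apply(ag$dist, 1L, distanceSD)
    o <- order(-meanDist, rownames(ag$dist))
    res <- data.frame(gene = rownames(ag$dist)[o], stringsAsFactors = FALSE)
    dd <- ag$dist[o, , drop = FALSE]
    colnames(dd) <- paste0("dist.", ag$contexts)
    res <- cbind(res, dd)
    res$meanDist <- meanDist[o]
    res$sdDist <- sdDist[o]
    res$flag <- "not_dtg"
    if (ag$C == 2L) {
        nFlag <- ceiling(topFracPair * N)
        res$flag[seq_len(nFlag)] <- "dtg_mean"
        thr <- NA_real_
    } else {
        nFlag <- ceiling(topFracMulti * N)
        res$flag[seq_len(nFlag)] <- "dtg_mean"
        thr <- if (sdAuto) stats::quantile(res$sdDist, 0.95, names = FALSE)
               else sdThreshold
        res$flag[res$flag == "not_dtg" & res$sdDist > thr] <- "dtg_sd"
    }
    rownames(res) <- NULL
    attr(res, "excluded") <- ag$excluded
    attr(res, "params") <- list(C = ag$C, topFracPair = topFracPair,
                                topFracMulti = topFracMulti,
                                sdThreshold = thr, sdAuto = sdAuto)
    res
}

#' Louvain gene modules of a signed network
#'
#' Community detection on the unsigned union graph with unit weights (the
#' modularity heuristic is undefined for negative weights; signs are kept
#' everywhere else in the package). Modules smaller than \code{minSize}
#' are dropped from the report, though their genes remain in the network.
#'
#' @param net a non-empty [SignedNetwork].
#' @param minSize minimum module size to retain (default 10).
#' @param seed optional integer seed (Louvain is stochastic).
#' @param resolution Louvain resolution parameter.
#' @return list with \code{membership} (named integer vector over all
#'   genes), \code{modules} (named list of retained gene sets) and
#'   \code{dropped} (list of too-small gene sets).
#' @export
louvainModules <- function(net, minSize = 10L, seed = NULL, resolution = 1) {
    stopifnot(is(net, "SignedNetwork"))
    if (!length(genes(net))) stop("empty network")
    if (!is.null(seed)) set.seed(seed)
    g <- .unionGraph(net)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    mem <- stats::setNames(igraph::membership(cl), igraph::V(g)$name)
    parts <- split(names(mem), mem)
    names(parts) <- paste0("m", names(parts))
    sizes <- lengths(parts)
    modules <- parts[sizes >= minSize]
    dropped <- parts[sizes < minSize]
    if (!length(modules))
        warning("no module reaches the minimum size of ", minSize)
    list(membership = mem, modules = modules, dropped = dropped)
}

#' Stability of anchor-context gene modules
#'
#' For each module found in the anchor context \code{c1}: the mean
#' embedding shift \code{||emb_u^c1 - emb_u^c2||} over the module genes
#' also present in context \code{c2}, and the fraction of module genes
#' absent from \code{c2} (\code{NA\%}). A large mean shift or a large NA\%
#' marks a module whose collective role changed between the states.
#'
#' @param modules named list of gene sets (e.g. \code{$modules} from
#'   [louvainModules()] on the anchor network).
#' @param emb a merged [EmbeddingTable] containing both contexts.
#' @param anchor,other context labels \code{c1}, \code{c2}.
#' @return data.frame: \code{module}, \code{size}, \code{shared},
#'   \code{meanDistance} (NA when no gene is shared), \code{naPct} in
#'   [0, 1], plus a \code{members} attribute.
#' @export
moduleStability <- function(modules, emb, anchor, other) {
    stopifnot(is(emb, "EmbeddingTable"))
    ids <- .splitIds(nodeIds(emb))
    if (!all(c(anchor, other) %in% ids$context))
        stop("embedding lacks context(s): ",
             paste(setdiff(c(anchor, other), ids$context), collapse = ", "))
    otherGenes <- ids$gene[ids$context == other]
    V <- emb@vectors
    rows <- lapply(names(modules), function(mn) {
        gs <- modules[[mn]]
        shared <- intersect(gs, otherGenes)
        md <- NA_real_
        if (length(shared)) {
            d <- sqrt(rowSums((V[paste(shared, anchor, sep = "::"), ,
                                 drop = FALSE] -
                               V[paste(shared, other, sep = "::"), ,
                                 drop = FALSE])^2))
            md <- mean(d)
        }
        data.frame(module = mn, size = length(gs), shared = length(shared),
                   meanDistance = md,
                   naPct = 1 - length(shared) / length(gs),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "members") <- modules
    out
}

#' Signed topology metrics per gene
#'
#' Eight per-gene descriptors of a signed network: degree centralities
#' \code{d+/(n-1)} and \code{d-/(n-1)}; normalised betweenness and
#' eigenvector centrality on the unsigned union graph (configurable);
#' local clustering coefficients on the positive-only and negative-only
#' subgraphs (0 for genes with fewer than two same-sign edges); and the
#' network-level degree assortativity of each sign-restricted subgraph,
#' attributed to every gene of that subgraph (NA elsewhere or when
#' undefined).
#'
#' @param net a non-empty [SignedNetwork].
#' @param centralityScope graph on which betweenness / eigenvector are
#'   computed: \code{"union"} (default), \code{"pos"}, or \code{"neg"}.
#' @return data.frame, one row per gene.
#' @export
topologyMetrics <- function(net, centralityScope = c("union", "pos", "neg")) {
    stopifnot(is(net, "SignedNetwork"))
    centralityScope <- match.arg(centralityScope)
    ns <- genes(net)
    n <- length(ns)
    if (!n) stop("empty network")
    deg <- signedDegree(net)
    cg <- switch(centralityScope,
                 union = .unionGraph(net),
                 pos = .signSubgraph(net, "pos"),
                 neg = .signSubgraph(net, "neg"))
    btw <- igraph::betweenness(cg, normalized = n > 2L)
    eig <- tryCatch(igraph::eigen_centrality(cg)$vector,
                    error = function(e) {
                        warning("eigenvector centrality did not converge")
                        stats::setNames(rep(NA_real_, n), ns)
                    })
    signPart <- function(sign) {
        sub <- .signSubgraph(net, sign)
        cc <- igraph::transitivity(sub, type = "local", isolates = "zero")
        cc <- stats::setNames(cc, igraph::V(sub)$name)
        active <- ns[deg[, sign] > 0L]
        subA <- .signSubgraph(net, sign, allNodes = FALSE)
        assort <- if (igraph::ecount(subA) >= 2L)
            suppressWarnings(igraph::assortativity_degree(subA,
                                                          directed = FALSE))
            else NA_real_
        if (is.nan(assort)) assort <- NA_real_
        av <- stats::setNames(rep(NA_real_, n), ns)
        av[active] <- assort
        list(clustering = cc[ns], assortativity = av)
    }
    pp <- signPart("pos"); nn <- signPart("neg")
    data.frame(
        gene = ns,
        degreeCentralityPos = deg[, "pos"] / max(n - 1L, 1L),
        degreeCentralityNeg = deg[, "neg"] / max(n - 1L, 1L),
        betweenness = as.numeric(btw[ns]),
        eigenvector = as.numeric(eig[ns]),
        assortativityPos = as.numeric(pp$assortativity),
        assortativityNeg = as.numeric(nn$assortativity),
        clusteringPos = as.numeric(pp$clustering),
        clusteringNeg = as.numeric(nn$clustering),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' K-means profile of embedding clusters
#'
#' Clusters the gene embeddings (K-means, k-means++-style multiple
#' restarts) and reports the mean of the eight [topologyMetrics()] per
#' cluster, plus a per-metric min-max scaled matrix ready for heatmap
#' export (each metric row spans exactly [0, 1] unless constant).
#'
#' @param emb an [EmbeddingTable] of a single network (plain gene ids, or
#'   \code{"gene::context"} ids matching \code{net}'s context).
#' @param net the [SignedNetwork] the metrics are computed on.
#' @param K number of clusters (default 10).
#' @param seed optional integer seed.
#' @param nstart random restarts (default 10).
#' @return list with \code{assignments} (named cluster ids), \code{means}
#'   (K x 8 data.frame) and \code{scaled} (8 x K matrix, min-max per row).
#' @export
clusterProfile <- function(emb, net, K = 10L, seed = NULL, nstart = 10L) {
    stopifnot(is(emb, "EmbeddingTable"), is(net, "SignedNetwork"))
    ids <- nodeIds(emb)
    want <- genes(net)
    rows <- if (all(want %in% ids)) want
            else paste(want, networkContext(net), sep = "::")
    if (!all(rows %in% ids))
        stop("embedding does not cover the network's genes")
    V <- emb@vectors[rows, , drop = FALSE]
    if (K > nrow(V)) stop("K (", K, ") exceeds node count (", nrow(V), ")")
    if (!is.null(seed)) set.seed(seed)
    km <- stats::kmeans(V, centers = K, nstart = nstart, iter.max = 100L)
    assign <- stats::setNames(km$cluster, want)
    tm <- topologyMetrics(net)
    metricCols <- setdiff(colnames(tm), "gene")
    means <- do.call(rbind, lapply(sort(unique(assign)), function(cl) {
        colMeans(tm[tm$gene %in% names(assign)[assign == cl], metricCols,
                    drop = FALSE], na.rm = TRUE)
    }))
    rownames(means) <- paste0("cluster", sort(unique(assign)))
    scaled <- matrix(0, ncol(means), nrow(means),
                     dimnames = list(colnames(means), rownames(means)))
    for (ci in seq_len(ncol(means))) {
        col <- means[, ci]
        rng <- suppressWarnings(range(col, na.rm = TRUE))
        if (all(is.finite(rng)) && diff(rng) > 0)
            scaled[ci, ] <- (col - rng[1L]) / diff(rng)
    }
    list(assignments = assign, means = as.data.frame(means), scaled = scaled)
}
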