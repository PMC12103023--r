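#' Generate biased random walks on the context graph
#'
#' Every node seeds \code{walksPerNode} walks starting at layer 0. At each
#' step the walker makes an intra-layer move with probability \code{q}
#' (choosing among the layer's links in proportion to their weights and
#' appending the destination node to the walk) or an inter-layer move with
#' probability \code{1 - q} (changing layer, appending nothing). A walk ends
#' once \code{walkLength} tokens have been emitted (the start node counts as
#' the first token). Fully reproducible for a given seed.
#'
#' @param g a [ContextGraph].
#' @param walksPerNode walks started per node (default 10).
#' @param walkLength tokens per walk (default 80).
#' @param q intra-layer transition probability (default 0.8).
#' @param seed integer seed.
#' @return a [WalkCorpus].
#' @export
generateWalks <- function(g, walksPerNode = 10L, walkLength = 80L, q = 0.8,
                          seed = 1L) {
    stopifnot(is(g, "ContextGraph"), walksPerNode >= 1, walkLength >= 1,
              q > 0, q < 1)
    if (length(g@nodeIds) < 2L) stop("need at least two nodes to walk")
    tab <- .walkTables(g, q)
    set.seed(seed)
    w <- .cppWalks(tab$nbr, tab$cum, tab$pIntra, tab$pUp,
                   as.integer(walksPerNode), as.integer(walkLength))
    new("WalkCorpus", walks = w, nodeIds = g@nodeIds,
        params = list(walksPerNode = walksPerNode, walkLength = walkLength,
                      q = q, seed = seed))
}

#' @rdname WalkCorpus-class
#' @aliases walks,WalkCorpus-method
setMethod("walks", "WalkCorpus", function(x)
    lapply(x@walks, function(w) x@nodeIds[w]))

#' @rdname WalkCorpus-class
setMethod("nodeIds", "WalkCorpus", function(x) x@nodeIds)

setMethod("show", "WalkCorpus", function(object) {
    cat("WalkCorpus:", length(object@walks), "walks over",
        length(object@nodeIds), "nodes\n")
})

#' Train Skip-Gram embeddings on a walk corpus
#'
#' Skip-Gram with negative sampling; the vocabulary is every token in the
#' corpus (min count 1), so each non-isolated node receives a vector.
#' Training is single-threaded and seeded, hence deterministic.
#'
#' @param corpus a [WalkCorpus].
#' @param dim embedding dimension (default 128; 2 is handy for plots).
#' @param window context window half-width (default 5; shrunk uniformly per
#'   center token, as in word2vec).
#' @param epochs passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param alpha,minAlpha initial / floor learning rate.
#' @param seed integer seed.
#' @return an [EmbeddingTable].
#' @export
trainEmbedding <- function(corpus, dim = 128L, window = 5L, epochs = 5L,
                           negative = 5L, alpha = 0.025, minAlpha = 1e-4,
                           seed = 1L) {
    stopifnot(is(corpus, "WalkCorpus"))
    if (dim < 1) stop("dim must be >= 1")
    if (!length(corpus@walks)) stop("empty walk corpus")
    n <- length(corpus@nodeIds)
    counts <- integer(n)
    tok <- table(unlist(corpus@walks, use.names = FALSE))
    counts[as.integer(names(tok))] <- as.integer(tok)
    if (all(counts == 0L)) stop("empty vocabulary")
    counts <- pmax(counts, 1L) # guard: every node id stays sampleable
    set.seed(seed)
    m <- .cppSGNS(corpus@walks, n, counts, as.integer(dim),
                  as.integer(window), as.integer(epochs),
                  as.integer(negative), alpha, minAlpha)
    rownames(m) <- corpus@nodeIds
    new("EmbeddingTable", vectors = m,
        params = c(corpus@params,
                   list(dim = dim, window = window, epochs = epochs,
                        negative = negative, alpha = alpha,
                        trainSeed = seed)))
}

#' @rdname EmbeddingTable-class
#' @aliases embeddingMatrix,EmbeddingTable-method
setMethod("embeddingMatrix", "EmbeddingTable", function(x) x@vectors)

#' @rdname EmbeddingTable-class
setMethod("nodeIds", "EmbeddingTable", function(x) rownames(x@vectors))

setMethod("show", "EmbeddingTable", function(object) {
    cat("EmbeddingTable:", nrow(object@vectors), "nodes x",
        ncol(object@vectors), "dimensions\n")
})

#' Save / load embeddings in word-vector text format
#'
#' First line \code{"N dim"}, then one row per node: the node id followed by
#' \code{dim} reals (whitespace-delimited), compatible with common
#' word-vector loaders. Round-trips within 1e-6.
#'
#' @param x an [EmbeddingTable].
#' @param path file path.
#' @return \code{loadEmbeddings} returns an [EmbeddingTable].
#' @export
saveEmbeddings <- function(x, path) {
    stopifnot(is(x, "EmbeddingTable"))
    m <- x@vectors
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(paste(nrow(m), ncol(m)), con)
    writeLines(paste(rownames(m),
                     apply(m, 1L, function(r) paste(sprintf("%.8e", r),
                                                    collapse = " "))), con)
    invisible(path)
}

#' @rdname saveEmbeddings
#' @export
loadEmbeddings <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) stop("empty embedding file")
    hd <- suppressWarnings(as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]))
    if (length(hd) != 2L || anyNA(hd))
        stop("malformed header; expected 'N dim'")
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    if (length(body) != hd[[1L]])
        stop("header declares ", hd[[1L]], " rows but file has ", length(body))
    parts <- strsplit(trimws(body), "\\s+")
    nf <- lengths(parts)
    if (any(nf != hd[[2L]] + 1L))
        stop("ragged row(s): ", paste(which(nf != hd[[2L]] + 1L), collapse = ", "))
    ids <- vapply(parts, `[[`, character(1), 1L)
    m <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hd[[2L]])))
    if (hd[[2L]] == 1L) m <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                                    ncol = 1L)
    rownames(m) <- ids
    new("EmbeddingTable", vectors = m, params = list(source = path))
}

#' End-to-end role embedding of one or more signed networks
#'
#' Full pipeline: (merged) signed degrees, multi-hop dissimilarities,
#' multilayer context graph, biased walks, Skip-Gram. For a list of
#' networks or a [MergedNetwork], all contexts share one embedding space and
#' node ids are \code{"gene::context"}.
#'
#' @param x a [SignedNetwork], [MergedNetwork], or list of context-labelled
#'   [SignedNetwork] objects.
#' @param kMax hop depth of the structural comparison (default 3).
#' @param dim,walksPerNode,walkLength,q,window,epochs,negative see
#'   [generateWalks()] and [trainEmbedding()].
#' @param seed integer seed driving walks and training.
#' @param ebedMinusOne see [ebed()].
#' @param maxNodes all-pairs guard, see [dissimilarityTable()].
#' @return an [EmbeddingTable].
#' @examples
#' net <- makeSimTree()
#' emb <- embedNetworks(net, dim = 8, walksPerNode = 2, walkLength = 20,
#'                      seed = 1)
#' dim(embeddingMatrix(emb))
#' @export
embedNetworks <- function(x, kMax = 3L, dim = 128L, walksPerNode = 10L,
                          walkLength = 80L, q = 0.8, window = 5L,
                          epochs = 5L, negative = 5L, seed = 1L,
                          ebedMinusOne = FALSE, maxNodes = 3000L) {
    if (is.list(x) && !is(x, "MergedNetwork")) x <- mergeNetworks(x)
    dt <- dissimilarityTable(x, kMax = kMax, ebedMinusOne = ebedMinusOne,
                             maxNodes = maxNodes)
    g <- buildContextGraph(dt)
    corpus <- generateWalks(g, walksPerNode = walksPerNode,
                            walkLength = walkLength, q = q, seed = seed)
    trainEmbedding(corpus, dim = dim, window = window, epochs = epochs,
                   negative = negative, seed = seed + 1L)
}
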