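#' Merge signed networks into one embedding space
#'
#' Combines per-context networks into their disjoint union. Merged node
#' identifiers are \code{"gene::context"}; no edge crosses contexts, so any
#' cross-context affinity later picked up by the embedding reflects
#' structural similarity alone.
#'
#' @param nets list of [SignedNetwork] objects with distinct, non-empty
#'   context labels (set via [SignedNetwork()] or [readEdgeList()]).
#' @return a [MergedNetwork].
#' @examples
#' a <- SignedNetwork(pos = rbind(c("A", "B")), context = "c1")
#' b <- SignedNetwork(pos = rbind(c("B", "C")), context = "c2")
#' m <- mergeNetworks(list(a, b))
#' sharedGenes(m, "c1", "c2")
#' @export
mergeNetworks <- function(nets) {
    if (!is.list(nets) || length(nets) < 2L)
        stop("need a list of at least two SignedNetwork objects")
    new("MergedNetwork", networks = nets)
}

#' @rdname MergedNetwork-class
#' @aliases sharedGenes,MergedNetwork-method
setMethod("sharedGenes", "MergedNetwork", function(x, c1, c2) {
    ctx <- contexts(x)
    if (!all(c(c1, c2) %in% ctx)) stop("unknown context label")
    intersect(genes(x@networks[[match(c1, ctx)]]),
              genes(x@networks[[match(c2, ctx)]]))
})

#' @rdname MergedNetwork-class
#' @export
contexts <- function(x) {
    stopifnot(is(x, "MergedNetwork"))
    vapply(x@networks, networkContext, character(1))
}

#' @rdname MergedNetwork-class
#' @export
mergedNodeIds <- function(x) {
    stopifnot(is(x, "MergedNetwork"))
    unlist(lapply(x@networks, function(n)
        paste(genes(n), networkContext(n), sep = "::")), use.names = FALSE)
}

#' @rdname MergedNetwork-class
setMethod("genes", "MergedNetwork", function(x)
    sort(unique(unlist(lapply(x@networks, genes), use.names = FALSE))))

setMethod("show", "MergedNetwork", function(object) {
    cat("MergedNetwork of", length(object@networks), "contexts (",
        paste(contexts(object), collapse = ", "), "),",
        length(mergedNodeIds(object)), "merged nodes\n")
})

# disjoint-union versions of the edge matrices / degree table on merged ids
.mergedEdges <- function(m, sign = c("pos", "neg")) {
    sign <- match.arg(sign)
    do.call(rbind, lapply(m@networks, function(n) {
        e <- if (sign == "pos") n@posEdges else n@negEdges
        if (!nrow(e)) return(matrix(character(0), ncol = 2))
        matrix(paste(e, networkContext(n), sep = "::"), ncol = 2)
    }))
}

setMethod("signedDegree", "MergedNetwork", function(x, v = NULL) {
    m <- do.call(rbind, lapply(x@networks, function(n) {
        d <- signedDegree(n)
        rownames(d) <- paste(rownames(d), networkContext(n), sep = "::")
        d
    }))
    if (is.null(v)) return(m)
    if (!v %in% rownames(m)) stop("unknown node: ", v)
    m[v, ]
})

.mergedUnionGraph <- function(m) {
    ed <- rbind(.mergedEdges(m, "pos"), .mergedEdges(m, "neg"))
    igraph::graph_from_data_frame(
        as.data.frame(ed, stringsAsFactors = FALSE), directed = FALSE,
        vertices = data.frame(name = mergedNodeIds(m), stringsAsFactors = FALSE))
}
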