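# canonical form for unordered pairs: row-wise sorted, deduplicated,
# lexicographically ordered
.canonPairs <- function(m) {
    if (is.null(m) || NROW(m) == 0L)
        return(matrix(character(0), ncol = 2))
    m <- as.matrix(m)
    storage.mode(m) <- "character"
    a <- unname(pmin(m[, 1L], m[, 2L]))
    b <- unname(pmax(m[, 1L], m[, 2L]))
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    o <- order(a, b)
    cbind(a[o], b[o], deparse.level = 0)
}

.pairKey <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")

#' Construct a SignedNetwork
#'
#' Builds a validated signed network from positive and negative edge pair
#' matrices. Pairs are canonicalised (undirected, deduplicated), self-loops
#' are dropped with a warning, and the node set is derived from the edges,
#' so isolated genes never occur.
#'
#' @param pos,neg two-column matrices (or data frames) of gene pairs; either
#'   may be empty.
#' @param context optional cell type / state label.
#' @param weights optional numeric edge weights named by
#'   \code{paste(min(u, v), max(u, v), sep = "|")}.
#' @param allowConflicts keep pairs appearing with both signs (each then
#'   contributes one positive and one negative incident edge); default
#'   \code{FALSE}, which makes a conflicting pair an error.
#' @return a [SignedNetwork].
#' @examples
#' net <- SignedNetwork(pos = rbind(c("A", "B")), neg = rbind(c("B", "C")))
#' genes(net)
#' @export
SignedNetwork <- function(pos = NULL, neg = NULL, context = "",
                          weights = numeric(0), allowConflicts = FALSE) {
    pos <- .canonPairs(pos)
    neg <- .canonPairs(neg)
    loops <- c(which(pos[, 1L] == pos[, 2L]), NROW(neg) + which(neg[, 1L] == neg[, 2L]))
    if (NROW(pos) && any(pos[, 1L] == pos[, 2L])) {
        warning("dropping ", sum(pos[, 1L] == pos[, 2L]), " self-loop(s)")
        pos <- pos[pos[, 1L] != pos[, 2L], , drop = FALSE]
    }
    if (NROW(neg) && any(neg[, 1L] == neg[, 2L])) {
        warning("dropping ", sum(neg[, 1L] == neg[, 2L]), " self-loop(s)")
        neg <- neg[neg[, 1L] != neg[, 2L], , drop = FALSE]
    }
    nodes <- sort(unique(c(as.vector(pos), as.vector(neg))))
    if (length(weights)) {
        valid <- .pairKey(c(pos[, 1L], neg[, 1L]), c(pos[, 2L], neg[, 2L]))
        weights <- weights[names(weights) %in% valid]
    }
    new("SignedNetwork", nodes = nodes, posEdges = pos, negEdges = neg,
        context = as.character(context), edgeWeights = weights,
        allowConflicts = isTRUE(allowConflicts))
}

#' @rdname SignedNetwork-class
#' @aliases genes,SignedNetwork-method
setMethod("genes", "SignedNetwork", function(x) x@nodes)

#' @rdname SignedNetwork-class
setMethod("posEdges", "SignedNetwork", function(x) x@posEdges)

#' @rdname SignedNetwork-class
setMethod("negEdges", "SignedNetwork", function(x) x@negEdges)

#' @rdname SignedNetwork-class
setMethod("networkContext", "SignedNetwork", function(x) x@context)

#' @rdname SignedNetwork-class
setMethod("edgeWeights", "SignedNetwork", function(x) x@edgeWeights)

#' @rdname signedDegree
setMethod("signedDegree", "SignedNetwork", function(x, v = NULL) {
    dpos <- table(factor(as.vector(x@posEdges), levels = x@nodes))
    dneg <- table(factor(as.vector(x@negEdges), levels = x@nodes))
    m <- cbind(pos = as.integer(dpos), neg = as.integer(dneg))
    rownames(m) <- x@nodes
    if (is.null(v)) return(m)
    if (!v %in% x@nodes) stop("unknown node: ", v)
    m[v, ]
})

setMethod("show", "SignedNetwork", function(object) {
    cat("SignedNetwork with", length(object@nodes), "genes,",
        nrow(object@posEdges), "positive and",
        nrow(object@negEdges), "negative edges")
    if (nzchar(object@context)) cat(" [context: ", object@context, "]", sep = "")
    cat("\n")
})

# unsigned union graph (igraph); used for hops, Louvain, betweenness etc.
.unionGraph <- function(net) {
    ed <- rbind(net@posEdges, net@negEdges)
    igraph::graph_from_data_frame(
        as.data.frame(ed, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = net@nodes, stringsAsFactors = FALSE))
}

.signSubgraph <- function(net, sign = c("pos", "neg"), allNodes = TRUE) {
    sign <- match.arg(sign)
    ed <- if (sign == "pos") net@posEdges else net@negEdges
    verts <- if (allNodes) net@nodes else sort(unique(as.vector(ed)))
    igraph::graph_from_data_frame(
        as.data.frame(ed, stringsAsFactors = FALSE), directed = FALSE,
        vertices = data.frame(name = verts, stringsAsFactors = FALSE))
}

#' Read a signed edge list
#'
#' Parses a delimited text file with at least three columns (source, target,
#' value) into a [SignedNetwork]. The delimiter (tab or comma) and an
#' optional header row are auto-detected (a header is assumed when the third
#' field of the first line is not numeric). Directionality is ignored:
#' reciprocal rows with equal sign collapse to one undirected edge, and with
#' opposite signs they trigger the conflict rule.
#'
#' @param path file path.
#' @param signMode \code{"sign_column"} (value must be +1/-1) or
#'   \code{"weight_sign"} (any nonzero real; the edge sign is the sign of
#'   the value and the magnitude is kept as an edge weight).
#' @param context optional context label.
#' @param allowConflicts see [SignedNetwork()].
#' @return a [SignedNetwork].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\t1", "B\tC\t-1"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path, signMode = c("sign_column", "weight_sign"),
                         context = "", allowConflicts = FALSE) {
    signMode <- match.arg(signMode)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty edge list: ", path)
    sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
    fields <- strsplit(lines, sep, fixed = TRUE)
    first <- fields[[1L]]
    if (length(first) < 3L)
        stop("line 1: expected at least 3 delimited columns")
    hasHeader <- is.na(suppressWarnings(as.numeric(trimws(first[[3L]]))))
    start <- if (hasHeader) 2L else 1L
    if (start > length(fields)) stop("no data rows in ", path)
    src <- tgt <- character(length(fields) - start + 1L)
    val <- numeric(length(src))
    for (i in seq_along(src)) {
        ln <- i + start - 1L
        f <- trimws(fields[[ln]])
        if (length(f) < 3L)
            stop("line ", ln, ": expected at least 3 columns, found ", length(f))
        v <- suppressWarnings(as.numeric(f[[3L]]))
        if (is.na(v))
            stop("line ", ln, ": value '", f[[3L]], "' is not numeric")
        if (v == 0)
            stop("line ", ln, ": value 0 is not a valid sign or weight")
        if (signMode == "sign_column" && !v %in% c(-1, 1))
            stop("line ", ln, ": sign column must be +1 or -1, found ", f[[3L]])
        src[i] <- f[[1L]]; tgt[i] <- f[[2L]]; val[i] <- v
    }
    pos <- cbind(src, tgt)[val > 0, , drop = FALSE]
    neg <- cbind(src, tgt)[val < 0, , drop = FALSE]
    weights <- numeric(0)
    if (signMode == "weight_sign") {
        key <- .pairKey(src, tgt)
        # reciprocal/duplicate rows: keep the largest magnitude per pair
        o <- order(key, -abs(val))
        keep <- !duplicated(key[o])
        weights <- stats::setNames(val[o][keep], key[o][keep])
    }
    SignedNetwork(pos = pos, neg = neg, context = context,
                  weights = weights, allowConflicts = allowConflicts)
}

#' Write a signed edge list
#'
#' Writes the canonical three-column TSV (\code{source}, \code{target},
#' \code{sign} in \{+1, -1\}) so that reading the file back reproduces the
#' same node and edge sets.
#'
#' @param net a [SignedNetwork] with at least one edge.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
    stopifnot(is(net, "SignedNetwork"))
    np <- nrow(net@posEdges); nn <- nrow(net@negEdges)
    if (np + nn == 0L) stop("network has no edges; nothing to write")
    df <- data.frame(
        source = c(net@posEdges[, 1L], net@negEdges[, 1L]),
        target = c(net@posEdges[, 2L], net@negEdges[, 2L]),
        sign = c(rep(1L, np), rep(-1L, nn)),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
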