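#' @useDynLib signedRoles, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' SignedNetwork: an undirected signed gene regulatory network
#'
#' Genes are nodes; regulatory interactions are undirected edges carrying a
#' sign (activation \code{+}, inhibition \code{-}). Positive and negative
#' edge sets are disjoint unless the object was built with
#' \code{allowConflicts = TRUE}, in which case a conflicting pair counts once
#' towards each signed degree component. Isolated genes are never stored:
#' every node is incident to at least one edge.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot posEdges,negEdges two-column character matrices of unordered gene
#'   pairs in canonical form (each row sorted, rows unique and ordered).
#' @slot context single character label naming the cell type or state the
#'   network was measured in; \code{""} when unset. Must not contain
#'   \code{"::"}, which is reserved for merged node identifiers.
#' @slot edgeWeights numeric vector of per-edge weights (e.g. Spearman rho)
#'   named by canonical pair key, or empty for unweighted networks.
#' @slot allowConflicts logical; whether a pair may occur in both edge sets.
#'
#' @seealso [SignedNetwork()], [readEdgeList()], [signedDegree()]
#' @export
setClass("SignedNetwork",
    representation(
        nodes = "character",
        posEdges = "matrix",
        negEdges = "matrix",
        context = "character",
        edgeWeights = "numeric",
        allowConflicts = "logical"
    ),
    prototype(
        nodes = character(0),
        posEdges = matrix(character(0), ncol = 2),
        negEdges = matrix(character(0), ncol = 2),
        context = "",
        edgeWeights = numeric(0),
        allowConflicts = FALSE
    )
)

setValidity("SignedNetwork", function(object) {
    msg <- character(0)
    pe <- object@posEdges
    ne <- object@negEdges
    if (ncol(pe) != 2L || ncol(ne) != 2L)
        return("edge matrices must have two columns")
    if (length(object@context) != 1L)
        return("context must be a single string")
    all_e <- rbind(pe, ne)
    if (nrow(all_e)) {
        if (any(all_e[, 1L] == all_e[, 2L]))
            msg <- c(msg, "self-loops are not allowed")
        if (!all(as.vector(all_e) %in% object@nodes))
            msg <- c(msg, "edge endpoint not in node set")
    }
    touched <- unique(as.vector(all_e))
    if (!all(object@nodes %in% touched))
        msg <- c(msg, "isolated nodes are not allowed (every node needs d+ + d- >= 1)")
    if (!object@allowConflicts && nrow(pe) && nrow(ne)) {
        pk <- paste(pe[, 1L], pe[, 2L], sep = "\r")
        nk <- paste(ne[, 1L], ne[, 2L], sep = "\r")
        bad <- intersect(pk, nk)
        if (length(bad))
            msg <- c(msg, paste0("pair(s) with conflicting signs: ",
                                 paste(gsub("\r", "--", bad), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' MergedNetwork: several signed networks sharing one embedding space
#'
#' The disjoint union of per-context [SignedNetwork] objects. Merged node
#' identifiers take the form \code{"gene::context"}; no edge crosses
#' contexts. Structural similarity is later computed across the full merged
#' node set, which is what places genes from different networks near one
#' another in the embedding.
#'
#' @slot networks list of [SignedNetwork] with unique, non-empty context
#'   labels free of \code{"::"}.
#' @seealso [mergeNetworks()], [sharedGenes()]
#' @export
setClass("MergedNetwork", representation(networks = "list"))

setValidity("MergedNetwork", function(object) {
    nets <- object@networks
    if (length(nets) < 2L) return("need at least two networks")
    if (!all(vapply(nets, is, logical(1), "SignedNetwork")))
        return("all elements must be SignedNetwork objects")
    ctx <- vapply(nets, function(n) n@context, character(1))
    if (any(!nzchar(ctx))) return("every network needs a non-empty context label")
    if (anyDuplicated(ctx)) return("context labels must be unique")
    if (any(grepl("::", ctx, fixed = TRUE)))
        return("context labels must not contain '::'")
    TRUE
})

#' DissimilarityTable: cumulative structural dissimilarity f_k
#'
#' For every unordered node pair, the cumulative dissimilarity
#' \code{f_k = f_{k-1} + D_k}, where \code{f_0} is the exponential log-ratio
#' distance (EBED) between signed degrees and \code{D_k} the DTW distance
#' between the k-hop degree rings. Entries are \code{NA} where a pair's
#' comparison was truncated because one ring ran empty.
#'
#' @slot kMax integer, deepest hop compared.
#' @slot nodeIds character, node identifiers indexing the matrices.
#' @slot f list of \code{kMax + 1} symmetric numeric matrices (layer k at
#'   position k + 1).
#' @slot ebedMinusOne logical, whether the shifted EBED variant was used.
#' @seealso [dissimilarityTable()], [buildContextGraph()]
#' @export
setClass("DissimilarityTable",
    representation(kMax = "integer", nodeIds = "character", f = "list",
                   ebedMinusOne = "logical"))

#' ContextGraph: the multilayer structural-similarity graph
#'
#' Layer k links every comparable node pair with weight
#' \code{w_k(u, v) = exp(-f_k(u, v))}; each node is also linked to its own
#' copy one layer up with weight \code{ln(Gamma_k(u) + e)} (Gamma counts the
#' node's layer-k links whose weight exceeds the layer mean) and one layer
#' down with weight 1.
#'
#' @slot kMax integer.
#' @slot nodeIds character.
#' @slot intra list of symmetric weight matrices per layer (NA = no link).
#' @slot gamma integer matrix, nodes x layers.
#' @slot up numeric matrix of upward inter-layer weights, nodes x kMax
#'   (column k holds the weight from layer k - 1 to layer k).
#' @slot layerMean numeric, mean intra-layer link weight per layer.
#' @seealso [buildContextGraph()], [transitionDistribution()], [generateWalks()]
#' @export
setClass("ContextGraph",
    representation(kMax = "integer", nodeIds = "character", intra = "list",
                   gamma = "matrix", up = "matrix", layerMean = "numeric"))

#' WalkCorpus: random-walk context sequences
#'
#' @slot walks list of integer vectors indexing \code{nodeIds}; each
#'   non-isolated node starts \code{walksPerNode} walks.
#' @slot nodeIds character.
#' @slot params list of generation parameters (walksPerNode, walkLength, q,
#'   seed).
#' @seealso [generateWalks()], [trainEmbedding()]
#' @export
setClass("WalkCorpus",
    representation(walks = "list", nodeIds = "character", params = "list"))

#' EmbeddingTable: node embeddings
#'
#' @slot vectors numeric matrix, one row per node (row names are node ids;
#'   merged runs use \code{"gene::context"} ids).
#' @slot params list of training settings including all seeds.
#' @seealso [trainEmbedding()], [embedNetworks()], [saveEmbeddings()]
#' @export
setClass("EmbeddingTable",
    representation(vectors = "matrix", params = "list"))

setValidity("EmbeddingTable", function(object) {
    if (is.null(rownames(object@vectors))) return("vectors must have row names")
    if (anyDuplicated(rownames(object@vectors))) return("duplicate node ids")
    TRUE
})
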