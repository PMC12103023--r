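#' @rdname SignedNetwork-class
#' @param x a package object.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("posEdges", function(x) standardGeneric("posEdges"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("negEdges", function(x) standardGeneric("negEdges"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("networkContext", function(x) standardGeneric("networkContext"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' Signed degree of genes
#'
#' The 2-vector \code{[d+, d-]} counting positive and negative edges
#' incident to each gene; the elementary topological descriptor every
#' downstream comparison builds on.
#'
#' @param x a [SignedNetwork].
#' @param v optional gene identifier; when given, the single degree vector
#'   is returned, otherwise an n x 2 matrix for all genes.
#' @return integer matrix with columns \code{pos}, \code{neg} (or a length-2
#'   vector for one gene).
#' @examples
#' net <- SignedNetwork(pos = rbind(c("A", "B"), c("A", "C")),
#'                      neg = rbind(c("A", "D")))
#' signedDegree(net, "A") # [3 incident edges: 2 positive, 1 negative]
#' @export
setGeneric("signedDegree", function(x, v = NULL) standardGeneric("signedDegree"))

#' @rdname MergedNetwork-class
#' @param x a [MergedNetwork].
#' @param c1,c2 context labels.
#' @export
setGeneric("sharedGenes", function(x, c1, c2) standardGeneric("sharedGenes"))

#' @rdname DissimilarityTable-class
#' @param x a package object with a layer structure.
#' @export
setGeneric("kMax", function(x) standardGeneric("kMax"))

#' @rdname DissimilarityTable-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname EmbeddingTable-class
#' @param x an [EmbeddingTable].
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname WalkCorpus-class
#' @param x a [WalkCorpus].
#' @export
setGeneric("walks", function(x) standardGeneric("walks"))
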