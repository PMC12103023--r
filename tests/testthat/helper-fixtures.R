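# small in-code fixtures shared across tests

# write an edge list to a temp file and return the path
edgeFile <- function(lines, ext = ".tsv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

# tiny labelled networks
pathNet <- function(context = "") # A - B - C, first edge +, second -
    SignedNetwork(pos = rbind(c("A", "B")), neg = rbind(c("B", "C")),
                  context = context)

starNet <- function() # center with 3 positive and 1 negative spoke
    SignedNetwork(pos = rbind(c("hub", "p1"), c("hub", "p2"), c("hub", "p3")),
                  neg = rbind(c("hub", "n1")))

cliqueEdges <- function(members) {
    t(utils::combn(members, 2L))
}

# EmbeddingTable straight from a matrix (for arithmetic tests)
embFromMatrix <- function(m) new("EmbeddingTable", vectors = m, params = list())

# relabel a network with a seeded random permutation; returns list(net, map)
relabelNet <- function(net, seed, context = networkContext(net),
                       prefix = "x") {
    g <- genes(net)
    set.seed(seed)
    map <- stats::setNames(sample(paste0(prefix, seq_along(g))), g)
    list(net = SignedNetwork(
             pos = matrix(map[posEdges(net)], ncol = 2),
             neg = matrix(map[negEdges(net)], ncol = 2),
             context = context),
         map = map)
}

# rank-based AUC of score separating TRUE labels upward
rankAUC <- function(score, label) {
    r <- rank(score)
    nPos <- sum(label); nNeg <- sum(!label)
    (sum(r[label]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
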