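#' The 31-gene simulated tree network
#'
#' A fixed scale-free-like signed tree used throughout the package's
#' examples and tests: a root hub (S0) with five intermediate hubs, each
#' fanning out into leaves; two of the hubs additionally carry one leaf
#' attached by a single negative edge (S9 and S15). Those two negative
#' leaves are automorphic twins -- identical signed degree \code{[0, 1]}
#' and identical degree rings at every hop -- which makes them the
#' canonical probe for role-based embeddings. The positive backbone is
#' connected and acyclic. Also shipped as a packaged edge list
#' (\code{system.file("extdata", "sim_tree_edges.tsv",
#' package = "signedRoles")}).
#'
#' @param context optional context label.
#' @return a [SignedNetwork] with 31 genes and 30 edges (2 negative).
#' @examples
#' net <- makeSimTree()
#' length(genes(net)) # 31
#' signedDegree(net, "S9") # [0, 1]
#' @export
makeSimTree <- function(context = "") {
    hub <- function(h, leaves) cbind(h, paste0("S", leaves))
    pos <- rbind(
        cbind("S0", paste0("S", 1:5)),
        hub("S1", c(6, 7, 8, 10)),
        hub("S2", 11:14),
        hub("S3", 16:20),
        hub("S4", 21:25),
        hub("S5", 26:30))
    neg <- rbind(c("S1", "S9"), c("S2", "S15"))
    SignedNetwork(pos = pos, neg = neg, context = context)
}

#' Scale-free signed network generator
#'
#' Preferential attachment: starting from \code{mAttach} unconnected seed
#' nodes, each new node attaches to \code{mAttach} distinct existing nodes
#' chosen with probability proportional to degree + 1, giving exactly
#' \code{mAttach * (n - mAttach)} edges and a power-law-ish degree
#' distribution, as observed in real GRNs. Each edge is independently
#' negative with probability \code{negFraction}.
#'
#' @param n number of genes (> \code{mAttach}).
#' @param mAttach edges per new node (default 2).
#' @param negFraction probability an edge is negative (default 0.3).
#' @param seed integer seed (mandatory: fixtures are pure functions of
#'   their parameters and seed).
#' @param context optional context label.
#' @param prefix gene-name prefix (names are \code{prefix1..prefixn}).
#' @return a [SignedNetwork].
#' @export
makeScaleFree <- function(n, mAttach = 2L, negFraction = 0.3, seed,
                          context = "", prefix = "g") {
    if (missing(seed)) stop("seed is mandatory")
    if (!(n > mAttach && mAttach >= 1L)) stop("need n > mAttach >= 1")
    if (negFraction < 0 || negFraction > 1) stop("negFraction must be in [0, 1]")
    set.seed(seed)
    deg <- integer(n)
    nEdges <- mAttach * (n - mAttach)
    ea <- eb <- integer(nEdges)
    at <- 0L
    for (i in (mAttach + 1L):n) {
        existing <- seq_len(i - 1L)
        targets <- sample(existing, mAttach, prob = deg[existing] + 1)
        for (t in targets) {
            at <- at + 1L
            ea[at] <- i; eb[at] <- t
            deg[i] <- deg[i] + 1L; deg[t] <- deg[t] + 1L
        }
    }
    isNeg <- stats::runif(nEdges) < negFraction
    nm <- paste0(prefix, seq_len(n))
    pos <- cbind(nm[ea[!isNeg]], nm[eb[!isNeg]])
    neg <- cbind(nm[ea[isNeg]], nm[eb[isNeg]])
    SignedNetwork(pos = pos, neg = neg, context = context)
}

# internal edge-frame representation used by the rewiring generators
.edgeFrame <- function(net) {
    pe <- net@posEdges; ne <- net@negEdges
    data.frame(a = c(pe[, 1L], ne[, 1L]), b = c(pe[, 2L], ne[, 2L]),
               sign = rep(c(1L, -1L), c(nrow(pe), nrow(ne))),
               stringsAsFactors = FALSE)
}

.frameToNetwork <- function(ef, context) {
    SignedNetwork(pos = ef[ef$sign > 0, c("a", "b")],
                  neg = ef[ef$sign < 0, c("a", "b")], context = context)
}

.frameDegrees <- function(ef, nodes) {
    dp <- table(factor(c(ef$a[ef$sign > 0], ef$b[ef$sign > 0]), levels = nodes))
    dn <- table(factor(c(ef$a[ef$sign < 0], ef$b[ef$sign < 0]), levels = nodes))
    cbind(pos = as.integer(dp), neg = as.integer(dn),
          deparse.level = 0) -> m
    rownames(m) <- nodes
    m
}

# Rewire each gene in `targets` while leaving bystander degree vectors
# unchanged wherever possible:
#   1. every edge incident to the gene has its far endpoint exchanged with a
#      uniformly chosen same-sign partner edge (a degree-preserving 2-swap:
#      (g,v),(x,y) -> (g,y),(x,v)), replacing the gene's neighbourhood
#      without touching any degree vector;
#   2. up to two incident edges -- preferring edges to other target genes --
#      are sign-flipped in the same direction, guaranteeing an L1 signed-
#      degree change of at least 2 for the gene at a collateral cost of at
#      most two bystanders (L1 change 2 each).
# Total edge count and total degree sequence are preserved.
.rewireGenes <- function(ef, nodes, targets) {
    for (g in targets) {
        inc <- which(ef$a == g | ef$b == g)
        for (i in inc) {
            v <- if (ef$a[i] == g) ef$b[i] else ef$a[i]
            s <- ef$sign[i]
            cand <- which(ef$sign == s & ef$a != g & ef$b != g)
            if (!length(cand)) next
            cand <- cand[sample.int(length(cand))]
            done <- FALSE
            for (j in utils::head(cand, 30L)) {
                for (sw in 1:2) {
                    x <- if (sw == 1L) ef$a[j] else ef$b[j]
                    y <- if (sw == 1L) ef$b[j] else ef$a[j]
                    if (y == v || x == v || y == g) next
                    Ng <- c(ef$b[ef$a == g], ef$a[ef$b == g])
                    if (y %in% Ng) next
                    Nx <- c(ef$b[ef$a == x], ef$a[ef$b == x])
                    if (v %in% Nx) next
                    ef$a[i] <- pmin(g, y); ef$b[i] <- pmax(g, y)
                    ef$a[j] <- pmin(x, v); ef$b[j] <- pmax(x, v)
                    done <- TRUE; break
                }
                if (done) break
            }
        }
        inc <- which(ef$a == g | ef$b == g)
        if (!length(inc)) next
        dir <- if (any(ef$sign[inc] > 0L)) 1L else -1L
        pool <- inc[ef$sign[inc] == dir]
        far <- ifelse(ef$a[pool] == g, ef$b[pool], ef$a[pool])
        pref <- order(!(far %in% targets), sample.int(length(pool)))
        flip <- utils::head(pool[pref], 2L)
        ef$sign[flip] <- -dir
    }
    ef
}

#' Paired networks with planted structurally rewired genes
#'
#' Copies \code{base} into two contexts and structurally rewires
#' \code{kGenes} randomly selected genes in the second copy: every incident
#' edge has its far endpoint exchanged with a uniformly drawn same-sign
#' partner edge (a degree-preserving 2-swap, so bystander degree vectors
#' stay untouched), and up to two incident edges -- preferring edges to
#' other selected genes -- are sign-flipped in one direction so the gene's
#' signed degree moves by at least 2 in L1. Total edge count and degree
#' sequence are preserved, isolating role change from density change.
#' Bystander genes whose degree changed anyway are returned, with a warning
#' when they outnumber \code{2 * kGenes}.
#'
#' @param base a [SignedNetwork].
#' @param kGenes number of genes to perturb (must be < |V| / 5).
#' @param seed integer seed.
#' @param contexts length-2 character, context labels of the two copies.
#' @return list: \code{netA}, \code{netB} ([SignedNetwork]s),
#'   \code{perturbed} (character), \code{collateral} (bystanders with
#'   changed degrees).
#' @export
makePerturbedPair <- function(base, kGenes, seed, contexts = c("c1", "c2")) {
    stopifnot(is(base, "SignedNetwork"), length(contexts) == 2L)
    nodes <- genes(base)
    if (kGenes >= length(nodes) / 5)
        stop("kGenes must be below |V|/5 = ", length(nodes) / 5)
    set.seed(seed)
    ef <- .edgeFrame(base)
    perturbed <- if (kGenes > 0L) sort(sample(nodes, kGenes)) else character(0)
    ef2 <- .rewireGenes(ef, nodes, perturbed)
    d0 <- .frameDegrees(ef, nodes)
    d1 <- .frameDegrees(ef2, nodes)
    changed <- nodes[rowSums(abs(d1 - d0)) > 0L]
    collateral <- setdiff(changed, perturbed)
    if (length(collateral) > 2L * max(kGenes, 1L))
        warning("rewiring touched ", length(collateral), " bystander gene(s): ",
                paste(utils::head(collateral, 10L), collapse = ", "),
                if (length(collateral) > 10L) ", ...")
    list(netA = .frameToNetwork(ef, contexts[[1L]]),
         netB = .frameToNetwork(ef2, contexts[[2L]]),
         perturbed = perturbed, collateral = collateral)
}

#' Network with planted automorphic twin pairs
#'
#' A scale-free core plus \code{nTwinPairs} pairs of added genes, the two
#' genes of each pair attached to an identical anchor set with identical
#' signs (and not to each other), making them automorphic: any role-based
#' embedding must place them near-identically.
#'
#' @param n total gene count (core is \code{n - 2 * nTwinPairs}).
#' @param nTwinPairs number of planted pairs (default 10).
#' @param negFraction,mAttach passed to [makeScaleFree()] for the core.
#' @param seed integer seed.
#' @param context optional context label.
#' @return list: \code{net} ([SignedNetwork]), \code{twins} (data.frame
#'   with columns \code{a}, \code{b}).
#' @export
makeTwinPairs <- function(n = 150L, nTwinPairs = 10L, negFraction = 0.3,
                          mAttach = 2L, seed, context = "") {
    if (missing(seed)) stop("seed is mandatory")
    nCore <- n - 2L * nTwinPairs
    if (nCore <= mAttach + 1L) stop("n too small for the requested twin pairs")
    core <- makeScaleFree(nCore, mAttach = mAttach, negFraction = negFraction,
                          seed = seed, context = context)
    set.seed(seed + 1L)
    pos <- core@posEdges; neg <- core@negEdges
    twins <- data.frame(a = character(nTwinPairs), b = character(nTwinPairs),
                        stringsAsFactors = FALSE)
    for (p in seq_len(nTwinPairs)) {
        nAnchor <- sample(1:3, 1L)
        anchors <- sample(genes(core), nAnchor)
        signs <- ifelse(stats::runif(nAnchor) < negFraction, -1L, 1L)
        a <- sprintf("twin%02da", p); b <- sprintf("twin%02db", p)
        if (any(signs > 0))
            pos <- rbind(pos, cbind(a, anchors[signs > 0]),
                         cbind(b, anchors[signs > 0]))
        if (any(signs < 0))
            neg <- rbind(neg, cbind(a, anchors[signs < 0]),
                         cbind(b, anchors[signs < 0]))
        twins$a[p] <- a; twins$b[p] <- b
    }
    list(net = SignedNetwork(pos = pos, neg = neg, context = context),
         twins = twins)
}

#' Multi-context cohort with two planted perturbation patterns
#'
#' Builds \code{C} copies of \code{base} (contexts \code{c1..cC}) and
#' plants two gene classes: \code{"all"} genes are rewired independently in
#' every context (expected signature: high mean centroid distance), and
#' \code{"one"} genes are rewired in exactly one randomly assigned context
#' (expected signature: high SD of distances relative to their mean rank).
#'
#' @param base a [SignedNetwork].
#' @param C number of contexts (>= 3).
#' @param kGenesPerClass genes planted in each class.
#' @param seed integer seed.
#' @return list: \code{merged} ([MergedNetwork]), \code{truth} (data.frame
#'   gene / class / perturbedIn).
#' @export
makeMultiContext <- function(base, C = 5L, kGenesPerClass = 10L, seed) {
    stopifnot(is(base, "SignedNetwork"), C >= 3L)
    nodes <- genes(base)
    if (2L * kGenesPerClass >= length(nodes) / 5)
        stop("kGenesPerClass too large for |V| = ", length(nodes))
    set.seed(seed)
    picked <- sample(nodes, 2L * kGenesPerClass)
    allCtx <- sort(picked[seq_len(kGenesPerClass)])
    oneCtx <- sort(picked[kGenesPerClass + seq_len(kGenesPerClass)])
    oneAssign <- stats::setNames(sample(C, kGenesPerClass, replace = TRUE),
                                 oneCtx)
    ef <- .edgeFrame(base)
    nets <- lapply(seq_len(C), function(ci) {
        targets <- sort(c(allCtx, oneCtx[oneAssign == ci]))
        efi <- if (length(targets)) .rewireGenes(ef, nodes, targets)
               else ef
        .frameToNetwork(efi, paste0("c", ci))
    })
    truth <- data.frame(gene = character(0), class = character(0),
                        perturbedIn = character(0), stringsAsFactors = FALSE)
    if (length(allCtx))
        truth <- rbind(truth, data.frame(
            gene = allCtx, class = "all",
            perturbedIn = paste(paste0("c", seq_len(C)), collapse = ","),
            stringsAsFactors = FALSE))
    if (length(oneCtx))
        truth <- rbind(truth, data.frame(
            gene = oneCtx, class = "one",
            perturbedIn = paste0("c", oneAssign), stringsAsFactors = FALSE))
    list(merged = mergeNetworks(nets), truth = truth)
}
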