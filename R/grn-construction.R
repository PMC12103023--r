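#' Read a gene x cell count matrix
#'
#' Accepts a dense CSV (genes as rows, first column gene names, header row
#' of cell names) or a MatrixMarket MTX file with sidecar gene / cell name
#' files (one name per line).
#'
#' @param path CSV or MTX file.
#' @param geneFile,cellFile required for MTX input.
#' @return numeric matrix with gene row names and cell column names.
#' @export
readCountMatrix <- function(path, geneFile = NULL, cellFile = NULL) {
    if (grepl("\\.mtx(\\.gz)?$", path)) {
        if (is.null(geneFile) || is.null(cellFile))
            stop("MTX input needs geneFile and cellFile sidecars")
        m <- as.matrix(Matrix::readMM(path))
        rownames(m) <- readLines(geneFile, warn = FALSE)
        colnames(m) <- readLines(cellFile, warn = FALSE)
    } else {
        df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
        m <- as.matrix(df)
    }
    if (anyDuplicated(rownames(m))) stop("duplicate gene names")
    if (any(m < 0)) stop("counts must be non-negative")
    storage.mode(m) <- "double"
    m
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p-transformed, library-size
#' normalised expression (each cell scaled to the median depth) and keeps
#' the top \code{n}. Ties and equal variances are broken by gene name for
#' determinism; the chosen set is invariant to input gene order.
#'
#' @param m genes x cells count matrix.
#' @param n number of genes to keep (default 2000).
#' @return the row-subset matrix (cell set unchanged).
#' @export
selectHVG <- function(m, n = 2000L) {
    if (n > nrow(m)) stop("n (", n, ") exceeds gene count (", nrow(m), ")")
    depth <- colSums(m)
    depth[depth == 0] <- 1
    sf <- depth / stats::median(depth)
    l <- log1p(sweep(m, 2L, sf, "/"))
    v <- apply(l, 1L, stats::var)
    keep <- rownames(m)[order(-v, rownames(m))][seq_len(n)]
    m[keep, , drop = FALSE]
}

# all-pairs Spearman rho and two-sided p (t approximation; exact via
# cor.test for small cell counts)
.spearmanAllPairs <- function(m, exact = FALSE) {
    nc <- ncol(m)
    rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    if (exact) {
        ng <- nrow(m)
        p <- matrix(NA_real_, ng, ng, dimnames = dimnames(rho))
        for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
            pv <- tryCatch(suppressWarnings(
                stats::cor.test(m[i, ], m[j, ], method = "spearman",
                                exact = TRUE)$p.value),
                error = function(e) NA_real_)
            p[i, j] <- p[j, i] <- pv
        }
    } else {
        r <- pmin(pmax(rho, -1), 1)
        tt <- r * sqrt((nc - 2) / pmax(1 - r^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), df = nc - 2)
        p[r == 1 | r == -1] <- 0
    }
    list(rho = rho, p = p)
}

#' Build a signed GRN by Spearman correlation
#'
#' For every gene pair, computes the Spearman rank correlation across cells
#' and its two-sided p-value; pairs with \code{p < pThreshold} and
#' \code{|rho| >= rhoThreshold} become edges, signed by the sign of rho.
#' Constant genes (zero rank variance) cannot be correlated and are skipped
#' with a warning. Monotone transforms of individual genes leave the result
#' unchanged, a property of rank correlation.
#'
#' @param m genes x cells count matrix (at least 3 cells).
#' @param pThreshold raw p-value cutoff (default 0.01; no multiple-testing
#'   correction, mirroring the raw-p edge rule used for such networks --
#'   set \code{fdr = TRUE} for a BH-adjusted variant).
#' @param rhoThreshold minimum absolute correlation (default 0.3).
#' @param context context label for the resulting network.
#' @param exact use the exact null distribution of rho (small cell counts);
#'   default is the t approximation.
#' @param fdr apply Benjamini-Hochberg to the pair p-values before
#'   thresholding.
#' @return a [SignedNetwork] with rho stored in [edgeWeights()].
#' @export
spearmanGRN <- function(m, pThreshold = 0.01, rhoThreshold = 0.3,
                        context = "", exact = FALSE, fdr = FALSE) {
    if (ncol(m) < 3L) stop("need at least 3 cells for rank correlation")
    constant <- apply(m, 1L, function(r) length(unique(r)) == 1L)
    if (any(constant)) {
        warning("skipping ", sum(constant), " constant gene(s): ",
                paste(utils::head(rownames(m)[constant], 5L), collapse = ", "))
        m <- m[!constant, , drop = FALSE]
    }
    if (nrow(m) < 2L) return(SignedNetwork(context = context))
    sp <- .spearmanAllPairs(m, exact = exact)
    ut <- upper.tri(sp$rho)
    idx <- which(ut, arr.ind = TRUE)
    p <- sp$p[ut]
    if (fdr) p <- stats::p.adjust(p, method = "BH")
    rho <- sp$rho[ut]
    keep <- !is.na(p) & !is.na(rho) & p < pThreshold & abs(rho) >= rhoThreshold
    src <- rownames(m)[idx[keep, 1L]]
    tgt <- rownames(m)[idx[keep, 2L]]
    r <- rho[keep]
    SignedNetwork(pos = cbind(src, tgt)[r > 0, , drop = FALSE],
                  neg = cbind(src, tgt)[r < 0, , drop = FALSE],
                  context = context,
                  weights = stats::setNames(r, .pairKey(src, tgt)))
}

#' Keep the strongest k edges
#'
#' Retains the \code{k} edges of largest absolute weight (ties broken by
#' descending |weight| then lexicographic pair key, so the result is
#' deterministic); genes left without edges drop out of the network.
#'
#' @param net a [SignedNetwork].
#' @param k number of edges to keep (default 2000).
#' @param weights named per-edge weights (canonical \code{"u|v"} keys);
#'   defaults to the network's stored [edgeWeights()].
#' @return a [SignedNetwork] with \code{min(k, |E|)} edges.
#' @export
topKEdges <- function(net, k = 2000L, weights = edgeWeights(net)) {
    stopifnot(is(net, "SignedNetwork"))
    if (k <= 0) stop("k must be positive")
    pe <- net@posEdges; ne <- net@negEdges
    keys <- c(.pairKey(pe[, 1L], pe[, 2L]), .pairKey(ne[, 1L], ne[, 2L]))
    if (!all(keys %in% names(weights)))
        stop("weights missing for ", sum(!keys %in% names(weights)), " edge(s)")
    w <- weights[keys]
    sgn <- rep(c(1L, -1L), c(nrow(pe), nrow(ne)))
    keep <- order(-abs(w), keys)[seq_len(min(k, length(keys)))]
    ed <- rbind(pe, ne)[keep, , drop = FALSE]
    SignedNetwork(pos = ed[sgn[keep] > 0, , drop = FALSE],
                  neg = ed[sgn[keep] < 0, , drop = FALSE],
                  context = net@context,
                  weights = w[keep])
}
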