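# file-level orchestration: manifest in, embedding/report files out, with a
# machine-readable JSON run log per run

#' Read a merged-network manifest
#'
#' Plain-text config with one \code{context<TAB>path} (or comma-separated)
#' pair per line; lines starting with \code{#} are ignored.
#'
#' @param path manifest file.
#' @param signMode passed to [readEdgeList()].
#' @return named list of [SignedNetwork]s (one per context).
#' @export
readManifest <- function(path, signMode = "sign_column") {
    if (!file.exists(path)) stop("manifest not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    nets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "[\t,]")[[1L]]
        if (length(f) < 2L)
            stop("manifest line ", i, ": expected 'context<TAB>path'")
        ctx <- trimws(f[[1L]]); fp <- trimws(f[[2L]])
        if (!file.exists(fp))
            stop("manifest line ", i, ": file not found: ", fp)
        nets[[ctx]] <- readEdgeList(fp, signMode = signMode, context = ctx)
    }
    nets
}

.runLog <- function(logFile, stage, params, inputs, timings) {
    log <- list(
        package = as.character(utils::packageVersion("signedRoles")),
        rVersion = R.version.string,
        stage = stage,
        params = params,
        inputHashes = if (length(inputs)) as.list(tools::md5sum(inputs))
                      else list(),
        secondsPerStage = timings,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(log, logFile, auto_unbox = TRUE, pretty = TRUE)
    invisible(log)
}

#' Run the embedding pipeline from a manifest
#'
#' Reads the manifest's signed networks, runs the full role-embedding
#' pipeline, writes the embedding file, and emits a JSON run log (package
#' version, parameters, input hashes, wall-clock per stage) sufficient to
#' reproduce the run.
#'
#' @param manifest manifest file path (see [readManifest()]); a single
#'   edge-list file is also accepted when \code{singleNetwork = TRUE}.
#' @param out output embedding file path.
#' @param singleNetwork treat \code{manifest} as one edge list (no merging).
#' @param logFile JSON run-log path (default \code{<out>.log.json}).
#' @inheritParams embedNetworks
#' @return the embedding file path, invisibly.
#' @export
runEmbedding <- function(manifest, out, kMax = 3L, dim = 128L,
                         walksPerNode = 10L, walkLength = 80L, q = 0.8,
                         window = 5L, epochs = 5L, negative = 5L, seed = 1L,
                         ebedMinusOne = FALSE, maxNodes = 3000L,
                         singleNetwork = FALSE,
                         logFile = paste0(out, ".log.json")) {
    t0 <- proc.time()[["elapsed"]]
    if (singleNetwork) {
        x <- readEdgeList(manifest)
        inputs <- manifest
    } else {
        nets <- readManifest(manifest)
        x <- if (length(nets) == 1L) nets[[1L]] else mergeNetworks(unname(nets))
        inputs <- manifest
    }
    t1 <- proc.time()[["elapsed"]]
    emb <- embedNetworks(x, kMax = kMax, dim = dim,
                         walksPerNode = walksPerNode,
                         walkLength = walkLength, q = q, window = window,
                         epochs = epochs, negative = negative, seed = seed,
                         ebedMinusOne = ebedMinusOne, maxNodes = maxNodes)
    t2 <- proc.time()[["elapsed"]]
    saveEmbeddings(emb, out)
    t3 <- proc.time()[["elapsed"]]
    .runLog(logFile, "embed",
            params = list(kMax = kMax, dim = dim,
                          walksPerNode = walksPerNode,
                          walkLength = walkLength, q = q, window = window,
                          epochs = epochs, negative = negative, seed = seed,
                          ebedMinusOne = ebedMinusOne),
            inputs = inputs,
            timings = list(read = t1 - t0, embed = t2 - t1, write = t3 - t2))
    invisible(out)
}

#' Run DTG identification on a saved embedding
#'
#' @param embFile embedding file (word-vector text format).
#' @param out output TSV path.
#' @param mode \code{"pair"} (two contexts, top-10\% rule) or \code{"multi"}
#'   (more than two contexts, top-5\% + SD rule); the mode must match the
#'   number of contexts found in the embedding.
#' @inheritParams classifyDTGs
#' @param logFile JSON run-log path.
#' @return the report path, invisibly.
#' @export
runDTG <- function(embFile, out, mode = c("pair", "multi"),
                   topFracPair = 0.10, topFracMulti = 0.05,
                   sdThreshold = 0.4, sdAuto = FALSE,
                   logFile = paste0(out, ".log.json")) {
    mode <- match.arg(mode)
    t0 <- proc.time()[["elapsed"]]
    emb <- loadEmbeddings(embFile)
    C <- length(unique(.splitIds(nodeIds(emb))$context))
    if (mode == "pair" && C != 2L)
        stop("pair mode needs exactly 2 contexts, found ", C,
             "; use mode = 'multi'")
    if (mode == "multi" && C <= 2L)
        stop("multi mode needs more than 2 contexts, found ", C,
             "; use mode = 'pair'")
    rep <- classifyDTGs(emb, topFracPair = topFracPair,
                        topFracMulti = topFracMulti,
                        sdThreshold = sdThreshold, sdAuto = sdAuto)
    utils::write.table(rep, out, sep = "\t", quote = FALSE, row.names = FALSE)
    .runLog(logFile, "dtg",
            params = list(mode = mode, topFracPair = topFracPair,
                          topFracMulti = topFracMulti,
                          sdThreshold = sdThreshold, sdAuto = sdAuto),
            inputs = embFile,
            timings = list(total = proc.time()[["elapsed"]] - t0))
    invisible(out)
}

#' Run gene-module stability scoring
#'
#' Louvain modules of the anchor network, then per-module mean embedding
#' shift and NA\% against the comparison context.
#'
#' @param embFile embedding file containing both contexts.
#' @param anchorEdgeList edge-list file of the anchor context's network.
#' @param anchor,other context labels.
#' @param out output TSV path.
#' @param minSize minimum retained module size (default 10).
#' @param seed Louvain seed.
#' @param logFile JSON run-log path.
#' @return the report path, invisibly.
#' @export
runModules <- function(embFile, anchorEdgeList, anchor, other, out,
                       minSize = 10L, seed = 1L,
                       logFile = paste0(out, ".log.json")) {
    t0 <- proc.time()[["elapsed"]]
    emb <- loadEmbeddings(embFile)
    net <- readEdgeList(anchorEdgeList, context = anchor)
    mods <- louvainModules(net, minSize = minSize, seed = seed)
    rep <- moduleStability(mods$modules, emb, anchor = anchor, other = other)
    utils::write.table(rep, out, sep = "\t", quote = FALSE, row.names = FALSE)
    .runLog(logFile, "modules",
            params = list(anchor = anchor, other = other, minSize = minSize,
                          seed = seed),
            inputs = c(embFile, anchorEdgeList),
            timings = list(total = proc.time()[["elapsed"]] - t0))
    invisible(out)
}
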