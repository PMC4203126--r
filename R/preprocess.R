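#' @include AllClasses.R utils.R io.R
NULL

#' Quantile normalization
#'
#' Forces every column (array) to share the same empirical distribution:
#' the cross-column means of the order statistics, mapped back by rank.
#' Ties within a column receive the mean of the values they span, so the
#' operation is idempotent.
#'
#' @param x numeric matrix, genes/probes x arrays; no missing values.
#' @return matrix of the same shape, row and column names preserved.
#' @examples
#' quantileNormalize(cbind(s1 = c(5, 2, 3), s2 = c(4, 1, 9)))
#' @export
quantileNormalize <- function(x) {
    stopIfNot(ncol(x) >= 1L, "at least one column is required")
    if (anyNA(x))
        stop("missing values are not allowed in quantile normalization",
             call. = FALSE)
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
}

#' Median polish of a log2 probe matrix
#'
#' Fits the additive model log2(PM) = overall + probe + sample + residual
#' by alternating row- and column-median sweeps, stopping when the largest
#' absolute change in the fit between sweeps drops below \code{tol}.
#'
#' @param logMat numeric matrix, probes x samples, log2 intensities.
#' @param tol convergence tolerance on the max absolute change.
#' @param maxIter sweep limit.
#' @return list with overall, row (probe effects), col (sample effects),
#'   residuals, iterations.
#' @seealso [summarizeProbeSets()] which applies this per probe set and
#'   reports overall + sample effect as the expression value.
#' @export
medianPolish <- function(logMat, tol = 1e-10, maxIter = 100L) {
    r <- logMat
    overall <- 0
    rowEff <- numeric(nrow(r))
    colEff <- numeric(ncol(r))
    for (it in seq_len(maxIter)) {
        delta <- 0
        rm <- apply(r, 1L, stats::median)
        r <- r - rm
        rowEff <- rowEff + rm
        delta <- max(delta, max(abs(rm)))
        cm <- stats::median(rowEff)
        rowEff <- rowEff - cm
        overall <- overall + cm
        cmed <- apply(r, 2L, stats::median)
        r <- sweep(r, 2L, cmed)
        colEff <- colEff + cmed
        delta <- max(delta, max(abs(cmed)))
        rm2 <- stats::median(colEff)
        colEff <- colEff - rm2
        overall <- overall + rm2
        if (delta < tol) break
    }
    list(overall = overall, row = rowEff, col = colEff, residuals = r,
         iterations = it)
}

#' RMA-style summarization of probe intensities
#'
#' Quantile-normalizes the PM matrix across arrays, takes log2, and
#' median-polishes each probe set; the reported expression is
#' overall + sample effect.  Background correction is deliberately not
#' modelled; see the package vignette.
#'
#' @param probes a \linkS4class{ProbeIntensities}.
#' @param normalize apply quantile normalization first (default TRUE).
#' @param tol,maxIter median polish controls.
#' @return An \linkS4class{ExpressionMatrix} (assay \code{"log2"}).
#' @export
summarizeProbeSets <- function(probes, normalize = TRUE, tol = 1e-10,
                               maxIter = 100L) {
    pmMat <- pm(probes)
    if (any(pmMat <= 0))
        stop("PM intensities must be positive before log transform",
             call. = FALSE)
    if (normalize) pmMat <- quantileNormalize(pmMat)
    logPM <- log2(pmMat)
    sets <- unique(probes@probeSet)
    expr <- matrix(NA_real_, length(sets), ncol(logPM),
                   dimnames = list(sets, colnames(logPM)))
    idx <- split(seq_along(probes@probeSet), probes@probeSet)
    for (s in sets) {
        fit <- medianPolish(logPM[idx[[s]], , drop = FALSE], tol = tol,
                            maxIter = maxIter)
        expr[s, ] <- fit$overall + fit$col
    }
    newExpressionMatrix(expr, sampleInfo(probes))
}

#' Replicate correlation QC
#'
#' Pearson correlation between the biological replicates of every
#' (genotype, stage) cell, over genes.  With more than two replicates all
#' pairwise correlations are reported.  A zero-variance replicate yields an
#' NA correlation with \code{flag = "undefined"} rather than propagating
#' NaN.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return data.frame with genotype, stage, rep_a, rep_b, r, flag.
#' @export
replicateCorrelation <- function(x) {
    m <- SummarizedExperiment::assay(x, "log2")
    cd <- as.data.frame(sampleInfo(x))
    out <- list()
    for (g in unique(cd$genotype)) for (st in unique(cd$stage)) {
        cols <- which(cd$genotype == g & cd$stage == st)
        if (length(cols) < 2L) next
        for (a in seq_along(cols)[-length(cols)])
            for (b in (a + 1L):length(cols)) {
                r <- pearson(m[, cols[a]], m[, cols[b]])
                out[[length(out) + 1L]] <- data.frame(
                    genotype = g, stage = st,
                    rep_a = cd$replicate[cols[a]],
                    rep_b = cd$replicate[cols[b]],
                    r = r,
                    flag = if (is.na(r)) "undefined" else "ok",
                    stringsAsFactors = FALSE)
            }
    }
    do.call(rbind, out)
}

# leaf sets of every internal node of an hclust tree
clusterLeafSets <- function(hc) {
    n <- length(hc$labels)
    sets <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        kids <- hc$merge[i, ]
        leaves <- unlist(lapply(kids, function(k)
            if (k < 0) hc$labels[-k] else sets[[k]]))
        sets[[i]] <- sort(leaves)
    }
    sets
}

#' Hierarchical clustering of samples with bootstrap support
#'
#' Average-linkage clustering on correlation distance (1 - Pearson over
#' genes), with ordinary bootstrap proportions: genes are resampled with
#' replacement \code{nBoot} times and each original internal node is scored
#' by the percentage of bootstrap trees containing the same leaf set.
#'
#' @param x an \linkS4class{ExpressionMatrix} with at least 3 samples.
#' @param nBoot bootstrap replicates (>= 1).
#' @param seed integer seed for the gene resampling.
#' @return A \linkS4class{BootstrapDendrogram}.
#' @export
bootstrapHclust <- function(x, nBoot = 100L, seed = 1) {
    m <- SummarizedExperiment::assay(x, "log2")
    stopIfNot(ncol(m) >= 3L, "at least 3 samples are required")
    stopIfNot(nBoot >= 1L, "'nBoot' must be at least 1")
    treeOf <- function(mat) {
        d <- stats::as.dist(1 - stats::cor(mat))
        stats::hclust(d, method = "average")
    }
    hc <- treeOf(m)
    orig <- clusterLeafSets(hc)
    origKey <- vapply(orig, paste, character(1), collapse = "\r")
    hits <- numeric(length(orig))
    withSeed(seed, {
        for (b in seq_len(nBoot)) {
            rows <- sample(nrow(m), nrow(m), replace = TRUE)
            bt <- treeOf(m[rows, , drop = FALSE])
            bkey <- vapply(clusterLeafSets(bt), paste, character(1),
                           collapse = "\r")
            hits <- hits + (origKey %in% bkey)
        }
    })
    new("BootstrapDendrogram", hclust = hc, support = 100 * hits / nBoot,
        nBoot = as.integer(nBoot))
}

#' Write a supported dendrogram as Newick
#'
#' Internal-node labels carry the bootstrap support percentages.
#'
#' @param dend a \linkS4class{BootstrapDendrogram}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(dend, path) {
    phy <- ape::as.phylo(dend@hclust)
    # ape numbers internal nodes by preorder; map hclust merge order to it
    lab <- rep("", phy$Nnode)
    sets <- clusterLeafSets(dend@hclust)
    phySets <- lapply(seq_len(phy$Nnode) + length(phy$tip.label), function(nd)
        sort(phy$tip.label[unlist(pickLeaves(phy, nd))]))
    key <- vapply(phySets, paste, character(1), collapse = "\r")
    for (i in seq_along(sets)) {
        j <- match(paste(sets[[i]], collapse = "\r"), key)
        if (!is.na(j)) lab[j] <- format(round(dend@support[i], 1))
    }
    phy$node.label <- lab
    ape::write.tree(phy, file = path)
    invisible(path)
}

# tips under a node of an ape phylo
pickLeaves <- function(phy, node) {
    nTip <- length(phy$tip.label)
    if (node <= nTip) return(node)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, pickLeaves, phy = phy))
}
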