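#' @include AllClasses.R utils.R
NULL

#' Signed linear fold change between two groups
#'
#' On log2 input, \code{delta = mean(groupB) - mean(groupA)}; the linear
#' fold change is \code{2^|delta|} with the sign of \code{delta}
#' (negative = down in B), so equal means give +1 and a 1-log2-unit
#' difference gives the boundary value 2.
#'
#' @param mat log2 matrix, genes x samples.
#' @param colsA,colsB column indices (or names) of the two groups.
#' @return data.frame with gene, log2fc, fc (signed linear).
#' @export
foldChange <- function(mat, colsA, colsB) {
    delta <- rowMeans(mat[, colsB, drop = FALSE]) -
        rowMeans(mat[, colsA, drop = FALSE])
    sgn <- ifelse(delta < 0, -1, 1)
    data.frame(gene = rownames(mat), log2fc = delta,
               fc = sgn * 2^abs(delta), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' SAM regularized t-like statistic
#'
#' \code{d = (mean_B - mean_A) / (s + s0)} with the SAM pooled standard
#' error \code{s = sqrt(((1/nA + 1/nB) / (nA + nB - 2)) * (SS_A + SS_B))}.
#' Genes with \code{s + s0 = 0} get d = 0 when the mean difference is also
#' zero, and +/-Inf (with a warning) otherwise.
#'
#' @param mat log2 matrix, genes x samples.
#' @param colsA,colsB group columns, at least 2 samples each.
#' @param s0 exchangeability constant; \code{NULL} (default) uses the
#'   median of the gene-wise \code{s}.
#' @return numeric vector \code{d} with attributes \code{s} and \code{s0}.
#' @export
samStatistic <- function(mat, colsA, colsB, s0 = NULL) {
    a <- mat[, colsA, drop = FALSE]; b <- mat[, colsB, drop = FALSE]
    nA <- ncol(a); nB <- ncol(b)
    stopIfNot(nA >= 2L && nB >= 2L, "at least 2 samples per group")
    ssA <- rowSums((a - rowMeans(a))^2)
    ssB <- rowSums((b - rowMeans(b))^2)
    s <- sqrt(((1 / nA + 1 / nB) / (nA + nB - 2)) * (ssA + ssB))
    if (is.null(s0)) s0 <- stats::median(s)
    delta <- rowMeans(b) - rowMeans(a)
    denom <- s + s0
    d <- ifelse(denom == 0, ifelse(delta == 0, 0, Inf * sign(delta)),
                delta / denom)
    if (any(is.infinite(d)))
        warning(sum(is.infinite(d)),
                " gene(s) with zero variance and s0 = 0 flagged infinite")
    attr(d, "s") <- s; attr(d, "s0") <- s0
    d
}

# all balanced relabelings: choose |colsA| of the pooled columns as group A
balancedRelabelings <- function(colsA, colsB) {
    pool <- c(colsA, colsB)
    picks <- utils::combn(length(pool), length(colsA), simplify = FALSE)
    lapply(picks, function(ix)
        list(a = pool[ix], b = pool[-ix]))
}

#' Permutation-based SAM q-values
#'
#' Enumerates the balanced relabelings of the two groups (all of them when
#' feasible, a seeded subsample otherwise), recomputes \code{d} under each,
#' and for every threshold |d| estimates FDR as the median across
#' relabelings of the null exceedance count over the observed count.  The
#' per-gene q-value is the smallest FDR over thresholds at or below that
#' gene's |d| (monotone in the |d| ranking).  Infinite null statistics
#' (zero-variance genes at s0 = 0) are excluded from the null counts.
#'
#' @param mat log2 matrix, genes x samples.
#' @param colsA,colsB group columns.
#' @param s0 as in [samStatistic()]; the observed-data default is reused
#'   for every relabeling.
#' @param nPerm \code{"all"} (default) or a maximum number of relabelings.
#' @param seed seed, only used when subsampling relabelings.
#' @return data.frame with gene, d, q.
#' @export
permutationFdr <- function(mat, colsA, colsB, s0 = NULL, nPerm = "all",
                           seed = 1) {
    d <- samStatistic(mat, colsA, colsB, s0 = s0)
    s0 <- attr(d, "s0")
    relab <- balancedRelabelings(colsA, colsB)
    stopIfNot(length(relab) >= 2L,
              "fewer than 2 distinct labelings; cannot permute")
    if (!identical(nPerm, "all") && length(relab) > nPerm)
        relab <- withSeed(seed, sample(relab, nPerm))
    absd <- abs(as.vector(d))
    ord <- order(absd, decreasing = TRUE)
    thr <- absd[ord]
    nullCounts <- vapply(relab, function(rl) {
        dstar <- abs(as.vector(samStatistic(mat, rl$a, rl$b, s0 = s0)))
        dstar <- dstar[is.finite(dstar)]
        # count of null |d*| >= each threshold, thresholds descending
        length(dstar) - findInterval(thr, sort(dstar), left.open = TRUE)
    }, numeric(length(thr)))
    if (is.null(dim(nullCounts)))
        nullCounts <- matrix(nullCounts, nrow = 1L)
    V <- apply(nullCounts, 1L, stats::median)
    R <- seq_along(thr)                      # observed count at each threshold
    fdr <- pmin(V / R, 1)
    q <- rev(cummin(rev(fdr)))               # best FDR at or below each |d|
    out <- data.frame(gene = rownames(mat), d = as.vector(d),
                      q = NA_real_, row.names = NULL,
                      stringsAsFactors = FALSE)
    out$q[ord] <- q
    out
}

#' Multiclass F-like SAM statistic
#'
#' For designs with more than two groups: the square root of the
#' between-group mean square over the regularized pooled within-group
#' standard deviation, \code{d = sqrt(sum_k n_k (m_k - m)^2 / (K - 1)) /
#' (s + s0)} with \code{s = sqrt(sum_k SS_k / (N - K))}.  Offered next to
#' the per-stage two-class statistic; both are documented in the vignette.
#'
#' @param mat log2 matrix, genes x samples.
#' @param groups factor/vector of group labels, one per column.
#' @param s0 exchangeability constant; default the median gene-wise s.
#' @return numeric vector d with attributes \code{s}, \code{s0}.
#' @export
samMulticlass <- function(mat, groups, s0 = NULL) {
    groups <- as.factor(groups)
    K <- nlevels(groups)
    stopIfNot(K >= 2L, "at least two groups are required")
    stopIfNot(all(table(groups) >= 2L), "at least 2 samples per group")
    N <- ncol(mat)
    gm <- rowMeans(mat)
    between <- 0; within <- 0
    for (lev in levels(groups)) {
        cols <- which(groups == lev)
        mk <- rowMeans(mat[, cols, drop = FALSE])
        between <- between + length(cols) * (mk - gm)^2
        within <- within +
            rowSums((mat[, cols, drop = FALSE] - mk)^2)
    }
    s <- sqrt(within / (N - K))
    if (is.null(s0)) s0 <- stats::median(s)
    d <- sqrt(between / (K - 1)) / (s + s0)
    attr(d, "s") <- s; attr(d, "s0") <- s0
    d
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up FDR adjustment, offered as the secondary q estimator next to
#' the SAM permutation FDR.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-stage differential testing between two genotypes
#'
#' For every stage, contrasts the second genotype against the first:
#' signed fold change, SAM d, permutation q, and the selection gate
#' q < \code{qCut} AND |linear FC| >= \code{fcCut}.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param qCut q-value cutoff (default 0.05).
#' @param fcCut linear fold-change cutoff, inclusive (default 2).
#' @param s0,nPerm,seed passed to [permutationFdr()].
#' @return named list, stage -> data.frame(gene, log2fc, fc, d, q,
#'   selected).
#' @export
runDifferential <- function(x, qCut = 0.05, fcCut = 2, s0 = NULL,
                            nPerm = "all", seed = 1) {
    m <- SummarizedExperiment::assay(x, "log2")
    cd <- as.data.frame(sampleInfo(x))
    genos <- unique(cd$genotype)
    stopIfNot(length(genos) == 2L,
              "exactly two genotypes are required for the contrasts")
    out <- list()
    for (st in unique(cd$stage)) {
        colsA <- which(cd$genotype == genos[1] & cd$stage == st)
        colsB <- which(cd$genotype == genos[2] & cd$stage == st)
        fc <- foldChange(m, colsA, colsB)
        pq <- permutationFdr(m, colsA, colsB, s0 = s0, nPerm = nPerm,
                             seed = seed)
        res <- data.frame(gene = fc$gene, log2fc = fc$log2fc, fc = fc$fc,
                          d = pq$d, q = pq$q, stringsAsFactors = FALSE)
        res$selected <- res$q < qCut & abs(res$fc) >= fcCut
        out[[st]] <- res
    }
    out
}

#' Select differentially expressed genes
#'
#' The published gate: q < 0.05 and |linear fold change| >= 2, with the
#' fold-change bound inclusive.  Returns up- and down-regulated gene lists
#' with their counts.
#'
#' @param res a per-contrast data.frame from [runDifferential()].
#' @param qCut,fcCut the two gates.
#' @return list with \code{up}, \code{down}, \code{counts}.
#' @export
selectDeg <- function(res, qCut = 0.05, fcCut = 2) {
    up <- res$gene[res$q < qCut & res$fc >= fcCut]
    down <- res$gene[res$q < qCut & res$fc <= -fcCut]
    list(up = up, down = down,
         counts = c(up = length(up), down = length(down)))
}
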