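#' @include AllClasses.R utils.R
NULL

#' Replicate-averaged expression over (genotype, stage) cells
#'
#' Averages the log2 values of the biological replicates within every
#' (genotype, stage) cell, and separately averages the linear-scale values
#' \code{2^log2} (the quantity the low-expression filter inspects).
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param genotypes optional subset of genotypes (e.g. the wild-type-only
#'   run); default all.
#' @return numeric matrix, genes x cells (log2 means), with a
#'   \code{linear} attribute holding the linear-scale means.
#' @export
replicateAverage <- function(x, genotypes = NULL) {
    m <- SummarizedExperiment::assay(x, "log2")
    cd <- as.data.frame(sampleInfo(x))
    if (!is.null(genotypes)) {
        keep <- cd$genotype %in% genotypes
        m <- m[, keep, drop = FALSE]; cd <- cd[keep, , drop = FALSE]
    }
    cells <- unique(cellOf(cd$genotype, cd$stage))
    avg <- lin <- matrix(NA_real_, nrow(m), length(cells),
                         dimnames = list(rownames(m), cells))
    for (cell in cells) {
        cols <- which(cellOf(cd$genotype, cd$stage) == cell)
        avg[, cell] <- rowMeans(m[, cols, drop = FALSE])
        lin[, cell] <- rowMeans(2^m[, cols, drop = FALSE])
    }
    attr(avg, "linear") <- lin
    avg
}

#' Remove probe sets with uniformly low expression
#'
#' Drops genes whose replicate-averaged linear-scale value is at or below
#' \code{threshold} in every (genotype, stage) cell; a gene exceeding the
#' threshold in even one cell is retained.  An empty result is allowed and
#' propagates cleanly.
#'
#' @param avg matrix from [replicateAverage()] (log2 means with the
#'   \code{linear} attribute).
#' @param threshold linear-scale cutoff, inclusive (default 30).
#' @return the filtered matrix, \code{linear} attribute subset to match.
#' @export
filterLowExpression <- function(avg, threshold = 30) {
    stopIfNot(threshold >= 0, "'threshold' must be non-negative")
    lin <- attr(avg, "linear")
    stopIfNot(!is.null(lin), "input must carry the 'linear' attribute")
    keep <- rowSums(lin > threshold) > 0
    out <- avg[keep, , drop = FALSE]
    attr(out, "linear") <- lin[keep, , drop = FALSE]
    out
}

# Kaufman-Rousseeuw fuzzy clustering objective:
#   sum_v (sum_ij u_iv^2 u_jv^2 d_ij) / (2 sum_j u_jv^2)
fkmObjective <- function(U, D) {
    X <- U^2
    M <- D %*% X
    sum(colSums(X * M) / (2 * colSums(X)))
}

#' Fuzzy K-means clustering of expression profiles (FANNY-style)
#'
#' Minimizes the Kaufman-Rousseeuw objective
#' \deqn{\sum_v \frac{\sum_{i,j} u_{iv}^2 u_{jv}^2 d_{ij}}{2 \sum_j u_{jv}^2}}
#' over membership rows on the simplex, with \code{d = 1 - Pearson}
#' between gene profiles, by the classic fixed-point membership update
#' (\code{u_iv} proportional to the reciprocal of the partial derivative of
#' the objective in \code{u_iv^2}).  A step-halving safeguard makes the
#' objective non-increasing across sweeps.  By default the first start is
#' seeded from an average-linkage cut of the dissimilarity (softened), with
#' further random Dirichlet starts; the best final objective wins.
#'
#' @param profiles numeric matrix, genes x cells, typically per-gene
#'   standardized; at least k rows.
#' @param k number of clusters (>= 2, or 1 for the degenerate case).
#' @param membExp membership exponent; only the classic value 2 is
#'   implemented.
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter sweep limit per start.
#' @param nStarts number of starts; the first three are deterministic
#'   hierarchical-cut seedings (average, Ward, complete linkage), further
#'   ones are random.
#' @param seed integer seed for the random starts.
#' @return A \linkS4class{FuzzyPartition}.
#' @export
fannyCluster <- function(profiles, k, membExp = 2, tol = 1e-8,
                         maxIter = 500L, nStarts = 3L, seed = 1) {
    n <- nrow(profiles)
    stopIfNot(k >= 1L, "'k' must be at least 1")
    stopIfNot(n >= k, "more clusters than genes requested")
    stopIfNot(membExp == 2, "only the classic membership exponent 2 is supported")
    if (k == 1L) {
        U <- matrix(1, n, 1, dimnames = list(rownames(profiles), "C01"))
        D <- 1 - stats::cor(t(profiles))
        return(new("FuzzyPartition", membership = U,
                   objective = fkmObjective(U, D), iterations = 0L,
                   converged = TRUE))
    }
    D <- 1 - stats::cor(t(profiles))
    diag(D) <- 0
    # deterministic seedings from hierarchical cuts under three linkages
    # (they partition tight groups differently, giving the fixed-point
    # iteration diverse basins), then random Dirichlet starts
    softInit <- function(cl) {
        U0 <- matrix(0.2 / k, n, k)
        U0[cbind(seq_len(n), cl)] <- U0[cbind(seq_len(n), cl)] + 0.8
        U0
    }
    linkages <- c("average", "ward.D2", "complete")
    starts <- vector("list", nStarts)
    for (s in seq_len(nStarts)) {
        starts[[s]] <- if (s <= length(linkages))
            softInit(stats::cutree(
                stats::hclust(stats::as.dist(D), linkages[s]), k))
        else withSeed(deriveSeed(seed, s), {
            g <- matrix(stats::rexp(n * k), n, k)
            g / rowSums(g)
        })
    }
    best <- NULL
    for (U in starts) {
        obj <- fkmObjective(U, D)
        it <- 0L; converged <- FALSE
        while (it < maxIter) {
            it <- it + 1L
            X <- U^2
            S <- colSums(X)
            M <- D %*% X                       # n x k
            numv <- colSums(X * M)
            E <- sweep(M, 2L, S, "/") -
                matrix(numv / (2 * S^2), n, k, byrow = TRUE)
            Unew <- matrix(0, n, k)
            pos <- E > 1e-12
            inv <- ifelse(pos, 1 / pmax(E, 1e-12), 0)
            badRows <- which(!apply(pos, 1L, all))
            okRows <- setdiff(seq_len(n), badRows)
            if (length(okRows))
                Unew[okRows, ] <- inv[okRows, , drop = FALSE] /
                    rowSums(inv[okRows, , drop = FALSE])
            for (i in badRows)                  # non-positive gradient: crisp
                Unew[i, which.min(E[i, ])] <- 1
            newObj <- fkmObjective(Unew, D)
            halvings <- 0L
            while (newObj > obj && halvings < 20L) {
                Unew <- (Unew + U) / 2
                newObj <- fkmObjective(Unew, D)
                halvings <- halvings + 1L
            }
            if (newObj > obj) { converged <- TRUE; break }
            done <- (obj - newObj) <= tol * max(abs(obj), 1e-12)
            U <- Unew; obj <- newObj
            if (done) { converged <- TRUE; break }
        }
        if (is.null(best) || obj < best$obj)
            best <- list(U = U, obj = obj, it = it, conv = converged)
    }
    if (!best$conv)
        warning("fuzzy clustering did not converge within ", maxIter,
                " sweeps")
    dimnames(best$U) <- list(rownames(profiles),
                             sprintf("C%02d", seq_len(k)))
    new("FuzzyPartition", membership = best$U, objective = best$obj,
        iterations = best$it, converged = best$conv)
}

#' Core genes and cluster prototypes
#'
#' A gene is a core member of cluster v when its membership there is at
#' least \code{m} AND v is its maximum-membership cluster (ties broken to
#' the lowest cluster index).  Each cluster's prototype is the mean of its
#' core genes' standardized profiles; clusters with an empty core are
#' dropped with a warning.
#'
#' @param partition a \linkS4class{FuzzyPartition}.
#' @param profiles the standardized profiles the partition was fit on.
#' @param m minimum core membership (default 0.44).
#' @return list with \code{prototypes} (clusters x cells), \code{cores}
#'   (cluster -> gene ids) and \code{sizes}.
#' @export
coreGenes <- function(partition, profiles, m = 0.44) {
    U <- membership(partition)
    top <- apply(U, 1L, which.max)             # ties: lowest index
    cores <- lapply(seq_len(ncol(U)), function(v)
        rownames(U)[top == v & U[, v] >= m])
    names(cores) <- colnames(U)
    empty <- lengths(cores) == 0L
    if (all(empty))
        stop("every cluster has an empty core; lower 'm'", call. = FALSE)
    if (any(empty))
        warning(sum(empty), " cluster(s) with no core genes dropped")
    cores <- cores[!empty]
    protos <- t(vapply(cores, function(g)
        colMeans(profiles[g, , drop = FALSE]), numeric(ncol(profiles))))
    list(prototypes = protos, cores = cores, sizes = lengths(cores))
}

#' Merge similar cluster prototypes into dominant patterns
#'
#' Repeatedly merges the pair of prototypes with the highest Pearson
#' correlation while that correlation is at least \code{mergeR}; a merged
#' prototype is the size-weighted mean of its members, and the provenance
#' (which raw clusters each pattern absorbed) is recorded.  Ties go to the
#' lowest index pair.
#'
#' @param prototypes matrix, clusters x cells.
#' @param sizes core sizes used as merge weights (default 1 each).
#' @param mergeR merge threshold on Pearson r (default 0.90).
#' @return list with \code{prototypes} (patterns x cells, renamed
#'   DP01...), \code{provenance} and \code{sizes}.
#' @export
mergeClusters <- function(prototypes, sizes = NULL, mergeR = 0.90) {
    stopIfNot(nrow(prototypes) >= 1L, "at least one prototype is required")
    if (is.null(sizes)) sizes <- rep(1, nrow(prototypes))
    protos <- prototypes
    prov <- as.list(rownames(prototypes))
    w <- sizes
    while (nrow(protos) > 1L) {
        cc <- stats::cor(t(protos))
        cc[lower.tri(cc, diag = TRUE)] <- -Inf
        top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
        if (cc[top[1], top[2]] < mergeR) break
        i <- top[1]; j <- top[2]
        merged <- (w[i] * protos[i, ] + w[j] * protos[j, ]) / (w[i] + w[j])
        prov[[i]] <- c(prov[[i]], prov[[j]])
        protos[i, ] <- merged
        w[i] <- w[i] + w[j]
        protos <- protos[-j, , drop = FALSE]
        prov <- prov[-j]; w <- w[-j]
    }
    ids <- sprintf("DP%02d", seq_len(nrow(protos)))
    rownames(protos) <- ids
    names(prov) <- ids
    list(prototypes = protos, provenance = prov,
         sizes = setNames(w, ids))
}

#' Correlation-gated assignment of genes to pattern prototypes
#'
#' Each gene goes to its single best-correlated prototype provided that
#' correlation is at least \code{rMin} (default 0.85); otherwise it stays
#' unassigned.  Constant (zero-variance) profiles have undefined
#' correlation and are flagged.
#'
#' @param profiles matrix, genes x cells (standardized or raw; Pearson is
#'   scale/shift invariant per gene).
#' @param prototypes matrix, patterns x cells.
#' @param rMin assignment gate on Pearson r, inclusive.
#' @return DataFrame with gene, pattern (NA if unassigned), r, flag.
#' @export
assignGenes <- function(profiles, prototypes, rMin = 0.85) {
    stopIfNot(ncol(profiles) == ncol(prototypes),
              "profiles and prototypes must share the same ordered cells")
    sdG <- apply(profiles, 1L, stats::sd)
    sdP <- apply(prototypes, 1L, stats::sd)
    stopIfNot(all(sdP > 0), "prototypes must not be constant")
    flat <- sdG == 0
    pattern <- rep(NA_character_, nrow(profiles))
    rBest <- rep(NA_real_, nrow(profiles))
    if (any(!flat)) {
        cc <- stats::cor(t(profiles[!flat, , drop = FALSE]), t(prototypes))
        bestIdx <- apply(cc, 1L, which.max)
        bestR <- cc[cbind(seq_len(nrow(cc)), bestIdx)]
        hit <- bestR >= rMin
        pat <- ifelse(hit, rownames(prototypes)[bestIdx], NA_character_)
        pattern[!flat] <- pat
        rBest[!flat] <- bestR
    }
    DataFrame(gene = rownames(profiles), pattern = unname(pattern),
              r = unname(rBest),
              flag = unname(ifelse(flat, "undefined correlation", "")))
}

#' The dominant-pattern procedure, end to end
#'
#' Replicate-averages the expression matrix, removes uniformly
#' low-expressed genes (linear value <= \code{filterThreshold} in every
#' cell), per-gene standardizes the profiles, clusters them with
#' [fannyCluster()] (k = 15 by default), forms core-gene prototypes at
#' membership \code{m}, merges similar prototypes, and assigns every
#' filtered gene to its best prototype at Pearson r >= \code{rMin}.
#' Zero-variance profiles are excluded from clustering and flagged
#' unassigned.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param genotypes optional genotype subset (wild-type-only run).
#' @param filterThreshold,k,m,mergeR,rMin the procedure's thresholds.
#' @param nStarts,seed clustering start controls.
#' @return A \linkS4class{DominantPatternSet}.
#' @export
dominantPatterns <- function(x, genotypes = NULL, filterThreshold = 30,
                             k = 15L, m = 0.44, mergeR = 0.90, rMin = 0.85,
                             nStarts = 3L, seed = 1) {
    avg <- replicateAverage(x, genotypes = genotypes)
    avg <- filterLowExpression(avg, threshold = filterThreshold)
    if (nrow(avg) == 0L)
        return(new("DominantPatternSet",
                   prototypes = matrix(numeric(), 0, ncol(avg),
                                       dimnames = list(NULL, colnames(avg))),
                   assignments = DataFrame(gene = character(),
                                           pattern = character(),
                                           r = numeric(), flag = character()),
                   provenance = list(), minCorrelation = rMin))
    z <- standardizeRows(avg)
    flat <- attr(z, "flat")
    zUse <- z[!flat, , drop = FALSE]
    kUse <- min(k, nrow(zUse))
    part <- fannyCluster(zUse, k = kUse, nStarts = nStarts, seed = seed)
    cg <- coreGenes(part, zUse, m = m)
    mg <- mergeClusters(cg$prototypes, sizes = cg$sizes, mergeR = mergeR)
    asn <- assignGenes(z, mg$prototypes, rMin = rMin)
    new("DominantPatternSet", prototypes = mg$prototypes,
        assignments = asn, provenance = mg$provenance,
        minCorrelation = rMin)
}

#' Long-format prototype table for bar plots
#'
#' One row per (pattern, cell), mirroring the usual dominant-pattern bar
#' figures.
#'
#' @param dps a \linkS4class{DominantPatternSet}.
#' @return data.frame with pattern, cell, value.
#' @export
prototypeLongFormat <- function(dps) {
    p <- prototypes(dps)
    data.frame(pattern = rep(rownames(p), ncol(p)),
               cell = rep(colnames(p), each = nrow(p)),
               value = as.vector(p), stringsAsFactors = FALSE)
}
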