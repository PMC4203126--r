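#' @include AllClasses.R utils.R
NULL

#' Upper-tail hypergeometric test
#'
#' \code{p = P(X >= k)} for \code{X ~ Hypergeom(N, K, n)}: drawing
#' \code{n} genes from a background of \code{N} of which \code{K} carry
#' the annotation, and observing \code{k} carriers.  Evaluated through the
#' log-space distribution function for numerical stability.
#'
#' @param k hits inside the gene set.
#' @param K hits in the background.
#' @param n gene-set size.
#' @param N background size.
#' @return the upper-tail probability, in (0, 1].
#' @examples
#' hypergeometricTest(3, 5, 5, 20)  # ~0.07262
#' @export
hypergeometricTest <- function(k, K, n, N) {
    ok <- K >= 0 & n >= 0 & K <= N & n <= N & k >= 0 & k <= pmin(n, K)
    if (!all(ok))
        stop(sprintf("inconsistent counts: k=%s K=%s n=%s N=%s",
                     paste(k[!ok], collapse = ","),
                     paste(K[!ok], collapse = ","),
                     paste(n[!ok], collapse = ","),
                     paste(N[!ok], collapse = ",")), call. = FALSE)
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' GO-term over-representation in a gene set
#'
#' One upper-tail hypergeometric test per GMT term with at least one
#' background member; the \code{enriched} flag applies the raw
#' \code{p < pCut} rule (default 0.001), and BH-adjusted p-values are
#' reported alongside.  Gene-set members absent from the background are
#' dropped with a warning.
#'
#' @param geneSet character vector of genes.
#' @param gmt named list, term -> member genes (see [readGmt()]).
#' @param background character vector, the gene universe (all genes on the
#'   array).
#' @param pCut raw-p enrichment threshold.
#' @return data.frame with term, description, k, K, n, N, p, p_adjusted,
#'   enriched.
#' @export
goEnrichment <- function(geneSet, gmt, background, pCut = 0.001) {
    geneSet <- unique(geneSet)
    missing <- setdiff(geneSet, background)
    if (length(missing)) {
        warning(length(missing),
                " gene(s) not in the background were dropped")
        geneSet <- intersect(geneSet, background)
    }
    if (length(geneSet) == 0L || length(gmt) == 0L)
        return(data.frame(term = character(), description = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(),
                          p_adjusted = numeric(), enriched = logical()))
    descr <- attr(gmt, "descriptions")
    N <- length(unique(background))
    n <- length(geneSet)
    rows <- lapply(names(gmt), function(tid) {
        members <- intersect(gmt[[tid]], background)
        K <- length(members)
        if (K == 0L) return(NULL)
        k <- length(intersect(geneSet, members))
        data.frame(term = tid,
                   description = if (!is.null(descr)) descr[[tid]] else NA,
                   k = k, K = K, n = n, N = N,
                   p = hypergeometricTest(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(goEnrichment(character(), list(), background))
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$enriched <- out$p < pCut
    rownames(out) <- NULL
    out
}

# exact IUPAC consensus hits on both strands of a promoter set; a match of
# the reverse complement is counted at its forward-strand position.  An N
# in a promoter never supports a match: candidate windows overlapping an N
# are discarded.
countMotifHits <- function(promoters, motif) {
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif))
        stop("invalid IUPAC motif: ", motif, call. = FALSE)
    rcm <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    fx <- c(pattern = FALSE, subject = TRUE)
    hasN <- Biostrings::alphabetFrequency(promoters)[, "N"] > 0
    counts <- as.integer(
        Biostrings::vcountPattern(motif, promoters, fixed = fx) +
        Biostrings::vcountPattern(rcm, promoters, fixed = fx))
    for (i in which(hasN)) {
        nPos <- Biostrings::start(
            Biostrings::matchPattern("N", promoters[[i]], fixed = TRUE))
        tally <- 0L
        for (pat in c(motif, rcm)) {
            hits <- Biostrings::matchPattern(pat, promoters[[i]],
                                             fixed = fx)
            keep <- vapply(seq_along(hits), function(j)
                !any(nPos >= Biostrings::start(hits)[j] &
                     nPos <= Biostrings::end(hits)[j]), logical(1))
            tally <- tally + sum(keep)
        }
        counts[i] <- tally
    }
    counts
}

#' Scan promoters for an IUPAC consensus motif
#'
#' Counts exact degenerate-consensus matches on both strands; a
#' palindromic motif is counted once per strand, i.e. twice per physical
#' site.  \code{N} in a promoter never matches.
#'
#' @param promoters a \code{DNAStringSet} (names = gene ids) or a named
#'   character vector of sequences.
#' @param motif IUPAC consensus string.
#' @return named integer vector of per-gene hit counts.
#' @examples
#' scanPromoters(c(g1 = "ATGCATG"), "ATG")  # 3: two forward + one reverse
#' @export
scanPromoters <- function(promoters, motif) {
    if (!methods::is(promoters, "DNAStringSet"))
        promoters <- Biostrings::DNAStringSet(promoters)
    setNames(countMotifHits(promoters, motif), names(promoters))
}

#' Promoter-motif over-representation in a gene set
#'
#' A gene is a motif hit when its promoter carries at least one exact
#' consensus match on either strand; each motif is then tested by the
#' upper-tail hypergeometric exactly as in [goEnrichment()].  Genes
#' without a promoter sequence are excluded from both the background and
#' the set, with a warning.
#'
#' @param geneSet character vector of genes.
#' @param promoters \code{DNAStringSet}, one per background gene.
#' @param motifTable data.frame with motif_id, consensus.
#' @param background the gene universe.
#' @param pCut raw-p enrichment threshold (default 0.001).
#' @return data.frame with motif_id, consensus, k, K, n, N, p,
#'   p_adjusted, enriched, plus a \code{hitGenes} attribute (motif ->
#'   genes in the set with >= 1 hit).
#' @export
motifEnrichment <- function(geneSet, promoters, motifTable, background,
                            pCut = 0.001) {
    geneSet <- unique(geneSet)
    noProm <- setdiff(background, names(promoters))
    if (length(noProm)) {
        warning(length(noProm),
                " background gene(s) without a promoter excluded")
        background <- setdiff(background, noProm)
        geneSet <- intersect(geneSet, background)
    }
    if (nrow(motifTable) == 0L) {
        out <- data.frame(motif_id = character(), consensus = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(),
                          p_adjusted = numeric(), enriched = logical())
        attr(out, "hitGenes") <- list()
        return(out)
    }
    proms <- promoters[background]
    N <- length(background)
    n <- length(geneSet)
    hitGenes <- list()
    rows <- lapply(seq_len(nrow(motifTable)), function(i) {
        counts <- countMotifHits(proms, motifTable$consensus[i])
        hit <- background[counts >= 1L]
        hitGenes[[motifTable$motif_id[i]]] <<- intersect(geneSet, hit)
        K <- length(hit)
        k <- length(intersect(geneSet, hit))
        data.frame(motif_id = motifTable$motif_id[i],
                   consensus = motifTable$consensus[i],
                   k = k, K = K, n = n, N = N,
                   p = hypergeometricTest(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$enriched <- out$p < pCut
    rownames(out) <- NULL
    attr(out, "hitGenes") <- hitGenes
    out
}

#' Heatmap-ready -log10(p) matrix
#'
#' Stacks several enrichment results (e.g. one per dominant pattern or per
#' contrast) into a terms x gene-sets matrix of -log10 p-values.
#'
#' @param results named list of data.frames from [goEnrichment()] or
#'   [motifEnrichment()].
#' @return numeric matrix, terms x gene sets.
#' @export
minusLog10Matrix <- function(results) {
    keyCol <- function(df) if ("term" %in% colnames(df)) df$term else df$motif_id
    terms <- sort(unique(unlist(lapply(results, keyCol))))
    out <- matrix(0, length(terms), length(results),
                  dimnames = list(terms, names(results)))
    for (s in names(results)) {
        df <- results[[s]]
        out[keyCol(df), s] <- -log10(df$p)
    }
    out
}
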