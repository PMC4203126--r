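#' @include AllClasses.R utils.R
NULL

#' Probe-pair discrimination scores
#'
#' \code{R_i = (PM_i - MM_i) / (PM_i + MM_i)}, one score per probe pair,
#' each in [-1, 1].  Pairs with \code{PM + MM = 0} are dropped with a
#' warning.
#'
#' @param pmVals,mmVals numeric vectors of PM and MM intensities.
#' @return numeric vector of scores.
#' @examples
#' discriminationScores(c(30, 10), c(10, 30))  # 0.5, -0.5
#' @export
discriminationScores <- function(pmVals, mmVals) {
    tot <- pmVals + mmVals
    bad <- tot == 0
    if (any(bad)) {
        warning(sum(bad), " probe pair(s) with PM + MM = 0 dropped")
        pmVals <- pmVals[!bad]; mmVals <- mmVals[!bad]; tot <- tot[!bad]
    }
    (pmVals - mmVals) / tot
}

# Exact one-sided Wilcoxon signed-rank p-value P(W >= w_obs) under random
# signs, handling ties through midranks: a dynamic-programming convolution
# over doubled (integer) ranks.  Used for n <= exactLimit; beyond that a
# tie-corrected normal approximation with continuity correction.
signedRankP <- function(d, exactLimit = 25L) {
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(1)
    rk <- rank(abs(d))
    w <- sum(rk[d > 0])
    if (n <= exactLimit) {
        r2 <- as.integer(round(2 * rk))
        tot <- sum(r2)
        # coef[s + 1] = number of sign assignments with doubled rank sum s
        coef <- numeric(tot + 1L)
        coef[1L] <- 1
        for (r in r2) {
            shifted <- c(numeric(r), coef[seq_len(tot + 1L - r)])
            coef <- coef + shifted
        }
        w2 <- round(2 * w)
        sum(coef[(w2 + 1L):(tot + 1L)]) / 2^n
    } else {
        mu <- sum(rk) / 2
        sigma <- sqrt(sum(rk^2) / 4)
        stats::pnorm((w - 0.5 - mu) / sigma, lower.tail = FALSE)
    }
}

#' Detection call from discrimination scores
#'
#' One-sided exact Wilcoxon signed-rank test of whether the median
#' discrimination score exceeds \code{tau}; the p-value is cut at
#' \code{alpha1}/\code{alpha2} into Present / Marginal / Absent.  Scores
#' equal to \code{tau} are dropped (the usual zero-difference convention),
#' and when every score ties with \code{tau} the p-value is 1 and the call
#' is Absent.
#'
#' @param scores numeric vector of discrimination scores (>= 3).
#' @param tau score threshold (default 0.015).
#' @param alpha1,alpha2 p-value cutoffs, 0 < alpha1 < alpha2 < 0.5.
#' @return list with \code{p} and \code{call} ("P", "M" or "A").
#' @examples
#' detectionCall(rep(1 / 3, 11))  # p = 2^-11, Present
#' @export
detectionCall <- function(scores, tau = 0.015, alpha1 = 0.04,
                          alpha2 = 0.06) {
    stopIfNot(length(scores) >= 3L, "at least 3 scores are required")
    stopIfNot(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 0.5,
              "need 0 < alpha1 < alpha2 < 0.5")
    p <- signedRankP(scores - tau)
    call <- if (p < alpha1) "P" else if (p < alpha2) "M" else "A"
    list(p = p, call = call)
}

#' Detection calls for every gene on every array
#'
#' Applies [discriminationScores()] and [detectionCall()] per probe set and
#' array, then forms the per-tissue consensus with [consensusPresent()].
#'
#' @param probes a \linkS4class{ProbeIntensities}.
#' @param tau,alpha1,alpha2 as in [detectionCall()].
#' @return A \linkS4class{DetectionCalls}.
#' @export
detectionCalls <- function(probes, tau = 0.015, alpha1 = 0.04,
                           alpha2 = 0.06) {
    sets <- unique(probes@probeSet)
    idx <- split(seq_along(probes@probeSet), probes@probeSet)
    nS <- ncol(pm(probes))
    calls <- matrix("A", length(sets), nS,
                    dimnames = list(sets, colnames(pm(probes))))
    pvals <- matrix(1, length(sets), nS, dimnames = dimnames(calls))
    for (s in sets) {
        pmSub <- pm(probes)[idx[[s]], , drop = FALSE]
        mmSub <- mm(probes)[idx[[s]], , drop = FALSE]
        for (j in seq_len(nS)) {
            r <- discriminationScores(pmSub[, j], mmSub[, j])
            dc <- detectionCall(r, tau, alpha1, alpha2)
            calls[s, j] <- dc$call
            pvals[s, j] <- dc$p
        }
    }
    cons <- consensusPresent(calls, sampleInfo(probes))
    new("DetectionCalls", calls = calls, pvalues = pvals, consensus = cons)
}

#' Replicate-consensus presence
#'
#' A gene is detected in a (genotype, stage) tissue only when it is called
#' 'P' in both biological replicates of that tissue (the boolean AND over
#' replicates; tissues with a missing replicate are skipped with a
#' warning).
#'
#' @param calls character matrix of P/M/A calls, genes x samples.
#' @param samples DataFrame with sample_id, genotype, stage, replicate.
#' @return logical matrix, genes x tissue cells, with a
#'   \code{detectedCounts} attribute giving the per-tissue detected-gene
#'   count.
#' @export
consensusPresent <- function(calls, samples) {
    cd <- as.data.frame(samples)
    cells <- unique(cellOf(cd$genotype, cd$stage))
    cons <- matrix(NA, nrow(calls), length(cells),
                   dimnames = list(rownames(calls), cells))
    for (cell in cells) {
        cols <- which(cellOf(cd$genotype, cd$stage) == cell)
        if (length(cols) < 2L) {
            warning("tissue ", cell, " lacks two replicates; skipped")
            next
        }
        cons[, cell] <- rowSums(calls[, cols, drop = FALSE] == "P") ==
            length(cols)
    }
    keep <- colSums(is.na(cons)) < nrow(cons)
    cons <- cons[, keep, drop = FALSE]
    attr(cons, "detectedCounts") <- colSums(cons)
    cons
}
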