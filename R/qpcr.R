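#' @include AllClasses.R utils.R
NULL

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (condition, gene); then
#' \code{dCt = Ct_target - Ct_reference} within each condition,
#' \code{ddCt = dCt_treated - dCt_calibrator}, and the relative expression
#' is \code{2^-ddCt}.  The replicate SD of dCt in the treated condition is
#' propagated into a fold range (\code{2^-(ddCt +/- sd)}), reported for
#' information.
#'
#' @param ct data.frame with columns sample, condition, gene, Ct (see
#'   [readCtTable()]).
#' @param target target gene id.
#' @param reference reference (normalizer) gene id; must be measured in
#'   every sample of both conditions.
#' @param treated,calibrator condition labels.
#' @return list with fold, ddCt, sd, fold_lo, fold_hi.
#' @examples
#' tab <- data.frame(sample = c("s1", "s1", "s2", "s2"),
#'                   condition = c("mut", "mut", "wt", "wt"),
#'                   gene = c("g", "ref", "g", "ref"),
#'                   Ct = c(20, 18, 22, 18))
#' ddct(tab, "g", "ref", "mut", "wt")$fold  # 4
#' @export
ddct <- function(ct, target, reference, treated, calibrator) {
    for (cond in c(treated, calibrator)) {
        sub <- ct[ct$condition == cond, , drop = FALSE]
        samples <- unique(sub$sample)
        noRef <- samples[!samples %in% sub$sample[sub$gene == reference]]
        if (length(noRef))
            stop("reference gene '", reference, "' missing in sample(s): ",
                 paste(noRef, collapse = ", "), call. = FALSE)
        if (!target %in% sub$gene)
            stop("target gene '", target, "' not measured in condition '",
                 cond, "'", call. = FALSE)
    }
    meanCt <- function(cond, gene)
        mean(ct$Ct[ct$condition == cond & ct$gene == gene])
    dctPerSample <- function(cond) {
        sub <- ct[ct$condition == cond, , drop = FALSE]
        vapply(unique(sub$sample), function(s)
            sub$Ct[sub$sample == s & sub$gene == target] -
                sub$Ct[sub$sample == s & sub$gene == reference],
            numeric(1))
    }
    dTreated <- meanCt(treated, target) - meanCt(treated, reference)
    dCal <- meanCt(calibrator, target) - meanCt(calibrator, reference)
    dd <- dTreated - dCal
    sdT <- stats::sd(dctPerSample(treated))
    if (is.na(sdT)) sdT <- 0
    list(fold = 2^-dd, ddCt = dd, sd = sdT,
         fold_lo = 2^-(dd + sdT), fold_hi = 2^-(dd - sdT))
}

#' 2^-ddCt for a panel of targets
#'
#' @param ct Ct table as in [ddct()].
#' @param targets character vector of target genes.
#' @param reference,treated,calibrator as in [ddct()].
#' @return data.frame with gene, condition, fold, sd (CSV-ready).
#' @export
ddctTable <- function(ct, targets, reference, treated, calibrator) {
    rows <- lapply(targets, function(g) {
        r <- ddct(ct, g, reference, treated, calibrator)
        data.frame(gene = g, condition = treated, fold = r$fold,
                   sd = r$sd, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
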