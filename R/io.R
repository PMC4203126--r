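#' @include AllClasses.R utils.R
NULL

#' Build an ExpressionMatrix from a log2 value matrix and sample sheet
#'
#' @param log2Values numeric matrix, genes x samples, finite log2 values.
#' @param samples DataFrame/data.frame with sample_id, genotype, stage,
#'   replicate; rows aligned with the matrix columns.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
newExpressionMatrix <- function(log2Values, samples) {
    samples <- DataFrame(samples)
    if (is.null(colnames(log2Values)))
        colnames(log2Values) <- samples$sample_id
    rownames(samples) <- samples$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = log2Values), colData = samples)
    new("ExpressionMatrix", se)
}

#' Read / write the tab-delimited probe-level table
#'
#' Long format with columns probe_set_id, probe_index, sample_id, PM, MM;
#' the sample sheet supplies the array annotation.
#'
#' @param probes a \linkS4class{ProbeIntensities} (for writing).
#' @param path TSV file.
#' @param sampleSheetPath CSV file with sample_id, genotype, stage,
#'   replicate (for reading).
#' @return `readProbeTable`: a \linkS4class{ProbeIntensities};
#'   `writeProbeTable`: `path`, invisibly.
#' @name probe-io
NULL

#' @rdname probe-io
#' @export
writeProbeTable <- function(probes, path, sampleSheetPath = NULL) {
    idx <- as.integer(stats::ave(seq_along(probes@probeSet),
                                 probes@probeSet, FUN = seq_along))
    long <- data.frame(
        probe_set_id = rep(probes@probeSet, ncol(probes@pm)),
        probe_index = rep(idx, ncol(probes@pm)),
        sample_id = rep(probes@sampleData$sample_id, each = nrow(probes@pm)),
        PM = as.vector(probes@pm), MM = as.vector(probes@mm))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sampleSheetPath))
        utils::write.csv(as.data.frame(probes@sampleData), sampleSheetPath,
                         row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname probe-io
#' @export
readProbeTable <- function(path, sampleSheetPath) {
    long <- utils::read.delim(path, stringsAsFactors = FALSE)
    sheet <- DataFrame(utils::read.csv(sampleSheetPath,
                                       stringsAsFactors = FALSE))
    key <- paste(long$probe_set_id, long$probe_index, sep = "_p")
    rows <- unique(key)
    cols <- sheet$sample_id
    pmM <- matrix(NA_real_, length(rows), length(cols),
                  dimnames = list(rows, cols))
    mmM <- pmM
    i <- cbind(match(key, rows), match(long$sample_id, cols))
    pmM[i] <- long$PM
    mmM[i] <- long$MM
    new("ProbeIntensities", pm = pmM, mm = mmM,
        probeSet = sub("_p[0-9]+$", "", rows), sampleData = sheet)
}

#' Read / write a gene-level expression matrix TSV
#'
#' Genes in rows (first column \code{gene}), samples in columns.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path TSV file.
#' @param sampleSheetPath CSV file with the sample annotation.
#' @return `readExpressionMatrix`: an \linkS4class{ExpressionMatrix}.
#' @name expression-io
NULL

#' @rdname expression-io
#' @export
writeExpressionMatrix <- function(x, path, sampleSheetPath = NULL) {
    m <- SummarizedExperiment::assay(x, "log2")
    out <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sampleSheetPath))
        utils::write.csv(as.data.frame(sampleInfo(x)), sampleSheetPath,
                         row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname expression-io
#' @export
readExpressionMatrix <- function(path, sampleSheetPath) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$gene
    sheet <- utils::read.csv(sampleSheetPath, stringsAsFactors = FALSE)
    newExpressionMatrix(m[, sheet$sample_id, drop = FALSE], sheet)
}

#' Read / write GMT gene-set files
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated.
#'
#' @param gmt named list, term id -> character vector of genes; an optional
#'   \code{descriptions} attribute (named character) supplies column 2.
#' @param path GMT file.
#' @return `readGmt`: a named list with a \code{descriptions} attribute.
#' @name gmt-io
NULL

#' @rdname gmt-io
#' @export
writeGmt <- function(gmt, path) {
    descr <- attr(gmt, "descriptions")
    lines <- vapply(names(gmt), function(tid) {
        d <- if (!is.null(descr) && tid %in% names(descr)) descr[[tid]] else "NA"
        paste(c(tid, d, gmt[[tid]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname gmt-io
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    gmt <- lapply(parts, function(p) p[-(1:2)])
    names(gmt) <- vapply(parts, `[`, character(1), 1L)
    attr(gmt, "descriptions") <- setNames(
        vapply(parts, `[`, character(1), 2L), names(gmt))
    gmt
}

#' Read a motif table / TF map TSV
#'
#' The motif table has columns motif_id and consensus (IUPAC); the TF map
#' has columns tf_gene_id and motif_id.
#'
#' @param path TSV file.
#' @return data.frame.
#' @name motif-io
NULL

#' @rdname motif-io
#' @export
readMotifTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopIfNot(all(c("motif_id", "consensus") %in% colnames(tab)),
              "motif table needs columns motif_id, consensus")
    tab
}

#' @rdname motif-io
#' @export
readTfMap <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopIfNot(all(c("tf_gene_id", "motif_id") %in% colnames(tab)),
              "TF map needs columns tf_gene_id, motif_id")
    tab
}

#' Read a qPCR Ct table CSV
#'
#' Columns sample, condition, gene, Ct; every (sample, gene) pair must be
#' unique.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopIfNot(all(c("sample", "condition", "gene", "Ct") %in% colnames(tab)),
              "Ct table needs columns sample, condition, gene, Ct")
    if (anyDuplicated(tab[, c("sample", "gene")]))
        stop("duplicate (sample, gene) measurements in Ct table",
             call. = FALSE)
    tab
}
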