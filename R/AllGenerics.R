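#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{pm}/\code{mm} return the probe-level intensity matrices,
#' \code{probeSets} the probe -> probe-set map, \code{sampleInfo} the array
#' annotation, \code{membership} the fuzzy membership matrix,
#' \code{prototypes} and \code{assignments} the dominant-pattern results,
#' \code{detectionMatrix} and \code{consensusMatrix} the P/M/A calls and
#' the two-replicate consensus, \code{moduleNodes}/\code{moduleEdges} the
#' typed graph tables, and \code{supportValues} the bootstrap proportions.
#'
#' @param x an object of the matching class.
#' @return The slot contents described above.
#' @name accessors
#' @aliases pm mm probeSets sampleInfo membership prototypes assignments
#'   detectionMatrix consensusMatrix moduleNodes moduleEdges supportValues
NULL

#' @rdname accessors
#' @export
setGeneric("pm", function(x) standardGeneric("pm"))
#' @rdname accessors
#' @export
setGeneric("mm", function(x) standardGeneric("mm"))
#' @rdname accessors
#' @export
setGeneric("probeSets", function(x) standardGeneric("probeSets"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("detectionMatrix", function(x) standardGeneric("detectionMatrix"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("moduleNodes", function(x) standardGeneric("moduleNodes"))
#' @rdname accessors
#' @export
setGeneric("moduleEdges", function(x) standardGeneric("moduleEdges"))
#' @rdname accessors
#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))

#' @rdname accessors
setMethod("pm", "ProbeIntensities", function(x) x@pm)
#' @rdname accessors
setMethod("mm", "ProbeIntensities", function(x) x@mm)
#' @rdname accessors
setMethod("probeSets", "ProbeIntensities", function(x) x@probeSet)
#' @rdname accessors
setMethod("sampleInfo", "ProbeIntensities", function(x) x@sampleData)
#' @rdname accessors
setMethod("sampleInfo", "ExpressionMatrix",
    function(x) SummarizedExperiment::colData(x))
#' @rdname accessors
setMethod("membership", "FuzzyPartition", function(x) x@membership)
#' @rdname accessors
setMethod("prototypes", "DominantPatternSet", function(x) x@prototypes)
#' @rdname accessors
setMethod("assignments", "DominantPatternSet", function(x) x@assignments)
#' @rdname accessors
setMethod("detectionMatrix", "DetectionCalls", function(x) x@calls)
#' @rdname accessors
setMethod("consensusMatrix", "DetectionCalls", function(x) x@consensus)
#' @rdname accessors
setMethod("moduleNodes", "ModuleGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("moduleEdges", "ModuleGraph", function(x) x@edges)
#' @rdname accessors
setMethod("supportValues", "BootstrapDendrogram", function(x) x@support)

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", length(object@genotypes), "genotype(s) x",
        length(object@stages), "stage(s) x", object@replicates,
        "replicate(s) =",
        length(object@genotypes) * length(object@stages) * object@replicates,
        "arrays\n")
    cat("  genotypes:", paste(object@genotypes, collapse = ", "), "\n")
    cat("  stages:   ", paste(object@stages, collapse = " -> "), "\n")
    cat("  genes:", object@nGenes, "| probe pairs per set:", object@nProbes,
        "\n")
})

setMethod("show", "ProbeIntensities", function(object) {
    cat("ProbeIntensities:", nrow(object@pm), "probes in",
        length(unique(object@probeSet)), "probe sets x",
        ncol(object@pm), "arrays\n")
})

setMethod("show", "FuzzyPartition", function(object) {
    cat("FuzzyPartition:", nrow(object@membership), "genes x",
        ncol(object@membership), "clusters; objective",
        format(object@objective, digits = 6), "after",
        object@iterations, "sweeps",
        if (object@converged) "(converged)\n" else "(NOT converged)\n")
})

setMethod("show", "DominantPatternSet", function(object) {
    n_as <- sum(!is.na(object@assignments$pattern))
    cat("DominantPatternSet:", nrow(object@prototypes), "patterns over",
        ncol(object@prototypes), "cells;", n_as, "of",
        nrow(object@assignments), "genes assigned (r >=",
        object@minCorrelation, ")\n")
})

setMethod("show", "DetectionCalls", function(object) {
    cat("DetectionCalls:", nrow(object@calls), "genes x",
        ncol(object@calls), "arrays;",
        sum(object@calls == "P"), "P /", sum(object@calls == "M"), "M /",
        sum(object@calls == "A"), "A calls\n")
})

setMethod("show", "ModuleGraph", function(object) {
    tab <- table(factor(object@nodes$type,
                        levels = c("TF", "motif", "GO_term", "gene")))
    cat("ModuleGraph:", nrow(object@nodes), "nodes (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ") and",
        nrow(object@edges), "edges\n")
})

setMethod("show", "BootstrapDendrogram", function(object) {
    cat("BootstrapDendrogram over", length(object@hclust$labels),
        "samples;", object@nBoot, "bootstrap replicates; support range",
        paste(range(round(object@support, 1)), collapse = "-"), "%\n")
})
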