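#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Study design for a two-genotype, multi-stage array experiment
#'
#' Describes the factorial layout of the experiment: genotypes crossed with
#' an ordered developmental stage series, with a fixed number of biological
#' replicates per (genotype, stage) cell.  The default layout is the
#' 16-array somatic-embryogenesis design: wild type and an ascorbate-deficient
#' mutant (\code{vtc2}) sampled at the bent-cotyledon zygotic embryo stage,
#' 7 and 14 days of induction, and the mature somatic embryo stage, with two
#' biological replicates each.
#'
#' @slot genotypes character vector of genotype labels.
#' @slot stages character vector of stage labels, in developmental order.
#'   The order is shared by every profile definition downstream.
#' @slot replicates integer, biological replicates per (genotype, stage) cell.
#' @slot nGenes integer, number of probe sets ("genes") on the array.
#' @slot nProbes integer, PM/MM probe pairs per probe set.
#'
#' @seealso [studyDesign()], [sampleSheet()]
#' @exportClass StudyDesign
setClass("StudyDesign",
    representation(
        genotypes  = "character",
        stages     = "character",
        replicates = "integer",
        nGenes     = "integer",
        nProbes    = "integer"
    )
)

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (length(object@genotypes) < 1L || anyDuplicated(object@genotypes))
        msg <- c(msg, "genotypes must be a non-empty set of unique labels")
    if (length(object@stages) < 1L || anyDuplicated(object@stages))
        msg <- c(msg, "stages must be a non-empty set of unique labels")
    if (length(object@replicates) != 1L || is.na(object@replicates) ||
        object@replicates < 1L)
        msg <- c(msg, "replicates must be a positive integer")
    if (length(object@nGenes) != 1L || is.na(object@nGenes) ||
        object@nGenes < 1L)
        msg <- c(msg, "nGenes must be a positive integer")
    if (length(object@nProbes) != 1L || is.na(object@nProbes) ||
        object@nProbes < 1L)
        msg <- c(msg, "nProbes must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' Probe-level PM/MM intensities
#'
#' Holds perfect-match (PM) and mismatch (MM) intensities for every probe on
#' every array, grouped into probe sets.  Rows are probes, columns are
#' arrays; \code{probeSet} maps each row to its probe set and
#' \code{sampleData} carries the (genotype, stage, replicate) annotation of
#' each array.
#'
#' @slot pm numeric matrix, probes x arrays, perfect-match intensities.
#' @slot mm numeric matrix, same shape, mismatch intensities.
#' @slot probeSet character vector, probe-set id of each row.
#' @slot sampleData DataFrame with columns sample_id, genotype, stage,
#'   replicate; one row per array.
#'
#' @seealso [simulateProbeIntensities()], [summarizeProbeSets()],
#'   [detectionCalls()]
#' @exportClass ProbeIntensities
setClass("ProbeIntensities",
    representation(
        pm         = "matrix",
        mm         = "matrix",
        probeSet   = "character",
        sampleData = "DataFrame"
    )
)

setValidity("ProbeIntensities", function(object) {
    msg <- character()
    if (!identical(dim(object@pm), dim(object@mm)))
        msg <- c(msg, "pm and mm must have identical dimensions")
    if (length(object@probeSet) != nrow(object@pm))
        msg <- c(msg, "probeSet must have one entry per probe row")
    if (nrow(object@sampleData) != ncol(object@pm))
        msg <- c(msg, "sampleData must have one row per array column")
    need <- c("sample_id", "genotype", "stage", "replicate")
    if (!all(need %in% colnames(object@sampleData)))
        msg <- c(msg, paste("sampleData must contain columns:",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Gene-level log2 expression with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} carrying one assay, \code{"log2"},
#' of gene-level log2 expression (genes x samples), with colData columns
#' \code{genotype}, \code{stage} and \code{replicate}.  The linear-scale
#' value used by the low-expression filter is \code{2^log2}.
#'
#' @seealso [newExpressionMatrix()], [summarizeProbeSets()],
#'   [replicateAverage()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an assay named 'log2' is required")
    else if (!all(is.finite(SummarizedExperiment::assay(object, "log2"))))
        msg <- c(msg, "log2 values must all be finite")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be unique")
    need <- c("genotype", "stage", "replicate")
    if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, paste("colData must contain columns:",
                            paste(need, collapse = ", ")))
    else {
        cd <- SummarizedExperiment::colData(object)
        key <- paste(cd$genotype, cd$stage, cd$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "each sample must map to a unique (genotype, stage, replicate)")
    }
    if (length(msg)) msg else TRUE
})

#' Fuzzy partition of genes into clusters
#'
#' Result of the fuzzy K-means (FANNY-style) clustering step: a membership
#' matrix whose rows are genes and columns clusters, each row non-negative
#' and summing to one, along with the Kaufman-Rousseeuw objective value at
#' convergence.
#'
#' @slot membership numeric matrix, genes x k; rows sum to 1.
#' @slot objective numeric, final objective value.
#' @slot iterations integer, sweeps performed.
#' @slot converged logical.
#'
#' @seealso [fannyCluster()], [coreGenes()]
#' @exportClass FuzzyPartition
setClass("FuzzyPartition",
    representation(
        membership = "matrix",
        objective  = "numeric",
        iterations = "integer",
        converged  = "logical"
    )
)

setValidity("FuzzyPartition", function(object) {
    msg <- character()
    u <- object@membership
    if (any(u < -1e-9))
        msg <- c(msg, "memberships must be non-negative")
    if (nrow(u) > 0 && any(abs(rowSums(u) - 1) > 1e-9))
        msg <- c(msg, "membership rows must sum to 1 (tolerance 1e-9)")
    if (length(msg)) msg else TRUE
})

#' Dominant pattern prototypes and gene assignments
#'
#' The outcome of the dominant-pattern (DP) procedure: merged pattern
#' prototypes (mean standardized profiles over the ordered
#' genotype x stage cells), the correlation-gated gene assignments, and the
#' provenance of each merged pattern (which raw clusters it absorbed).
#'
#' @slot prototypes numeric matrix, patterns x cells; rownames are pattern
#'   ids, colnames the ordered (genotype, stage) cell labels.
#' @slot assignments DataFrame with columns gene, pattern, r; pattern is NA
#'   for unassigned genes, and the flag column marks genes whose profile had
#'   zero variance (correlation undefined).
#' @slot provenance list, pattern id -> character vector of raw cluster ids.
#' @slot minCorrelation numeric, the assignment gate applied (default 0.85).
#'
#' @seealso [dominantPatterns()], [mergeClusters()], [assignGenes()]
#' @exportClass DominantPatternSet
setClass("DominantPatternSet",
    representation(
        prototypes     = "matrix",
        assignments    = "DataFrame",
        provenance     = "list",
        minCorrelation = "numeric"
    )
)

setValidity("DominantPatternSet", function(object) {
    msg <- character()
    a <- object@assignments
    if (!all(c("gene", "pattern", "r") %in% colnames(a)))
        msg <- c(msg, "assignments needs columns gene, pattern, r")
    else {
        ok <- !is.na(a$pattern)
        if (any(ok) && any(a$r[ok] < object@minCorrelation - 1e-12))
            msg <- c(msg, "every assigned gene must meet the correlation gate")
        if (any(ok) && !all(a$pattern[ok] %in% rownames(object@prototypes)))
            msg <- c(msg, "assigned patterns must exist among prototypes")
    }
    if (length(msg)) msg else TRUE
})

#' Detection calls with replicate consensus
#'
#' Per-gene, per-array Present/Marginal/Absent calls with their Wilcoxon
#' signed-rank detection p-values, plus the per-(genotype, stage) consensus:
#' a gene counts as detected in a tissue only when called 'P' in both
#' biological replicates of that tissue.
#'
#' @slot calls character matrix, genes x samples, values in P/M/A.
#' @slot pvalues numeric matrix, same shape.
#' @slot consensus logical matrix, genes x (genotype.stage) cells.
#'
#' @seealso [detectionCalls()], [consensusPresent()]
#' @exportClass DetectionCalls
setClass("DetectionCalls",
    representation(
        calls     = "matrix",
        pvalues   = "matrix",
        consensus = "matrix"
    )
)

setValidity("DetectionCalls", function(object) {
    msg <- character()
    if (!identical(dim(object@calls), dim(object@pvalues)))
        msg <- c(msg, "calls and pvalues must have identical dimensions")
    if (length(object@calls) && !all(object@calls %in% c("P", "M", "A")))
        msg <- c(msg, "calls must be P, M or A")
    if (length(msg)) msg else TRUE
})

#' Transcriptional module graph
#'
#' A typed graph linking transcription factors to the promoter motif they
#' bind and onward to the target genes carrying that motif, with GO terms
#' attached to genes as annotation nodes.  Node display roles follow the
#' usual module-figure convention: TF octagon, motif diamond, GO term
#' circle, gene ellipse.  Edge relations are \code{binds} (TF -> motif),
#' \code{targets} (motif -> gene) and \code{annotates} (GO term -> gene);
#' no other edge type is ever emitted, so the graph stays
#' tripartite-plus-annotation.
#'
#' @slot nodes DataFrame with columns id, type (TF/motif/GO_term/gene),
#'   role (octagon/diamond/circle/ellipse), orphan (logical; motifs with no
#'   mapped TF).
#' @slot edges DataFrame with columns from, relation, to.
#'
#' @seealso [buildModule()], [exportCytoscape()]
#' @exportClass ModuleGraph
setClass("ModuleGraph",
    representation(nodes = "DataFrame", edges = "DataFrame")
)

setValidity("ModuleGraph", function(object) {
    msg <- character()
    if (!all(c("id", "type", "role") %in% colnames(object@nodes)))
        msg <- c(msg, "nodes needs columns id, type, role")
    if (!all(c("from", "relation", "to") %in% colnames(object@edges)))
        msg <- c(msg, "edges needs columns from, relation, to")
    else if (nrow(object@edges)) {
        if (!all(object@edges$relation %in% c("binds", "targets", "annotates")))
            msg <- c(msg, "edge relations limited to binds/targets/annotates")
        ntype <- setNames(object@nodes$type, object@nodes$id)
        from <- ntype[object@edges$from]
        to <- ntype[object@edges$to]
        rel <- object@edges$relation
        bad <- (rel == "binds" & !(from == "TF" & to == "motif")) |
            (rel == "targets" &
                 !(from == "motif" & to %in% c("gene", "TF"))) |
            (rel == "annotates" &
                 !(from == "GO_term" & to %in% c("gene", "TF")))
        if (any(bad))
            msg <- c(msg, "edge endpoints inconsistent with relation types")
    }
    if (length(msg)) msg else TRUE
})

#' Sample dendrogram with bootstrap support
#'
#' Average-linkage hierarchical clustering of samples on correlation
#' distance, with ordinary bootstrap proportions (percent of gene-resampled
#' trees containing each original cluster) attached to the internal nodes.
#'
#' @slot hclust the \code{\link[stats]{hclust}} tree over samples.
#' @slot support numeric vector, one value in [0, 100] per internal node
#'   (merge), in \code{hclust} merge order.
#' @slot nBoot integer, bootstrap replicates used.
#'
#' @seealso [bootstrapHclust()], [writeNewick()]
#' @exportClass BootstrapDendrogram
setClass("BootstrapDendrogram",
    representation(hclust = "ANY", support = "numeric", nBoot = "integer")
)

setValidity("BootstrapDendrogram", function(object) {
    msg <- character()
    if (!inherits(object@hclust, "hclust"))
        msg <- c(msg, "hclust slot must be an hclust object")
    else if (length(object@support) != nrow(object@hclust$merge))
        msg <- c(msg, "one support value per internal node is required")
    if (length(object@support) &&
        (any(object@support < 0) || any(object@support > 100)))
        msg <- c(msg, "support values must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})
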