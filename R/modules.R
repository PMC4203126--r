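#' @include AllClasses.R utils.R
NULL

#' Assemble a transcriptional module graph
#'
#' For every motif enriched in the gene set (raw p below the enrichment
#' rule, as flagged in \code{motifEnrich}), adds: the motif node (diamond);
#' every transcription factor the TF map links to that motif, provided the
#' TF is itself a member of the gene set (octagon; set
#' \code{requireTfInSet = FALSE} to admit any mapped TF); every set gene
#' whose promoter carries at least one motif site (ellipse); and the GO
#' terms enriched in the set, attached to their member genes as annotation
#' nodes (circle).  An enriched motif with no mapped TF is retained and
#' flagged orphan.  Node and edge ordering is deterministic
#' (lexicographic), so rebuilding from the same inputs is byte-stable.
#'
#' @param geneSet character vector of genes the module describes.
#' @param motifEnrich result of [motifEnrichment()] on this set (its
#'   \code{hitGenes} attribute supplies the per-motif target genes).
#' @param tfMap data.frame with tf_gene_id, motif_id.
#' @param goEnrich optional result of [goEnrichment()] on the same set;
#'   only rows with \code{enriched = TRUE} become annotation nodes.
#' @param gmt the term -> genes list used for \code{goEnrich} (needed to
#'   know which genes each enriched term annotates).
#' @param requireTfInSet require TFs to belong to the gene set.
#' @return A \linkS4class{ModuleGraph}.
#' @export
buildModule <- function(geneSet, motifEnrich, tfMap, goEnrich = NULL,
                        gmt = NULL, requireTfInSet = TRUE) {
    nodes <- data.frame(id = character(), type = character(),
                        role = character(), orphan = logical(),
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = character(), relation = character(),
                        to = character(), stringsAsFactors = FALSE)
    addNode <- function(id, type, role, orphan = FALSE) {
        if (!id %in% nodes$id)
            nodes <<- rbind(nodes, data.frame(id = id, type = type,
                                              role = role, orphan = orphan,
                                              stringsAsFactors = FALSE))
    }
    hitGenes <- attr(motifEnrich, "hitGenes")
    enrichedMotifs <- motifEnrich$motif_id[motifEnrich$enriched]
    for (mid in sort(enrichedMotifs)) {
        tfs <- sort(tfMap$tf_gene_id[tfMap$motif_id == mid])
        if (requireTfInSet) tfs <- intersect(tfs, geneSet)
        addNode(mid, "motif", "diamond", orphan = length(tfs) == 0L)
        targets <- sort(intersect(hitGenes[[mid]], geneSet))
        for (tf in tfs) {
            addNode(tf, "TF", "octagon")
            edges <- rbind(edges, data.frame(from = tf, relation = "binds",
                                             to = mid,
                                             stringsAsFactors = FALSE))
        }
        for (g in setdiff(targets, tfs)) addNode(g, "gene", "ellipse")
        for (g in targets) {
            if (!g %in% nodes$id) addNode(g, "gene", "ellipse")
            edges <- rbind(edges, data.frame(from = mid,
                                             relation = "targets", to = g,
                                             stringsAsFactors = FALSE))
        }
    }
    if (!is.null(goEnrich) && !is.null(gmt) && nrow(nodes)) {
        geneNodes <- nodes$id[nodes$type %in% c("gene", "TF")]
        for (tid in sort(goEnrich$term[goEnrich$enriched])) {
            annotated <- sort(intersect(gmt[[tid]], geneNodes))
            if (!length(annotated)) next
            addNode(tid, "GO_term", "circle")
            for (g in annotated)
                edges <- rbind(edges, data.frame(from = tid,
                                                 relation = "annotates",
                                                 to = g,
                                                 stringsAsFactors = FALSE))
        }
    }
    ordN <- order(nodes$type, nodes$id)
    ordE <- order(edges$relation, edges$from, edges$to)
    new("ModuleGraph", nodes = DataFrame(nodes[ordN, , drop = FALSE]),
        edges = DataFrame(edges[ordE, , drop = FALSE]))
}

#' Export a module graph to Cytoscape files
#'
#' Writes \code{<prefix>.sif} (one tab-separated
#' \code{source relation target} interaction per line),
#' \code{<prefix>_node_attributes.tsv} (id, type, role, orphan) and
#' \code{<prefix>_edge_attributes.tsv} (source, relation, target).
#' Parsing the SIF back with [readSif()] reproduces the edge set exactly.
#'
#' @param graph a \linkS4class{ModuleGraph}.
#' @param prefix output path prefix.
#' @return the SIF path, invisibly.
#' @export
exportCytoscape <- function(graph, prefix) {
    nodes <- as.data.frame(moduleNodes(graph))
    edges <- as.data.frame(moduleEdges(graph))
    ids <- unique(c(nodes$id, edges$from, edges$to))
    if (any(grepl("[\t\n]", ids)))
        stop("node ids must not contain tabs or newlines", call. = FALSE)
    sif <- file.path(paste0(prefix, ".sif"))
    writeLines(if (nrow(edges))
        paste(edges$from, edges$relation, edges$to, sep = "\t")
        else character(), sif)
    utils::write.table(nodes, paste0(prefix, "_node_attributes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edges, paste0(prefix, "_edge_attributes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(sif)
}

#' Read a SIF file back as an edge table
#'
#' @param path a SIF file written by [exportCytoscape()].
#' @return data.frame with from, relation, to (zero rows for an empty
#'   graph).
#' @export
readSif <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(from = character(), relation = character(),
                          to = character(), stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, character(1), 1L),
               relation = vapply(parts, `[`, character(1), 2L),
               to = vapply(parts, `[`, character(1), 3L),
               stringsAsFactors = FALSE)
}

#' Serialize a module graph to JSON
#'
#' @param graph a \linkS4class{ModuleGraph}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModuleJson <- function(graph, path) {
    jsonlite::write_json(list(nodes = as.data.frame(moduleNodes(graph)),
                              edges = as.data.frame(moduleEdges(graph))),
                         path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
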