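# Minimal enrichment scaffolding for module construction without running
# the whole pipeline.
fakeMotifEnrich <- function(motifs, enriched, hitGenes) {
    df <- data.frame(motif_id = motifs, consensus = "AAAATATCT",
                     k = lengths(hitGenes)[motifs], K = 10L, n = 10L,
                     N = 100L, p = ifelse(motifs %in% enriched, 1e-6, 0.5),
                     p_adjusted = NA_real_,
                     enriched = motifs %in% enriched,
                     stringsAsFactors = FALSE)
    attr(df, "hitGenes") <- hitGenes
    df
}

test_that("a one-TF/one-motif module reproduces the expected topology", {
    set <- c("TF1", "BAM3", "BAM1", "GRP7", "GRP8", "OTHER")
    me <- fakeMotifEnrich("EE", "EE",
                          list(EE = c("BAM3", "BAM1", "GRP7", "GRP8")))
    tfMap <- data.frame(tf_gene_id = "TF1", motif_id = "EE",
                        stringsAsFactors = FALSE)
    gmt <- list("GO:amylase" = c("BAM3", "BAM1"),
                "GO:osmotic" = c("GRP7", "GRP8"))
    go <- data.frame(term = names(gmt), p = c(1e-5, 1e-5),
                     enriched = c(TRUE, TRUE), stringsAsFactors = FALSE)
    g <- buildModule(set, me, tfMap, goEnrich = go, gmt = gmt)
    nd <- as.data.frame(moduleNodes(g)); ed <- as.data.frame(moduleEdges(g))
    expect_equal(sum(nd$type == "TF"), 1L)
    expect_equal(sum(nd$type == "motif"), 1L)
    expect_equal(sum(ed$relation == "binds"), 1L)
    expect_setequal(ed$to[ed$relation == "targets"],
                    c("BAM3", "BAM1", "GRP7", "GRP8"))
    expect_setequal(ed$to[ed$relation == "annotates" &
                          ed$from == "GO:amylase"], c("BAM3", "BAM1"))
    expect_false(nd$orphan[nd$id == "EE"])
})

test_that("no enriched motifs yields an empty graph with a valid empty SIF", {
    me <- fakeMotifEnrich("EE", character(), list(EE = character()))
    g <- buildModule(c("a", "b"), me,
                     data.frame(tf_gene_id = character(),
                                motif_id = character()))
    expect_equal(nrow(moduleNodes(g)), 0L)
    prefix <- tempfile()
    exportCytoscape(g, prefix)
    expect_equal(nrow(readSif(paste0(prefix, ".sif"))), 0L)
})

test_that("five TFs mapped to one motif all point at the motif node", {
    tfs <- paste0("ATHB", c(1, 5, 6, 16, 53))
    targets <- paste0("t", 1:8)
    set <- c(tfs, targets)
    me <- fakeMotifEnrich("ATHB6bs", "ATHB6bs",
                          list(ATHB6bs = c(tfs, targets)))
    tfMap <- data.frame(tf_gene_id = tfs, motif_id = "ATHB6bs",
                        stringsAsFactors = FALSE)
    g <- buildModule(set, me, tfMap)
    ed <- as.data.frame(moduleEdges(g))
    expect_equal(sum(ed$relation == "binds"), 5L)
    expect_setequal(ed$from[ed$relation == "binds"], tfs)
    expect_equal(unique(ed$to[ed$relation == "binds"]), "ATHB6bs")
})

test_that("TF inclusion requires set membership unless relaxed; orphans flagged", {
    me <- fakeMotifEnrich("EE", "EE", list(EE = c("x", "y")))
    tfMap <- data.frame(tf_gene_id = "TFOUT", motif_id = "EE",
                        stringsAsFactors = FALSE)
    g1 <- buildModule(c("x", "y"), me, tfMap)
    nd1 <- as.data.frame(moduleNodes(g1))
    expect_equal(sum(nd1$type == "TF"), 0L)
    expect_true(nd1$orphan[nd1$id == "EE"])
    g2 <- buildModule(c("x", "y"), me, tfMap, requireTfInSet = FALSE)
    expect_equal(sum(as.data.frame(moduleNodes(g2))$type == "TF"), 1L)
})

test_that("the graph stays tripartite: illegal edges are rejected by validity", {
    nodes <- DataFrame(id = c("TF1", "g1"), type = c("TF", "gene"),
                       role = c("octagon", "ellipse"),
                       orphan = c(FALSE, FALSE))
    edges <- DataFrame(from = "TF1", relation = "targets", to = "g1")
    expect_error(new("ModuleGraph", nodes = nodes, edges = edges),
                 "inconsistent")
})

test_that("SIF round trip preserves the edge multiset and rebuilds are byte-identical", {
    set.seed(8)
    tfs <- paste0("tf", 1:5)
    genes <- paste0("g", 1:40)
    hit <- sample(genes, 25)
    me <- fakeMotifEnrich(c("M1", "M2"), c("M1", "M2"),
                          list(M1 = hit[1:15], M2 = hit[10:25]))
    tfMap <- data.frame(tf_gene_id = rep(tfs, 2),
                        motif_id = rep(c("M1", "M2"), each = 5),
                        stringsAsFactors = FALSE)
    g <- buildModule(c(tfs, genes), me, tfMap)
    p1 <- tempfile(); p2 <- tempfile()
    exportCytoscape(g, p1)
    back <- readSif(paste0(p1, ".sif"))
    ed <- as.data.frame(moduleEdges(g))
    expect_equal(back[order(back$relation, back$from, back$to), ],
                 ed[order(ed$relation, ed$from, ed$to), ],
                 ignore_attr = TRUE)
    g2 <- buildModule(c(tfs, genes), me, tfMap)
    exportCytoscape(g2, p2)
    expect_identical(readLines(paste0(p1, ".sif")),
                     readLines(paste0(p2, ".sif")))
    badNodes <- DataFrame(id = "a\tb", type = "gene", role = "ellipse",
                          orphan = FALSE)
    badG <- new("ModuleGraph", nodes = badNodes,
                edges = DataFrame(from = character(),
                                  relation = character(),
                                  to = character()))
    expect_error(exportCytoscape(badG, tempfile()), "tabs")
})
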