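test_that("noiseless probe intensities round-trip through median polish", {
    d <- smallDesign(nGenes = 40L)
    tr <- simulateTruth(d, nPatterns = 5L, seed = 3)
    sim <- simulateProbeIntensities(d, tr, noiseSd = 0, seed = 1)
    ex <- summarizeProbeSets(sim$probes, normalize = FALSE)
    mu <- truthMuMatrix(tr, d)
    got <- SummarizedExperiment::assay(ex, "log2")[rownames(mu), ]
    expect_lt(max(abs(got - mu)), 1e-6)
})

test_that("planted-absent genes are called Absent on every array", {
    d <- smallDesign(nGenes = 40L)
    tr <- simulateTruth(d, nPatterns = 4L, absentFraction = 0.3, seed = 5)
    sim <- simulateProbeIntensities(d, tr, noiseSd = 0, seed = 2)
    dc <- detectionCalls(sim$probes)
    expect_true(all(detectionMatrix(dc)[tr@absentGenes, ] == "A"))
})

test_that("identical seeds give byte-identical generated files", {
    d <- smallDesign(nGenes = 30L)
    mk <- function() {
        tr <- simulateTruth(d, nPatterns = 4L, seed = 11)
        sim <- simulateProbeIntensities(d, tr, noiseSd = 0.25, seed = 11)
        ann <- simulateAnnotations(d, tr, promoterLength = 200L, seed = 11)
        f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
        writeProbeTable(sim$probes, f1, f2)
        writeGmt(ann$gmt, f3)
        c(tools::md5sum(c(f1, f2, f3)))
    }
    expect_identical(unname(mk()), unname(mk()))
})

test_that("planted prototypes are pairwise Pearson r below 0.5", {
    d8 <- smallDesign(nGenes = 60L)
    tr <- simulateTruth(d8, nPatterns = 13L, seed = 2)
    cc <- stats::cor(t(tr@prototypes))
    expect_lt(max(cc[upper.tri(cc)]), 0.5)
    d4 <- studyDesign(genotypes = "WT", nGenes = 60L)
    tr4 <- simulateTruth(d4, nPatterns = 9L, dePerContrast = 0L, seed = 2)
    cc4 <- stats::cor(t(tr4@prototypes))
    expect_lt(max(cc4[upper.tri(cc4)]), 0.5)
})

test_that("planted DE effects are at least one log2 unit and land on the mutant", {
    d <- smallDesign(nGenes = 80L)
    tr <- simulateTruth(d, nPatterns = 3L, dePerContrast = 10L,
                        deEffect = 3, seed = 4)
    expect_true(all(abs(unlist(tr@deGenes)) >= 1))
    mu <- truthMuMatrix(tr, d)
    sheet <- as.data.frame(sampleSheet(d))
    st <- d@stages[2]
    eff <- tr@deGenes[[st]]
    dmu <- rowMeans(mu[names(eff), sheet$genotype == "vtc2" &
                                   sheet$stage == st, drop = FALSE]) -
        rowMeans(mu[names(eff), sheet$genotype == "WT" &
                                sheet$stage == st, drop = FALSE])
    expect_equal(unname(dmu), unname(eff))
})

test_that("generated GMT has one line per planted term and round-trips", {
    d <- smallDesign(nGenes = 60L)
    tr <- simulateTruth(d, nPatterns = 4L, nNullTerms = 3L, seed = 6)
    ann <- simulateAnnotations(d, tr, promoterLength = 120L, seed = 6)
    f <- tempfile(fileext = ".gmt")
    writeGmt(ann$gmt, f)
    expect_length(readLines(f), length(tr@terms))
    back <- readGmt(f)
    expect_identical(back[names(ann$gmt)], ann$gmt[names(ann$gmt)])
})

test_that("planted motif sites are exact IUPAC matches in the emitted FASTA", {
    d <- smallDesign(nGenes = 60L)
    tr <- simulateTruth(d, nPatterns = 4L, seed = 9)
    ann <- simulateAnnotations(d, tr, promoterLength = 150L, seed = 9)
    for (i in seq_len(nrow(tr@motifs))) {
        mid <- tr@motifs$motif_id[i]
        counts <- scanPromoters(ann$promoters, tr@motifs$consensus[i])
        carriers <- names(counts)[counts >= 1L]
        expect_setequal(carriers, tr@motifPromoters[[mid]])
    }
})

test_that("generator rejects invalid parameters with informative errors", {
    expect_error(studyDesign(nGenes = 0), "nGenes")
    expect_error(studyDesign(replicates = -1), "replicates")
    d <- smallDesign(nGenes = 30L)
    tr <- simulateTruth(d, nPatterns = 3L, seed = 1)
    expect_error(simulateProbeIntensities(d, tr, noiseSd = -1), "noiseSd")
    tr@motifs$consensus[1] <- "AAQT"
    expect_error(simulateAnnotations(d, tr, seed = 1), "IUPAC")
})

test_that("qPCR table recovers planted fold change through 2^-ddCt", {
    d <- smallDesign(nGenes = 60L)
    tr <- simulateTruth(d, nPatterns = 0L, dePerContrast = 6L,
                        deEffect = 2, seed = 8)
    st <- d@stages[1]
    up <- names(tr@deGenes[[st]])[tr@deGenes[[st]] > 0][1]
    flat <- setdiff(names(tr@patternAssignments),
                    c(unlist(lapply(tr@deGenes, names)), tr@absentGenes))[1]
    tab <- simulateQpcr(d, tr, genes = c(up, flat), stage = st,
                        noiseSd = 0, seed = 1)
    expect_equal(ddct(tab, up, "REF1", "vtc2", "WT")$fold, 4)
    expect_equal(ddct(tab, flat, "REF1", "vtc2", "WT")$fold, 1)
    expect_error(simulateQpcr(d, tr, genes = c(up, "REF1"),
                              referenceGene = "REF1"), "reference")
})

test_that("noisy qPCR recovery stays within Monte-Carlo tolerance", {
    d <- smallDesign(nGenes = 60L)
    tr <- simulateTruth(d, nPatterns = 0L, dePerContrast = 6L,
                        deEffect = 2, seed = 8)
    st <- d@stages[1]
    up <- names(tr@deGenes[[st]])[tr@deGenes[[st]] > 0][1]
    folds <- vapply(1:100, function(s) {
        tab <- simulateQpcr(d, tr, genes = up, stage = st, noiseSd = 0.1,
                            replicates = 3L, seed = s)
        ddct(tab, up, "REF1", "vtc2", "WT")$fold
    }, numeric(1))
    # ddCt noise SD ~ sqrt(4 * 0.1^2 / 3) ~ 0.115 cycles around ddCt = -2
    expect_lt(abs(mean(log2(folds)) - 2), 0.05)
    expect_lt(stats::sd(log2(folds)), 0.25)
})
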