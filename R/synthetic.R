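#' @include AllClasses.R utils.R
NULL

#' Planted ground truth for a simulated experiment
#'
#' Records everything the generator planted, so every downstream stage can
#' be scored against a known answer: pattern prototypes and gene-to-pattern
#' assignments, per-contrast differential genes with their log2 effects,
#' absent (undetectable) genes, GO-term memberships with the planted
#' set-to-term enrichments, motif consensus sequences with the promoters
#' carrying at least one site, and the TF-to-motif map.
#'
#' @slot cells ordered (genotype, stage) cell labels.
#' @slot prototypes matrix, planted patterns x cells, standardized profiles.
#' @slot patternAssignments named character, gene -> pattern id (NA = none).
#' @slot baseline named numeric, gene -> baseline log2 expression.
#' @slot amplitude numeric, log2 scale of the standardized prototype swing.
#' @slot deGenes list, stage -> named numeric of planted log2 effects
#'   (second genotype minus first).
#' @slot stageJitter matrix, genes x stages: per-gene idiosyncratic stage
#'   profile shared by both genotypes (zero for pattern and absent genes),
#'   so non-pattern genes vary across development without forming tight
#'   co-expression groups and without touching any genotype contrast.
#' @slot absentGenes character, genes simulated as undetectable (PM ~ MM).
#' @slot terms list, GO term id -> member genes (the GMT content).
#' @slot termDescriptions named character, term id -> description.
#' @slot enrichedTerms list, gene-set label -> term ids planted as enriched.
#' @slot motifs data.frame with columns motif_id, consensus (IUPAC).
#' @slot motifPromoters list, motif id -> genes whose promoter carries >= 1
#'   exact site.
#' @slot tfMap data.frame with columns tf_gene_id, motif_id.
#' @slot moduleSets list, motif id -> gene-set label it was planted into.
#'
#' @seealso [simulateTruth()]
#' @exportClass PlantedTruth
setClass("PlantedTruth",
    representation(
        cells              = "character",
        prototypes         = "matrix",
        patternAssignments = "character",
        baseline           = "numeric",
        amplitude          = "numeric",
        deGenes            = "list",
        stageJitter        = "matrix",
        absentGenes        = "character",
        terms              = "list",
        termDescriptions   = "character",
        enrichedTerms      = "list",
        motifs             = "data.frame",
        motifPromoters     = "list",
        tfMap              = "data.frame",
        moduleSets         = "list"
    )
)

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(object@patternAssignments), "genes;",
        nrow(object@prototypes), "planted patterns;",
        sum(lengths(object@deGenes)), "planted DE effects;",
        length(object@terms), "GO terms;",
        nrow(object@motifs), "motifs\n")
})

# Evaluate expr with a temporary RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

#' Construct a study design
#'
#' @param genotypes genotype labels; the second is treated as the mutant in
#'   differential contrasts. Default \code{c("WT", "vtc2")}.
#' @param stages ordered developmental stage labels. Default the four-stage
#'   somatic-embryogenesis series: bent-cotyledon zygotic embryo, day 7 of
#'   induction, day 14 of induction, mature somatic embryo.
#' @param replicates biological replicates per (genotype, stage) cell.
#' @param nGenes number of probe sets; the default matches the ATH1 array
#'   scale. Simulation-based tests typically use 500-2000.
#' @param nProbes PM/MM probe pairs per probe set.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' studyDesign(nGenes = 500)
#' @export
studyDesign <- function(genotypes = c("WT", "vtc2"),
                        stages = c("zygotic", "D7I", "D14I", "matureSE"),
                        replicates = 2L, nGenes = 22810L, nProbes = 11L) {
    for (nm in c("replicates", "nGenes", "nProbes")) {
        v <- get(nm)
        if (length(v) != 1L || !is.finite(v) || v < 1)
            stop("'", nm, "' must be a positive integer", call. = FALSE)
    }
    new("StudyDesign", genotypes = as.character(genotypes),
        stages = as.character(stages),
        replicates = as.integer(replicates),
        nGenes = as.integer(nGenes), nProbes = as.integer(nProbes))
}

#' Sample sheet for a design
#'
#' One row per array: sample_id, genotype, stage, replicate, in
#' genotype-major, stage-minor, replicate-innermost order.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return A \code{DataFrame}.
#' @export
sampleSheet <- function(design) {
    grid <- expand.grid(replicate = seq_len(design@replicates),
                        stage = design@stages,
                        genotype = design@genotypes,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("genotype", "stage", "replicate")]
    DataFrame(
        sample_id = paste(grid$genotype, grid$stage,
                          paste0("r", grid$replicate), sep = "_"),
        genotype = grid$genotype, stage = grid$stage,
        replicate = as.integer(grid$replicate))
}

# Well-separated standardized prototype profiles: n unit directions in the
# (nCells-1)-dim contrast space with pairwise inner product (= Pearson r of
# the profiles) below maxR, found by penalized multi-start optimization.
makePrototypes <- function(n, cells, maxR = 0.45, seed = 1) {
    nCells <- length(cells)
    stopIfNot(nCells >= 3, "need at least 3 cells for distinct prototypes")
    d <- nCells - 1L
    basis <- qr.Q(qr(cbind(1, stats::contr.helmert(nCells))))[, -1, drop = FALSE]
    obj <- function(x) {
        v <- matrix(x, n, d)
        v <- v / sqrt(rowSums(v^2))
        g <- tcrossprod(v)
        ex <- pmax(g[upper.tri(g)] - maxR, 0)
        sum(ex^2)
    }
    best <- NULL
    for (try in seq_len(25L)) {
        x0 <- withSeed(deriveSeed(seed, try), stats::rnorm(n * d))
        fit <- stats::optim(x0, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14))
        v <- matrix(fit$par, n, d)
        v <- v / sqrt(rowSums(v^2))
        g <- tcrossprod(v)
        mx <- max(g[upper.tri(g)])
        if (is.null(best) || mx < best$mx) best <- list(v = v, mx = mx)
        if (best$mx <= maxR + 1e-8) break
    }
    stopIfNot(best$mx < 0.5,
              "could not place prototypes with pairwise Pearson r < 0.5")
    p <- sqrt(nCells - 1) * best$v %*% t(basis)
    dimnames(p) <- list(sprintf("DP%02d", seq_len(n)), cells)
    p
}

#' Plant the ground truth for a simulated experiment
#'
#' Chooses, deterministically under \code{seed}, everything the synthetic
#' data will encode: which genes follow which accumulation pattern, which
#' are differential per stage (effects of at least 1 log2 unit, by
#' construction), which are absent, the GO-term memberships, the promoter
#' motifs and the promoters carrying them, and the TF-to-motif map.  Two
#' transcriptional-module configurations are planted by default: a
#' single-TF/single-motif module (an Evening-Element-like circadian motif)
#' in the up-regulated set of the first stage, and a five-TF/one-motif
#' module (an ATHB-binding-site-like motif) in the up-regulated set of the
#' third stage.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param nPatterns planted dominant patterns (13 mirrors the two-genotype
#'   run; 9 the wild-type-only run).
#' @param unassignedFraction fraction of genes following no pattern.
#' @param absentFraction fraction of genes simulated as undetectable.
#' @param amplitude log2 swing applied to the standardized prototypes.
#' @param dePerContrast planted differential genes per stage (half up, half
#'   down), drawn from the pattern-free pool.
#' @param deEffect planted |log2| effect (second genotype minus first).
#' @param nNullTerms random (non-enriched) GO terms added to the GMT.
#' @param termFraction fraction of each pattern's genes forming its planted
#'   GO term.
#' @param nullTermSize size of each random GO term.
#' @param stageJitterSd SD of the per-gene, per-stage log2 profile
#'   variation given to non-pattern, non-absent genes.  It is shared by
#'   both genotypes, so it cancels in every genotype contrast.
#' @param motifFraction fraction of each module gene set's promoters that
#'   carry the module motif.
#' @param backgroundMotifRate fraction of non-module promoters carrying a
#'   motif (0 keeps the background motif-free by rejection sampling).
#' @param tfCounts integer vector: number of TFs for each planted module.
#' @param motifConsensus IUPAC consensus strings for the planted motifs.
#' @param seed integer seed; identical seeds give identical truth.
#' @return A \linkS4class{PlantedTruth}.
#' @examples
#' d <- studyDesign(nGenes = 300)
#' simulateTruth(d, seed = 7)
#' @export
simulateTruth <- function(design, nPatterns = 13L,
                          unassignedFraction = 0.25, absentFraction = 0.15,
                          amplitude = 1.5, dePerContrast = 20L, deEffect = 3,
                          stageJitterSd = 0.3,
                          nNullTerms = 10L, termFraction = 0.8,
                          nullTermSize = 50L, motifFraction = 0.8,
                          backgroundMotifRate = 0,
                          tfCounts = c(1L, 5L),
                          motifConsensus = c(EE = "AAAATATCT",
                                             ATHB = "CAATTATTA"),
                          seed = 1) {
    stopIfNot(design@nGenes >= 1L, "'nGenes' must be at least 1")
    stopIfNot(abs(deEffect) >= 1 || dePerContrast == 0,
              "planted DE effects must be at least 1 log2 unit")
    cells <- cellLabels(design)
    genes <- sprintf("SG%05d", seq_len(design@nGenes))
    withSeed(seed, {
        proto <- if (nPatterns >= 1L)
            makePrototypes(nPatterns, cells, seed = deriveSeed(seed, 101))
        else matrix(numeric(), 0L, length(cells),
                    dimnames = list(character(), cells))

        nAbsent <- round(absentFraction * design@nGenes)
        nAssigned <- if (nPatterns >= 1L)
            design@nGenes - nAbsent - round(unassignedFraction * design@nGenes)
        else 0L
        stopIfNot(nAssigned >= nPatterns,
                  "too few genes to populate every pattern")
        shuffled <- sample(genes)
        assigned <- shuffled[seq_len(nAssigned)]
        absent <- if (nAbsent) shuffled[nAssigned + seq_len(nAbsent)] else character()
        free <- setdiff(shuffled, c(assigned, absent))

        pat <- setNames(rep(NA_character_, design@nGenes), genes)
        pat[assigned] <- rownames(proto)[rep_len(seq_len(nPatterns),
                                                 nAssigned)]

        baseline <- setNames(stats::runif(design@nGenes, 6, 11), genes)
        baseline[absent] <- stats::runif(length(absent), 2.5, 3.5)

        # idiosyncratic developmental profile for genes outside the
        # planted patterns (zero for pattern and absent genes)
        jitter <- matrix(stats::rnorm(design@nGenes * length(design@stages),
                                      sd = stageJitterSd),
                         design@nGenes, length(design@stages),
                         dimnames = list(genes, design@stages))
        jitter[!is.na(pat) | genes %in% absent, ] <- 0

        # planted DE genes: from the pattern-free, present pool
        deGenes <- setNames(vector("list", length(design@stages)),
                            design@stages)
        pool <- free
        for (st in design@stages) {
            nDe <- min(dePerContrast, length(pool))
            pick <- pool[seq_len(nDe)]
            pool <- setdiff(pool, pick)
            eff <- rep(c(deEffect, -deEffect), length.out = nDe)
            deGenes[[st]] <- setNames(eff, pick)
        }

        # GO terms: one planted term per pattern, plus random null terms
        terms <- list(); descr <- character(); enriched <- list()
        for (p in rownames(proto)) {
            members <- names(pat)[!is.na(pat) & pat == p]
            k <- max(1L, round(termFraction * length(members)))
            tid <- paste0("GO:", p)
            terms[[tid]] <- sort(sample(members, k))
            descr[tid] <- paste("planted process for pattern", p)
            enriched[[p]] <- c(enriched[[p]], tid)
        }
        for (st in design@stages) {
            up <- names(deGenes[[st]])[deGenes[[st]] > 0]
            if (length(up)) {
                tid <- paste0("GO:UP_", st)
                terms[[tid]] <- sort(up)
                descr[tid] <- paste("planted process up-regulated at", st)
                enriched[[paste0("up.", st)]] <- tid
            }
        }
        present <- setdiff(genes, absent)
        for (i in seq_len(nNullTerms)) {
            tid <- sprintf("GO:NULL%03d", i)
            terms[[tid]] <- sort(sample(present,
                                        min(nullTermSize, length(present))))
            descr[tid] <- "random background term"
        }

        # motifs + modules: motif m planted in the up-set of a chosen stage
        nMod <- min(length(tfCounts), length(motifConsensus),
                    length(design@stages))
        motifs <- data.frame(motif_id = names(motifConsensus),
                             consensus = unname(motifConsensus),
                             stringsAsFactors = FALSE)
        motifProm <- setNames(vector("list", nrow(motifs)), motifs$motif_id)
        tfMap <- data.frame(tf_gene_id = character(), motif_id = character(),
                            stringsAsFactors = FALSE)
        moduleSets <- list()
        modStages <- design@stages[c(1L, 3L)][seq_len(nMod)]
        for (i in seq_len(nMod)) {
            st <- modStages[i]
            mid <- motifs$motif_id[i]
            set <- names(deGenes[[st]])[deGenes[[st]] > 0]
            if (!length(set)) next
            tfs <- set[seq_len(min(tfCounts[i], length(set)))]
            nHit <- max(length(tfs), ceiling(motifFraction * length(set)))
            hits <- unique(c(tfs, sample(setdiff(set, tfs),
                                         max(0L, nHit - length(tfs)))))
            motifProm[[mid]] <- sort(hits)
            tfMap <- rbind(tfMap, data.frame(tf_gene_id = tfs,
                                             motif_id = mid,
                                             stringsAsFactors = FALSE))
            moduleSets[[mid]] <- paste0("up.", st)
        }
        if (backgroundMotifRate > 0) {
            for (mid in motifs$motif_id) {
                bg <- setdiff(genes, unlist(motifProm))
                extra <- sample(bg, round(backgroundMotifRate * length(bg)))
                motifProm[[mid]] <- sort(union(motifProm[[mid]], extra))
            }
        }
        for (mid in motifs$motif_id)
            if (is.null(motifProm[[mid]])) motifProm[[mid]] <- character()

        new("PlantedTruth", cells = cells, prototypes = proto,
            patternAssignments = pat, baseline = baseline,
            amplitude = amplitude, deGenes = deGenes,
            stageJitter = jitter,
            absentGenes = sort(absent), terms = terms,
            termDescriptions = descr, enrichedTerms = enriched,
            motifs = motifs, motifPromoters = motifProm, tfMap = tfMap,
            moduleSets = moduleSets)
    })
}

#' Noise-free log2 expression implied by a planted truth
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param design the matching \linkS4class{StudyDesign}.
#' @return numeric matrix, genes x samples (one column per array).
#' @export
truthMuMatrix <- function(truth, design) {
    sheet <- sampleSheet(design)
    genes <- names(truth@patternAssignments)
    mu <- matrix(truth@baseline[genes], nrow = length(genes),
                 ncol = nrow(sheet),
                 dimnames = list(genes, sheet$sample_id))
    cellIdx <- match(cellOf(sheet$genotype, sheet$stage), truth@cells)
    if (nrow(truth@stageJitter))
        mu <- mu + truth@stageJitter[genes, sheet$stage, drop = FALSE]
    pat <- truth@patternAssignments
    hasPat <- !is.na(pat)
    if (any(hasPat)) {
        patRow <- match(pat[hasPat], rownames(truth@prototypes))
        mu[hasPat, ] <- mu[hasPat, ] +
            truth@amplitude * truth@prototypes[patRow, cellIdx, drop = FALSE]
    }
    mutant <- design@genotypes[length(design@genotypes)]
    for (st in names(truth@deGenes)) {
        eff <- truth@deGenes[[st]]
        if (!length(eff)) next
        colsMut <- sheet$genotype == mutant & sheet$stage == st
        mu[names(eff), colsMut] <- mu[names(eff), colsMut] + eff
    }
    mu
}

#' Simulate a gene-level expression matrix
#'
#' Additive Gaussian noise on the log2 scale around the planted noise-free
#' values -- the standard fixture for the differential and pattern stages.
#'
#' @param design,truth design and planted truth.
#' @param noiseSd per-array log2 noise standard deviation.
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
simulateExpression <- function(design, truth, noiseSd = 0.25, seed = 1) {
    mu <- truthMuMatrix(truth, design)
    vals <- withSeed(seed,
        mu + stats::rnorm(length(mu), sd = noiseSd))
    newExpressionMatrix(vals, sampleSheet(design))
}

#' Simulate probe-level PM/MM intensities
#'
#' PM intensities are lognormal around \code{2^mu} with probe affinities
#' shared across arrays (median-centred so a noiseless median polish
#' returns \code{mu} exactly); for detectable genes MM is an attenuated,
#' noisy copy of PM, while for planted-absent genes MM tracks PM so the
#' discrimination scores hover around zero and the detection call comes
#' out Absent.
#'
#' @param design,truth design and planted truth.
#' @param noiseSd lognormal noise SD on the log2 scale (0 = noiseless).
#' @param mmAttenuation MM/PM ratio for detectable genes (0 < a < 1).
#' @param affinitySd SD of per-probe log2 affinities.
#' @param seed integer seed; identical seeds give identical tables.
#' @return A list with elements \code{probes} (a
#'   \linkS4class{ProbeIntensities}) and \code{truth} (the input truth,
#'   unchanged, for convenience).
#' @export
simulateProbeIntensities <- function(design, truth, noiseSd = 0.25,
                                     mmAttenuation = 0.5, affinitySd = 0.5,
                                     seed = 1) {
    stopIfNot(noiseSd >= 0, "'noiseSd' must be non-negative")
    stopIfNot(mmAttenuation > 0 && mmAttenuation < 1,
              "'mmAttenuation' must be in (0, 1)")
    mu <- truthMuMatrix(truth, design)
    nG <- nrow(mu); nP <- design@nProbes; nS <- ncol(mu)
    withSeed(seed, {
        aff <- matrix(stats::rnorm(nG * nP, sd = affinitySd), nG, nP)
        aff <- aff - apply(aff, 1L, stats::median)  # median-zero per gene
        logPM <- mu[rep(seq_len(nG), each = nP), , drop = FALSE] +
            as.vector(t(aff)) +
            matrix(stats::rnorm(nG * nP * nS, sd = noiseSd), nG * nP, nS)
        pmMat <- 2^logPM
        isAbsent <- names(truth@patternAssignments) %in% truth@absentGenes
        att <- ifelse(isAbsent, 1, mmAttenuation)[rep(seq_len(nG), each = nP)]
        mmNoise <- if (noiseSd > 0)
            matrix(stats::rnorm(nG * nP * nS, sd = noiseSd), nG * nP, nS)
        else 0
        mmMat <- pmMat * att * 2^mmNoise
        probeIds <- rep(rownames(mu), each = nP)
        rn <- paste(probeIds, rep(seq_len(nP), nG), sep = "_p")
        dimnames(pmMat) <- dimnames(mmMat) <- list(rn, colnames(mu))
        probes <- new("ProbeIntensities", pm = pmMat, mm = mmMat,
                      probeSet = probeIds, sampleData = sampleSheet(design))
        list(probes = probes, truth = truth)
    })
}

# sample a motif-free promoter by rejection against all consensus motifs
randomCleanPromoter <- function(len, consensi, maxTries = 200L) {
    for (i in seq_len(maxTries)) {
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        hits <- vapply(consensi, function(m)
            countMotifHits(Biostrings::DNAStringSet(s), m), integer(1))
        if (all(hits == 0L)) return(s)
    }
    stop("could not sample a motif-free background promoter", call. = FALSE)
}

#' Simulate the annotation inputs: GMT, promoters, motif and TF tables
#'
#' Promoters are uniform-composition random sequences; every promoter the
#' truth marks as carrying a motif receives at least one exact consensus
#' insertion (random strand, random position), and all other promoters are
#' rejection-sampled to be motif-free.
#'
#' @param design,truth design and planted truth.
#' @param promoterLength promoter length in bp.
#' @param seed integer seed.
#' @return list with \code{gmt} (term -> genes, with \code{descriptions}
#'   attribute), \code{promoters} (\code{DNAStringSet}, one per gene),
#'   \code{motifTable} (motif_id, consensus) and \code{tfMap}
#'   (tf_gene_id, motif_id).
#' @export
simulateAnnotations <- function(design, truth, promoterLength = 1000L,
                                seed = 1) {
    consensi <- truth@motifs$consensus
    names(consensi) <- truth@motifs$motif_id
    stopIfNot(all(nchar(consensi) <= promoterLength),
              "promoter length must be at least the motif length")
    bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", consensi)
    if (any(bad))
        stop("motif not expressible in the IUPAC alphabet: ",
             paste(consensi[bad], collapse = ", "), call. = FALSE)
    genes <- names(truth@patternAssignments)
    withSeed(seed, {
        seqs <- vapply(genes, function(g)
            randomCleanPromoter(promoterLength, consensi), character(1))
        for (mid in names(consensi)) {
            motif <- consensi[[mid]]
            for (g in truth@motifPromoters[[mid]]) {
                ins <- motif
                if (stats::runif(1) < 0.5)
                    ins <- as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(motif)))
                pos <- sample(promoterLength - nchar(ins) + 1L, 1L)
                substr(seqs[g], pos, pos + nchar(ins) - 1L) <- ins
            }
        }
        promoters <- Biostrings::DNAStringSet(seqs)
        names(promoters) <- genes
        gmt <- truth@terms
        attr(gmt, "descriptions") <- truth@termDescriptions
        list(gmt = gmt, promoters = promoters,
             motifTable = truth@motifs, tfMap = truth@tfMap)
    })
}

#' Simulate a qPCR Ct table
#'
#' Ct values consistent with the planted expression model via
#' \code{Ct = ctBase - log2(expression)}; the reference gene has constant
#' expression across conditions so reference-normalized quantities recover
#' the planted fold changes.
#'
#' @param design,truth design and planted truth.
#' @param genes target genes to measure.
#' @param stage the stage whose two genotypes form the conditions.
#' @param referenceGene id for the synthetic reference transcript (added to
#'   the table; must not clash with a target).
#' @param replicates technical/biological replicate measurements.
#' @param noiseSd Ct measurement noise SD (cycles).
#' @param ctBase offset so Cts land in a realistic range.
#' @param seed integer seed.
#' @return data.frame with columns sample, condition, gene, Ct.
#' @export
simulateQpcr <- function(design, truth, genes, stage = design@stages[1],
                         referenceGene = "REF1", replicates = 3L,
                         noiseSd = 0, ctBase = 30, seed = 1) {
    stopIfNot(!referenceGene %in% genes,
              "the reference gene must be distinct from the targets")
    stopIfNot(stage %in% design@stages, "unknown stage")
    mu <- truthMuMatrix(truth, design)
    sheet <- sampleSheet(design)
    rows <- list()
    withSeed(seed, {
        for (g in design@genotypes) {
            cols <- which(sheet$genotype == g & sheet$stage == stage)
            level <- rowMeans(mu[genes, cols, drop = FALSE])
            for (r in seq_len(replicates)) {
                ct <- ctBase - level + stats::rnorm(length(genes), sd = noiseSd)
                rows[[length(rows) + 1L]] <- data.frame(
                    sample = paste(g, stage, paste0("q", r), sep = "_"),
                    condition = g, gene = genes, Ct = unname(ct),
                    stringsAsFactors = FALSE)
                refCt <- ctBase - 15 + stats::rnorm(1, sd = noiseSd)
                rows[[length(rows) + 1L]] <- data.frame(
                    sample = paste(g, stage, paste0("q", r), sep = "_"),
                    condition = g, gene = referenceGene, Ct = refCt,
                    stringsAsFactors = FALSE)
            }
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Serialize a planted truth to JSON
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
    x <- list(
        cells = truth@cells,
        prototypes = truth@prototypes,
        patternAssignments = as.list(truth@patternAssignments),
        baseline = as.list(truth@baseline),
        amplitude = truth@amplitude,
        deGenes = lapply(truth@deGenes, as.list),
        absentGenes = truth@absentGenes,
        terms = truth@terms,
        enrichedTerms = truth@enrichedTerms,
        motifs = truth@motifs,
        motifPromoters = truth@motifPromoters,
        tfMap = truth@tfMap,
        moduleSets = truth@moduleSets)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
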