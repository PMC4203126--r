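#' @include AllClasses.R utils.R io.R
NULL

#' Default pipeline configuration
#'
#' All thresholds default to the published analysis values: low-expression
#' filter at linear 30, K = 15 fuzzy clusters, core membership m = 0.44,
#' assignment gate r >= 0.85, selection gate q < 0.05 with |FC| >= 2, and
#' enrichment at raw p < 0.001.  The merge threshold (r >= 0.90) and the
#' detection-call parameters (tau = 0.015, alpha1 = 0.04, alpha2 = 0.06)
#' are documented analogue choices.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param nGenes genes simulated when the simulate stage is on.
#' @return named list of configuration values.
#' @export
defaultConfig <- function(seed = 1, nGenes = 500L) {
    list(
        seed = seed,
        n_genes = nGenes,
        n_patterns = 13L,
        probe_noise_sd = 0.25,
        de_per_contrast = 20L,
        de_effect = 3,
        quantile_normalize = TRUE,
        filter = 30,
        k = 15L,
        m = 0.44,
        assign_r = 0.85,
        merge_r = 0.90,
        q_cut = 0.05,
        fc_cut = 2,
        enrich_p = 0.001,
        tau = 0.015,
        alpha1 = 0.04,
        alpha2 = 0.06,
        n_boot = 100L,
        stages = list(simulate = TRUE, preprocess = TRUE, detect = TRUE,
                      diff = TRUE, patterns = TRUE, enrich = TRUE,
                      modules = TRUE),
        inputs = list(probe_table = NULL, sample_sheet = NULL, gmt = NULL,
                      promoters = NULL, motif_table = NULL, tf_map = NULL)
    )
}

#' Validate a pipeline configuration
#'
#' Range-checks every threshold and rejects unknown keys.
#'
#' @param config a configuration list (see [defaultConfig()]).
#' @return character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validateConfig <- function(config) {
    errs <- character()
    known <- names(defaultConfig())
    unknown <- setdiff(names(config), known)
    if (length(unknown))
        errs <- c(errs, paste("unknown configuration key(s):",
                              paste(unknown, collapse = ", ")))
    chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
    chk(is.numeric(config$seed) && length(config$seed) == 1L,
        "seed must be a single number")
    chk(config$n_genes >= 1, "n_genes must be >= 1")
    chk(config$k >= 2, "k must be >= 2")
    chk(config$m > 0 && config$m <= 1, "m must lie in (0, 1]")
    chk(config$assign_r >= -1 && config$assign_r <= 1,
        "assign_r must be a correlation in [-1, 1]")
    chk(config$merge_r >= -1 && config$merge_r <= 1,
        "merge_r must be a correlation in [-1, 1]")
    chk(config$q_cut > 0 && config$q_cut < 1, "q_cut must lie in (0, 1)")
    chk(config$fc_cut >= 1, "fc_cut must be >= 1")
    chk(config$enrich_p > 0 && config$enrich_p < 1,
        "enrich_p must lie in (0, 1)")
    chk(config$filter >= 0, "filter must be non-negative")
    chk(config$alpha1 > 0 && config$alpha1 < config$alpha2 &&
            config$alpha2 < 0.5, "need 0 < alpha1 < alpha2 < 0.5")
    chk(is.logical(config$quantile_normalize),
        "quantile_normalize must be TRUE or FALSE")
    chk(config$n_boot >= 1, "n_boot must be >= 1")
    errs
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> detect -> diff -> patterns ->
#' enrich -> modules (each stage optional via the \code{stages} toggles),
#' writing every stage's files under \code{outDir} plus a manifest
#' recording the configuration, per-stage row counts and output file
#' hashes.  Re-running with the same seed and configuration reproduces
#' identical files.  On a stage failure the error names the stage and the
#' stage's partial outputs are kept with a \code{.partial} suffix.
#'
#' @param config configuration list; validated before anything runs.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = tempfile("run")) {
    errs <- validateConfig(config)
    if (length(errs))
        stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
             call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package_version =
                         as.character(utils::packageVersion("DominantPatterns")),
                     seed = config$seed, config = config, stages = list())
    on <- config$stages
    out <- function(...) file.path(outDir, paste0(...))
    written <- character()
    env <- new.env()

    runStage <- function(name, files, fun) {
        if (!isTRUE(on[[name]])) return(invisible(NULL))
        counts <- tryCatch(fun(), error = function(e) {
            for (f in files) if (file.exists(f))
                file.rename(f, paste0(f, ".partial"))
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        written <<- c(written, files[file.exists(files)])
        manifest$stages[[name]] <<- counts
    }

    runStage("simulate",
        c(out("probes.tsv"), out("sample_sheet.csv"), out("terms.gmt"),
          out("promoters.fasta"), out("motifs.tsv"), out("tf_map.tsv"),
          out("truth.json")), function() {
        design <- studyDesign(nGenes = config$n_genes)
        truth <- simulateTruth(design, nPatterns = config$n_patterns,
                               dePerContrast = config$de_per_contrast,
                               deEffect = config$de_effect,
                               seed = deriveSeed(config$seed, 1))
        sim <- simulateProbeIntensities(design, truth,
                                        noiseSd = config$probe_noise_sd,
                                        seed = deriveSeed(config$seed, 2))
        ann <- simulateAnnotations(design, truth,
                                   seed = deriveSeed(config$seed, 3))
        writeProbeTable(sim$probes, out("probes.tsv"),
                        out("sample_sheet.csv"))
        writeGmt(ann$gmt, out("terms.gmt"))
        Biostrings::writeXStringSet(ann$promoters, out("promoters.fasta"))
        utils::write.table(ann$motifTable, out("motifs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(ann$tfMap, out("tf_map.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeTruth(truth, out("truth.json"))
        env$design <- design; env$truth <- truth; env$probes <- sim$probes
        env$gmt <- ann$gmt; env$promoters <- ann$promoters
        env$motifTable <- ann$motifTable; env$tfMap <- ann$tfMap
        list(genes = design@nGenes,
             arrays = nrow(sampleSheet(design)))
    })

    if (!isTRUE(on$simulate)) {
        ins <- config$inputs
        for (f in c("probe_table", "sample_sheet", "gmt", "promoters",
                    "motif_table", "tf_map")) {
            if (is.null(ins[[f]]) || !file.exists(ins[[f]]))
                stop("required input '", f, "' missing: ",
                     if (is.null(ins[[f]])) "(not set)" else ins[[f]],
                     call. = FALSE)
        }
        env$probes <- readProbeTable(ins$probe_table, ins$sample_sheet)
        env$gmt <- readGmt(ins$gmt)
        env$promoters <- Biostrings::readDNAStringSet(ins$promoters)
        env$motifTable <- readMotifTable(ins$motif_table)
        env$tfMap <- readTfMap(ins$tf_map)
    }

    runStage("preprocess",
        c(out("expression.tsv"), out("replicate_qc.csv"),
          out("dendrogram.nwk")), function() {
        env$expr <- summarizeProbeSets(env$probes,
                                       normalize = config$quantile_normalize)
        writeExpressionMatrix(env$expr, out("expression.tsv"))
        qc <- replicateCorrelation(env$expr)
        utils::write.csv(qc, out("replicate_qc.csv"), row.names = FALSE)
        dend <- bootstrapHclust(env$expr, nBoot = config$n_boot,
                                seed = deriveSeed(config$seed, 4))
        writeNewick(dend, out("dendrogram.nwk"))
        list(genes = nrow(env$expr), mean_replicate_r = mean(qc$r))
    })

    runStage("detect",
        c(out("detection_calls.tsv"), out("detection_consensus.tsv")),
        function() {
        dc <- detectionCalls(env$probes, tau = config$tau,
                             alpha1 = config$alpha1,
                             alpha2 = config$alpha2)
        env$calls <- dc
        callsLong <- data.frame(
            gene = rep(rownames(detectionMatrix(dc)),
                       ncol(detectionMatrix(dc))),
            sample = rep(colnames(detectionMatrix(dc)),
                         each = nrow(detectionMatrix(dc))),
            p = as.vector(dc@pvalues),
            call = as.vector(detectionMatrix(dc)))
        utils::write.table(callsLong, out("detection_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cons <- consensusMatrix(dc)
        utils::write.table(data.frame(gene = rownames(cons), cons,
                                      check.names = FALSE),
                           out("detection_consensus.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        as.list(attr(cons, "detectedCounts"))
    })

    runStage("diff", out("summary_counts.json"), function() {
        res <- runDifferential(env$expr, qCut = config$q_cut,
                               fcCut = config$fc_cut,
                               seed = deriveSeed(config$seed, 5))
        env$diff <- res
        counts <- list()
        for (st in names(res)) {
            f <- out("diff_", st, ".tsv")
            utils::write.table(res[[st]], f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            written <<- c(written, f)
            sel <- selectDeg(res[[st]], qCut = config$q_cut,
                             fcCut = config$fc_cut)
            counts[[st]] <- as.list(sel$counts)
        }
        jsonlite::write_json(counts, out("summary_counts.json"),
                             auto_unbox = TRUE, digits = NA)
        counts
    })

    runStage("patterns",
        c(out("prototypes.tsv"), out("assignments.tsv"),
          out("pattern_sizes.json"), out("prototypes_long.csv")),
        function() {
        dps <- dominantPatterns(env$expr,
                                filterThreshold = config$filter,
                                k = config$k, m = config$m,
                                mergeR = config$merge_r,
                                rMin = config$assign_r,
                                seed = deriveSeed(config$seed, 6))
        env$dps <- dps
        utils::write.table(data.frame(pattern = rownames(prototypes(dps)),
                                      prototypes(dps), check.names = FALSE),
                           out("prototypes.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(as.data.frame(assignments(dps)),
                           out("assignments.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        sizes <- table(assignments(dps)$pattern)
        jsonlite::write_json(as.list(sizes), out("pattern_sizes.json"),
                             auto_unbox = TRUE, digits = NA)
        utils::write.csv(prototypeLongFormat(dps),
                         out("prototypes_long.csv"), row.names = FALSE)
        list(patterns = nrow(prototypes(dps)),
             assigned = sum(!is.na(assignments(dps)$pattern)))
    })

    runStage("enrich",
        c(out("enrichment_go.csv"), out("enrichment_motif.csv"),
          out("enrichment_heatmap.tsv")), function() {
        background <- rownames(env$expr)
        sets <- list()
        for (st in names(env$diff)) {
            sel <- selectDeg(env$diff[[st]], qCut = config$q_cut,
                             fcCut = config$fc_cut)
            sets[[paste0("up.", st)]] <- sel$up
            sets[[paste0("down.", st)]] <- sel$down
        }
        asn <- assignments(env$dps)
        for (p in rownames(prototypes(env$dps)))
            sets[[p]] <- asn$gene[!is.na(asn$pattern) & asn$pattern == p]
        goAll <- list(); moAll <- list()
        for (s in names(sets)) {
            if (!length(sets[[s]])) next
            goAll[[s]] <- goEnrichment(sets[[s]], env$gmt, background,
                                       pCut = config$enrich_p)
            moAll[[s]] <- motifEnrichment(sets[[s]], env$promoters,
                                          env$motifTable, background,
                                          pCut = config$enrich_p)
        }
        env$geneSets <- sets; env$goAll <- goAll; env$moAll <- moAll
        bindWithSet <- function(lst) do.call(rbind, lapply(names(lst),
            function(s) cbind(gene_set = s, lst[[s]])))
        utils::write.csv(bindWithSet(goAll), out("enrichment_go.csv"),
                         row.names = FALSE)
        utils::write.csv(bindWithSet(moAll), out("enrichment_motif.csv"),
                         row.names = FALSE)
        hm <- minusLog10Matrix(goAll)
        utils::write.table(data.frame(term = rownames(hm), hm,
                                      check.names = FALSE),
                           out("enrichment_heatmap.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        list(gene_sets = length(goAll),
             enriched_go = sum(vapply(goAll, function(d) sum(d$enriched),
                                      numeric(1))),
             enriched_motifs = sum(vapply(moAll,
                                          function(d) sum(d$enriched),
                                          numeric(1))))
    })

    runStage("modules", character(), function() {
        nMod <- 0L
        for (s in names(env$moAll)) {
            if (!any(env$moAll[[s]]$enriched)) next
            g <- buildModule(env$geneSets[[s]], env$moAll[[s]], env$tfMap,
                             goEnrich = env$goAll[[s]], gmt = env$gmt)
            prefix <- out("module_", gsub("[^A-Za-z0-9_.]", "_", s))
            exportCytoscape(g, prefix)
            writeModuleJson(g, paste0(prefix, ".json"))
            written <<- c(written, paste0(prefix, ".sif"),
                          paste0(prefix, "_node_attributes.tsv"),
                          paste0(prefix, "_edge_attributes.tsv"),
                          paste0(prefix, ".json"))
            env$modules[[s]] <- g
            nMod <- nMod + 1L
        }
        list(modules = nMod)
    })

    manifest$files <- as.list(tools::md5sum(sort(unique(written))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outDir <- outDir
    manifest$env <- env
    invisible(manifest)
}
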