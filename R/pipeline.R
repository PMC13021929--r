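#' @importFrom utils packageVersion
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the stage functions, with the defaults used
#' throughout the package. Unknown fields are rejected (a misspelled
#' override never passes silently, because only the named arguments
#' below exist).
#'
#' @param preset simulation preset (\code{"lce"}, \code{"hce"},
#'   \code{"null"}).
#' @param seed integer seed for the simulation stage.
#' @param outDir optional output directory; when \code{NULL} nothing is
#'   written and results are returned in memory only.
#' @param minUnits,minGap,window motif-scanner tunables (bp / units).
#' @param flankBind,binBind element metaprofile geometry (bp).
#' @param flankGro,binGro,bodyBins metagene geometry (bp / columns).
#' @param psi CPM pseudocount for all log ratios.
#' @param lfcCut,padjCut target-classification thresholds.
#' @param fdrCut differential-binding significance threshold.
#' @param maxFragmentLen fragment-length filter (bp).
#' @param antisenseFlank antisense-counting half-window (bp).
#' @param sim optional \linkS4class{SimConfig} override; defaults to
#'   \code{simConfig(seed)}.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(preset = "lce", seed = 1L, outDir = NULL,
                           minUnits = 4L, minGap = 20L, window = 200L,
                           flankBind = 1500L, binBind = 10L,
                           flankGro = 3000L, binGro = 50L,
                           bodyBins = 100L, psi = 1,
                           lfcCut = 1, padjCut = 0.01, fdrCut = 0.05,
                           maxFragmentLen = 1000L,
                           antisenseFlank = 1000L,
                           sim = NULL) {
    if (!preset %in% c("lce", "hce", "null"))
        stop("'preset' must be one of lce/hce/null")
    if (is.null(sim)) sim <- simConfig(seed = seed)
    stopifnot(minUnits >= 2, minGap >= 0, window >= 0,
              flankBind %% binBind == 0, flankGro %% binGro == 0,
              psi >= 0, padjCut > 0, padjCut <= 1,
              fdrCut > 0, fdrCut <= 1, maxFragmentLen > 0)
    cfg <- list(preset = preset, seed = as.integer(seed),
                outDir = outDir,
                minUnits = as.integer(minUnits),
                minGap = as.integer(minGap),
                window = as.integer(window),
                flankBind = as.integer(flankBind),
                binBind = as.integer(binBind),
                flankGro = as.integer(flankGro),
                binGro = as.integer(binGro),
                bodyBins = as.integer(bodyBins),
                psi = psi, lfcCut = lfcCut, padjCut = padjCut,
                fdrCut = fdrCut,
                maxFragmentLen = as.integer(maxFragmentLen),
                antisenseFlank = as.integer(antisenseFlank),
                sim = sim)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Hash of the tunable part of a pipeline configuration
#'
#' Changes iff any tunable changes; output paths are excluded.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return md5 hex string.
#' @export
configHash <- function(config) {
    tun <- config[setdiff(names(config), "outDir")]
    tun$sim <- lapply(slotNames(tun$sim), function(s) slot(tun$sim, s))
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(deparse(tun), tmp)
    unname(tools::md5sum(tmp))
}

# Internal: stage log line.
.stageMsg <- function(stage, text) {
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", text)
}

#' Run the integrated binding + nascent-transcription pipeline
#'
#' Executes the stages in dependency order on a simulated experiment:
#' simulate, motif scanning, target classification, differential
#' binding, nascent-transcription quantitation, and the per-element
#' integration join. Re-running with an unchanged configuration
#' produces identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with the stage outputs (\code{sim}, \code{elements},
#'   \code{targets}, \code{tertiles}, \code{binding}, \code{windows},
#'   \code{ei}, \code{metagene}, \code{tes}, \code{antisense},
#'   \code{master}) and a \code{report} summarizing per-stage record
#'   counts and key statistics.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    report <- list(version = as.character(packageVersion("cutTagGro")),
                   config_hash = configHash(config),
                   preset = config$preset, seed = config$seed)

    .stageMsg("simulate", paste("preset", config$preset))
    sim <- simulateExperiment(config$preset, config$sim)
    report$n_genes <- length(sim$genes)
    report$n_planted_elements <- length(sim$elements)
    report$gro_library_sizes <-
        vapply(sim$readSets, librarySize, 1L)
    report$ct_library_sizes <-
        vapply(sim$fragmentSets, librarySize, 1L)

    .stageMsg("motifs", "scanning genome for GGAA elements")
    found <- scanGenomeElements(sim$genome, minUnits = config$minUnits,
                                minGap = config$minGap,
                                window = config$window)
    report$n_ggaa <- length(found$ggaa)
    report$n_microsatellites <- length(found$microsatellites)
    report$n_isolated <- length(found$isolated)
    report$element_class_counts <-
        c(microsatellite = length(found$microsatellites),
          isolated_ggaa = length(found$isolated),
          table(mcols(found$tandem)$element_class))

    .stageMsg("targets", "classifying knockdown targets")
    targets <- classifyTargets(sim$deTable, lfcCut = config$lfcCut,
                               padjCut = config$padjCut)
    tertiles <- partitionByLengthTertiles(sim$genes)
    report$tertile_boundaries <- tertiles$boundaries
    report$target_counts <- table(targets$target_class)

    .stageMsg("bind", "quantifying differential binding")
    conds <- vapply(sim$fragmentSets, sampleCondition, "")
    counts <- countFragments(sim$fragmentSets, sim$peaks)
    libs <- vapply(sim$fragmentSets, librarySize, 1L)
    cpm <- cpmNormalize(counts, libs)
    binding <- differentialBinding(cpm, conds, control = "control",
                                   treated = "treated",
                                   psi = config$psi,
                                   fdrCut = config$fdrCut)
    report$n_diff_peaks <- sum(binding$significant)
    report$frip <- vapply(sim$fragmentSets, frip, numeric(1),
                          peaks = sim$peaks)
    rc <- replicateCorrelation(cpm)
    report$min_replicate_correlation <- min(rc, na.rm = TRUE)
    # element-centered fragment profiles, one representative library per
    # condition, at the discovered microsatellites
    seqlensG <- setNames(BiocGenerics::width(sim$genome),
                         names(sim$genome))
    msCenters <- found$microsatellites
    metaprofile <- NULL
    if (length(msCenters)) {
        pick <- function(cond) sim$fragmentSets[[
            which(conds == cond)[1L]]]
        metaprofile <- list(
            control = siteMetaprofile(pick("control"), msCenters,
                                      flank = config$flankBind,
                                      binWidth = config$binBind,
                                      seqlens = seqlensG)$profile,
            treated = siteMetaprofile(pick("treated"), msCenters,
                                      flank = config$flankBind,
                                      binWidth = config$binBind,
                                      seqlens = seqlensG)$profile)
    }

    .stageMsg("gro", "quantifying nascent transcription")
    gw <- geneWindows(sim$genes)
    wc <- countWindowReads(sim$readSets, gw)
    ei <- elongationIndex(wc, "control", "treated", psi = config$psi)
    report$mean_delta_ei_by_tertile <- meanDeltaEiByTertile(ei, tertiles)
    ctl <- Filter(function(r) sampleCondition(r) == "control",
                  sim$readSets)
    trt <- Filter(function(r) sampleCondition(r) == "treated",
                  sim$readSets)
    metagene <- scaledMetagene(trt, ctl, sim$genes,
                               flank = config$flankGro,
                               binWidth = config$binGro,
                               bodyBins = config$bodyBins,
                               psi = config$psi, seqlens = seqlensG)
    report$metagene_body_slope <- metageneBodySlope(metagene)
    tes <- tesGroupStats(wc, targets, "control", "treated")
    # TES pooled log2 ratio per gene (for the integration join)
    tesC <- .pooledCPM(wc, "tes", "control")
    tesT <- .pooledCPM(wc, "tes", "treated")
    tesFC <- data.frame(gene_id = rownames(wc),
                        tes_log2fc = log2((tesT + config$psi) /
                                          (tesC + config$psi)))
    peaksAnn <- sim$peaks
    gid <- annotateNearestGene(peaksAnn, sim$genes)
    gstr <- setNames(as.character(strand(sim$genes)),
                     mcols(sim$genes)$gene_id)
    strand(peaksAnn) <- ifelse(is.na(gid), "*", gstr[gid])
    antis <- antisenseInitiation(trt, ctl, peaksAnn,
                                 flank = config$antisenseFlank,
                                 psi = config$psi)

    .stageMsg("integrate", "joining per-element master table")
    elements <- .discoveredElements(found)
    mcols(elements)$gene_id <- annotateNearestGene(elements, sim$genes)
    master <- integrateElementTable(elements, targets, binding,
                                    sim$peaks, ei, tesFC, antis)
    report$n_master_rows <- nrow(master)

    out <- list(sim = sim, found = found, elements = elements,
                targets = targets, tertiles = tertiles,
                binding = binding, metaprofile = metaprofile,
                windows = wc, ei = ei,
                metagene = metagene, tes = tes, antisense = antis,
                master = master, report = report)
    if (!is.null(config$outDir)) .writePipelineOutputs(out, config)
    out
}

# Internal: one GRanges of discovered elements across classes, with ids;
# tandem sites contribute one row per (site, cofactor class).
.discoveredElements <- function(found) {
    ms <- found$microsatellites
    iso <- found$isolated
    tan <- found$tandem
    rows <- list()
    if (length(ms)) {
        mcols(ms) <- DataFrame(element_class = "microsatellite",
                               unit_count = mcols(ms)$unit_count)
        rows$ms <- ms
    }
    if (length(iso)) {
        mcols(iso) <- DataFrame(element_class = "isolated_ggaa",
                                unit_count = NA_integer_)
        rows$iso <- iso
    }
    if (length(tan)) {
        cls <- mcols(tan)$element_class
        mcols(tan) <- DataFrame(element_class = cls,
                                unit_count = NA_integer_)
        rows$tan <- tan
    }
    el <- do.call(c, unname(rows))
    el <- el[order(as.character(seqnames(el)), start(el),
                   mcols(el)$element_class)]
    mcols(el)$element_id <- sprintf("el_%05d", seq_along(el))
    el
}

#' Join element, target, binding and transcription evidence
#'
#' One row per (element, class label). Missing joins are kept as
#' \code{NA}, never dropped: the output has exactly one row per input
#' element.
#'
#' @param elements \link[GenomicRanges]{GRanges} with \code{element_id},
#'   \code{element_class} and \code{gene_id} metadata columns.
#' @param targets result of \code{\link{classifyTargets}}.
#' @param binding result of \code{\link{differentialBinding}}.
#' @param peaks the peak \link[GenomicRanges]{GRanges} the binding
#'   records refer to (metadata column \code{name} = peak_id).
#' @param ei result of \code{\link{elongationIndex}}.
#' @param tesFC data.frame with \code{gene_id}, \code{tes_log2fc}.
#' @param antisense result of \code{\link{antisenseInitiation}}.
#' @return data.frame, one row per element.
#' @export
integrateElementTable <- function(elements, targets, binding, peaks,
                                  ei, tesFC, antisense) {
    ids <- mcols(elements)$element_id
    if (anyDuplicated(ids))
        stop("duplicate element ids")
    n <- length(elements)
    # element -> overlapping peak (nearest-start on multi-hit)
    peakId <- rep(NA_character_, n)
    if (length(peaks) && !is.null(mcols(peaks)$name)) {
        hits <- findOverlaps(elements, peaks, maxgap = 0L,
                             ignore.strand = TRUE)
        if (length(hits)) {
            q <- S4Vectors::queryHits(hits)
            s <- S4Vectors::subjectHits(hits)
            o <- order(q, start(peaks)[s])
            q <- q[o]; s <- s[o]
            first <- !duplicated(q)
            peakId[q[first]] <- mcols(peaks)$name[s[first]]
        }
    }
    look <- function(df, key, val, keys) {
        df[[val]][match(keys, df[[key]])]
    }
    gene <- mcols(elements)$gene_id
    data.frame(
        element_id = ids,
        chrom = as.character(seqnames(elements)),
        start = start(elements) - 1L,
        end = end(elements),
        element_class = mcols(elements)$element_class,
        gene_id = gene,
        target_class = look(targets, "gene_id", "target_class", gene),
        peak_id = peakId,
        binding_log2fc = look(binding, "peak_id", "log2fc", peakId),
        binding_fdr = look(binding, "peak_id", "fdr", peakId),
        delta_ei = look(ei, "gene_id", "delta_ei", gene),
        tes_log2fc = look(tesFC, "gene_id", "tes_log2fc", gene),
        antisense_log2fc = look(antisense, "peak_id", "log2fc", peakId),
        stringsAsFactors = FALSE
    )
}

# Internal: write the pipeline outputs under config$outDir.
.writePipelineOutputs <- function(out, config) {
    d <- config$outDir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(out$master, file.path(d, "master_elements.tsv"))
    .writeTsv(out$binding, file.path(d, "differential_binding.tsv"))
    .writeTsv(out$ei, file.path(d, "elongation_index.tsv"))
    .writeTsv(out$targets, file.path(d, "targets.tsv"))
    writeBed6(out$elements, file.path(d, "elements.bed"),
              name = mcols(out$elements)$element_class,
              score = ifelse(is.na(mcols(out$elements)$unit_count), 0,
                             100 * mcols(out$elements)$unit_count))
    writeTruthTables(out$sim$truth, d)
    rep <- out$report
    flat <- vapply(names(rep), function(k) {
        paste(k, paste(format(rep[[k]], digits = 10, trim = TRUE),
                       collapse = ","), sep = "\t")
    }, "")
    writeLines(flat, file.path(d, "run_report.tsv"))
    invisible(d)
}
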