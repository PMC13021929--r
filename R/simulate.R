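#' @importFrom stats rlnorm rnbinom rnorm rpois runif
NULL

# fraction of nascent reads drawn as uniform genome-wide background
.GRO_BG_FRAC <- 0.02

# Internal: draw NB counts with mean mu and dispersion phi
# (variance mu + phi mu^2); phi = 0 degenerates to Poisson.
.rnb <- function(n, mu, phi) {
    if (phi <= 0) return(rpois(n, mu))
    rnbinom(n, mu = mu, size = 1 / phi)
}

# Internal: one concrete instance of an IUPAC consensus, avoiding the
# creation of GGAA/TTCC inside the instance where the consensus allows a
# choice.
.consensusInstance <- function(pattern) {
    letters <- strsplit(pattern, "")[[1L]]
    inst <- vapply(letters, function(l) {
        opts <- strsplit(.IUPAC[[l]], "")[[1L]]
        opts[1L]
    }, "")
    seqs <- paste(inst, collapse = "")
    # E2F-style SS positions: prefer expansions without internal GGAA
    if (grepl("GGAA|TTCC", seqs)) {
        amb <- which(nchar(.IUPAC[letters]) > 1L)
        for (i in amb) {
            for (o in strsplit(.IUPAC[[letters[i]]], "")[[1L]]) {
                trial <- inst
                trial[i] <- o
                if (!grepl("GGAA|TTCC", paste(trial, collapse = ""))) {
                    inst <- trial
                    break
                }
            }
        }
        seqs <- paste(inst, collapse = "")
    }
    seqs
}

# Internal: remove chance GGAA/TTCC occurrences around a planted element.
# chars: character vector of the chromosome; [protect_start, protect_end]
# is the planted insert, whose bases are never mutated and whose fully
# internal matches are left alone; [zone_start, zone_end] is the region
# cleaned. Mutates and returns chars.
.scrubGGAA <- function(chars, zone_start, zone_end,
                       protect_start, protect_end) {
    n <- length(chars)
    zs <- max(1L, zone_start - 3L)
    ze <- min(n, zone_end + 3L)
    repeat {
        seg <- paste(chars[zs:ze], collapse = "")
        hits <- gregexpr("(?=(GGAA|TTCC))", seg, perl = TRUE)[[1L]]
        if (hits[1L] == -1L) break
        starts <- zs + as.integer(hits) - 1L
        bad <- starts[starts < protect_start | starts + 3L > protect_end]
        if (!length(bad)) break
        changed <- FALSE
        for (b in bad) {
            pos <- setdiff(b:(b + 3L), protect_start:protect_end)
            if (!length(pos)) next
            p <- pos[1L]
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]),
                               1L)
            changed <- TRUE
        }
        if (!changed) break
    }
    chars
}

#' Simulate a synthetic genome with planted response elements
#'
#' Generates uniform-random background sequence, places non-overlapping
#' gene models whose lengths populate three size strata, and plants GGAA
#' response elements of every class in intergenic space:
#' microsatellites as perfect \code{(GGAA)k} runs, isolated GGAA motifs
#' with scrubbed flanks (no chance GGAA/TTCC within the isolation gap),
#' and tandem sites as a GGAA paired with a concrete cofactor-consensus
#' instance at a sampled edge distance. Deterministic under the
#' configured seed.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{genome} (named
#'   \link[Biostrings]{DNAStringSet}), \code{genes} (stranded
#'   \link[GenomicRanges]{GRanges} with \code{gene_id}), and
#'   \code{elements} (\link[GenomicRanges]{GRanges} with
#'   \code{element_id}, \code{element_class}, \code{unit_count},
#'   \code{partner_distance}).
#' @export
simulateGenome <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(cfg@seed)
    chromNames <- paste0("chr", seq_len(cfg@nChroms))
    chars <- lapply(chromNames, function(x)
        sample(c("A", "C", "G", "T"), cfg@chromLen, replace = TRUE))
    names(chars) <- chromNames

    # --- gene placement -------------------------------------------------
    third <- cfg@nGenes %/% 3L
    nSmall <- third
    nMedium <- third
    nLarge <- cfg@nGenes - 2L * third
    lens <- c(
        sample(cfg@geneLenSmall[1L]:cfg@geneLenSmall[2L], nSmall, TRUE),
        sample(cfg@geneLenMedium[1L]:cfg@geneLenMedium[2L], nMedium, TRUE),
        sample(cfg@geneLenLarge[1L]:cfg@geneLenLarge[2L], nLarge, TRUE))
    lens <- sample(lens)
    edge <- 1000L   # reserved at contig edges (window/flank room)
    perChrom <- split(seq_len(cfg@nGenes),
                      rep_len(seq_len(cfg@nChroms), cfg@nGenes))
    geneRows <- list()
    freeSegs <- list()
    for (ci in seq_len(cfg@nChroms)) {
        idx <- perChrom[[ci]]
        glens <- lens[idx]
        free <- cfg@chromLen - 2L * edge - sum(glens)
        if (free < 400L * (length(idx) + 1L))
            stop("infeasible packing: genes do not fit; ",
                 "increase 'chromLen' or reduce 'nGenes'")
        w <- runif(length(idx) + 1L, 0.2, 1)
        gaps <- floor(free * w / sum(w))
        pos <- edge + 1L
        for (k in seq_along(idx)) {
            pos <- pos + gaps[k]
            geneRows[[length(geneRows) + 1L]] <- data.frame(
                chrom = chromNames[ci], start = pos,
                end = pos + glens[k] - 1L,
                strand = sample(c("+", "-"), 1L))
            freeStart <- if (k == 1L) edge + 1L else
                geneRows[[length(geneRows) - 1L]]$end + 1L
            freeSegs[[length(freeSegs) + 1L]] <- data.frame(
                chrom = chromNames[ci], start = freeStart, end = pos - 1L)
            pos <- pos + glens[k]
        }
        freeSegs[[length(freeSegs) + 1L]] <- data.frame(
            chrom = chromNames[ci], start = pos,
            end = cfg@chromLen - edge)
    }
    genesDf <- do.call(rbind, geneRows)
    segs <- do.call(rbind, freeSegs)
    segs <- segs[segs$end - segs$start + 1L >= 300L, , drop = FALSE]

    # --- element placement ---------------------------------------------
    cofNames <- names(defaultCofactorPatterns())
    classes <- c(rep("microsatellite", cfg@nMicrosat),
                 rep("isolated_ggaa", cfg@nIsolated),
                 rep(.tandemClass(cofNames),
                     each = cfg@nTandemPerClass))
    classes <- sample(classes)
    # scrubPad: flank width cleaned of chance GGAA/TTCC (isolation rule).
    # exclPad: exclusion margin consumed around every planted element so
    # that true peaks (center +/- 250 bp) plus fragment reach never
    # overlap a neighbouring element -- per-element truth labels are only
    # well-defined when planted signals do not bleed into each other.
    scrubPad <- 24L
    exclPad <- 400L
    elemRows <- list()
    for (ei in seq_along(classes)) {
        cl <- classes[ei]
        if (cl == "microsatellite") {
            units <- sample(cfg@microsatUnits[1L]:cfg@microsatUnits[2L],
                            1L)
            insert <- strrep("GGAA", units)
        } else if (cl == "isolated_ggaa") {
            units <- NA_integer_
            insert <- "GGAA"
        } else {
            units <- NA_integer_
            cof <- cofNames[.tandemClass(cofNames) == cl]
            inst <- .consensusInstance(defaultCofactorPatterns()[[cof]])
            d <- sample(24:180, 1L)
            # A/C-only spacer cannot form GGAA or TTCC
            spacer <- paste(sample(c("A", "C"), d, TRUE), collapse = "")
            insert <- paste0("GGAA", spacer, inst)
        }
        span <- nchar(insert)
        need <- span + 2L * exclPad
        ok <- which(segs$end - segs$start + 1L >= need)
        if (!length(ok))
            stop("infeasible packing: no intergenic room for element ",
                 ei, "; increase 'chromLen'")
        cap <- segs$end[ok] - segs$start[ok] + 1L - need
        pick <- sample.int(length(ok), 1L, prob = cap + 1)
        si <- ok[pick]
        off <- sample.int(cap[pick] + 1L, 1L) - 1L
        s <- segs$start[si] + exclPad + off
        e <- s + span - 1L
        chrom <- segs$chrom[si]
        v <- chars[[chrom]]
        v[s:e] <- strsplit(insert, "")[[1L]]
        v <- .scrubGGAA(v, s - scrubPad, e + scrubPad, s, e)
        chars[[chrom]] <- v
        elemRows[[ei]] <- data.frame(
            chrom = chrom, start = s,
            end = if (cl == "microsatellite" || cl == "isolated_ggaa")
                e else s + 3L,
            element_class = cl,
            unit_count = units,
            partner_distance = if (startsWith(cl, "tandem"))
                e - (s + 3L) - nchar(inst) else NA_integer_)
        # split the used segment (consume the exclusion footprint)
        left <- data.frame(chrom = chrom, start = segs$start[si],
                           end = s - exclPad - 1L)
        right <- data.frame(chrom = chrom, start = e + exclPad + 1L,
                            end = segs$end[si])
        segs <- rbind(segs[-si, , drop = FALSE], left, right)
        segs <- segs[segs$end - segs$start + 1L >= 300L, , drop = FALSE]
    }
    elemDf <- do.call(rbind, elemRows)

    genome <- DNAStringSet(vapply(chars, paste, "", collapse = ""))
    names(genome) <- chromNames
    genes <- GRanges(genesDf$chrom,
                     IRanges(genesDf$start, genesDf$end),
                     strand = genesDf$strand)
    o <- order(as.character(seqnames(genes)), start(genes))
    genes <- genes[o]
    mcols(genes)$gene_id <- sprintf("gene_%03d", seq_along(genes))
    elements <- GRanges(elemDf$chrom,
                        IRanges(elemDf$start, elemDf$end),
                        strand = "+")
    mcols(elements)$element_class <- elemDf$element_class
    mcols(elements)$unit_count <- elemDf$unit_count
    mcols(elements)$partner_distance <- elemDf$partner_distance
    elements <- elements[order(as.character(seqnames(elements)),
                               start(elements))]
    mcols(elements)$element_id <-
        sprintf("elem_%03d", seq_along(elements))
    list(genome = genome, genes = genes, elements = elements)
}

#' Build planted ground truth for a perturbation preset
#'
#' Assigns target labels, per-gene initiation (\code{lambda}) and
#' attrition (\code{kappa}) rates per condition, and per-element
#' occupancies per condition, realizing one of three presets:
#' \describe{
#'   \item{lce}{initiation-only: induced targets lose initiation
#'     (\code{lfcInduced} log2 units), repressed targets gain it;
#'     attrition unchanged.}
#'   \item{hce}{attrition: \code{deltaKappaHCE} added genome-wide, plus
#'     milder (half-size) initiation effects at targets.}
#'   \item{null}{treated identical to control in expectation.}
#' }
#'
#' @param sim result of \code{\link{simulateGenome}}.
#' @param preset \code{"lce"}, \code{"hce"} or \code{"null"}.
#' @param cfg the \linkS4class{SimConfig} used for the genome.
#' @return a \linkS4class{SimTruth}.
#' @export
buildSimTruth <- function(sim, preset = c("lce", "hce", "null"), cfg) {
    preset <- match.arg(preset)
    set.seed(cfg@seed + 1L)
    genes <- sim$genes
    n <- length(genes)
    if (cfg@nInduced + cfg@nRepressed > n)
        stop("more targets than genes")
    lab <- rep("neither", n)
    pick <- sample.int(n, cfg@nInduced + cfg@nRepressed)
    lab[pick[seq_len(cfg@nInduced)]] <- "induced"
    lab[pick[cfg@nInduced + seq_len(cfg@nRepressed)]] <- "repressed"
    lam <- rlnorm(n, meanlog = 0, sdlog = 0.4)
    kapC <- rep(cfg@kappaControl, n)
    shift <- rep(0, n)
    if (preset == "lce") {
        shift[lab == "induced"] <- cfg@lfcInduced
        shift[lab == "repressed"] <- -cfg@lfcInduced
        kapT <- kapC
    } else if (preset == "hce") {
        shift[lab == "induced"] <- cfg@lfcInduced / 2
        shift[lab == "repressed"] <- -cfg@lfcInduced / 2
        kapT <- kapC + cfg@deltaKappaHCE
    } else {
        kapT <- kapC
    }
    mcols(genes)$lambda_control <- lam
    mcols(genes)$lambda_treated <- lam * 2^shift
    mcols(genes)$kappa_control <- kapC
    mcols(genes)$kappa_treated <- kapT
    mcols(genes)$target_class <- lab

    elements <- sim$elements
    ne <- length(elements)
    oC <- rlnorm(ne, meanlog = 0, sdlog = 0.3)
    # occupancy shifts are drawn in balanced +/- pairs over elements of
    # similar baseline occupancy, so the total chromatin-bound signal is
    # conserved in expectation and relative (CPM) measurements of the
    # planted per-element shifts are free of composition bias
    nNull <- round(ne * cfg@nullFraction)
    if ((ne - nNull) %% 2L == 1L) nNull <- nNull + 1L
    dlt <- rep(0, ne)
    if (ne - nNull > 0L && preset != "null") {
        shifted <- sample.int(ne, ne - nNull)
        shifted <- shifted[order(oC[shifted])]
        npair <- length(shifted) %/% 2L
        mags <- runif(npair, cfg@occShiftRange[1L],
                      cfg@occShiftRange[2L])
        sgn <- sample(c(-1, 1), npair, replace = TRUE)
        for (k in seq_len(npair)) {
            dlt[shifted[2L * k - 1L]] <- sgn[k] * mags[k]
            dlt[shifted[2L * k]] <- -sgn[k] * mags[k]
        }
    }
    mcols(elements)$occupancy_control <- oC
    mcols(elements)$occupancy_treated <- oC * 2^dlt
    mcols(elements)$delta_log2_occupancy <- dlt
    anti <- rep(FALSE, ne)
    if (cfg@antisense)
        anti[sample.int(ne, max(1L, ne %/% 10L))] <- TRUE
    mcols(elements)$antisense <- anti
    # sense strand of the nearest gene, for the antisense component
    ng <- annotateNearestGene(elements, genes)
    gstr <- setNames(as.character(strand(genes)), mcols(genes)$gene_id)
    mcols(elements)$gene_id <- ng
    mcols(elements)$gene_strand <- unname(gstr[ng])

    new("SimTruth", genes = genes, elements = elements,
        preset = preset, config = cfg)
}

# Internal: simulate reads for one sample (condition x replicate).
.simulateGroSample <- function(truth, cfg, condition, replicate,
                               depthScale) {
    genes <- truth@genes
    lamCol <- if (condition == "control") "lambda_control"
        else "lambda_treated"
    kapCol <- if (condition == "control") "kappa_control"
        else "kappa_treated"
    bw <- 50L
    posL <- list(); chrL <- list(); strL <- list()
    for (i in seq_along(genes)) {
        g <- genes[i]
        lam <- mcols(genes)[[lamCol]][i]
        kap <- mcols(genes)[[kapCol]][i]
        L <- width(g) + 300L
        nb <- ceiling(L / bw)
        dmid <- (seq_len(nb) - 0.5) * bw          # bp from TSS
        mu <- depthScale * lam * exp(-kap * dmid / 1000) *
            ifelse(dmid < 300, cfg@pauseBoost, 1)
        cnt <- .rnb(nb, mu, cfg@dispersion)
        tot <- sum(cnt)
        if (!tot) next
        offs <- rep((seq_len(nb) - 1L) * bw, cnt) +
            sample.int(bw, tot, replace = TRUE) - 1L
        offs <- offs[offs < L]
        minus <- as.character(strand(g)) == "-"
        tss <- if (minus) end(g) else start(g)
        pos <- if (minus) tss - offs else tss + offs
        posL[[length(posL) + 1L]] <- pos
        chrL[[length(chrL) + 1L]] <- rep(as.character(seqnames(g)),
                                         length(pos))
        strL[[length(strL) + 1L]] <- rep(if (minus) "-" else "+",
                                         length(pos))
    }
    # uniform background on both strands; an aggregate of many
    # independent low-rate positions, hence Poisson, not per-unit NB
    nbg <- rpois(1L, cfg@groDepth * .GRO_BG_FRAC)
    if (nbg > 0) {
        chromLens <- setNames(rep(cfg@chromLen, cfg@nChroms),
                              paste0("chr", seq_len(cfg@nChroms)))
        bgc <- sample(names(chromLens), nbg, replace = TRUE)
        bgp <- sample.int(cfg@chromLen, nbg, replace = TRUE)
        posL[[length(posL) + 1L]] <- bgp
        chrL[[length(chrL) + 1L]] <- bgc
        strL[[length(strL) + 1L]] <- sample(c("+", "-"), nbg, TRUE)
    }
    # treated-only antisense bursts at flagged elements
    el <- truth@elements
    flag <- which(mcols(el)$antisense & condition == "treated" &
                      !is.na(mcols(el)$gene_strand))
    for (i in flag) {
        nA <- .rnb(1L, 100, cfg@dispersion)
        if (!nA) next
        ctr <- floor((start(el)[i] + end(el)[i]) / 2)
        p <- pmax(1L, pmin(cfg@chromLen,
                           round(rnorm(nA, ctr, 150))))
        posL[[length(posL) + 1L]] <- p
        chrL[[length(chrL) + 1L]] <- rep(as.character(seqnames(el))[i],
                                         nA)
        strL[[length(strL) + 1L]] <-
            rep(if (mcols(el)$gene_strand[i] == "+") "-" else "+", nA)
    }
    pos <- unlist(posL); chrom <- unlist(chrL); str <- unlist(strL)
    pos <- pmax(pos, 1L)
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = str)
    gr <- gr[order(as.character(seqnames(gr)), start(gr),
                   as.character(strand(gr)))]
    ReadSet(gr, sampleId = paste0("gro_", condition, "_rep", replicate),
            condition = condition, replicate = replicate)
}

#' Simulate stranded nascent-transcription reads
#'
#' Expected sense-read count in a 50 bp bin at distance \eqn{d} kb from
#' the TSS of gene \eqn{g} under condition \eqn{c} is
#' \deqn{\mu = depth \cdot \lambda_{g,c} \cdot e^{-\kappa_{g,c} d}
#'   \cdot boost(d)}
#' with the pause boost applied within the first 300 bp. Counts are
#' negative-binomial with dispersion \code{phi}, independent per
#' replicate; signal extends 300 bp past the TES; a small uniform
#' background is added on both strands. Deterministic under the
#' configured seed.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param cfg the generating \linkS4class{SimConfig}.
#' @return named list of \linkS4class{ReadSet}s, one per condition x
#'   replicate (conditions \code{"control"} and \code{"treated"}).
#' @export
simulateGroseq <- function(truth, cfg) {
    set.seed(cfg@seed + 2L)
    genes <- truth@genes
    # calibrate depth so a control replicate totals ~groDepth reads
    bw <- 50
    expSum <- sum(vapply(seq_along(genes), function(i) {
        L <- width(genes)[i] + 300
        nb <- ceiling(L / bw)
        dmid <- (seq_len(nb) - 0.5) * bw
        sum(mcols(genes)$lambda_control[i] *
                exp(-mcols(genes)$kappa_control[i] * dmid / 1000) *
                ifelse(dmid < 300, cfg@pauseBoost, 1))
    }, numeric(1)))
    depthScale <- cfg@groDepth * (1 - .GRO_BG_FRAC) / expSum
    out <- list()
    for (cond in c("control", "treated")) {
        for (r in seq_len(cfg@nReplicates)) {
            rs <- .simulateGroSample(truth, cfg, cond, r, depthScale)
            out[[sampleId(rs)]] <- rs
        }
    }
    out
}

#' Simulate CUT&Tag fragments and true peaks
#'
#' Per element and replicate, the expected fragment count is
#' \code{fragDepth * occupancy}, negative-binomially realized; fragment
#' midpoints are normal around the element center (sd 60 bp) and
#' lengths normal (\code{fragLenMean}, \code{fragLenSd}) truncated to
#' [50, maxFragmentLen). Uniform background fragments are added
#' genome-wide. True peaks are element centers +/- 250 bp.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param cfg the generating \linkS4class{SimConfig}.
#' @return list with \code{fragmentSets} (named list of
#'   \linkS4class{FragmentSet}s) and \code{peaks}
#'   (\link[GenomicRanges]{GRanges} named by element id).
#' @export
simulateCuttag <- function(truth, cfg) {
    set.seed(cfg@seed + 3L)
    el <- truth@elements
    ctr <- floor((start(el) + end(el)) / 2)
    chrom <- as.character(seqnames(el))
    out <- list()
    rlen <- function(n) {
        pmin(pmax(round(rnorm(n, cfg@fragLenMean, cfg@fragLenSd)), 50L),
             cfg@maxFragmentLen - 1L)
    }
    # sequencing depth, not biology, sets the library total: the expected
    # per-replicate total is held equal across conditions by letting the
    # background compartment absorb the (small, pairing-balanced) excess
    # of element-bound signal
    excess <- cfg@fragDepth * (sum(mcols(el)$occupancy_treated) -
                               sum(mcols(el)$occupancy_control))
    bgMean <- c(control = cfg@bgFragsPerRep,
                treated = cfg@bgFragsPerRep - excess)
    if (any(bgMean <= 0))
        stop("element signal exceeds library capacity; ",
             "increase 'bgFragsPerRep'")
    for (cond in c("control", "treated")) {
        occ <- if (cond == "control") mcols(el)$occupancy_control
            else mcols(el)$occupancy_treated
        for (r in seq_len(cfg@nReplicates)) {
            cnt <- .rnb(length(el), cfg@fragDepth * occ, cfg@dispersion)
            mids <- round(rnorm(sum(cnt), rep(ctr, cnt), 60))
            lens <- rlen(sum(cnt))
            chr <- rep(chrom, cnt)
            # genome-wide background aggregates many independent sites:
            # Poisson total, uniform placement
            nbg <- rpois(1L, bgMean[[cond]])
            if (nbg > 0) {
                chr <- c(chr, sample(paste0("chr",
                                            seq_len(cfg@nChroms)),
                                     nbg, replace = TRUE))
                mids <- c(mids, sample.int(cfg@chromLen, nbg, TRUE))
                lens <- c(lens, rlen(nbg))
            }
            s <- pmax(1L, mids - lens %/% 2L)
            gr <- GRanges(chr, IRanges(s, width = lens))
            gr <- gr[order(as.character(seqnames(gr)), start(gr),
                           end(gr))]
            fs <- FragmentSet(gr,
                              sampleId = paste0("ct_", cond, "_rep", r),
                              condition = cond, replicate = r)
            out[[sampleId(fs)]] <- fs
        }
    }
    peaks <- GRanges(chrom, IRanges(pmax(ctr - 250L, 1L), ctr + 250L))
    mcols(peaks)$name <- mcols(el)$element_id
    list(fragmentSets = out, peaks = peaks)
}

#' Simulate a driver-silencing differential-expression table
#'
#' Planted induced targets receive strongly negative silencing fold
#' changes with tiny adjusted p; repressed targets the mirror image;
#' unaffected genes get near-zero fold changes and adjusted p of at
#' least 0.02, so re-applying the classification thresholds recovers
#' the planted labels exactly.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return data.frame with \code{gene_id}, \code{log2FoldChange},
#'   \code{padj}.
#' @export
simulateDETable <- function(truth) {
    cfg <- truth@config
    set.seed(cfg@seed + 4L)
    lab <- mcols(truth@genes)$target_class
    n <- length(lab)
    lfc <- rnorm(n, 0, 0.3)
    padj <- runif(n, 0.02, 1)
    ind <- lab == "induced"
    rep_ <- lab == "repressed"
    lfc[ind] <- -runif(sum(ind), 1.5, 3.5)
    lfc[rep_] <- runif(sum(rep_), 1.5, 3.5)
    padj[ind | rep_] <- 10^-runif(sum(ind | rep_), 3, 8)
    data.frame(gene_id = mcols(truth@genes)$gene_id,
               log2FoldChange = lfc, padj = padj,
               stringsAsFactors = FALSE)
}

#' Write planted-truth tables as TSV
#'
#' Numeric values are written with full precision so a write/read
#' round-trip is exact.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths (genes, elements).
#' @export
writeTruthTables <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- truth@genes
    gdf <- data.frame(
        gene_id = mcols(g)$gene_id,
        chrom = as.character(seqnames(g)),
        start = start(g) - 1L, end = end(g),
        strand = as.character(strand(g)),
        length = width(g),
        lambda_control = mcols(g)$lambda_control,
        lambda_treated = mcols(g)$lambda_treated,
        kappa_control = mcols(g)$kappa_control,
        kappa_treated = mcols(g)$kappa_treated,
        target_class = mcols(g)$target_class,
        stringsAsFactors = FALSE)
    e <- truth@elements
    edf <- data.frame(
        element_id = mcols(e)$element_id,
        chrom = as.character(seqnames(e)),
        start = start(e) - 1L, end = end(e),
        element_class = mcols(e)$element_class,
        unit_count = mcols(e)$unit_count,
        occupancy_control = mcols(e)$occupancy_control,
        occupancy_treated = mcols(e)$occupancy_treated,
        delta_log2_occupancy = mcols(e)$delta_log2_occupancy,
        antisense = mcols(e)$antisense,
        gene_id = mcols(e)$gene_id,
        stringsAsFactors = FALSE)
    gp <- file.path(dir, "truth_genes.tsv")
    ep <- file.path(dir, "truth_elements.tsv")
    .writeTsv(gdf, gp)
    .writeTsv(edf, ep)
    c(genes = gp, elements = ep)
}

#' Simulate a complete experiment
#'
#' Genome, gene models, planted elements, ground truth under a preset,
#' nascent-transcription read sets, CUT&Tag fragment sets with true
#' peaks, and a driver-silencing DE table.
#'
#' @param preset \code{"lce"}, \code{"hce"} or \code{"null"}.
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with components \code{genome}, \code{genes},
#'   \code{elements}, \code{truth}, \code{readSets},
#'   \code{fragmentSets}, \code{peaks}, \code{deTable}.
#' @export
simulateExperiment <- function(preset = c("lce", "hce", "null"),
                               cfg = simConfig()) {
    preset <- match.arg(preset)
    sim <- simulateGenome(cfg)
    truth <- buildSimTruth(sim, preset, cfg)
    reads <- simulateGroseq(truth, cfg)
    ct <- simulateCuttag(truth, cfg)
    de <- simulateDETable(truth)
    list(genome = sim$genome, genes = truth@genes,
         elements = truth@elements, truth = truth,
         readSets = reads, fragmentSets = ct$fragmentSets,
         peaks = ct$peaks, deTable = de)
}
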