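#' @importFrom stats wilcox.test median lm coef
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowRanges
NULL

#' TSS / gene-body / TES quantitation windows
#'
#' In transcription coordinates the three windows tile
#' \code{[TSS - 300, TES + 300)}: the TSS window is
#' \code{[TSS - 300, TSS + 30)}, the gene body
#' \code{[TSS + 30, TES - 30)} and the TES window
#' \code{[TES - 30, TES + 300)}. Windows are mapped back to genome
#' coordinates respecting strand. Genes of length 60 bp or less have an
#' empty body and are excluded with a warning.
#'
#' @param genes stranded \link[GenomicRanges]{GRanges} with
#'   \code{gene_id}.
#' @return list of three \link[GenomicRanges]{GRanges} (\code{tss},
#'   \code{body}, \code{tes}), parallel to the retained genes, each
#'   stranded like its gene and carrying \code{gene_id}; plus
#'   \code{genes}, the retained gene models.
#' @export
geneWindows <- function(genes) {
    ok <- width(genes) > 60L
    if (any(!ok)) {
        warning(sum(!ok), " gene(s) of length <= 60 bp excluded ",
                "(empty gene body)")
        genes <- genes[ok]
    }
    if (!length(genes)) stop("no genes longer than 60 bp")
    s <- start(genes)
    e <- end(genes)
    minus <- as.character(strand(genes)) == "-"
    chrom <- as.character(seqnames(genes))
    st <- as.character(strand(genes))
    gid <- mcols(genes)$gene_id
    mk <- function(a, b) {
        gr <- GRanges(chrom, IRanges(pmax(a, 1L), b), strand = st)
        mcols(gr)$gene_id <- gid
        gr
    }
    # plus strand: tss [s-300, s+29], body [s+30, e-30], tes [e-29, e+300]
    tss <- mk(ifelse(minus, e - 29L, s - 300L),
              ifelse(minus, e + 300L, s + 29L))
    body <- mk(s + 30L, e - 30L)
    tes <- mk(ifelse(minus, s - 300L, e - 29L),
              ifelse(minus, s + 29L, e + 300L))
    list(tss = tss, body = body, tes = tes, genes = genes)
}

#' Count sense-strand reads in gene windows
#'
#' A read counts toward a window iff its 5'-end position lies inside the
#' window and its strand matches the gene's strand (sense-only
#' counting).
#'
#' @param readSets a \linkS4class{ReadSet} or list of them.
#' @param windows output of \code{\link{geneWindows}}.
#' @return a \link[SummarizedExperiment]{RangedSummarizedExperiment}
#'   with assays \code{tss}, \code{body}, \code{tes} (gene x sample read
#'   counts); \code{colData} carries \code{sample_id}, \code{condition},
#'   \code{replicate}, \code{library_size}.
#' @export
countWindowReads <- function(readSets, windows) {
    if (is(readSets, "SampleIntervalSet")) readSets <- list(readSets)
    one <- function(win) {
        vapply(readSets, function(rs) {
            countOverlaps(win, intervals(rs), ignore.strand = FALSE)
        }, integer(length(win)))
    }
    gid <- mcols(windows$genes)$gene_id
    sids <- vapply(readSets, sampleId, "")
    shape <- function(m) {
        m <- matrix(m, nrow = length(gid), dimnames = list(gid, sids))
        m
    }
    SummarizedExperiment(
        assays = list(tss = shape(one(windows$tss)),
                      body = shape(one(windows$body)),
                      tes = shape(one(windows$tes))),
        rowRanges = windows$genes,
        colData = DataFrame(
            sample_id = sids,
            condition = vapply(readSets, sampleCondition, ""),
            replicate = vapply(readSets, sampleReplicate, 1L),
            library_size = vapply(readSets, librarySize, 1L),
            row.names = sids)
    )
}

#' Window CPM values
#'
#' @param wc result of \code{\link{countWindowReads}}.
#' @param which one of \code{"tss"}, \code{"body"}, \code{"tes"}.
#' @return CPM matrix (genes x samples).
#' @export
windowCPM <- function(wc, which = c("tss", "body", "tes")) {
    which <- match.arg(which)
    cpmNormalize(assay(wc, which), colData(wc)$library_size)
}

# Internal: pooled (summed counts, summed library sizes) CPM per
# condition for one window assay.
.pooledCPM <- function(wc, which, condition) {
    sel <- colData(wc)$condition == condition
    if (!any(sel))
        stop("no samples with condition '", condition, "'")
    cnt <- rowSums(assay(wc, which)[, sel, drop = FALSE])
    cnt * 1e6 / sum(colData(wc)$library_size[sel])
}

#' Elongation (processivity) index
#'
#' For each gene and condition the index is
#' \code{ei = log2((tes_cpm + psi) / (tss_cpm + psi))} on
#' replicate-pooled CPM; \code{delta_ei = ei_treated - ei_control}. A
#' drop in the index under treatment indicates signal attrition along
#' the gene, i.e. impaired RNA-polymerase processivity, as opposed to a
#' change in initiation which moves TSS and TES signal together.
#'
#' @param wc result of \code{\link{countWindowReads}}.
#' @param control,treated condition labels.
#' @param psi CPM pseudocount (default 1).
#' @return data.frame with \code{gene_id}, \code{ei_control},
#'   \code{ei_treated}, \code{delta_ei}.
#' @export
elongationIndex <- function(wc, control = "control", treated = "treated",
                            psi = 1) {
    tssC <- .pooledCPM(wc, "tss", control)
    tssT <- .pooledCPM(wc, "tss", treated)
    tesC <- .pooledCPM(wc, "tes", control)
    tesT <- .pooledCPM(wc, "tes", treated)
    eiC <- log2((tesC + psi) / (tssC + psi))
    eiT <- log2((tesT + psi) / (tssT + psi))
    data.frame(gene_id = rownames(wc),
               ei_control = unname(eiC),
               ei_treated = unname(eiT),
               delta_ei = unname(eiT - eiC),
               stringsAsFactors = FALSE)
}

#' Mean delta-EI per gene-size tertile
#'
#' @param ei result of \code{\link{elongationIndex}}.
#' @param tertiles result of \code{\link{partitionByLengthTertiles}}.
#' @return named numeric vector (small, medium, large).
#' @export
meanDeltaEiByTertile <- function(ei, tertiles) {
    cls <- tertiles$classes[ei$gene_id]
    vapply(c("small", "medium", "large"),
           function(k) mean(ei$delta_ei[cls == k]), numeric(1))
}

# Internal: pooled 5'-end counts of a list of ReadSets on a set of bins.
.pooledBinCounts <- function(readSets, bins, ignoreStrand = TRUE) {
    cnt <- numeric(length(bins))
    lib <- 0
    for (rs in readSets) {
        cnt <- cnt + countOverlaps(bins, intervals(rs),
                                   ignore.strand = ignoreStrand)
        lib <- lib + librarySize(rs)
    }
    list(counts = cnt, librarySize = lib)
}

#' Binned log2-ratio coverage track
#'
#' Replicates are pooled by summed counts, CPM-scaled, and compared per
#' bin: \code{log2((cpm_t + psi) / (cpm_c + psi))}. The final bin of a
#' contig keeps its true (possibly partial) width.
#'
#' @param treatedSets,controlSets lists of \linkS4class{ReadSet}s.
#' @param seqlens named vector of contig lengths.
#' @param binWidth bin width in bp (default 50).
#' @param psi CPM pseudocount (default 1).
#' @return \link[GenomicRanges]{GRanges} of bins with metadata columns
#'   \code{cpm_control}, \code{cpm_treated}, \code{log2fc}.
#' @export
log2fcTrack <- function(treatedSets, controlSets, seqlens,
                        binWidth = 50L, psi = 1) {
    bins <- GenomicRanges::tileGenome(seqlens, tilewidth = binWidth,
                                      cut.last.tile.in.chrom = TRUE)
    trt <- .pooledBinCounts(treatedSets, bins)
    ctl <- .pooledBinCounts(controlSets, bins)
    cpmT <- trt$counts * 1e6 / trt$librarySize
    cpmC <- ctl$counts * 1e6 / ctl$librarySize
    mcols(bins)$cpm_control <- cpmC
    mcols(bins)$cpm_treated <- cpmT
    mcols(bins)$log2fc <- log2((cpmT + psi) / (cpmC + psi))
    bins
}

# Internal: per-gene column bins in transcription order.
# Returns GRanges of length ncol (flankBins + bodyBins + flankBins) on
# the gene's strand, plus the per-column width used for length weighting.
.geneColumnBins <- function(gene, flank, binWidth, bodyBins) {
    s <- start(gene); e <- end(gene)
    minus <- as.character(strand(gene)) == "-"
    chrom <- as.character(seqnames(gene))
    fb <- flank %/% binWidth
    # body column boundaries (0-based offsets within the gene)
    L <- e - s + 1L
    cuts <- floor(seq(0, L, length.out = bodyBins + 1L))
    bs <- s + cuts[-length(cuts)]
    be <- s + cuts[-1L] - 1L
    if (minus) {
        ups <- rev(seq(e + 1L, e + flank, by = binWidth))
        upBins <- IRanges(ups, width = binWidth)
        dns <- rev(seq(s - flank, s - 1L, by = binWidth))
        dnBins <- IRanges(dns, width = binWidth)
        bodyBinsR <- IRanges(rev(bs), rev(be))
        ir <- c(upBins, bodyBinsR, dnBins)
    } else {
        upBins <- IRanges(seq(s - flank, s - 1L, by = binWidth),
                          width = binWidth)
        dnBins <- IRanges(seq(e + 1L, e + flank, by = binWidth),
                          width = binWidth)
        ir <- c(upBins, IRanges(bs, be), dnBins)
    }
    gr <- GRanges(chrom, ir, strand = if (minus) "-" else "+")
    gr
}

#' Scaled-regions metagene log2-ratio matrix
#'
#' Each gene is mapped to a fixed number of columns: \code{flank /
#' binWidth} fixed-width bins upstream of the TSS, \code{bodyBins}
#' columns resampling the gene body by length-weighted averaging, and
#' \code{flank / binWidth} bins downstream of the TES. Values are
#' \code{log2((cpm_t + psi) / (cpm_c + psi))} of sense-strand binned CPM
#' coverage, with each column's count scaled to a per-\code{binWidth}-bp
#' equivalent so body columns of different genomic width are comparable.
#' Minus-strand genes are reversed into transcription orientation.
#' Columns clipped by a contig edge are \code{NA}.
#'
#' In \code{mode = "reference"} the matrix instead centers on the TSS
#' with \code{2 * flank / binWidth} fixed-width columns and no body
#' scaling.
#'
#' @param treatedSets,controlSets lists of \linkS4class{ReadSet}s.
#' @param genes stranded \link[GenomicRanges]{GRanges} with
#'   \code{gene_id}.
#' @param flank flank size in bp (default 3000).
#' @param binWidth flank bin width in bp (default 50).
#' @param bodyBins body pseudo-length in columns (default 100).
#' @param psi CPM pseudocount (default 1).
#' @param mode \code{"scale"} (TSS-to-TES) or \code{"reference"}
#'   (TSS-centered).
#' @param seqlens optional contig lengths for edge clipping.
#' @return list with \code{matrix} (genes x columns), \code{profile}
#'   (data.frame of column index, column label and mean), and
#'   \code{columnType} (\code{"flank5"}, \code{"body"}, \code{"flank3"}
#'   or \code{"ref"}).
#' @export
scaledMetagene <- function(treatedSets, controlSets, genes,
                           flank = 3000L, binWidth = 50L,
                           bodyBins = 100L, psi = 1,
                           mode = c("scale", "reference"),
                           seqlens = NULL) {
    mode <- match.arg(mode)
    if (flank %% binWidth != 0L)
        stop("'flank' must be divisible by 'binWidth'")
    fb <- flank %/% binWidth
    if (mode == "scale") {
        keep <- width(genes) > 2L * binWidth
        genes <- genes[keep]
        ncolM <- 2L * fb + bodyBins
        colType <- c(rep("flank5", fb), rep("body", bodyBins),
                     rep("flank3", fb))
    } else {
        ncolM <- 2L * fb
        colType <- rep("ref", ncolM)
    }
    if (!length(genes)) stop("no eligible genes")
    n <- length(genes)
    lvl <- unique(as.character(seqnames(genes)))
    # gather all column bins, then count once per condition
    binList <- vector("list", n)
    for (i in seq_len(n)) {
        g <- genes[i]
        if (mode == "scale") {
            binList[[i]] <- .geneColumnBins(g, flank, binWidth, bodyBins)
        } else {
            minus <- as.character(strand(g)) == "-"
            tss <- if (minus) end(g) else start(g)
            offs <- seq(-flank, flank - binWidth, by = binWidth)
            starts <- if (minus) tss - offs - binWidth + 1L else tss + offs
            ir <- IRanges(starts, width = binWidth)
            binList[[i]] <- GRanges(as.character(seqnames(g)), ir,
                                    strand = as.character(strand(g)))
        }
        GenomeInfoDb::seqlevels(binList[[i]]) <- lvl
    }
    allBins <- do.call(c, binList)
    clipped <- start(allBins) < 1L
    if (!is.null(seqlens)) {
        lim <- unname(seqlens[as.character(seqnames(allBins))])
        clipped <- clipped | end(allBins) > lim
    }
    # shift invalid bins into range for counting; values become NA below
    start(allBins)[start(allBins) < 1L] <- 1L
    trt <- .pooledBinCounts(treatedSets, allBins, ignoreStrand = FALSE)
    ctl <- .pooledBinCounts(controlSets, allBins, ignoreStrand = FALSE)
    w <- width(allBins)
    scale_t <- 1e6 / trt$librarySize * (binWidth / w)
    scale_c <- 1e6 / ctl$librarySize * (binWidth / w)
    val <- log2((trt$counts * scale_t + psi) /
                (ctl$counts * scale_c + psi))
    val[clipped | w == 0L] <- NA_real_
    m <- matrix(val, nrow = n, byrow = TRUE,
                dimnames = list(mcols(genes)$gene_id, NULL))
    profile <- data.frame(
        column = seq_len(ncolM),
        type = colType,
        mean = colMeans(m, na.rm = TRUE)
    )
    list(matrix = m, profile = profile, columnType = colType)
}

#' Fitted slope of the metagene profile across body columns
#'
#' Ordinary least-squares slope of the column-mean log2-ratio profile
#' over the gene-body columns, in log2 units per body column. A
#' body-flat profile (initiation-only perturbation) has slope near zero;
#' distance-dependent attrition yields a negative slope.
#'
#' @param metagene result of \code{\link{scaledMetagene}} in
#'   \code{"scale"} mode.
#' @return the slope (log2 units per column).
#' @export
metageneBodySlope <- function(metagene) {
    sel <- metagene$profile$type == "body"
    y <- metagene$profile$mean[sel]
    x <- seq_along(y)
    unname(coef(lm(y ~ x))[2L])
}

#' Scale a group of tracks to the control maximum
#'
#' All tracks in the group are divided by the control track's maximum,
#' so the control scales to a maximum of exactly 1.
#'
#' @param tracks list of numeric vectors (or a single vector).
#' @param control numeric control track with a positive maximum.
#' @return list of scaled tracks (or a single vector).
#' @export
groupScale <- function(tracks, control) {
    m <- max(control, na.rm = TRUE)
    if (!is.finite(m) || m <= 0)
        stop("control track must have a positive maximum")
    if (is.numeric(tracks)) return(tracks / m)
    lapply(tracks, function(t) t / m)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @return the two-sided p-value.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))  # exact 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- (length(x) + length(y) <= 12L) && !ties
    p <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value
    )
    # fully tied samples: zero-variance statistic, no evidence -> p = 1
    if (is.nan(p)) p <- 1
    p
}

#' TES signal statistics per target class
#'
#' For each target class, collects per-gene per-replicate
#' \code{log10(CPM + 1)} values of TES-window signal in each condition,
#' summarizes them (median and quartiles), and compares conditions with
#' a two-sided Wilcoxon rank-sum test.
#'
#' @param wc result of \code{\link{countWindowReads}}.
#' @param targets result of \code{\link{classifyTargets}}.
#' @param control,treated condition labels.
#' @return list with \code{summary} (data.frame: class, condition, n,
#'   median, q25, q75) and \code{tests} (data.frame: class, p).
#'   Empty classes are skipped with a warning.
#' @export
tesGroupStats <- function(wc, targets, control = "control",
                          treated = "treated") {
    cpm <- windowCPM(wc, "tes")
    val <- log10(cpm + 1)
    cond <- colData(wc)$condition
    cls <- setNames(targets$target_class, targets$gene_id)[rownames(val)]
    sm <- list(); ts <- list()
    for (k in c("induced", "repressed", "neither")) {
        rows <- which(!is.na(cls) & cls == k)
        if (!length(rows)) {
            warning("no genes in target class '", k, "'; skipped")
            next
        }
        vc <- as.vector(val[rows, cond == control, drop = FALSE])
        vt <- as.vector(val[rows, cond == treated, drop = FALSE])
        sm[[paste(k, "control")]] <- data.frame(
            class = k, condition = control, n = length(vc),
            median = median(vc), q25 = unname(quantile(vc, 0.25)),
            q75 = unname(quantile(vc, 0.75)))
        sm[[paste(k, "treated")]] <- data.frame(
            class = k, condition = treated, n = length(vt),
            median = median(vt), q25 = unname(quantile(vt, 0.25)),
            q75 = unname(quantile(vt, 0.75)))
        ts[[k]] <- data.frame(class = k, p = wilcoxonRankSum(vt, vc))
    }
    list(summary = do.call(rbind, c(sm, list(make.row.names = FALSE))),
         tests = do.call(rbind, c(ts, list(make.row.names = FALSE))))
}

#' Antisense initiation at binding peaks
#'
#' Counts reads on the strand opposite the annotated gene within
#' \code{center +/- flank} of each peak, per condition (replicates
#' pooled), and reports the pseudocounted CPM log2 ratio. Peaks without
#' a sense-strand annotation are skipped with a warning.
#'
#' @param treatedSets,controlSets lists of \linkS4class{ReadSet}s.
#' @param peaks \link[GenomicRanges]{GRanges} whose strand is the
#'   annotated gene's (sense) strand; \code{*} means unannotated.
#' @param flank half-window in bp (default 1000).
#' @param psi CPM pseudocount (default 1).
#' @return data.frame with \code{peak_id}, \code{antisense_cpm_control},
#'   \code{antisense_cpm_treated}, \code{log2fc}.
#' @export
antisenseInitiation <- function(treatedSets, controlSets, peaks,
                                flank = 1000L, psi = 1) {
    sense <- as.character(strand(peaks))
    bad <- sense == "*"
    if (any(bad)) {
        warning(sum(bad), " unannotated peak(s) skipped")
        peaks <- peaks[!bad]
        sense <- sense[!bad]
    }
    if (!length(peaks))
        return(data.frame(peak_id = character(),
                          antisense_cpm_control = numeric(),
                          antisense_cpm_treated = numeric(),
                          log2fc = numeric()))
    mid <- floor((start(peaks) + end(peaks)) / 2)
    anti <- ifelse(sense == "+", "-", "+")
    win <- GRanges(seqnames(peaks),
                   IRanges(pmax(mid - flank, 1L), mid + flank),
                   strand = anti)
    trt <- .pooledBinCounts(treatedSets, win, ignoreStrand = FALSE)
    ctl <- .pooledBinCounts(controlSets, win, ignoreStrand = FALSE)
    cpmT <- trt$counts * 1e6 / trt$librarySize
    cpmC <- ctl$counts * 1e6 / ctl$librarySize
    data.frame(
        peak_id = mcols(peaks)$name %||%
            paste0("peak_", seq_along(peaks)),
        antisense_cpm_control = cpmC,
        antisense_cpm_treated = cpmT,
        log2fc = log2((cpmT + psi) / (cpmC + psi)),
        stringsAsFactors = FALSE
    )
}
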