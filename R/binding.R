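#' @importFrom stats p.adjust t.test cor phyper setNames
#' @importFrom GenomicRanges countOverlaps findOverlaps
NULL

#' Load CUT&Tag fragments from BED6
#'
#' Reads fragment intervals and applies the fragment-length filter:
#' fragments of length \code{maxFragmentLen} bp or more are removed
#' (lengths strictly below the maximum are kept). The library size is
#' the post-filter fragment count.
#'
#' @param path BED file (>= 3 columns).
#' @param sampleId,condition,replicate sample annotation.
#' @param maxFragmentLen length cutoff in bp (default 1000).
#' @return a \linkS4class{FragmentSet}.
#' @export
loadFragments <- function(path, sampleId = basename(path),
                          condition = "control", replicate = 1L,
                          maxFragmentLen = 1000L) {
    gr <- readBed6(path)
    strand(gr) <- "*"
    keep <- width(gr) < maxFragmentLen
    if (any(!keep))
        message(sum(!keep), " fragment(s) of length >= ", maxFragmentLen,
                " bp removed from ", sampleId)
    FragmentSet(gr[keep], sampleId = sampleId, condition = condition,
                replicate = replicate)
}

#' Load stranded read 5' ends from BED6
#'
#' @param path BED6 file of 1 bp stranded intervals.
#' @param sampleId,condition,replicate sample annotation.
#' @return a \linkS4class{ReadSet}.
#' @export
loadReads <- function(path, sampleId = basename(path),
                      condition = "control", replicate = 1L) {
    ReadSet(readBed6(path), sampleId = sampleId, condition = condition,
            replicate = replicate)
}

# Internal: named, sorted peak GRanges from BED or GRanges.
.asPeaks <- function(peaks) {
    if (!"name" %in% names(mcols(peaks)))
        mcols(peaks)$name <- paste0("peak_", seq_along(peaks))
    if (anyDuplicated(mcols(peaks)$name))
        stop("peak names must be unique")
    .positionSort(peaks)
}

#' Count fragments per peak
#'
#' A fragment contributes 1 to every peak it overlaps by at least 1 bp
#' (half-open semantics: abutting intervals do not overlap).
#'
#' @param fragSets a \linkS4class{FragmentSet} or list of them.
#' @param peaks \link[GenomicRanges]{GRanges} with unique \code{name}s
#'   (added if absent).
#' @return integer matrix (peaks x samples) with dimnames.
#' @export
countFragments <- function(fragSets, peaks) {
    if (is(fragSets, "SampleIntervalSet")) fragSets <- list(fragSets)
    peaks <- .asPeaks(peaks)
    counts <- vapply(fragSets, function(fs) {
        countOverlaps(peaks, intervals(fs), minoverlap = 1L,
                      ignore.strand = TRUE)
    }, integer(length(peaks)))
    counts <- matrix(counts, nrow = length(peaks),
                     dimnames = list(mcols(peaks)$name,
                                     vapply(fragSets, sampleId, "")))
    counts
}

#' Counts-per-million normalization
#'
#' \code{cpm = count * 1e6 / library_size}, per sample column.
#'
#' @param counts matrix (features x samples).
#' @param librarySizes numeric vector, one per column.
#' @param pseudocount added to counts before scaling (default 0).
#' @return numeric matrix of the same shape.
#' @export
cpmNormalize <- function(counts, librarySizes, pseudocount = 0) {
    if (length(librarySizes) != ncol(counts))
        stop("need one library size per sample column")
    if (any(librarySizes <= 0))
        stop("library sizes must be positive")
    sweep(counts + pseudocount, 2L, librarySizes, "/") * 1e6
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotone
#' enforcement; input order preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhFDR <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Differential binding between two conditions
#'
#' Per peak: condition means of CPM, a pseudocounted log2 fold change
#' \code{log2((mean_treated + psi) / (mean_control + psi))}, a two-sided
#' per-peak location test on \code{log2(cpm + psi)} across replicates,
#' and Benjamini-Hochberg FDR over all peaks.
#'
#' The default test is a moderated t (limma: peak-wise linear model with
#' empirical-Bayes variance shrinkage across peaks), the standard remedy
#' for the low per-peak degrees of freedom of typical replicate counts.
#' \code{method = "welch"} gives a plain unequal-variance Welch t
#' instead; with Welch, peaks whose log-CPM values are constant within
#' both groups are assigned p = 1 when the groups are equal and p = 0
#' otherwise.
#'
#' @param cpm matrix (peaks x samples) of CPM values.
#' @param conditions character vector naming each column's condition.
#' @param control,treated the two condition labels to compare.
#' @param psi pseudocount in CPM units (default 1).
#' @param fdrCut significance threshold on FDR (default 0.05).
#' @param method \code{"moderated"} (default) or \code{"welch"}.
#' @return data.frame with columns \code{peak_id},
#'   \code{mean_cpm_control}, \code{mean_cpm_treated}, \code{log2fc},
#'   \code{p}, \code{fdr}, \code{significant}.
#' @export
differentialBinding <- function(cpm, conditions, control = "control",
                                treated = "treated", psi = 1,
                                fdrCut = 0.05,
                                method = c("moderated", "welch")) {
    method <- match.arg(method)
    if (length(conditions) != ncol(cpm))
        stop("need one condition label per sample column")
    ci <- which(conditions == control)
    ti <- which(conditions == treated)
    if (length(ci) < 2L || length(ti) < 2L)
        stop("need >= 2 replicates in each condition")
    mc <- rowMeans(cpm[, ci, drop = FALSE])
    mt <- rowMeans(cpm[, ti, drop = FALSE])
    l2 <- log2(cpm + psi)
    if (method == "moderated") {
        design <- cbind(intercept = 1,
                        treat = rep(c(0, 1), c(length(ci), length(ti))))
        fit <- limma::lmFit(l2[, c(ci, ti), drop = FALSE], design)
        fit <- limma::eBayes(fit)
        pvals <- unname(fit$p.value[, "treat"])
        pvals[is.na(pvals)] <- 1
    } else {
        pvals <- vapply(seq_len(nrow(cpm)), function(i) {
            x <- l2[i, ti]
            y <- l2[i, ci]
            if (diff(range(x)) == 0 && diff(range(y)) == 0) {
                if (x[1L] == y[1L]) 1 else 0
            } else {
                t.test(x, y, var.equal = FALSE)$p.value
            }
        }, numeric(1))
    }
    fdr <- bhFDR(pvals)
    data.frame(
        peak_id = rownames(cpm) %||% paste0("peak_", seq_len(nrow(cpm))),
        mean_cpm_control = mc,
        mean_cpm_treated = mt,
        log2fc = log2((mt + psi) / (mc + psi)),
        p = pvals,
        fdr = fdr,
        significant = fdr < fdrCut,
        row.names = NULL,
        stringsAsFactors = FALSE
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of fragments in peaks (FRiP)
#'
#' @param fragSet a \linkS4class{FragmentSet}.
#' @param peaks \link[GenomicRanges]{GRanges}.
#' @return fraction in [0, 1] of fragments overlapping at least one peak.
#' @export
frip <- function(fragSet, peaks) {
    if (librarySize(fragSet) == 0L)
        stop("empty fragment set: FRiP undefined")
    hits <- countOverlaps(intervals(fragSet), peaks, minoverlap = 1L,
                          ignore.strand = TRUE) > 0L
    sum(hits) / librarySize(fragSet)
}

#' Pairwise Spearman correlation of samples
#'
#' Spearman correlation (mid-rank Pearson) of per-peak signal between
#' every pair of samples. A constant column has an undefined correlation
#' and yields \code{NA}, never 0.
#'
#' @param cpm matrix (features x samples), >= 2 columns.
#' @return symmetric samples x samples matrix.
#' @export
replicateCorrelation <- function(cpm) {
    if (ncol(cpm) < 2L) stop("need >= 2 samples")
    suppressWarnings(cor(cpm, method = "spearman"))
}

#' Element-centered fragment metaprofile
#'
#' Per-site binned CPM fragment coverage on \code{center +/- flank}. A
#' bin value is the number of fragments overlapping the bin, scaled to
#' CPM. Minus-strand sites are reversed so the left edge of the matrix
#' is always upstream of the element. Bins clipped by a contig edge are
#' set to \code{NA} and excluded from column means.
#'
#' @param fragSet a \linkS4class{FragmentSet}.
#' @param centers \link[GenomicRanges]{GRanges} of sites (midpoints are
#'   used as centers; strand orients the profile).
#' @param flank half-window in bp (default 1500).
#' @param binWidth bin width in bp (default 10); must divide
#'   \code{flank}.
#' @param seqlens optional named vector of contig lengths for edge
#'   clipping.
#' @return list with \code{matrix} (sites x bins, CPM), \code{profile}
#'   (data.frame of bin offset midpoints and column means), and
#'   \code{binOffsets}.
#' @export
siteMetaprofile <- function(fragSet, centers, flank = 1500L,
                            binWidth = 10L, seqlens = NULL) {
    if (flank %% binWidth != 0L)
        stop("'flank' must be divisible by 'binWidth'")
    nbin <- 2L * flank %/% binWidth
    n <- length(centers)
    offs <- seq(-flank, flank - binWidth, by = binWidth)
    mid <- floor((start(centers) + end(centers)) / 2)
    chrom <- as.character(seqnames(centers))
    minus <- as.character(strand(centers)) == "-"
    # genomic bin starts for every site x bin (sites vary only by offset)
    binStart <- outer(mid, offs, "+")            # n x nbin, 1-based
    binEnd <- binStart + binWidth - 1L
    allBins <- GRanges(rep(chrom, nbin),
                       IRanges(pmax(as.vector(binStart), 1L),
                               pmax(as.vector(binEnd), 1L)))
    cnt <- countOverlaps(allBins, intervals(fragSet), minoverlap = 1L,
                         ignore.strand = TRUE)
    m <- matrix(as.numeric(cnt), nrow = n)
    # clip: bins extending beyond the contig are undefined
    clipLo <- as.vector(binStart) < 1L
    clip <- matrix(clipLo, nrow = n)
    if (!is.null(seqlens)) {
        lim <- unname(seqlens[chrom])
        clip <- clip | matrix(as.vector(binEnd) > rep(lim, nbin),
                              nrow = n)
    }
    m[clip] <- NA_real_
    m <- m * 1e6 / librarySize(fragSet)
    if (any(minus)) m[minus, ] <- m[minus, nbin:1L, drop = FALSE]
    rownames(m) <- if (!is.null(names(centers))) names(centers)
    profile <- data.frame(
        offset = offs + binWidth / 2,
        mean = colMeans(m, na.rm = TRUE)
    )
    list(matrix = m, profile = profile, binOffsets = offs)
}

#' Hypergeometric known-motif enrichment
#'
#' Upper-tail (cumulative) hypergeometric probability of observing at
#' least \code{fgWith} motif-bearing sites in a foreground of
#' \code{fgTotal} drawn from a background universe of \code{bgTotal}
#' sites of which \code{bgWith} bear the motif:
#' \eqn{P[X \ge fgWith]} for
#' \eqn{X \sim Hypergeom(N = bgTotal, K = bgWith, n = fgTotal)}.
#'
#' @param fgWith,fgTotal foreground counts.
#' @param bgWith,bgTotal background (universe) counts.
#' @return the upper-tail p-value.
#' @export
motifEnrichmentHypergeom <- function(fgWith, fgTotal, bgWith, bgTotal) {
    if (fgWith > fgTotal) stop("fgWith must be <= fgTotal")
    if (bgWith > bgTotal) stop("bgWith must be <= bgTotal")
    if (fgTotal > bgTotal) stop("foreground must be drawn from background")
    if (fgWith > bgWith) stop("fgWith must be <= bgWith")
    phyper(fgWith - 1, bgWith, bgTotal - bgWith, fgTotal,
           lower.tail = FALSE)
}
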