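#' @importFrom Biostrings DNAString DNAStringSet matchPattern
#'   reverseComplement
NULL

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# Internal: coerce to DNAString, rejecting anything outside the IUPAC
# nucleotide alphabet.
.asDNA <- function(seq, what = "sequence") {
    if (is(seq, "DNAString")) return(seq)
    s <- toupper(as.character(seq))
    letters <- unique(strsplit(s, "")[[1L]])
    bad <- setdiff(letters, names(.IUPAC))
    if (length(bad))
        stop("invalid nucleotide letter(s) in ", what, ": ",
             paste(bad, collapse = ", "))
    DNAString(s)
}

# Internal: views -> GRanges on a given strand with matched sequence.
.viewsToSites <- function(v, chrom, strand, motif_name) {
    n <- length(v)
    if (!n) return(.emptySites())
    GRanges(chrom,
            IRanges(BiocGenerics::start(v), BiocGenerics::end(v)),
            strand = strand,
            motif_name = rep(motif_name, n),
            matched_seq = as.character(v))
}

.emptySites <- function() {
    gr <- GRanges()
    mcols(gr)$motif_name <- character()
    mcols(gr)$matched_seq <- character()
    gr
}

# concatenate GRanges pieces, dropping empties (their empty seqinfo
# would otherwise trigger merge warnings)
.bindSites <- function(...) {
    args <- list(...)
    pieces <- Filter(length, args)
    if (!length(pieces)) return(args[[1L]])
    if (length(pieces) == 1L) return(pieces[[1L]])
    suppressWarnings(do.call(c, pieces))
}

# Internal: drop matches whose subject sequence contains ambiguity codes;
# an N (or any other ambiguity letter) in the subject never matches.
.dropAmbiguousMatches <- function(gr) {
    if (!length(gr)) return(gr)
    gr[!grepl("[^ACGT]", mcols(gr)$matched_seq)]
}

#' Scan a sequence for GGAA core motifs
#'
#' Finds every occurrence of \code{GGAA} on the plus strand and of its
#' reverse complement \code{TTCC} on the minus strand, including
#' overlapping occurrences. \code{N} (and any other ambiguity letter) in
#' the subject never matches.
#'
#' @param seq nucleotide sequence (character or
#'   \link[Biostrings]{DNAString}); IUPAC letters only.
#' @param chrom sequence name for the returned coordinates.
#' @return \link[GenomicRanges]{GRanges} of motif sites sorted by start,
#'   with metadata columns \code{motif_name} (\code{"GGAA"}) and
#'   \code{matched_seq}.
#' @examples
#' scanGGAA("GGAAGGAAGG", "chr1")
#' @export
scanGGAA <- function(seq, chrom = "chr1") {
    subject <- .asDNA(seq)
    plus <- .viewsToSites(matchPattern("GGAA", subject), chrom, "+", "GGAA")
    minus <- .viewsToSites(matchPattern("TTCC", subject), chrom, "-", "GGAA")
    out <- .dropAmbiguousMatches(.bindSites(plus, minus))
    out[order(start(out), as.character(strand(out)))]
}

#' Find GGAA microsatellites
#'
#' A microsatellite is a maximal run of perfect, zero-spacer \code{GGAA}
#' units (or \code{TTCC} units, reported on the minus strand) with at
#' least \code{minUnits} units. Runs found in both orientations are
#' deduplicated by interval.
#'
#' @inheritParams scanGGAA
#' @param minUnits minimum number of consecutive units (default 4).
#' @return \link[GenomicRanges]{GRanges} with metadata column
#'   \code{unit_count}; widths equal \code{4 * unit_count}.
#' @examples
#' findMicrosatellites(paste0("AAAA", strrep("GGAA", 6), "AAAA"), "chr1")
#' @export
findMicrosatellites <- function(seq, chrom = "chr1", minUnits = 4L) {
    if (minUnits < 2L) stop("'minUnits' must be >= 2")
    subject <- .asDNA(seq)
    runs1 <- .unitRuns(matchPattern("GGAA", subject), chrom, "+", minUnits)
    runs2 <- .unitRuns(matchPattern("TTCC", subject), chrom, "-", minUnits)
    out <- .bindSites(runs1, runs2)
    if (length(out) > 1L) {
        key <- paste(start(out), end(out))
        out <- out[!duplicated(key)]
    }
    out[order(start(out))]
}

# Internal: collapse unit matches (all width 4, pairwise >= 4 apart) into
# maximal runs of consecutive units spaced exactly 4 bp.
.unitRuns <- function(v, chrom, strand, minUnits) {
    s <- BiocGenerics::start(v)
    seqs <- as.character(v)
    keep <- !grepl("[^ACGT]", seqs)
    s <- sort(s[keep])
    if (!length(s)) return(.emptyMicrosat())
    new_run <- c(TRUE, diff(s) != 4L)
    run_id <- cumsum(new_run)
    first <- s[new_run]
    units <- as.integer(table(run_id))
    ok <- units >= minUnits
    if (!any(ok)) return(.emptyMicrosat())
    GRanges(chrom,
            IRanges(first[ok], width = 4L * units[ok]),
            strand = strand,
            unit_count = units[ok])
}

.emptyMicrosat <- function() {
    gr <- GRanges()
    mcols(gr)$unit_count <- integer()
    gr
}

#' Select isolated GGAA sites
#'
#' A site is isolated when every other GGAA/TTCC site (either strand) is
#' at nearest-edge distance of at least \code{minGap} bp; a gap of exactly
#' \code{minGap} qualifies. Overlapping sites are never isolated.
#'
#' @param sites \link[GenomicRanges]{GRanges} from \code{\link{scanGGAA}},
#'   sorted by (chrom, start).
#' @param minGap minimum nearest-edge gap in bp (default 20).
#' @return the isolated subset of \code{sites}, order preserved.
#' @export
findIsolatedGGAA <- function(sites, minGap = 20L) {
    if (minGap < 0L) stop("'minGap' must be >= 0")
    .checkSorted(sites, "sites")
    n <- length(sites)
    if (n < 2L) return(sites)
    chrom <- as.character(seqnames(sites))
    s0 <- start(sites) - 1L   # 0-based half-open
    e0 <- end(sites)
    gap_prev <- c(Inf, ifelse(chrom[-1L] == chrom[-n],
                              s0[-1L] - cummax_by(e0, chrom)[-n], Inf))
    # cummax within chromosome guards against contained intervals
    gap_next <- c(ifelse(chrom[-n] == chrom[-1L], s0[-1L] - e0[-n], Inf),
                  Inf)
    keep <- pmin(gap_prev, gap_next) >= minGap
    sites[keep]
}

# Internal: running maximum of x within groups (groups are contiguous).
cummax_by <- function(x, group) {
    out <- x
    for (g in unique(group)) {
        i <- which(group == g)
        out[i] <- cummax(x[i])
    }
    out
}

#' Default cofactor consensus patterns
#'
#' Short IUPAC consensi for the AP-1, RUNX2, E2F and FLI1-core binding
#' motifs used in tandem-site classification. These are configurable
#' defaults, not measured position-weight matrices.
#'
#' @return named character vector of IUPAC patterns.
#' @export
defaultCofactorPatterns <- function() {
    c(AP1 = "TGASTCA",
      RUNX2 = "TGYGGTY",
      E2F = "GCGSSAAA",
      FLI1 = "CCGGAAGT")
}

#' Scan for cofactor consensus motifs
#'
#' Both-strand exact IUPAC-consensus matching for each named pattern.
#' Palindromic matches occupying the same interval on both strands are
#' reported once, on the plus strand. Ambiguity letters in the subject
#' never match.
#'
#' @inheritParams scanGGAA
#' @param patterns named character vector of IUPAC consensi
#'   (default \code{\link{defaultCofactorPatterns}()}).
#' @return \link[GenomicRanges]{GRanges} sorted by start with metadata
#'   columns \code{motif_name} and \code{matched_seq}.
#' @export
scanCofactorMotifs <- function(seq, chrom = "chr1",
                               patterns = defaultCofactorPatterns()) {
    subject <- .asDNA(seq)
    if (!length(patterns)) return(.emptySites())
    if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
        stop("'patterns' must be a named vector")
    out <- .emptySites()
    for (nm in names(patterns)) {
        pat <- .asDNA(patterns[[nm]], paste0("pattern '", nm, "'"))
        plus <- .viewsToSites(
            matchPattern(pat, subject, fixed = "subject"),
            chrom, "+", nm)
        minus <- .viewsToSites(
            matchPattern(reverseComplement(pat), subject,
                         fixed = "subject"),
            chrom, "-", nm)
        hits <- .dropAmbiguousMatches(.bindSites(plus, minus))
        if (length(hits) > 1L) {
            # palindromes: same interval on both strands -> keep '+'
            hits <- hits[order(start(hits), end(hits),
                               as.character(strand(hits)) != "+")]
            key <- paste(start(hits), end(hits))
            hits <- hits[!duplicated(key)]
        }
        out <- .bindSites(out, hits)
    }
    out[order(start(out), mcols(out)$motif_name)]
}

#' Retain intervals of one set overlapping another
#'
#' Half-open overlap semantics: abutting intervals do not overlap. Every
#' member of \code{a} that overlaps at least one member of \code{b} by at
#' least 1 bp is retained once, in \code{a}'s input order.
#'
#' @param a,b sorted \link[GenomicRanges]{GRanges}.
#' @param ignoreStrand ignore strand when testing overlap (default TRUE).
#' @return the retained subset of \code{a}.
#' @export
intersectIntervals <- function(a, b, ignoreStrand = TRUE) {
    .checkSorted(a, "a")
    .checkSorted(b, "b")
    a[GenomicRanges::countOverlaps(a, b, minoverlap = 1L,
                                   ignore.strand = ignoreStrand) > 0L]
}

# element_class label for a cofactor name, e.g. AP1 -> tandem_ggaa_ap1.
.tandemClass <- function(cofactor) {
    paste0("tandem_ggaa_", tolower(sub("_?core$", "", cofactor)))
}

#' Classify heterotypic tandem GGAA sites
#'
#' For each GGAA site and each cofactor class, emits a tandem response
#' element when some cofactor site of that class lies within
#' \code{window} bp (nearest-edge distance; overlap counts as distance
#' 0). One GGAA may join several classes (multi-label). The partner is
#' the nearest qualifying cofactor site; ties resolve to the smaller
#' start.
#'
#' @param ggaa sorted \link[GenomicRanges]{GRanges} of GGAA sites.
#' @param cofactors sorted \link[GenomicRanges]{GRanges} from
#'   \code{\link{scanCofactorMotifs}} (metadata column \code{motif_name}).
#' @param window maximum nearest-edge distance in bp (default 200).
#' @return \link[GenomicRanges]{GRanges} of tandem elements (GGAA
#'   coordinates) with metadata columns \code{element_class},
#'   \code{partner_start}, \code{partner_end}, \code{partner_strand},
#'   \code{partner_distance}.
#' @export
classifyTandemSites <- function(ggaa, cofactors, window = 200L) {
    if (window < 0L) stop("'window' must be >= 0")
    .checkSorted(ggaa, "ggaa")
    .checkSorted(cofactors, "cofactors")
    out <- GRanges()
    if (!length(ggaa) || !length(cofactors)) {
        mcols(out) <- DataFrame(element_class = character(),
                                partner_start = integer(),
                                partner_end = integer(),
                                partner_strand = character(),
                                partner_distance = integer())
        return(out)
    }
    pieces <- list()
    for (nm in unique(mcols(cofactors)$motif_name)) {
        cof <- cofactors[mcols(cofactors)$motif_name == nm]
        hits <- GenomicRanges::findOverlaps(ggaa, cof, maxgap = window,
                                            ignore.strand = TRUE)
        if (!length(hits)) next
        q <- S4Vectors::queryHits(hits)
        s <- S4Vectors::subjectHits(hits)
        d <- GenomicRanges::distance(ggaa[q], cof[s], ignore.strand = TRUE)
        ord <- order(q, d, start(cof)[s])
        q <- q[ord]; s <- s[ord]; d <- d[ord]
        first <- !duplicated(q)
        el <- ggaa[q[first]]
        mcols(el) <- DataFrame(
            element_class = rep(.tandemClass(nm), sum(first)),
            partner_start = start(cof)[s[first]],
            partner_end = end(cof)[s[first]],
            partner_strand = as.character(strand(cof))[s[first]],
            partner_distance = as.integer(d[first]))
        pieces[[nm]] <- el
    }
    if (!length(pieces)) {
        mcols(out) <- DataFrame(element_class = character(),
                                partner_start = integer(),
                                partner_end = integer(),
                                partner_strand = character(),
                                partner_distance = integer())
        return(out)
    }
    out <- do.call(c, unname(pieces))
    out[order(start(out), mcols(out)$element_class)]
}

#' Scan a whole genome for GGAA response elements
#'
#' Convenience wrapper running \code{\link{scanGGAA}},
#' \code{\link{findMicrosatellites}}, \code{\link{findIsolatedGGAA}},
#' \code{\link{scanCofactorMotifs}} and \code{\link{classifyTandemSites}}
#' over every record of a genome.
#'
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param minUnits,minGap,window scanner tunables.
#' @param patterns cofactor consensi.
#' @return list with components \code{ggaa}, \code{microsatellites},
#'   \code{isolated}, \code{cofactors}, \code{tandem} (each a
#'   \link[GenomicRanges]{GRanges}).
#' @export
scanGenomeElements <- function(genome, minUnits = 4L, minGap = 20L,
                               window = 200L,
                               patterns = defaultCofactorPatterns()) {
    harmonize <- function(gr) {
        GenomeInfoDb::seqlevels(gr) <- names(genome)
        gr
    }
    per <- lapply(names(genome), function(chr) {
        s <- genome[[chr]]
        list(ggaa = harmonize(scanGGAA(s, chr)),
             micro = harmonize(
                 findMicrosatellites(s, chr, minUnits = minUnits)),
             cof = harmonize(
                 scanCofactorMotifs(s, chr, patterns = patterns)))
    })
    ggaa <- .positionSort(do.call(c, lapply(per, `[[`, "ggaa")))
    micro <- .positionSort(do.call(c, lapply(per, `[[`, "micro")))
    cof <- .positionSort(do.call(c, lapply(per, `[[`, "cof")))
    isolated <- findIsolatedGGAA(ggaa, minGap = minGap)
    tandem <- classifyTandemSites(isolated, cof, window = window)
    list(ggaa = ggaa, microsatellites = micro, isolated = isolated,
         cofactors = cof, tandem = tandem)
}
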