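# Brute-force reference implementations used to cross-check the scanners
# and counters, plus small fixture builders. Deliberately naive
# (quadratic / character-level) and independent of the package code paths.

library(GenomicRanges)
library(IRanges)
library(S4Vectors)

randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
}

# every GGAA (+) / TTCC (-) occurrence via character-level comparison
oracleGGAA <- function(seq) {
    s <- strsplit(seq, "")[[1L]]
    n <- length(s)
    if (n < 4L) return(data.frame(start = integer(), strand = character()))
    quad <- paste0(s[1:(n - 3)], s[2:(n - 2)], s[3:(n - 1)], s[4:n])
    plus <- which(quad == "GGAA")
    minus <- which(quad == "TTCC")
    data.frame(start = c(plus, minus),
               strand = rep(c("+", "-"), c(length(plus), length(minus))))
}

# maximal zero-spacer unit runs by run-length encoding of unit starts
oracleMicrosat <- function(seq, minUnits = 4L) {
    runs <- function(st) {
        st <- sort(st)
        out <- NULL
        i <- 1L
        while (i <= length(st)) {
            j <- i
            while (j < length(st) && st[j + 1L] == st[j] + 4L) j <- j + 1L
            units <- j - i + 1L
            if (units >= minUnits)
                out <- rbind(out, data.frame(start = st[i], units = units))
            i <- j + 1L
        }
        out
    }
    occ <- oracleGGAA(seq)
    r <- rbind(runs(occ$start[occ$strand == "+"]),
               runs(occ$start[occ$strand == "-"]))
    if (is.null(r)) data.frame(start = integer(), units = integer())
    else unique(r[order(r$start), , drop = FALSE])
}

# all-pairs nearest-edge isolation check (0-based half-open gaps)
oracleIsolated <- function(df, minGap = 20L) {
    if (nrow(df) < 2L) return(df)
    keep <- vapply(seq_len(nrow(df)), function(i) {
        gaps <- vapply(seq_len(nrow(df))[-i], function(j) {
            if (df$chrom[j] != df$chrom[i]) return(Inf)
            max(df$start0[j] - df$end0[i], df$start0[i] - df$end0[j])
        }, numeric(1))
        all(gaps >= minGap)
    }, logical(1))
    df[keep, , drop = FALSE]
}

.IUPAC_TEST <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                 M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                 N = "ACGT")

iupacRegex <- function(pattern) {
    paste(vapply(strsplit(pattern, "")[[1L]], function(l) {
        e <- .IUPAC_TEST[[l]]
        if (nchar(e) == 1L) e else paste0("[", e, "]")
    }, ""), collapse = "")
}

revComp <- function(seq) {
    comp <- c(A = "T", C = "G", G = "C", T = "A",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", D = "H", H = "D", V = "B", N = "N")
    paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
}

# both-strand regex IUPAC matching with '+'-preferred dedup
oracleCofactor <- function(seq, patterns) {
    out <- NULL
    for (nm in names(patterns)) {
        w <- nchar(patterns[[nm]])
        for (std in c("+", "-")) {
            pat <- if (std == "+") patterns[[nm]] else
                revComp(patterns[[nm]])
            m <- gregexpr(paste0("(?=", iupacRegex(pat), ")"), seq,
                          perl = TRUE)[[1L]]
            if (m[1L] == -1L) next
            out <- rbind(out, data.frame(start = as.integer(m),
                                         motif = nm, strand = std,
                                         width = w))
        }
    }
    if (is.null(out))
        return(data.frame(start = integer(), motif = character(),
                          strand = character(), width = integer()))
    out <- out[order(out$start, out$motif, out$strand != "+"), ,
               drop = FALSE]
    out[!duplicated(paste(out$start, out$motif)), , drop = FALSE]
}

# quadratic 1bp-overlap retention of a in b
oracleIntersect <- function(a, b) {
    keep <- vapply(seq_len(nrow(a)), function(i) {
        any(b$chrom == a$chrom[i] &
                b$start0 < a$end0[i] & a$start0[i] < b$end0)
    }, logical(1))
    a[keep, , drop = FALSE]
}

# all-pairs tandem classification with nearest-partner tie rule
oracleTandem <- function(ggaa, cof, window = 200L) {
    out <- NULL
    for (i in seq_len(nrow(ggaa))) {
        for (nm in unique(cof$motif)) {
            cc <- cof[cof$motif == nm & cof$chrom == ggaa$chrom[i], ,
                      drop = FALSE]
            if (!nrow(cc)) next
            d <- pmax(cc$start0 - ggaa$end0[i],
                      ggaa$start0[i] - cc$end0, 0)
            ok <- which(d <= window)
            if (!length(ok)) next
            best <- ok[order(d[ok], cc$start0[ok])][1L]
            out <- rbind(out, data.frame(
                start0 = ggaa$start0[i], motif = nm,
                partner_start0 = cc$start0[best],
                distance = d[best]))
        }
    }
    out
}

grToDf <- function(gr) {
    data.frame(chrom = as.character(seqnames(gr)),
               start0 = start(gr) - 1L, end0 = end(gr),
               strand = as.character(strand(gr)),
               stringsAsFactors = FALSE)
}

# compact configuration for fast end-to-end tests
tinySimConfig <- function(seed = 1L, ...) {
    simConfig(seed = seed, nChroms = 1L, chromLen = 220000L,
              nGenes = 6L, nMicrosat = 5L, nIsolated = 5L,
              nTandemPerClass = 2L, nInduced = 2L, nRepressed = 2L,
              groDepth = 30000, fragDepth = 150, bgFragsPerRep = 8000,
              ...)
}

makeReadSet <- function(pos, strand, chrom = "chr1", sampleId = "s1",
                        condition = "control", replicate = 1L) {
    ReadSet(GRanges(rep_len(chrom, length(pos)),
                    IRanges(pos, width = 1L), strand = strand),
            sampleId = sampleId, condition = condition,
            replicate = replicate)
}

makeFragmentSet <- function(start, end, chrom = "chr1",
                            sampleId = "f1", condition = "control",
                            replicate = 1L) {
    FragmentSet(GRanges(rep_len(chrom, length(start)),
                        IRanges(start, end)),
                sampleId = sampleId, condition = condition,
                replicate = replicate)
}
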