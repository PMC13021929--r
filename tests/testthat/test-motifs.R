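test_that("scanGGAA finds plus, minus and overlapping-run occurrences", {
    g <- scanGGAA("GGAA", "chrZ")
    expect_equal(start(g), 1L)
    expect_equal(as.character(strand(g)), "+")
    expect_equal(as.character(seqnames(g)), "chrZ")

    t <- scanGGAA("TTCC")
    expect_equal(start(t), 1L)
    expect_equal(as.character(strand(t)), "-")

    # brute-force over all 4-mers of GGAAGGAAGG: + sites at offsets 0, 4
    r <- scanGGAA("GGAAGGAAGG")
    ora <- oracleGGAA("GGAAGGAAGG")
    expect_equal(start(r), sort(ora$start))
    expect_equal(length(r), 2L)
})

test_that("scanGGAA rejects bad letters and never matches N", {
    expect_error(scanGGAA("GGXA"), "invalid nucleotide")
    expect_length(scanGGAA("GGNA"), 0L)
    expect_length(scanGGAA("NGAANTCC"), 0L)
})

test_that("microsatellite runs are maximal, thresholded and deduplicated", {
    one <- findMicrosatellites(paste0("AAAAA", strrep("GGAA", 4), "CCCCC"))
    expect_equal(mcols(one)$unit_count, 4L)
    expect_equal(width(one), 16L)

    expect_length(findMicrosatellites(strrep("GGAA", 3)), 0L)
    expect_error(findMicrosatellites("GGAA", minUnits = 1), ">= 2")

    set.seed(42)
    s <- paste0(randomSeq(1000), strrep("GGAA", 6), randomSeq(9000 - 24))
    got <- findMicrosatellites(s)
    ora <- oracleMicrosat(s)
    expect_equal(start(got), ora$start)
    expect_equal(mcols(got)$unit_count, ora$units)
    expect_true(any(start(got) == 1001L & mcols(got)$unit_count == 6L))
})

test_that("isolation uses nearest-edge gaps with the boundary included", {
    lone <- scanGGAA(paste0(strrep("C", 48), "GGAA", strrep("C", 48)))
    expect_length(findIsolatedGGAA(lone), 1L)

    # 10 bp spacer: gap 10 < 20, neither isolated
    near <- scanGGAA(paste0("GGAA", strrep("C", 10), "GGAA"))
    expect_length(findIsolatedGGAA(near), 0L)

    # exactly 20 bp spacer: both isolated (boundary inclusive)
    edge <- scanGGAA(paste0("GGAA", strrep("C", 20), "GGAA"))
    expect_length(findIsolatedGGAA(edge), 2L)

    unsorted <- rev(edge)
    expect_error(findIsolatedGGAA(unsorted), "sorted")
})

test_that("cofactor scanning expands IUPAC codes and dedups palindromes", {
    ap1 <- scanCofactorMotifs("TGACTCA", patterns = c(AP1 = "TGASTCA"))
    expect_equal(start(ap1), 1L)
    expect_equal(as.character(strand(ap1)), "+")

    # palindromic under the consensus: one '+' site only
    pal <- scanCofactorMotifs("TGAGTCA", patterns = c(AP1 = "TGASTCA"))
    expect_length(pal, 1L)
    expect_equal(as.character(strand(pal)), "+")

    expect_length(scanCofactorMotifs("ACGT", patterns = character()), 0L)
    expect_error(
        scanCofactorMotifs("ACGT", patterns = c(X = "QQ")),
        "invalid nucleotide")
})

test_that("interval intersection keeps 1bp overlaps, drops abutting", {
    a <- GRanges("chr1", IRanges(11, 20))   # [10,20) in bed coords
    b <- GRanges("chr1", IRanges(20, 30))   # [19,30)
    expect_length(intersectIntervals(a, b), 1L)
    b2 <- GRanges("chr1", IRanges(21, 30))  # [20,30) abutting
    expect_length(intersectIntervals(a, b2), 0L)

    set.seed(7)
    mk <- function(n) {
        s <- sample.int(5000, n)
        gr <- GRanges(sample(c("chr1", "chr2"), n, TRUE),
                      IRanges(s, s + sample.int(50, n, replace = TRUE)))
        gr[order(as.character(seqnames(gr)), start(gr))]
    }
    a <- mk(100); b <- mk(100)
    got <- intersectIntervals(a, b)
    ora <- oracleIntersect(grToDf(a), grToDf(b))
    expect_equal(grToDf(got)[, 1:3], ora[, 1:3],
                 ignore_attr = TRUE)
})

test_that("tandem classification is edge-distance based and multi-label", {
    # GGAA at [500,504), AP1 at [600,607): edge distance 96 <= 200
    ggaa <- GRanges("chr1", IRanges(501, 504), strand = "+")
    cof <- GRanges("chr1", IRanges(601, 607), strand = "+",
                   motif_name = "AP1")
    el <- classifyTandemSites(ggaa, cof, window = 200)
    expect_equal(mcols(el)$element_class, "tandem_ggaa_ap1")
    expect_equal(mcols(el)$partner_distance, 96L)

    far <- GRanges("chr1", IRanges(501 + 250 + 4, 504 + 250 + 4),
                   strand = "+", motif_name = "AP1")
    expect_length(classifyTandemSites(ggaa, far, window = 200), 0L)

    multi <- c(GRanges("chr1", IRanges(560, 567), strand = "+",
                       motif_name = "AP1"),
               GRanges("chr1", IRanges(630, 637), strand = "+",
                       motif_name = "E2F"))
    el2 <- classifyTandemSites(ggaa, multi, window = 200)
    expect_setequal(mcols(el2)$element_class,
                    c("tandem_ggaa_ap1", "tandem_ggaa_e2f"))
})

test_that("scanners agree exactly with brute-force oracles", {
    set.seed(11)
    pats <- defaultCofactorPatterns()
    for (i in 1:40) {
        s <- randomSeq(10000)
        got <- scanGGAA(s)
        ora <- oracleGGAA(s)
        ora <- ora[order(ora$start, ora$strand != "+"), ]
        expect_equal(start(got), ora$start)
        expect_equal(as.character(strand(got)), ora$strand)

        gm <- findMicrosatellites(s, minUnits = 2)
        om <- oracleMicrosat(s, minUnits = 2)
        expect_equal(start(gm), om$start)
        expect_equal(mcols(gm)$unit_count, om$units)

        iso <- findIsolatedGGAA(got)
        oi <- oracleIsolated(grToDf(got))
        expect_equal(start(iso) - 1L, oi$start0)

        gc <- scanCofactorMotifs(s, patterns = pats)
        oc <- oracleCofactor(s, pats)
        oc <- oc[order(oc$start, oc$motif), ]
        key_got <- paste(start(gc), mcols(gc)$motif_name,
                         as.character(strand(gc)))
        key_ora <- paste(oc$start, oc$motif, oc$strand)
        expect_equal(key_got, key_ora)
    }
})

test_that("tandem pairing agrees with the all-pairs oracle", {
    set.seed(12)
    for (i in 1:10) {
        s <- randomSeq(10000)
        ggaa <- findIsolatedGGAA(scanGGAA(s))
        cof <- scanCofactorMotifs(s, patterns = c(AP1 = "TGASTCA",
                                                  E2F = "SSAA"))
        got <- classifyTandemSites(ggaa, cof)
        ora <- oracleTandem(grToDf(ggaa), {
            d <- grToDf(cof); d$motif <- mcols(cof)$motif_name; d
        })
        if (is.null(ora)) {
            expect_length(got, 0L)
        } else {
            ora$class <- paste0("tandem_ggaa_", tolower(ora$motif))
            ora <- ora[order(ora$start0, ora$class), ]
            expect_equal(start(got) - 1L, ora$start0)
            expect_equal(mcols(got)$element_class, ora$class)
            expect_equal(mcols(got)$partner_start - 1L,
                         ora$partner_start0)
        }
    }
})

test_that("scanner thresholds are monotone", {
    set.seed(13)
    s <- randomSeq(20000)
    sites <- scanGGAA(s)
    iso <- lapply(c(5, 20, 50), function(g)
        start(findIsolatedGGAA(sites, minGap = g)))
    expect_true(all(iso[[2]] %in% iso[[1]]))
    expect_true(all(iso[[3]] %in% iso[[2]]))

    ms <- lapply(2:4, function(u)
        start(findMicrosatellites(s, minUnits = u)))
    expect_true(all(ms[[2]] %in% ms[[1]]))
    expect_true(all(ms[[3]] %in% ms[[2]]))

    cof <- scanCofactorMotifs(s)
    tan <- lapply(c(50, 200, 500), function(w) {
        t <- classifyTandemSites(findIsolatedGGAA(sites), cof,
                                 window = w)
        paste(start(t), mcols(t)$element_class)
    })
    expect_true(all(tan[[1]] %in% tan[[2]]))
    expect_true(all(tan[[2]] %in% tan[[3]]))
})

test_that("reverse-complementing the genome mirrors all scanner output", {
    set.seed(14)
    s <- paste0(randomSeq(3000), strrep("GGAA", 5), randomSeq(3000))
    n <- nchar(s)
    rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))

    flip <- function(st, en) c(n - en + 1L, n - st + 1L)
    g1 <- scanGGAA(s); g2 <- scanGGAA(rc)
    expect_equal(sort(n - end(g1) + 1L), sort(start(g2)))
    sw <- c("+" = "-", "-" = "+")
    expect_equal(
        sort(paste(n - end(g1) + 1L, sw[as.character(strand(g1))])),
        sort(paste(start(g2), as.character(strand(g2)))))

    m1 <- findMicrosatellites(s); m2 <- findMicrosatellites(rc)
    expect_equal(sort(n - end(m1) + 1L), sort(start(m2)))
    expect_equal(sort(mcols(m1)$unit_count), sort(mcols(m2)$unit_count))

    i1 <- findIsolatedGGAA(g1); i2 <- findIsolatedGGAA(g2)
    expect_equal(sort(n - end(i1) + 1L), sort(start(i2)))
})

test_that("every planted element is recovered from simulated genomes", {
    cfg <- tinySimConfig(seed = 5)
    sim <- simulateGenome(cfg)
    found <- scanGenomeElements(sim$genome)
    el <- sim$elements
    keyOf <- function(gr) paste(seqnames(gr), start(gr), end(gr))

    ms <- el[mcols(el)$element_class == "microsatellite"]
    expect_true(all(keyOf(ms) %in% keyOf(found$microsatellites)))
    msF <- found$microsatellites[match(keyOf(ms),
                                       keyOf(found$microsatellites))]
    expect_equal(mcols(msF)$unit_count, mcols(ms)$unit_count)

    iso <- el[mcols(el)$element_class == "isolated_ggaa"]
    expect_true(all(keyOf(iso) %in% keyOf(found$isolated)))

    tan <- el[startsWith(mcols(el)$element_class, "tandem")]
    keyT <- function(gr, cls) paste(seqnames(gr), start(gr), cls)
    expect_true(all(
        keyT(tan, mcols(tan)$element_class) %in%
            keyT(found$tandem, mcols(found$tandem)$element_class)))

    # discovered extras must themselves satisfy the brute-force oracle
    for (chr in names(sim$genome)) {
        s <- as.character(sim$genome[[chr]])
        om <- oracleMicrosat(s)
        fm <- found$microsatellites[seqnames(found$microsatellites) ==
                                        chr]
        expect_equal(start(fm), om$start)
    }
})
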