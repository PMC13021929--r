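test_that("gene windows tile [TSS-300, TES+300) in transcription order", {
    # plus strand, 0-based TSS 1000 / TES 5000 => 1-based gene [1001,5000]
    gp <- GRanges("chr1", IRanges(1001, 5000), strand = "+",
                  gene_id = "gp")
    wp <- geneWindows(gp)
    expect_equal(c(start(wp$tss), end(wp$tss)), c(701, 1030))
    expect_equal(c(start(wp$body), end(wp$body)), c(1031, 4970))
    expect_equal(c(start(wp$tes), end(wp$tes)), c(4971, 5300))

    # minus strand mirrors through strand reflection
    gm <- GRanges("chr1", IRanges(1001, 5000), strand = "-",
                  gene_id = "gm")
    wm <- geneWindows(gm)
    expect_equal(c(start(wm$tss), end(wm$tss)), c(4971, 5300))
    expect_equal(c(start(wm$body), end(wm$body)), c(1031, 4970))
    expect_equal(c(start(wm$tes), end(wm$tes)), c(701, 1030))

    short <- GRanges("chr1", IRanges(1001, 1060), strand = "+",
                     gene_id = "tiny")
    expect_warning(expect_error(geneWindows(short), "no genes"),
                   "excluded")

    # tiling: contiguous, non-overlapping
    expect_equal(end(wp$tss) + 1L, start(wp$body))
    expect_equal(end(wp$body) + 1L, start(wp$tes))
})

test_that("window counting is sense-strand-only on 5' ends", {
    g <- GRanges("chr1", IRanges(1001, 5000), strand = "+",
                 gene_id = "g1")
    w <- geneWindows(g)
    sense <- makeReadSet(1011, "+")       # TSS+10
    anti <- makeReadSet(1011, "-")
    wcS <- countWindowReads(sense, w)
    wcA <- countWindowReads(anti, w)
    expect_equal(SummarizedExperiment::assay(wcS, "tss")["g1", 1], 1L)
    expect_equal(SummarizedExperiment::assay(wcA, "tss")["g1", 1], 0L)

    set.seed(41)
    genes <- GRanges("chr1",
                     IRanges(seq(2000, by = 6000, length.out = 50),
                             width = 4000),
                     strand = sample(c("+", "-"), 50, TRUE),
                     gene_id = sprintf("g%02d", 1:50))
    w2 <- geneWindows(genes)
    pos <- sample.int(310000, 5000)
    std <- sample(c("+", "-"), 5000, TRUE)
    rs <- makeReadSet(pos, std)
    wc <- countWindowReads(rs, w2)
    for (win in c("tss", "body", "tes")) {
        wgr <- w2[[win]]
        ora <- vapply(seq_along(wgr), function(i) {
            sum(pos >= start(wgr)[i] & pos <= end(wgr)[i] &
                    std == as.character(strand(wgr))[i])
        }, numeric(1))
        expect_equal(unname(SummarizedExperiment::assay(wc, win)[, 1]),
                     as.integer(ora))
    }
    # conservation: per-gene totals equal membership sum; never exceeds
    # the library
    tot <- sum(SummarizedExperiment::assay(wc, "tss") +
                   SummarizedExperiment::assay(wc, "body") +
                   SummarizedExperiment::assay(wc, "tes"))
    expect_lte(tot, librarySize(rs) * 2)  # genes may overlap windows
})

test_that("elongation index captures TES/TSS ratio changes", {
    g <- GRanges("chr1", IRanges(1001, 11000), strand = "+",
                 gene_id = "g1")
    w <- geneWindows(g)
    mkwc <- function(tssN, tesN, cond, rep) {
        makeReadSet(c(rep(1005, tssN), rep(10995, tesN)),
                    rep("+", tssN + tesN),
                    sampleId = paste0(cond, rep), condition = cond,
                    replicate = rep)
    }
    # equal ratios both conditions -> delta 0
    wc0 <- countWindowReads(list(mkwc(100, 100, "control", 1L),
                                 mkwc(100, 100, "treated", 1L)), w)
    ei0 <- elongationIndex(wc0)
    expect_equal(ei0$delta_ei, 0, tolerance = 1e-6)

    # treated TES halved -> delta -> -1 at small psi
    wc1 <- countWindowReads(list(mkwc(1000, 1000, "control", 1L),
                                 mkwc(1000, 500, "treated", 1L)), w)
    ei1 <- elongationIndex(wc1, psi = 1e-6)
    expect_equal(ei1$delta_ei, -1, tolerance = 0.01)
    expect_error(elongationIndex(wc0, treated = "absent"), "absent")
})

test_that("log2fc tracks equal direct per-bin recomputation", {
    sl <- c(chr1 = 10000L)
    set.seed(42)
    mk <- function(n, id, cond) {
        makeReadSet(sample.int(10000, n, TRUE),
                    sample(c("+", "-"), n, TRUE),
                    sampleId = id, condition = cond)
    }
    ctl <- list(mk(2000, "c1", "control"), mk(2000, "c2", "control"))
    trt <- list(mk(2000, "t1", "treated"), mk(2000, "t2", "treated"))
    tr <- log2fcTrack(trt, ctl, sl, binWidth = 50)
    expect_equal(length(tr), 200L)
    # direct recomputation
    allc <- c(start(intervals(ctl[[1]])), start(intervals(ctl[[2]])))
    allt <- c(start(intervals(trt[[1]])), start(intervals(trt[[2]])))
    bin <- function(p) tabulate(ceiling(p / 50), 200)
    cpmc <- bin(allc) * 1e6 / 4000
    cpmt <- bin(allt) * 1e6 / 4000
    expect_equal(mcols(tr)$log2fc, log2((cpmt + 1) / (cpmc + 1)))

    # identical sets -> all-zero track
    same <- log2fcTrack(ctl, ctl, sl)
    expect_true(all(mcols(same)$log2fc == 0))
})

test_that("scaled metagene is flat for equal coverage and strand-symmetric", {
    genes <- GRanges("chr1", IRanges(c(10001, 30001), width = 5000),
                     strand = c("+", "-"),
                     gene_id = c("gp", "gm"))
    set.seed(43)
    # identical sense-coverage patterns in transcription coordinates
    offs <- sample.int(5000, 3000, TRUE) - 1L
    posP <- 10001L + offs
    posM <- 35000L - offs
    rs <- function(id, cond) {
        makeReadSet(c(posP, posM), rep(c("+", "-"), each = 3000),
                    sampleId = id, condition = cond)
    }
    mg <- scaledMetagene(list(rs("t", "treated")),
                         list(rs("c", "control")), genes,
                         flank = 1000, binWidth = 50, bodyBins = 20)
    expect_true(all(mg$matrix == 0))
    expect_equal(mg$matrix["gp", ], mg$matrix["gm", ])
    expect_equal(ncol(mg$matrix), 20 + 20 + 20)

    # treated-only linear decay across the body -> decreasing body means
    dec <- sample.int(5000, 30000, TRUE, prob = rev(seq_len(5000))) - 1L
    rsDec <- makeReadSet(10001L + dec, rep("+", length(dec)),
                         sampleId = "td", condition = "treated")
    flat <- makeReadSet(10001L + sample.int(5000, 30000, TRUE) - 1L,
                        rep("+", 30000), sampleId = "cf",
                        condition = "control")
    mg2 <- scaledMetagene(list(rsDec), list(flat), genes[1],
                          flank = 1000, binWidth = 50, bodyBins = 10)
    body <- mg2$profile$mean[mg2$profile$type == "body"]
    expect_true(all(diff(body) < 0))
    expect_lt(metageneBodySlope(mg2), 0)
})

test_that("group scaling pins the control maximum at one", {
    ctl <- c(2, 10, 4)
    trt <- c(5, 20, 1)
    sc <- groupScale(list(control = ctl, treated = trt), ctl)
    expect_equal(max(sc$control), 1)
    expect_equal(max(sc$treated), 2)
    expect_equal(groupScale(trt, ctl), trt / 10)
    expect_error(groupScale(trt, c(0, 0)), "positive maximum")
})

test_that("rank-sum p-values are exact when small and tie-safe", {
    expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 1 / 3,
                 tolerance = 1e-12)
    # enumeration oracle for a second configuration
    x <- c(1, 5); y <- c(2, 3, 4)
    combs <- combn(5, 2)
    vals <- c(x, y)
    W <- sum(rank(vals)[1:2])
    allW <- apply(combs, 2, function(ix) sum(rank(vals)[ix]))
    exact <- mean(abs(allW - 6) >= abs(W - 6))
    expect_equal(wilcoxonRankSum(x, y), exact, tolerance = 1e-12)

    expect_equal(wilcoxonRankSum(c(3, 3, 3), c(3, 3, 3)), 1)
    expect_error(wilcoxonRankSum(numeric(), 1), "non-empty")
})

test_that("TES class statistics summarize log10 CPM by target class", {
    g <- GRanges("chr1", IRanges(c(1001, 20001), width = 5000),
                 strand = "+", gene_id = c("gi", "gn"))
    w <- geneWindows(g)
    mk <- function(n1, n2, id, cond, rep) {
        makeReadSet(c(rep(5990, n1), rep(24990, n2)),
                    rep("+", n1 + n2), sampleId = id,
                    condition = cond, replicate = rep)
    }
    rs <- list(mk(90, 50, "c1", "control", 1L),
               mk(90, 50, "c2", "control", 2L),
               mk(9, 50, "t1", "treated", 1L),
               mk(9, 50, "t2", "treated", 2L))
    wc <- countWindowReads(rs, w)
    targets <- data.frame(gene_id = c("gi", "gn"),
                          target_class = c("induced", "neither"))
    got <- suppressWarnings(tesGroupStats(wc, targets))
    si <- got$summary[got$summary$class == "induced", ]
    # treated median below control for the induced class
    expect_lt(si$median[si$condition == "treated"],
              si$median[si$condition == "control"])
    expect_true(all(got$tests$p >= 0 & got$tests$p <= 1))

    # all-zero counts give log10(0+1) = 0; CPM 9 gives exactly 1
    expect_equal(log10(9 + 1), 1)
    zero <- countWindowReads(
        list(makeReadSet(99000, "+", sampleId = "z1",
                         condition = "control"),
             makeReadSet(99000, "+", sampleId = "z2",
                         condition = "treated")), w)
    gz <- suppressWarnings(tesGroupStats(zero, targets))
    expect_equal(gz$summary$median, rep(0, nrow(gz$summary)))
})

test_that("antisense initiation counts opposite-strand reads near peaks", {
    peaks <- GRanges("chr1", IRanges(5000, 5100), strand = "+",
                     name = "pk")
    senseOnly <- makeReadSet(rep(5050, 50), rep("+", 50),
                             sampleId = "c", condition = "control")
    trtSense <- makeReadSet(rep(5050, 50), rep("+", 50),
                            sampleId = "t", condition = "treated")
    none <- antisenseInitiation(list(trtSense), list(senseOnly), peaks)
    expect_equal(none$antisense_cpm_control, 0)
    expect_equal(none$antisense_cpm_treated, 0)
    expect_equal(none$log2fc, 0)

    burst <- makeReadSet(c(rep(5050, 50), rep(5060, 30)),
                         c(rep("+", 50), rep("-", 30)),
                         sampleId = "tb", condition = "treated")
    got <- antisenseInitiation(list(burst), list(senseOnly), peaks)
    expect_gt(got$log2fc, 0)

    unann <- GRanges("chr1", IRanges(5000, 5100), strand = "*")
    expect_warning(out <- antisenseInitiation(list(burst),
                                              list(senseOnly), unann),
                   "unannotated")
    expect_equal(nrow(out), 0L)
})
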