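test_that("reference simulation is deterministic and hits the GC target", {
    a <- simulateReference(100000, gcTarget = 0.6, seed = 7)
    b <- simulateReference(100000, gcTarget = 0.6, seed = 7)
    expect_identical(as.character(a$seq), as.character(b$seq))
    gc <- Biostrings::letterFrequency(a$seq[[1]], "GC", as.prob = TRUE)
    expect_lt(abs(gc - 0.6), 0.02)

    withN <- simulateReference(5000, nRuns = data.frame(start = 101,
                                                        len = 50),
                               seed = 1)
    fa <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(withN$seq, fa)
    rt <- loadReference(fa, "simchr")
    expect_identical(which(nMask(rt)), 101:150)
})

test_that("embedding TDs grows the donor by the duplicated bases", {
    ref <- simulateReference(200000, seed = 3)
    emb <- embedTandemDuplications(ref$seq, nTD = 4L,
                                   copyRange = c(1L, 6L),
                                   lenRange = c(1000L, 3000L),
                                   margin = 5000L, minGap = 2000L,
                                   seed = 4)
    tr <- emb$truth
    expect_length(tr, 4L)
    k <- S4Vectors::mcols(tr)$nCopies
    expect_true(all(k >= 1L & k <= 6L))
    expect_equal(Biostrings::width(emb$donorSeq),
                 200000L + sum(k * IRanges::width(tr)))
    # truth sorted and disjoint with the configured gap
    expect_false(is.unsorted(GenomicRanges::start(tr)))
    expect_true(all(GenomicRanges::start(tr)[-1] -
                    GenomicRanges::end(tr)[-4] > 2000))
    # donor contains the tandem repeat: segment == its following copy
    s <- GenomicRanges::start(tr)[1]; e <- GenomicRanges::end(tr)[1]
    donor <- as.character(emb$donorSeq[[1]])
    seg <- substring(donor, s, e)
    expect_identical(substring(donor, e + 1, e + (e - s + 1)), seg)
})

test_that("truth sets round-trip through BED", {
    ref <- simulateReference(100000, seed = 9)
    emb <- embedTandemDuplications(ref$seq, nTD = 3L,
                                   lenRange = c(500L, 1500L),
                                   margin = 2000L, minGap = 1000L,
                                   seed = 10)
    path <- tempfile(fileext = ".bed")
    writeTruth(emb$truth, path)
    back <- readTruth(path)
    expect_equal(GenomicRanges::start(back),
                 GenomicRanges::start(emb$truth))
    expect_equal(GenomicRanges::end(back),
                 GenomicRanges::end(emb$truth))
    expect_equal(S4Vectors::mcols(back)$nCopies,
                 S4Vectors::mcols(emb$truth)$nCopies)
})

test_that("rendered depth doubles over a single-copy TD at purity 1", {
    ref <- simulateReference(300000, seed = 21)
    emb <- embedTandemDuplications(ref$seq, nTD = 1L,
                                   copyRange = c(1L, 1L),
                                   lenRange = c(20000L, 20000L),
                                   margin = 20000L, seed = 22)
    bam <- renderBam(ref$seq, emb$donorSeq, emb$truth,
                     outPrefix = tempfile(), coverage = 20,
                     purity = 1, seed = 23, withSeq = FALSE)
    fa <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(ref$seq, fa)
    rt <- loadReference(fa, "simchr")
    ps <- extractPositionSignals(bam, "simchr", rt)
    s <- GenomicRanges::start(emb$truth)
    e <- GenomicRanges::end(emb$truth)
    inside <- mean(readCount(ps)[(s + 500):(e - 500)])
    outside <- mean(readCount(ps)[1:(s - 500)])
    expect_lt(abs(inside / outside - 2), 0.15)
    # depth conservation: aligned bases ~ coverage * refLen
    expect_lt(abs(sum(readCount(ps)) / (20 * 300000) - 1), 0.05)
})

test_that("junction-spanning reads carry one clip anchored at the truth", {
    ref <- simulateReference(200000, seed = 31)
    emb <- embedTandemDuplications(ref$seq, nTD = 2L,
                                   copyRange = c(2L, 3L),
                                   lenRange = c(5000L, 8000L),
                                   margin = 10000L, minGap = 5000L,
                                   seed = 32)
    bam <- renderBam(ref$seq, emb$donorSeq, emb$truth,
                     outPrefix = tempfile(), coverage = 30,
                     purity = 1, seed = 33, withSeq = FALSE)
    sp <- extractSplitSignals(bam, "simchr", minClipLen = 10L)
    expect_gt(nrow(sp), 0)
    starts <- GenomicRanges::start(emb$truth)
    ends <- GenomicRanges::end(emb$truth)
    expect_true(all(sp$breakpoint[sp$kind == "post_alignment"] %in%
                    starts))
    expect_true(all(sp$breakpoint[sp$kind == "pre_alignment"] %in%
                    ends))
    # both boundary types observed for every TD (coverage 30, k >= 2)
    expect_true(all(starts %in% sp$breakpoint))
    expect_true(all(ends %in% sp$breakpoint))
})

test_that("same seed reproduces the identical sample", {
    d1 <- tempfile(); d2 <- tempfile()
    s1 <- simulateSample(d1, refLength = 100000, nTD = 2L,
                         lenRange = c(2000L, 4000L), margin = 5000L,
                         minGap = 3000L, coverage = 5, seed = 41,
                         withSeq = FALSE)
    s2 <- simulateSample(d2, refLength = 100000, nTD = 2L,
                         lenRange = c(2000L, 4000L), margin = 5000L,
                         minGap = 3000L, coverage = 5, seed = 41,
                         withSeq = FALSE)
    expect_identical(readLines(s1$ref), readLines(s2$ref))
    expect_identical(readLines(s1$truthBed), readLines(s2$truthBed))
    p <- Rsamtools::ScanBamParam(what = c("qname", "pos", "cigar",
                                          "mapq"))
    r1 <- Rsamtools::scanBam(s1$bam, param = p)[[1]]
    r2 <- Rsamtools::scanBam(s2$bam, param = p)[[1]]
    expect_identical(r1$pos, r2$pos)
    expect_identical(r1$cigar, r2$cigar)
    expect_identical(r1$mapq, r2$mapq)
})

test_that("mapping quality is degraded only where donor reads overlap TDs", {
    ref <- simulateReference(200000, seed = 51)
    emb <- embedTandemDuplications(ref$seq, nTD = 1L,
                                   copyRange = c(2L, 2L),
                                   lenRange = c(10000L, 10000L),
                                   margin = 20000L, seed = 52)
    bam <- renderBam(ref$seq, emb$donorSeq, emb$truth,
                     outPrefix = tempfile(), coverage = 10,
                     purity = 1, seed = 53, withSeq = FALSE)
    p <- Rsamtools::ScanBamParam(what = c("pos", "mapq", "cigar"))
    rec <- Rsamtools::scanBam(bam, param = p)[[1]]
    s <- GenomicRanges::start(emb$truth); e <- GenomicRanges::end(emb$truth)
    inside <- rec$pos >= s & rec$pos <= e - 100
    outside <- rec$pos < s - 200 | rec$pos > e + 200
    expect_true(all(rec$mapq[outside] == 60L))
    expect_true(all(rec$mapq[inside] <= 30L))
})
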