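test_that("consecutive noise bins merge into regions with right coordinates", {
    prof <- makeProfile(rep(20, 15), lenBin = 2000L)
    # bins 6..8 and 13 (1-based) span [10001,16000] and [24001,26000]
    reg <- mergeNoiseBins(c(6L, 7L, 8L, 13L), prof)
    expect_equal(GenomicRanges::start(reg), c(10001L, 24001L))
    expect_equal(GenomicRanges::end(reg), c(16000L, 26000L))
    expect_equal(S4Vectors::mcols(reg)$nBins, c(3L, 1L))
    expect_true(all(S4Vectors::mcols(reg)$stage == "rough"))

    expect_length(mergeNoiseBins(integer(0), prof), 0L)
    single <- mergeNoiseBins(4L, prof)
    expect_equal(IRanges::width(single), 2000L)
})

test_that("noise runs separated only by invalid bins are bridged", {
    rd <- rep(20, 10); rd[5] <- NA
    prof <- makeProfile(rd, lenBin = 2000L)
    bridged <- mergeNoiseBins(c(4L, 6L), prof, bridgeInvalid = TRUE)
    expect_length(bridged, 1L)
    expect_equal(GenomicRanges::start(bridged), 6001L)
    expect_equal(GenomicRanges::end(bridged), 12000L)
    split <- mergeNoiseBins(c(4L, 6L), prof, bridgeInvalid = FALSE)
    expect_length(split, 2L)
    # a valid non-noise bin in between always splits
    expect_length(mergeNoiseBins(c(2L, 4L), prof), 2L)
})

test_that("merged regions are disjoint and sorted", {
    set.seed(88)
    prof <- makeProfile(rep(20, 200), lenBin = 1000L)
    for (i in 1:10) {
        idx <- sort(sample(200L, 40))
        reg <- mergeNoiseBins(idx, prof)
        expect_false(is.unsorted(GenomicRanges::start(reg)))
        if (length(reg) > 1)
            expect_true(all(GenomicRanges::start(reg)[-1] >
                            GenomicRanges::end(reg)[-length(reg)]))
        expect_equal(sum(S4Vectors::mcols(reg)$nBins), 40L)
    }
})

splitRow <- function(pos, kind, matchedLen, readLen = 100L) {
    data.frame(pos = pos, kind = kind, matchedLen = matchedLen,
               clipLen = readLen - matchedLen, readLen = readLen,
               breakpoint = ifelse(kind == "pre_alignment",
                                   pos + matchedLen - 1L, pos))
}

test_that("breakpoints refine to the supported split positions", {
    prof <- makeProfile(rep(20, 20), lenBin = 2000L)
    rough <- mergeNoiseBins(6L:8L, prof)    # [10001, 16000]
    splits <- rbind(
        splitRow(rep(10050L, 3), "post_alignment", 70L),
        splitRow(rep(15000L, 4), "pre_alignment", 50L))
    ref <- refineBreakpoints(rough, splits, searchPad = 2000L)
    expect_equal(GenomicRanges::start(ref), 10050L)
    expect_equal(GenomicRanges::end(ref), 15000L + 50L - 1L)
    expect_equal(S4Vectors::mcols(ref)$leftSupport, 3L)
    expect_equal(S4Vectors::mcols(ref)$rightSupport, 4L)
    expect_equal(S4Vectors::mcols(ref)$stage, "refined")

    # no split signals: region unchanged, still rough
    keep <- refineBreakpoints(rough, splits[0, ], searchPad = 2000L)
    expect_equal(GenomicRanges::start(keep), 10001L)
    expect_equal(S4Vectors::mcols(keep)$stage, "rough")
})

test_that("candidate selection: support, then proximity, then coordinate", {
    prof <- makeProfile(rep(20, 20), lenBin = 2000L)
    rough <- mergeNoiseBins(6L:8L, prof)     # a = 10001
    # higher support wins even if farther
    splits <- rbind(
        splitRow(rep(11500L, 5), "post_alignment", 70L),
        splitRow(rep(10010L, 2), "post_alignment", 70L))
    ref <- refineBreakpoints(rough, splits, searchPad = 2000L)
    expect_equal(GenomicRanges::start(ref), 11500L)
    # equal support: closest to the rough boundary wins
    tie <- rbind(
        splitRow(rep(10400L, 2), "post_alignment", 70L),
        splitRow(rep(9900L, 2), "post_alignment", 70L))
    expect_equal(GenomicRanges::start(
        refineBreakpoints(rough, tie, searchPad = 2000L)), 9900L)
    # equal support and distance: smaller coordinate wins
    tie2 <- rbind(
        splitRow(rep(9901L, 2), "post_alignment", 70L),
        splitRow(rep(10101L, 2), "post_alignment", 70L))
    expect_equal(GenomicRanges::start(
        refineBreakpoints(rough, tie2, searchPad = 2000L)), 9901L)
})

test_that("refinement stays inside the padded rough region", {
    prof <- makeProfile(rep(20, 20), lenBin = 2000L)
    rough <- mergeNoiseBins(6L:8L, prof)   # [10001, 16000], pad 2000
    splits <- rbind(
        splitRow(7500L, "post_alignment", 70L),    # outside a - pad
        splitRow(18500L, "pre_alignment", 50L))    # bp 18549 > b + pad
    ref <- refineBreakpoints(rough, splits, searchPad = 2000L)
    expect_equal(GenomicRanges::start(ref), 10001L)
    expect_equal(GenomicRanges::end(ref), 16000L)
    set.seed(99)
    for (i in 1:10) {
        sp <- splitRow(sample(5000:21000, 20, replace = TRUE),
                       sample(c("pre_alignment", "post_alignment"), 20,
                              replace = TRUE), 50L)
        out <- refineBreakpoints(rough, sp, searchPad = 2000L)
        expect_gte(GenomicRanges::start(out), 10001L - 2000L)
        expect_lte(GenomicRanges::end(out), 16000L + 2000L)
    }
})

test_that("duplication-direction filter drops low-depth regions when enabled", {
    prof <- makeProfile(c(rep(10, 8), 20, 20, rep(10, 8), 5, 5),
                        lenBin = 2000L)
    regions <- mergeNoiseBins(c(9L, 10L, 19L, 20L), prof)
    expect_length(filterDuplicationLike(regions, prof, enabled = FALSE),
                  2L)
    kept <- filterDuplicationLike(regions, prof, enabled = TRUE)
    expect_length(kept, 1L)
    expect_equal(S4Vectors::mcols(kept)$meanRd, 20)
})

test_that("calls round-trip through the BED writer", {
    prof <- makeProfile(rep(20, 20), lenBin = 2000L)
    regions <- refineBreakpoints(
        mergeNoiseBins(c(3L, 4L, 10L), prof),
        splitRow(rep(4100L, 3), "post_alignment", 70L),
        searchPad = 2000L)
    path <- tempfile(fileext = ".bed")
    writeCalls(regions, path)
    back <- readCalls(path)
    expect_equal(GenomicRanges::start(back),
                 GenomicRanges::start(regions))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(regions))
    expect_equal(S4Vectors::mcols(back)$leftSupport,
                 S4Vectors::mcols(regions)$leftSupport)
    expect_equal(S4Vectors::mcols(back)$meanRd,
                 S4Vectors::mcols(regions)$meanRd)
    # 0-based half-open on disk
    line <- readLines(path)[2]
    expect_equal(strsplit(line, "\t")[[1]][2], "4099")

    # empty set -> header-only file -> empty GRanges
    empty <- tempfile(fileext = ".bed")
    writeCalls(regions[0], empty)
    expect_length(readCalls(empty), 0L)
})
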