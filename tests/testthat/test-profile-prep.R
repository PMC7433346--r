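psFromVectors <- function(rc, mq, chrom = "chrT") {
    new("PositionSignals", chrom = chrom, readCount = rc, mqMean = mq)
}
rtFromMasks <- function(n, nPos = integer(0), gcPos = integer(0)) {
    nm <- gm <- rep(FALSE, n)
    nm[nPos] <- TRUE
    gm[gcPos] <- TRUE
    new("ReferenceTrack", chrom = "chrT", nMask = nm, gcMask = gm)
}

test_that("per-bin RD, MQ and GC are means over bin positions", {
    rc <- c(2, 2, 4, 4, 1, 1, 1, 1)
    mq <- c(60, 60, 0, 0, 30, 30, 30, 30)
    bp <- binSignals(psFromVectors(rc, mq),
                     rtFromMasks(8, gcPos = c(1, 2, 3)), lenBin = 4L)
    mc <- S4Vectors::mcols(binRanges(bp))
    expect_equal(mc$rd, c(3, 1))
    expect_equal(mc$mq, c(30, 30))
    expect_equal(mc$gc, c(0.75, 0))
    expect_true(all(mc$valid))
})

test_that("a bin containing any N position is filtered out", {
    rc <- c(1, 1, 1, 1, NA, 1, 1, 1)
    mq <- c(rep(60, 4), NA, rep(60, 3))
    bp <- binSignals(psFromVectors(rc, mq), rtFromMasks(8, nPos = 5),
                     lenBin = 4L)
    mc <- S4Vectors::mcols(binRanges(bp))
    expect_identical(mc$valid, c(TRUE, FALSE))
    expect_true(is.na(mc$rd[2]))
})

test_that("terminal partial bins follow the half-bin rule", {
    # 10 positions, lenBin 4: bins [1,4], [5,8], terminal [9,10] has
    # 2 < 4/2 ... 2 >= 2, kept; with lenBin 6 terminal [7,10] has 4 >= 3
    rc <- rep(1, 10); mq <- rep(60, 10)
    bp <- binSignals(psFromVectors(rc, mq), rtFromMasks(10), lenBin = 4L)
    expect_equal(length(binRanges(bp)), 3L)
    # 11 positions, lenBin 4 -> terminal width 3 >= 2 kept; 9 positions
    # -> terminal width 1 < 2 dropped
    bp2 <- binSignals(psFromVectors(rep(1, 9), rep(60, 9)),
                      rtFromMasks(9), lenBin = 4L)
    expect_equal(length(binRanges(bp2)), 2L)
    expect_warning(
        binSignals(psFromVectors(rc, mq), rtFromMasks(10), lenBin = 50L),
        "single bin")
})

test_that("GC correction follows the stratified median-ratio formula", {
    # single stratum: corrected = n / n_GC * value with n_GC = n
    v <- c(10, 6, 2)
    expect_equal(gcCorrect(v, rep(0.5, 3)), v)
    # two separated strata: each rescaled to the global median
    v2 <- c(10, 10, 20, 20)
    gc2 <- c(0.3, 0.3, 0.6, 0.6)
    n <- median(v2)
    expect_equal(gcCorrect(v2, gc2), c(n, n, n, n))
    # direct arithmetic: value 10, n = 6, n_GC = 12 -> 5
    v3 <- c(10, 12, 14, 4, 6, 8)
    gc3 <- c(0.6, 0.6, 0.6, 0.2, 0.2, 0.2)
    out <- gcCorrect(v3, gc3)
    expect_equal(out[1], median(v3) / 12 * 10)  # = 7/12*10... computed
    expect_equal(out[1], 10 * median(v3) / median(c(10, 12, 14)))
})

test_that("GC correction equalizes stratum medians and is scale-equivariant", {
    set.seed(33)
    for (i in 1:10) {
        nb <- sample(20:200, 1)
        gc <- sample(seq(0.3, 0.6, by = 0.01), nb, replace = TRUE)
        v <- rgamma(nb, shape = 4, rate = 0.1)
        out <- gcCorrect(v, gc)
        n <- median(v)
        for (g in unique(gc))
            expect_equal(median(out[abs(gc - g) <= 0.001]), n)
        expect_equal(gcCorrect(3.7 * v, gc), 3.7 * out)
    }
})

test_that("zero-median GC strata are guarded", {
    expect_warning(out <- gcCorrect(c(0, 0, 5, 7, 9),
                                    c(0.2, 0.2, 0.5, 0.5, 0.5)),
                   "median 0")
    expect_equal(out[1:2], c(0, 0))
})

test_that("MQ normalization maps onto the RD range and keeps order", {
    expect_equal(normalizeMQ(c(0, 30, 60), rd = c(2, 7, 12)),
                 c(2, 7, 12))
    set.seed(44)
    mq <- runif(100, 0, 60)
    rd <- runif(100, 5, 40)
    out <- normalizeMQ(mq, rd)
    expect_equal(range(out), range(rd))
    expect_identical(order(out), order(mq))
    expect_warning(flat <- normalizeMQ(rep(10, 4), c(2, 4, 6, 8)),
                   "identical")
    expect_equal(flat, rep(5, 4))
})

test_that("prepareProfile adds the processed tracks on valid bins only", {
    rd <- c(10, 11, NA, 30, 31)
    bp <- makeProfile(rd, lenBin = 4L)
    # rebuild as raw profile (no processed columns)
    gr <- binRanges(bp)
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[c("rd", "mq", "gc",
                                                   "valid")]
    raw <- new("BinProfile", bins = gr, lenBin = 4L)
    expect_warning(out <- prepareProfile(raw, lam = 0.25),
                   "identical")        # constant MQ in this toy profile
    mc <- S4Vectors::mcols(binRanges(out))
    expect_true(all(is.na(mc$rdSmooth[!mc$valid])))
    expect_true(all(!is.na(mc$rdSmooth[mc$valid])))
    expect_true(all(c("rdCorr", "mqCorr", "rdSmooth", "mqSmooth",
                      "mqNorm") %in% colnames(mc)))
})
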