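#' ReferenceTrack: per-position masks for one chromosome
#'
#' Holds the two per-base annotations of a reference chromosome that the
#' caller needs: which positions are undetermined (N) and which are G/C.
#' N positions are kept rather than dropped so that downstream coordinates
#' stay aligned with the reference; coverage over them is treated as
#' missing and any bin touching them is filtered.
#'
#' @slot chrom chromosome name.
#' @slot nMask logical, \code{TRUE} where the reference base is N
#'   (case-insensitive).
#' @slot gcMask logical, \code{TRUE} where the base is G or C
#'   (case-insensitive).
#'
#' @seealso [loadReference()]
#' @export
setClass("ReferenceTrack",
    representation(chrom = "character", nMask = "logical", gcMask = "logical"))

setValidity("ReferenceTrack", function(object) {
    msg <- NULL
    if (length(object@chrom) != 1L)
        msg <- c(msg, "'chrom' must be a single string")
    if (length(object@nMask) != length(object@gcMask))
        msg <- c(msg, "'nMask' and 'gcMask' must have the same length")
    if (anyNA(object@nMask) || anyNA(object@gcMask))
        msg <- c(msg, "masks must not contain NA")
    if (any(object@nMask & object@gcMask))
        msg <- c(msg, "a position cannot be both N and G/C")
    if (is.null(msg)) TRUE else msg
})

#' PositionSignals: per-base read count and mapping quality
#'
#' The per-position pileup extracted from a coordinate-sorted BAM for one
#' chromosome: for every reference position, the number of primary
#' alignments whose aligned (M) bases cover it, and the mean MAPQ of those
#' alignments. Positions that are N in the reference carry \code{NA} in
#' both tracks; covered/uncovered non-N positions carry counts and a mean
#' MAPQ (0 where uncovered).
#'
#' @slot chrom chromosome name.
#' @slot readCount numeric, per-position read count (\code{NA} at N
#'   positions).
#' @slot mqMean numeric, per-position mean MAPQ of covering reads; 0 where
#'   uncovered, \code{NA} at N positions.
#'
#' @seealso [extractPositionSignals()]
#' @export
setClass("PositionSignals",
    representation(chrom = "character", readCount = "numeric",
                   mqMean = "numeric"))

setValidity("PositionSignals", function(object) {
    msg <- NULL
    if (length(object@chrom) != 1L)
        msg <- c(msg, "'chrom' must be a single string")
    if (length(object@readCount) != length(object@mqMean))
        msg <- c(msg, "'readCount' and 'mqMean' must have the same length")
    rc <- object@readCount
    if (any(rc[!is.na(rc)] < 0))
        msg <- c(msg, "'readCount' must be non-negative where defined")
    if (!identical(is.na(rc), is.na(object@mqMean)))
        msg <- c(msg, "NA pattern of 'readCount' and 'mqMean' must agree")
    if (is.null(msg)) TRUE else msg
})

#' BinProfile: the per-bin feature table fed to clustering
#'
#' Non-overlapping bins tiling one chromosome, each annotated with read
#' depth (RD), mapping quality (MQ) and GC fraction, plus the processed
#' tracks added by [prepareProfile()]: GC-corrected (\code{rdCorr},
#' \code{mqCorr}), TV-denoised (\code{rdSmooth}, \code{mqSmooth}) and the
#' MQ track rescaled onto the RD range (\code{mqNorm}). Bins containing
#' any N position are marked invalid and excluded from every downstream
#' statistic.
#'
#' @slot bins a [GenomicRanges::GRanges] with metadata columns \code{rd},
#'   \code{mq}, \code{gc}, \code{valid} (and after processing
#'   \code{rdCorr}, \code{mqCorr}, \code{rdSmooth}, \code{mqSmooth},
#'   \code{mqNorm}).
#' @slot lenBin integer, the nominal bin width in bases.
#'
#' @seealso [binSignals()], [prepareProfile()]
#' @export
setClass("BinProfile",
    representation(bins = "GRanges", lenBin = "integer"))

setValidity("BinProfile", function(object) {
    msg <- NULL
    mc <- S4Vectors::mcols(object@bins)
    need <- c("rd", "mq", "gc", "valid")
    if (!all(need %in% colnames(mc)))
        msg <- c(msg, paste0("bins must carry metadata columns: ",
                             paste(need, collapse = ", ")))
    if (length(object@lenBin) != 1L || is.na(object@lenBin) ||
        object@lenBin < 1L)
        msg <- c(msg, "'lenBin' must be a single positive integer")
    if (all(need %in% colnames(mc))) {
        gc <- mc$gc
        ok <- is.na(gc) | (gc >= 0 & gc <= 1)
        if (!all(ok))
            msg <- c(msg, "'gc' must lie in [0, 1]")
        rd <- mc$rd
        if (any(rd[!is.na(rd)] < 0))
            msg <- c(msg, "'rd' must be non-negative where defined")
    }
    if (is.null(msg)) TRUE else msg
})
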