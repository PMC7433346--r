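#' @title Accessors for TandemScan classes
#' @name accessors
#' @description Small accessor generics so that user code never reaches
#'   into slots directly.
#' @param x a TandemScan object.
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname accessors
#' @export
setGeneric("nMask", function(x) standardGeneric("nMask"))
#' @rdname accessors
#' @export
setGeneric("gcMask", function(x) standardGeneric("gcMask"))
#' @rdname accessors
#' @export
setGeneric("readCount", function(x) standardGeneric("readCount"))
#' @rdname accessors
#' @export
setGeneric("mqMean", function(x) standardGeneric("mqMean"))
#' @rdname accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))

#' @rdname accessors
#' @export
setMethod("chromName", "ReferenceTrack", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("chromName", "PositionSignals", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("seqLength", "ReferenceTrack", function(x) length(x@nMask))
#' @rdname accessors
#' @export
setMethod("seqLength", "PositionSignals", function(x) length(x@readCount))
#' @rdname accessors
#' @export
setMethod("nMask", "ReferenceTrack", function(x) x@nMask)
#' @rdname accessors
#' @export
setMethod("gcMask", "ReferenceTrack", function(x) x@gcMask)
#' @rdname accessors
#' @export
setMethod("readCount", "PositionSignals", function(x) x@readCount)
#' @rdname accessors
#' @export
setMethod("mqMean", "PositionSignals", function(x) x@mqMean)
#' @rdname accessors
#' @export
setMethod("binRanges", "BinProfile", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("binSize", "BinProfile", function(x) x@lenBin)
#' @rdname accessors
#' @export
setMethod("validBins", "BinProfile",
    function(x) which(S4Vectors::mcols(x@bins)$valid))

setMethod("show", "ReferenceTrack", function(object) {
    n <- length(object@nMask)
    cat("ReferenceTrack for", object@chrom, "|", n, "bp |",
        sum(object@nMask), "N positions |",
        sprintf("GC %.3f\n", if (n > sum(object@nMask))
            sum(object@gcMask) / (n - sum(object@nMask)) else NA_real_))
})

setMethod("show", "PositionSignals", function(object) {
    rc <- object@readCount
    cat("PositionSignals for", object@chrom, "|", length(rc), "bp |",
        sprintf("mean depth %.2f (non-N)\n", mean(rc, na.rm = TRUE)))
})

setMethod("show", "BinProfile", function(object) {
    mc <- S4Vectors::mcols(object@bins)
    cat("BinProfile |", length(object@bins), "bins of", object@lenBin,
        "bp |", sum(mc$valid), "valid |",
        if ("rdSmooth" %in% colnames(mc)) "processed\n" else "raw\n")
})
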