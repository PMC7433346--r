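#' Merge consecutive noise bins into rough TD regions
#'
#' Maximal runs of consecutive noise bins become one region spanning
#' from the first bin's start to the last bin's end. By default a run
#' interrupted only by invalid (N-filtered) bins is still merged: an
#' N gap in the reference should not split one duplication event in two.
#'
#' @param noiseIdx ascending indices (into the full bin profile) of
#'   noise bins, e.g. valid-bin indices mapped back from
#'   [dbscanCluster()].
#' @param profile the processed [BinProfile-class].
#' @param bridgeInvalid merge runs separated only by invalid bins
#'   (default TRUE).
#' @return a [GenomicRanges::GRanges] of rough regions with metadata
#'   \code{stage} ("rough"), \code{nBins} (noise bins merged),
#'   \code{leftSupport}/\code{rightSupport} (0), \code{meanRd} (mean
#'   smoothed RD over the region's noise bins).
#' @export
mergeNoiseBins <- function(noiseIdx, profile, bridgeInvalid = TRUE) {
    stopifnot(is(profile, "BinProfile"))
    gr <- binRanges(profile)
    mc <- S4Vectors::mcols(gr)
    empty <- GenomicRanges::GRanges(
        seqnames = character(0), ranges = IRanges::IRanges(),
        stage = character(0), nBins = integer(0),
        leftSupport = integer(0), rightSupport = integer(0),
        meanRd = numeric(0))
    if (!length(noiseIdx))
        return(empty)
    noiseIdx <- sort(as.integer(noiseIdx))
    if (any(noiseIdx < 1L | noiseIdx > length(gr)))
        stop("noise indices out of bin-profile range")
    # bins are consecutive if adjacent in index, or separated only by
    # invalid bins when bridging is on
    joined <- logical(length(noiseIdx) - 1L)
    if (length(noiseIdx) > 1L) {
        for (i in seq_len(length(noiseIdx) - 1L)) {
            a <- noiseIdx[i]; b <- noiseIdx[i + 1L]
            joined[i] <- (b == a + 1L) ||
                (bridgeInvalid && b > a + 1L &&
                 !any(mc$valid[(a + 1L):(b - 1L)]))
        }
    }
    runId <- cumsum(c(1L, !joined))
    starts <- tapply(noiseIdx, runId, min)
    ends <- tapply(noiseIdx, runId, max)
    rdCol <- if ("rdSmooth" %in% colnames(mc)) mc$rdSmooth else mc$rd
    regions <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(gr)[starts],
        ranges = IRanges::IRanges(
            start = GenomicRanges::start(gr)[starts],
            end = GenomicRanges::end(gr)[ends]))
    S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
        stage = rep("rough", length(starts)),
        nBins = as.integer(tapply(noiseIdx, runId, length)),
        leftSupport = integer(length(starts)),
        rightSupport = integer(length(starts)),
        meanRd = as.numeric(tapply(rdCol[noiseIdx], runId, mean)))
    sort(regions)
}

## Pick one breakpoint from candidate positions: maximum support, then
## closest to the rough boundary, then smallest coordinate.
.pickBreakpoint <- function(cand, roughPos) {
    if (!length(cand))
        return(NULL)
    tab <- table(cand)
    posVal <- as.integer(names(tab))
    support <- as.integer(tab)
    ord <- order(-support, abs(posVal - roughPos), posVal)
    list(pos = posVal[ord[1L]], support = support[ord[1L]])
}

#' Refine rough TD boundaries with split-read signals
#'
#' For each rough region \code{[a, b]} (1-based inclusive), collects
#' the split signals of the extended region \code{[a - searchPad,
#' b + searchPad]}: post-alignment records (\code{xS(L-x)M}) with
#' mapped position in \code{[a - searchPad, b]} vote for the low
#' boundary (\code{a = pos}); pre-alignment records (\code{yM(L-y)S})
#' with implied end \code{pos + y - 1} in \code{[a, b + searchPad]}
#' vote for the high boundary. Searching the whole extended region
#' (rather than a window around each edge) makes refinement robust to
#' a rough region that over-extends by a bin: all copy junctions of a
#' duplication produce clips at the same two true breakpoints, so the
#' votes concentrate there. On each side the candidate with the most
#' supporting records wins (ties: closest to the rough boundary, then
#' the smaller coordinate). A side with no candidate keeps its rough
#' coordinate and support 0; a region with at least one refined side
#' is staged "refined". A refined boundary never lies outside
#' \code{[a - searchPad, b + searchPad]}.
#'
#' @param regions rough regions from [mergeNoiseBins()].
#' @param splits split-signal data.frame from [extractSplitSignals()].
#' @param searchPad search half-width in bases around each rough
#'   boundary (default: one bin).
#' @return the regions with updated coordinates, \code{stage} and
#'   support counts.
#' @export
refineBreakpoints <- function(regions, splits, searchPad = 2000L) {
    stopifnot(searchPad >= 0)
    if (!length(regions))
        return(regions)
    mc <- S4Vectors::mcols(regions)
    newStart <- GenomicRanges::start(regions)
    newEnd <- GenomicRanges::end(regions)
    post <- splits[splits$kind == "post_alignment", , drop = FALSE]
    pre <- splits[splits$kind == "pre_alignment", , drop = FALSE]
    for (i in seq_along(regions)) {
        a <- GenomicRanges::start(regions)[i]
        b <- GenomicRanges::end(regions)[i]
        left <- .pickBreakpoint(
            post$breakpoint[post$breakpoint >= a - searchPad &
                            post$breakpoint <= b], a)
        right <- .pickBreakpoint(
            pre$breakpoint[pre$breakpoint >= a &
                           pre$breakpoint <= b + searchPad], b)
        s <- if (is.null(left)) a else left$pos
        e <- if (is.null(right)) b else right$pos
        if (s < e) {            # guard against degenerate refinements
            newStart[i] <- s
            newEnd[i] <- e
            mc$leftSupport[i] <- if (is.null(left)) 0L else left$support
            mc$rightSupport[i] <- if (is.null(right)) 0L else
                right$support
            if (!is.null(left) || !is.null(right))
                mc$stage[i] <- "refined"
        }
    }
    IRanges::ranges(regions) <- IRanges::IRanges(newStart, newEnd)
    S4Vectors::mcols(regions) <- mc
    sort(regions)
}

#' Optional duplication-direction filter
#'
#' DBSCAN noise is sign-agnostic: a deletion depresses depth the same
#' way a duplication raises it. When enabled, regions whose mean
#' smoothed depth does not exceed the global median depth of valid bins
#' are dropped. Disabled by default (every noise region is reported as
#' a TD candidate).
#'
#' @param regions regions with a \code{meanRd} column.
#' @param profile the processed [BinProfile-class].
#' @param enabled apply the filter (default FALSE).
#' @return the (possibly filtered) regions.
#' @export
filterDuplicationLike <- function(regions, profile, enabled = FALSE) {
    if (!enabled || !length(regions))
        return(regions)
    mc <- S4Vectors::mcols(binRanges(profile))
    rdCol <- if ("rdSmooth" %in% colnames(mc)) mc$rdSmooth else mc$rd
    med <- stats::median(rdCol[mc$valid], na.rm = TRUE)
    regions[S4Vectors::mcols(regions)$meanRd > med]
}

.CALL_COLUMNS <- c("chrom", "start", "end", "name", "score",
                   "leftSupport", "rightSupport", "meanRd", "stage")

#' Write TD calls as BED-style text
#'
#' BED coordinates on disk are 0-based half-open; the in-memory GRanges
#' is 1-based inclusive. Columns: chrom, start, end, name (TD1, TD2,
#' ...), score (number of merged noise bins), leftSupport, rightSupport,
#' meanRd, stage. Deterministic ordering by (chrom, start). An empty
#' call set yields a header-only file.
#'
#' @param regions call regions (rough or refined).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCalls <- function(regions, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(.CALL_COLUMNS, collapse = "\t")), con)
    if (length(regions)) {
        regions <- sort(regions)
        mc <- S4Vectors::mcols(regions)
        df <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(regions)),
            start = GenomicRanges::start(regions) - 1L,
            end = GenomicRanges::end(regions),
            name = paste0("TD", seq_along(regions)),
            score = mc$nBins,
            leftSupport = mc$leftSupport,
            rightSupport = mc$rightSupport,
            meanRd = format(mc$meanRd, digits = 17, trim = TRUE,
                            scientific = FALSE),
            stage = mc$stage)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read TD calls written by [writeCalls()]
#'
#' @param path BED-style calls file.
#' @return a [GenomicRanges::GRanges] with the call metadata columns.
#' @export
readCalls <- function(path) {
    lines <- readLines(path)
    if (!length(grep("^[^#]", lines)))
        return(GenomicRanges::GRanges(
            seqnames = character(0), ranges = IRanges::IRanges(),
            stage = character(0), nBins = integer(0),
            leftSupport = integer(0), rightSupport = integer(0),
            meanRd = numeric(0)))
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            col.names = .CALL_COLUMNS,
                            colClasses = c("character", "integer",
                                           "integer", "character",
                                           "integer", "integer",
                                           "integer", "numeric",
                                           "character"))
    gr <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start + 1L, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        stage = df$stage, nBins = df$score,
        leftSupport = df$leftSupport, rightSupport = df$rightSupport,
        meanRd = df$meanRd)
    gr
}
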