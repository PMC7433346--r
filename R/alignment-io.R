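#' Load one chromosome of a reference FASTA as per-position masks
#'
#' Reads the chromosome sequence and computes the N mask and the G/C mask
#' used for bin filtering and GC-bias correction. Case is ignored.
#'
#' @param fastaPath path to a FASTA file.
#' @param chrom chromosome (record) name; the part of the FASTA header
#'   before the first whitespace.
#' @return a [ReferenceTrack-class] object.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "ACGTNacgtn"), fa)
#' rt <- loadReference(fa, "chrT")
#' sum(nMask(rt))   # 2
#' @export
loadReference <- function(fastaPath, chrom) {
    if (!file.exists(fastaPath))
        stop("FASTA file not found: ", fastaPath)
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (!chrom %in% names(seqs))
        stop("chromosome '", chrom, "' not found in ", fastaPath,
             "; available: ", paste(names(seqs), collapse = ", "))
    bases <- charToRaw(toupper(as.character(seqs[[chrom]])))
    nMask <- bases == charToRaw("N")
    gcMask <- bases == charToRaw("G") | bases == charToRaw("C")
    new("ReferenceTrack", chrom = chrom, nMask = as.logical(nMask),
        gcMask = as.logical(gcMask & !nMask))
}

## Shared BAM sanity checks: coordinate-sorted + indexed, chrom present.
.checkBam <- function(bamPath, chrom) {
    if (!file.exists(bamPath))
        stop("alignment file not found: ", bamPath)
    hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]
    if (!chrom %in% names(hdr$targets))
        stop("chromosome '", chrom, "' not in BAM header; available: ",
             paste(names(hdr$targets), collapse = ", "))
    hd <- unlist(hdr$text[names(hdr$text) == "@HD"])
    so <- grep("^SO:", hd, value = TRUE)
    if (length(so) && !any(so == "SO:coordinate"))
        stop("BAM is not coordinate-sorted (", so[1],
             "); sort it with 'samtools sort' first")
    bai <- c(paste0(bamPath, ".bai"), sub("\\.bam$", ".bai", bamPath))
    if (!any(file.exists(bai)))
        stop("BAM index not found; index with 'samtools index ",
             bamPath, "'")
    unname(hdr$targets[chrom])
}

## Keep primary, mapped, non-duplicate records only. Low-MAPQ reads are
## deliberately retained: degraded mapping quality inside duplicated
## regions is one of the two clustering features.
.primaryFlag <- function() {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isDuplicate = FALSE)
}

#' Extract per-position read count and mapping quality from a BAM
#'
#' Builds the per-base pileup for one chromosome: every reference base
#' aligned as a match (CIGAR M/=/X) in a retained record increments the
#' read count at that position and contributes the record's MAPQ. A read
#' straddling a bin boundary therefore contributes to both bins.
#' Secondary, supplementary, unmapped and duplicate-flagged records are
#' skipped; no MAPQ filter is applied. Positions that are N in the
#' reference are set to \code{NA}.
#'
#' @param bamPath coordinate-sorted, indexed BAM.
#' @param chrom chromosome name.
#' @param ref the matching [ReferenceTrack-class].
#' @return a [PositionSignals-class] object.
#' @export
extractPositionSignals <- function(bamPath, chrom, ref) {
    stopifnot(is(ref, "ReferenceTrack"), chromName(ref) == chrom)
    seqlen <- .checkBam(bamPath, chrom)
    if (seqlen != seqLength(ref))
        stop("reference length (", seqLength(ref),
             ") does not match BAM header (", seqlen, ") for ", chrom)
    param <- Rsamtools::ScanBamParam(
        flag = .primaryFlag(),
        what = c("pos", "cigar", "mapq"),
        which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1, seqlen)))
    rec <- Rsamtools::scanBam(bamPath, param = param)[[1]]
    rc <- numeric(seqlen)
    mqSum <- numeric(seqlen)
    if (length(rec$pos)) {
        mapq <- rec$mapq
        mapq[is.na(mapq)] <- 0
        rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
            rec$cigar, pos = rec$pos, ops = c("M", "=", "X"))
        flat <- unlist(rl, use.names = FALSE)
        grp <- rep(seq_along(rl), lengths(rl))
        # clip to chromosome bounds
        flat <- IRanges::restrict(flat, start = 1L, end = as.integer(seqlen))
        keep <- IRanges::width(flat) > 0L
        flat <- flat[keep]; grp <- grp[keep]
        rc <- as.numeric(IRanges::coverage(flat, width = seqlen))
        mqSum <- as.numeric(
            IRanges::coverage(flat, width = seqlen, weight = mapq[grp]))
    }
    mq <- numeric(seqlen)
    covered <- rc > 0
    mq[covered] <- mqSum[covered] / rc[covered]
    rc[nMask(ref)] <- NA_real_
    mq[nMask(ref)] <- NA_real_
    new("PositionSignals", chrom = chrom, readCount = rc, mqMean = mq)
}

#' Extract split-read (clipped) signals from a BAM
#'
#' Scans for records whose CIGAR consists of exactly one clip (soft or
#' hard) and one match, the two discordant shapes that pin TD
#' breakpoints: clip-first (\code{xS(L-x)M}, "post-alignment") anchors
#' the low boundary at the record's mapped position, and clip-last
#' (\code{yM(L-y)S}, "pre-alignment") anchors the high boundary at
#' \code{pos + y - 1}. All other CIGAR shapes are ignored, as are clips
#' shorter than \code{minClipLen} (short clips are dominated by
#' sequencing error).
#'
#' @param bamPath coordinate-sorted, indexed BAM.
#' @param chrom chromosome name.
#' @param minClipLen minimum clip length in bases (default 10).
#' @return a data.frame with columns \code{pos} (1-based leftmost mapped
#'   position of the matched segment), \code{kind}
#'   (\code{"pre_alignment"}/\code{"post_alignment"}), \code{matchedLen},
#'   \code{clipLen}, \code{readLen}, \code{breakpoint} (the implied
#'   1-based breakpoint: \code{pos} for post-alignment,
#'   \code{pos + matchedLen - 1} for pre-alignment).
#' @export
extractSplitSignals <- function(bamPath, chrom, minClipLen = 10L) {
    .checkBam(bamPath, chrom)
    hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]
    seqlen <- unname(hdr$targets[chrom])
    param <- Rsamtools::ScanBamParam(
        flag = .primaryFlag(),
        what = c("pos", "cigar"),
        which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1, seqlen)))
    rec <- Rsamtools::scanBam(bamPath, param = param)[[1]]
    cig <- rec$cigar
    pos <- rec$pos
    out <- data.frame(pos = integer(0), kind = character(0),
                      matchedLen = integer(0), clipLen = integer(0),
                      readLen = integer(0), breakpoint = integer(0))
    if (!length(cig))
        return(out)
    isPost <- grepl("^[0-9]+[SH][0-9]+M$", cig)
    isPre <- grepl("^[0-9]+M[0-9]+[SH]$", cig)
    res <- list()
    if (any(isPost)) {
        cc <- cig[isPost]
        clip <- as.integer(sub("^([0-9]+)[SH].*$", "\\1", cc))
        mat <- as.integer(sub("^[0-9]+[SH]([0-9]+)M$", "\\1", cc))
        res$post <- data.frame(pos = pos[isPost],
                               kind = "post_alignment",
                               matchedLen = mat, clipLen = clip,
                               readLen = clip + mat,
                               breakpoint = pos[isPost])
    }
    if (any(isPre)) {
        cc <- cig[isPre]
        mat <- as.integer(sub("^([0-9]+)M.*$", "\\1", cc))
        clip <- as.integer(sub("^[0-9]+M([0-9]+)[SH]$", "\\1", cc))
        res$pre <- data.frame(pos = pos[isPre], kind = "pre_alignment",
                              matchedLen = mat, clipLen = clip,
                              readLen = clip + mat,
                              breakpoint = pos[isPre] + mat - 1L)
    }
    out <- do.call(rbind, res)
    if (is.null(out) || !nrow(out))
        return(data.frame(pos = integer(0), kind = character(0),
                          matchedLen = integer(0), clipLen = integer(0),
                          readLen = integer(0), breakpoint = integer(0)))
    out <- out[out$clipLen >= minClipLen, , drop = FALSE]
    out <- out[order(out$pos, out$kind, out$matchedLen), , drop = FALSE]
    rownames(out) <- NULL
    out
}
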