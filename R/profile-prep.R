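#' Summarize position signals into non-overlapping bins
#'
#' Tiles the chromosome with bins of \code{lenBin} bases and computes,
#' per bin, the read depth RD (mean per-position read count), the
#' mapping quality MQ (mean per-position mean MAPQ) and the GC fraction
#' (G/C bases over non-N bases). A bin containing any N position has an
#' undefined depth and is marked invalid; invalid bins are excluded from
#' all downstream statistics. A terminal partial bin is kept when it
#' covers at least half of \code{lenBin}, otherwise dropped.
#'
#' @param ps a [PositionSignals-class].
#' @param ref the matching [ReferenceTrack-class].
#' @param lenBin bin width in bases (default 2000).
#' @return a [BinProfile-class].
#' @export
binSignals <- function(ps, ref, lenBin = 2000L) {
    stopifnot(is(ps, "PositionSignals"), is(ref, "ReferenceTrack"))
    if (chromName(ps) != chromName(ref) ||
        seqLength(ps) != seqLength(ref))
        stop("position signals and reference track do not match")
    lenBin <- as.integer(lenBin)
    if (lenBin < 1L) stop("'lenBin' must be >= 1")
    L <- seqLength(ps)
    if (lenBin > L) {
        warning("'lenBin' (", lenBin, ") exceeds chromosome length (",
                L, "); using a single bin")
        starts <- 1L
    } else {
        starts <- seq.int(1L, L, by = lenBin)
    }
    ends <- pmin(starts + lenBin - 1L, L)
    widths <- ends - starts + 1L
    # terminal partial bin: keep only if >= half a bin
    keep <- widths >= ceiling(lenBin / 2) | seq_along(starts) == 1L
    starts <- starts[keep]; ends <- ends[keep]; widths <- widths[keep]

    f <- rep.int(seq_along(starts), widths)
    npos <- sum(widths)
    rc <- readCount(ps)[seq_len(npos)]
    mq <- mqMean(ps)[seq_len(npos)]
    nm <- nMask(ref)[seq_len(npos)]
    gcm <- gcMask(ref)[seq_len(npos)]

    rd <- as.numeric(rowsum(rc, f)) / widths       # NA propagates
    mqBin <- as.numeric(rowsum(mq, f)) / widths
    nonN <- as.numeric(rowsum(as.numeric(!nm), f))
    gcCount <- as.numeric(rowsum(as.numeric(gcm), f))
    gc <- ifelse(nonN > 0, gcCount / nonN, NA_real_)
    valid <- !is.na(rd)

    gr <- GenomicRanges::GRanges(chromName(ps),
                                 IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        rd = rd, mq = mqBin, gc = gc, valid = valid)
    new("BinProfile", bins = gr, lenBin = lenBin)
}

#' GC-bias correction by stratified median scaling
#'
#' Rescales each bin's value by the ratio of the global median to the
#' median of bins with a similar GC fraction:
#' \deqn{\tilde r_i = \frac{n}{n_{GC}} \, r_i,}
#' where \eqn{n} is the median over all supplied bins and \eqn{n_{GC}}
#' the median over bins \eqn{j} with \eqn{|gc_j - gc_i| \le} the
#' similarity window (default 0.001). Applied independently to the RD
#' and MQ tracks. If a bin's GC stratum has median 0 its corrected value
#' is set to 0 with a warning (the ratio would be infinite).
#'
#' @param values numeric vector over valid bins.
#' @param gc matching GC fractions in [0, 1].
#' @param window GC similarity half-width (default 0.001).
#' @return corrected values, same length.
#' @export
gcCorrect <- function(values, gc, window = 0.001) {
    stopifnot(length(values) == length(gc), window > 0)
    if (anyNA(values) || anyNA(gc))
        stop("'values' and 'gc' must not contain NA (valid bins only)")
    if (!length(values)) return(values)
    n <- stats::median(values)
    # bins sharing one GC value share one stratum: compute n_GC per
    # unique GC value only
    ug <- unique(gc)
    nGCu <- vapply(ug, function(g)
        stats::median(values[abs(gc - g) <= window]), numeric(1))
    nGC <- nGCu[match(gc, ug)]
    zero <- any(nGC == 0)
    out <- ifelse(nGC == 0, 0, n / nGC * values)
    if (zero)
        warning("some GC strata have median 0; their corrected values ",
                "were set to 0")
    out
}

#' Rescale the MQ track onto the RD range
#'
#' Affine min-max transform so that both clustering features share one
#' scale (MAPQ is otherwise an order of magnitude larger than depth and
#' would dominate the Euclidean distance):
#' \deqn{\widetilde{MQ} = \frac{MQ - MQ_{min}}{MQ_{max} - MQ_{min}}
#'   (RD_{max} - RD_{min}) + RD_{min}.}
#' Monotone, so the ordering (and shape) of the MQ values is unchanged;
#' the output range is exactly \code{[min(rd), max(rd)]}.
#'
#' @param mq MQ values over valid bins.
#' @param rd RD values over the same bins (defines the target range).
#' @return rescaled MQ values.
#' @export
normalizeMQ <- function(mq, rd) {
    stopifnot(length(mq) == length(rd))
    if (anyNA(mq) || anyNA(rd))
        stop("'mq' and 'rd' must not contain NA (valid bins only)")
    rng <- range(mq)
    rdRng <- range(rd)
    if (rng[1] == rng[2]) {
        warning("all MQ values identical; mapping to the RD midpoint")
        return(rep(mean(rdRng), length(mq)))
    }
    (mq - rng[1]) / (rng[2] - rng[1]) * (rdRng[2] - rdRng[1]) + rdRng[1]
}

#' Run the full per-bin preprocessing chain
#'
#' On the valid bins of a raw [BinProfile-class]: GC-correct RD and MQ,
#' TV-denoise both corrected tracks with one shared penalty, then
#' rescale the denoised MQ onto the denoised RD range. Adds the columns
#' \code{rdCorr}, \code{mqCorr}, \code{rdSmooth}, \code{mqSmooth},
#' \code{mqNorm} (NA on invalid bins). The (\code{rdSmooth},
#' \code{mqNorm}) pairs are the 2D point cloud handed to clustering.
#'
#' @param bp a raw [BinProfile-class] from [binSignals()].
#' @param lam TV penalty (default 0.25).
#' @param gcWindow GC similarity half-width (default 0.001).
#' @return the [BinProfile-class] with processed columns added.
#' @export
prepareProfile <- function(bp, lam = 0.25, gcWindow = 0.001) {
    stopifnot(is(bp, "BinProfile"))
    gr <- binRanges(bp)
    mc <- S4Vectors::mcols(gr)
    v <- which(mc$valid)
    na <- rep(NA_real_, length(gr))
    mc$rdCorr <- mc$mqCorr <- mc$rdSmooth <- mc$mqSmooth <- mc$mqNorm <- na
    if (length(v) >= 1L) {
        rdCorr <- gcCorrect(mc$rd[v], mc$gc[v], gcWindow)
        mqCorr <- gcCorrect(mc$mq[v], mc$gc[v], gcWindow)
        rdSmooth <- tvDenoise(rdCorr, lam)
        mqSmooth <- tvDenoise(mqCorr, lam)
        mqNorm <- if (length(v) == 1L) rdSmooth else
            normalizeMQ(mqSmooth, rdSmooth)
        mc$rdCorr[v] <- rdCorr
        mc$mqCorr[v] <- mqCorr
        mc$rdSmooth[v] <- rdSmooth
        mc$mqSmooth[v] <- mqSmooth
        mc$mqNorm[v] <- mqNorm
    }
    S4Vectors::mcols(gr) <- mc
    new("BinProfile", bins = gr, lenBin = binSize(bp))
}

#' Write a bin profile as TSV (for debugging/inspection)
#'
#' @param bp a [BinProfile-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfile <- function(bp, path) {
    gr <- binRanges(bp)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,   # BED-style on disk
        end = GenomicRanges::end(gr),
        as.data.frame(S4Vectors::mcols(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
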