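## Evaluate code under a temporary RNG state so that simulator calls are
## reproducible under `seed` without disturbing the caller's stream.
.withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
        if (had)
            old <- get(".Random.seed", envir = globalenv())
        on.exit(if (had) assign(".Random.seed", old,
                                envir = globalenv())
                else suppressWarnings(rm(".Random.seed",
                                         envir = globalenv())))
        set.seed(as.integer(seed))
    }
    code
}

#' Simulate a reference chromosome
#'
#' I.i.d. A/C/G/T bases with a configurable GC fraction, plus optional
#' injected runs of N (to exercise the bin-filtering path).
#' Deterministic under \code{seed}.
#'
#' @param length chromosome length in bases.
#' @param gcTarget target GC fraction (default 0.41, human-like).
#' @param nRuns optional integer matrix/data.frame with columns
#'   \code{start}, \code{len}: runs of N to inject (1-based starts).
#' @param chrom chromosome name (default "simchr").
#' @param seed RNG seed.
#' @return a named list: \code{seq} (a [Biostrings::DNAStringSet] of
#'   length 1) and \code{chrom}.
#' @export
simulateReference <- function(length, gcTarget = 0.41, nRuns = NULL,
                              chrom = "simchr", seed = NULL) {
    stopifnot(length >= 1, gcTarget >= 0, gcTarget <= 1)
    .withSeed(seed, {
        probs <- c(A = (1 - gcTarget) / 2, C = gcTarget / 2,
                   G = gcTarget / 2, T = (1 - gcTarget) / 2)
        bases <- charToRaw("ACGT")[sample.int(4L, length,
                                              replace = TRUE,
                                              prob = probs)]
        if (!is.null(nRuns)) {
            nRuns <- as.data.frame(nRuns)
            for (i in seq_len(nrow(nRuns))) {
                s <- nRuns$start[i]
                e <- min(s + nRuns$len[i] - 1L, length)
                bases[s:e] <- charToRaw("N")
            }
        }
        seq <- Biostrings::DNAStringSet(rawToChar(bases))
        names(seq) <- chrom
        list(seq = seq, chrom = chrom)
    })
}

#' Embed tandem duplications into a reference sequence
#'
#' Chooses non-overlapping source segments and builds the donor genome
#' in which each segment of length l with copy count k is immediately
#' followed by k extra tandem copies (donor length grows by the sum of
#' k*l). The truth set records the reference-coordinate span of each
#' source segment.
#'
#' @param refSeq reference sequence: a [Biostrings::DNAStringSet] of
#'   length 1 (as from [simulateReference()]), a
#'   [Biostrings::DNAString], or a character string.
#' @param nTD number of TDs to embed (default 10).
#' @param copyRange integer range of extra copy counts (default 1..6).
#' @param lenRange integer range of TD lengths in bases (default
#'   10000..50000).
#' @param margin minimum distance of a TD from either chromosome end
#'   (default 10000).
#' @param minGap minimum gap between TDs (default 10000; keeps junction
#'   reads of neighbouring events from interfering).
#' @param chrom chromosome name for the truth set.
#' @param seed RNG seed.
#' @param maxTries placement retries before giving up.
#' @return list: \code{donorSeq} ([Biostrings::DNAStringSet]),
#'   \code{truth} (sorted disjoint [GenomicRanges::GRanges] with
#'   metadata \code{nCopies}).
#' @export
embedTandemDuplications <- function(refSeq, nTD = 10L,
                                    copyRange = c(1L, 6L),
                                    lenRange = c(10000L, 50000L),
                                    margin = 10000L, minGap = 10000L,
                                    chrom = "simchr", seed = NULL,
                                    maxTries = 1000L) {
    refChar <- .asSingleSequence(refSeq)
    L <- nchar(refChar)
    stopifnot(nTD >= 1L, lenRange[1] >= 1L,
              copyRange[1] >= 1L, copyRange[2] >= copyRange[1])
    .withSeed(seed, {
        lens <- sample.int(lenRange[2] - lenRange[1] + 1L, nTD,
                           replace = TRUE) + lenRange[1] - 1L
        copies <- sample.int(copyRange[2] - copyRange[1] + 1L, nTD,
                             replace = TRUE) + copyRange[1] - 1L
        starts <- .placeDisjoint(L, lens, margin, minGap, maxTries)
        ord <- order(starts)
        starts <- starts[ord]
        lens <- lens[ord]
        copies <- copies[ord]
        truth <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(starts, width = lens),
            nCopies = as.integer(copies))
        pieces <- character(0)
        cursor <- 1L
        for (i in seq_len(nTD)) {
            s <- starts[i]; e <- s + lens[i] - 1L
            pieces <- c(pieces, substring(refChar, cursor, e),
                        rep(substring(refChar, s, e), copies[i]))
            cursor <- e + 1L
        }
        pieces <- c(pieces, substring(refChar, cursor, L))
        donor <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
        names(donor) <- paste0(chrom, "_donor")
        list(donorSeq = donor, truth = truth)
    })
}

.asSingleSequence <- function(x) {
    if (is(x, "DNAStringSet")) {
        stopifnot(length(x) == 1L)
        as.character(x[[1L]])
    } else if (is(x, "DNAString")) {
        as.character(x)
    } else if (is.character(x) && length(x) == 1L) {
        x
    } else stop("unsupported sequence representation")
}

## Rejection-sample disjoint placements (one start per supplied length,
## kept in the same order) with end margins and inter-TD gaps.
.placeDisjoint <- function(L, lens, margin, minGap, maxTries) {
    n <- length(lens)
    need <- sum(lens) + 2 * margin + (n - 1) * minGap
    if (need > L)
        stop("cannot place ", n, " TDs of total length ", sum(lens),
             " in a ", L, " bp chromosome with margin ", margin,
             " and gap ", minGap)
    for (try in seq_len(maxTries)) {
        hi <- L - margin - lens + 1L
        lo <- margin + 1L
        starts <- lo + vapply(hi - lo + 1L,
                              function(w) sample.int(w, 1L) - 1L,
                              integer(1))
        ord <- order(starts)
        ends <- starts + lens - 1L
        ok <- n == 1L ||
            all(starts[ord][-1L] - ends[ord][-n] > minGap)
        if (ok)
            return(starts)
    }
    stop("failed to place TDs disjointly after ", maxTries, " tries")
}

## Donor -> reference colinear block map. Each block maps donor
## positions [dStart, dEnd] onto reference positions starting at
## rStart; consecutive blocks that continue the reference are merged,
## so every remaining internal boundary is a duplication junction.
.donorBlockMap <- function(truth, refLen) {
    s <- GenomicRanges::start(truth)
    e <- GenomicRanges::end(truth)
    k <- S4Vectors::mcols(truth)$nCopies
    dStart <- integer(0); rStart <- integer(0); len <- integer(0)
    cursor <- 1L; d <- 1L
    addBlock <- function(rs, l) {
        dStart <<- c(dStart, d); rStart <<- c(rStart, rs)
        len <<- c(len, l); d <<- d + l
    }
    for (i in seq_along(truth)) {
        addBlock(cursor, e[i] - cursor + 1L)          # ... up to e_i
        for (j in seq_len(k[i])) addBlock(s[i], e[i] - s[i] + 1L)
        cursor <- e[i] + 1L
    }
    addBlock(cursor, refLen - cursor + 1L)
    # merge reference-continuous neighbours
    keep <- c(TRUE, rStart[-1L] != rStart[-length(rStart)] +
                  len[-length(len)])
    grp <- cumsum(keep)
    data.frame(
        dStart = as.integer(tapply(dStart, grp, min)),
        rStart = as.integer(tapply(rStart, grp, min)),
        len = as.integer(tapply(len, grp, sum)))
}

#' Render aligner-style reads for a simulated sample directly to BAM
#'
#' Draws single-end reads uniformly from a donor/reference mixture
#' (fraction \code{purity} from the donor — the "tumor purity" of the
#' sample) and writes the alignment records a read aligner would
#' produce, without running one: reads from extra tandem copies map
#' back onto the source segment (raising depth there), and reads
#' spanning a copy junction are emitted with the clipped CIGAR shapes
#' \code{yM(L-y)S} (longer matched prefix; pre-alignment) or
#' \code{xS(L-x)M} (longer matched suffix; post-alignment) anchored at
#' the true breakpoints. MAPQ is \code{mapqHigh} everywhere except for
#' donor-origin reads overlapping an embedded TD span, which draw
#' uniformly from \code{0..mapqLowMax}, mimicking the degraded
#' confidence of multi-mapping reads; a purity-0 sample therefore
#' carries no TD signal. The output BAM is coordinate-sorted and
#' indexed.
#'
#' @param refSeq reference sequence (any form accepted by
#'   [embedTandemDuplications()]).
#' @param donorSeq donor sequence from [embedTandemDuplications()].
#' @param truth the truth [GenomicRanges::GRanges].
#' @param outPrefix output path prefix; writes
#'   \code{<outPrefix>.bam/.bam.bai}.
#' @param coverage mean fold coverage over the reference (default 30).
#' @param purity donor read fraction in (0, 1] (default 0.9); 0 gives a
#'   pure reference sample.
#' @param readLen read length (default 100).
#' @param mapqHigh MAPQ outside duplicated spans (default 60).
#' @param mapqLowMax MAPQ inside duplicated spans is uniform on
#'   0..mapqLowMax (default 30).
#' @param errRate per-base substitution error rate (default 0).
#' @param withSeq emit real base sequences (default TRUE); FALSE writes
#'   SEQ "*" for compactness.
#' @param chrom chromosome name (must match the truth set).
#' @param seed RNG seed.
#' @param fastqOut optional path: also write the reads as FASTQ so a
#'   real aligner can be run instead.
#' @return path of the BAM file, invisibly.
#' @export
renderBam <- function(refSeq, donorSeq, truth, outPrefix,
                      coverage = 30, purity = 0.9, readLen = 100L,
                      mapqHigh = 60L, mapqLowMax = 30L, errRate = 0,
                      withSeq = TRUE, chrom = "simchr", seed = NULL,
                      fastqOut = NULL) {
    refChar <- .asSingleSequence(refSeq)
    donorChar <- .asSingleSequence(donorSeq)
    refLen <- nchar(refChar)
    donorLen <- nchar(donorChar)
    stopifnot(purity >= 0, purity <= 1, coverage > 0,
              readLen >= 2L, readLen < refLen)
    .withSeed(seed, {
        nTotal <- round(coverage * refLen / readLen)
        nDonor <- round(purity * nTotal)
        nRef <- nTotal - nDonor
        blocks <- .donorBlockMap(truth, refLen)
        dEnd <- blocks$dStart + blocks$len - 1L

        ## donor-origin reads
        d1 <- if (nDonor > 0)
            sample.int(donorLen - readLen + 1L, nDonor, replace = TRUE)
        else integer(0)
        t1 <- findInterval(d1, blocks$dStart)
        d2 <- d1 + readLen - 1L
        inside <- d2 <= dEnd[t1]
        # defensive: drop reads spanning more than one junction
        spill <- !inside & (t1 >= nrow(blocks) | d2 > dEnd[pmin(t1 + 1L,
                                                      nrow(blocks))])
        keep <- !spill
        d1 <- d1[keep]; d2 <- d2[keep]; t1 <- t1[keep]
        inside <- inside[keep]
        posIn <- d1 - blocks$dStart[t1] + blocks$rStart[t1]
        leftLen <- dEnd[t1] - d1 + 1L
        rightLen <- readLen - leftLen
        nD <- length(d1)
        fullM <- paste0(readLen, "M")
        pos <- posIn
        cigar <- rep.int(fullM, nD)
        mEnd <- posIn + readLen - 1L
        pre <- !inside & leftLen >= rightLen      # clip-last junction
        pst <- !inside & leftLen < rightLen       # clip-first junction
        if (any(pre)) {
            cigar[pre] <- paste0(leftLen[pre], "M", rightLen[pre], "S")
            mEnd[pre] <- posIn[pre] + leftLen[pre] - 1L
        }
        if (any(pst)) {
            pos[pst] <- blocks$rStart[t1[pst] + 1L]
            cigar[pst] <- paste0(leftLen[pst], "S", rightLen[pst], "M")
            mEnd[pst] <- pos[pst] + rightLen[pst] - 1L
        }
        donorReads <- data.frame(pos = as.integer(pos), cigar = cigar,
                                 mEnd = as.integer(mEnd),
                                 srcStart = d1,
                                 donorOrigin = rep(TRUE, nD))

        ## reference-origin (normal contamination) reads
        refReads <- if (nRef > 0) {
            p <- sample.int(refLen - readLen + 1L, nRef, replace = TRUE)
            data.frame(pos = p, cigar = paste0(readLen, "M"),
                       mEnd = p + readLen - 1L, srcStart = p,
                       donorOrigin = FALSE)
        } else {
            data.frame(pos = integer(0), cigar = character(0),
                       mEnd = integer(0), srcStart = integer(0),
                       donorOrigin = logical(0))
        }
        reads <- rbind(donorReads, refReads)
        n <- nrow(reads)

        ## MAPQ: degraded for donor-origin reads overlapping an
        ## embedded TD span (the reads the aligner would consider
        ## multi-mapping); reference-origin reads stay confident, so a
        ## purity-0 sample carries no TD signal at all
        inDup <- rep(FALSE, n)
        for (i in seq_along(truth)) {
            inDup <- inDup | (reads$donorOrigin &
                              reads$pos <= GenomicRanges::end(truth)[i] &
                              reads$mEnd >= GenomicRanges::start(truth)[i])
        }
        mapq <- rep(as.integer(mapqHigh), n)
        if (any(inDup))
            mapq[inDup] <- sample.int(mapqLowMax + 1L, sum(inDup),
                                      replace = TRUE) - 1L

        ## sequences
        seqs <- if (withSeq) {
            src <- character(n)
            isD <- reads$donorOrigin
            src[isD] <- substring(donorChar, reads$srcStart[isD],
                                  reads$srcStart[isD] + readLen - 1L)
            src[!isD] <- substring(refChar, reads$srcStart[!isD],
                                   reads$srcStart[!isD] + readLen - 1L)
            if (errRate > 0)
                src <- .addSubstitutions(src, errRate)
            src
        } else rep("*", n)

        ord <- order(reads$pos)
        qname <- paste0("r", seq_len(n))
        sam <- tempfile(fileext = ".sam")
        header <- c("@HD\tVN:1.6\tSO:coordinate",
                    paste0("@SQ\tSN:", chrom, "\tLN:", refLen))
        lines <- paste(qname[ord], 0L, chrom, reads$pos[ord],
                       mapq[ord], reads$cigar[ord], "*", 0L, 0L,
                       seqs[ord], "*", sep = "\t")
        writeLines(c(header, lines), sam)
        bam <- Rsamtools::asBam(sam, destination = outPrefix,
                                overwrite = TRUE,
                                indexDestination = TRUE)
        unlink(sam)
        if (!is.null(fastqOut)) {
            if (!withSeq)
                stop("fastqOut requires withSeq = TRUE")
            fq <- paste0("@", qname, "\n", seqs, "\n+\n",
                         strrep("I", readLen))
            writeLines(fq, fastqOut)
        }
        invisible(bam)
    })
}

.addSubstitutions <- function(seqs, errRate) {
    nt <- c("A", "C", "G", "T")
    vapply(seqs, function(s) {
        L <- nchar(s)
        nerr <- stats::rbinom(1L, L, errRate)
        if (nerr == 0L) return(s)
        at <- sample.int(L, nerr)
        ch <- strsplit(s, "")[[1L]]
        ch[at] <- sample(nt, nerr, replace = TRUE)
        paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Write / read a truth set as BED
#'
#' On-disk coordinates are 0-based half-open; columns chrom, start,
#' end, name, nCopies.
#'
#' @param truth a truth [GenomicRanges::GRanges] with \code{nCopies}.
#' @param path BED path.
#' @return \code{writeTruth}: the path, invisibly; \code{readTruth}:
#'   the truth GRanges.
#' @export
writeTruth <- function(truth, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tnCopies", con)
    if (length(truth)) {
        df <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(truth)),
            start = GenomicRanges::start(truth) - 1L,
            end = GenomicRanges::end(truth),
            name = paste0("truth", seq_along(truth)),
            nCopies = S4Vectors::mcols(truth)$nCopies)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    lines <- readLines(path)
    if (!length(grep("^[^#]", lines)))
        return(GenomicRanges::GRanges(nCopies = integer(0)))
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            col.names = c("chrom", "start", "end",
                                          "name", "nCopies"))
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end),
                           nCopies = as.integer(df$nCopies))
}

#' Simulate a complete benchmark sample
#'
#' One call that simulates a reference, embeds TDs, renders the BAM and
#' writes everything (\code{ref.fa}, \code{donor.fa}, \code{truth.bed},
#' \code{reads.bam(.bai)}) under a directory. Defaults follow the
#' benchmark conditions used throughout the package documentation:
#' 10 TDs of 10--50 kb with 1--6 extra copies, 30x coverage, purity
#' 0.9, 100 bp reads.
#'
#' @param outDir output directory (created if missing).
#' @param refLength reference length (default 5 Mb).
#' @param gcTarget reference GC fraction.
#' @param nTD,copyRange,lenRange,margin,minGap see
#'   [embedTandemDuplications()].
#' @param coverage,purity,readLen,mapqHigh,mapqLowMax,errRate,withSeq
#'   see [renderBam()].
#' @param chrom chromosome name.
#' @param seed RNG seed; the whole sample is deterministic under it.
#' @return list with paths (\code{ref}, \code{donor}, \code{truthBed},
#'   \code{bam}) and the in-memory \code{truth} GRanges and
#'   \code{chrom}.
#' @export
simulateSample <- function(outDir, refLength = 5e6, gcTarget = 0.41,
                           nTD = 10L, copyRange = c(1L, 6L),
                           lenRange = c(10000L, 50000L),
                           margin = 10000L, minGap = 10000L,
                           coverage = 30, purity = 0.9,
                           readLen = 100L, mapqHigh = 60L,
                           mapqLowMax = 30L, errRate = 0,
                           withSeq = TRUE, chrom = "simchr",
                           seed = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .withSeed(seed, {
        ref <- simulateReference(refLength, gcTarget, chrom = chrom)
        emb <- embedTandemDuplications(ref$seq, nTD = nTD,
                                       copyRange = copyRange,
                                       lenRange = lenRange,
                                       margin = margin,
                                       minGap = minGap, chrom = chrom)
        refFa <- file.path(outDir, "ref.fa")
        donorFa <- file.path(outDir, "donor.fa")
        Biostrings::writeXStringSet(ref$seq, refFa)
        Biostrings::writeXStringSet(emb$donorSeq, donorFa)
        truthBed <- file.path(outDir, "truth.bed")
        writeTruth(emb$truth, truthBed)
        bam <- renderBam(ref$seq, emb$donorSeq, emb$truth,
                         outPrefix = file.path(outDir, "reads"),
                         coverage = coverage, purity = purity,
                         readLen = readLen, mapqHigh = mapqHigh,
                         mapqLowMax = mapqLowMax, errRate = errRate,
                         withSeq = withSeq, chrom = chrom)
        list(ref = refFa, donor = donorFa, truthBed = truthBed,
             bam = bam, truth = emb$truth, chrom = chrom)
    })
}
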