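# Independent oracles and tiny fixture builders shared across tests.

# Exact TV minimizer via the dual box-constrained QP:
# min_u 1/2 ||b - D'u||^2  s.t.  -lam <= u <= lam,  a = b - D'u.
# A completely different route (interior active-set QP) from the
# package's direct algorithm.
tvOracleQP <- function(b, lam) {
    n <- length(b)
    if (n == 1L || lam == 0)
        return(b)
    D <- diff(diag(n))
    Dmat <- D %*% t(D)
    m <- n - 1L
    u <- quadprog::solve.QP(Dmat, as.numeric(D %*% b),
                            cbind(diag(m), -diag(m)),
                            rep(-lam, 2L * m))$solution
    as.numeric(b - t(D) %*% u)
}

# Naive all-pairs DBSCAN sharing only the label-propagation helper.
naiveNeighborhoods <- function(pts, eps) {
    d2 <- outer(pts[, 1], pts[, 1], "-")^2 +
          outer(pts[, 2], pts[, 2], "-")^2
    lapply(seq_len(nrow(pts)), function(i) which(d2[i, ] <= eps^2))
}

naiveDbscan <- function(pts, eps, minPts) {
    TandemScan:::.dbscanFromNeighborhoods(
        naiveNeighborhoods(pts, eps), minPts)
}

bruteRange <- function(pts, q, eps) {
    sort(which((pts[, 1] - q[1])^2 + (pts[, 2] - q[2])^2 <= eps^2))
}

# Build a sorted, indexed BAM from hand-written alignment rows.
# rows: data.frame(qname, flag, pos, mapq, cigar, seq)
makeBam <- function(rows, chrom = "chrT", seqlen = 100000L,
                    prefix = tempfile()) {
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                paste0("@SQ\tSN:", chrom, "\tLN:", seqlen))
    rows <- rows[order(rows$pos), , drop = FALSE]
    lines <- paste(rows$qname, rows$flag, chrom, rows$pos, rows$mapq,
                   rows$cigar, "*", 0L, 0L, rows$seq, "*", sep = "\t")
    sam <- paste0(prefix, ".sam")
    writeLines(c(header, lines), sam)
    bam <- Rsamtools::asBam(sam, destination = prefix,
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    bam
}

alnRow <- function(qname, pos, cigar, mapq = 60L, flag = 0L,
                   seq = NULL) {
    if (is.null(seq)) {
        # query length = sum of query-consuming ops (M/I/S/=/X)
        ops <- regmatches(cigar,
                          gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
        qlen <- sum(vapply(ops, function(o) {
            if (grepl("[MIS=X]$", o))
                as.integer(sub("[A-Z=]$", "", o)) else 0L
        }, integer(1)))
        seq <- strrep("A", qlen)
    }
    data.frame(qname = qname, flag = flag, pos = pos, mapq = mapq,
               cigar = cigar, seq = seq)
}

# Write a FASTA with one record.
makeFasta <- function(seqChar, chrom = "chrT", path = tempfile(fileext = ".fa")) {
    writeLines(c(paste0(">", chrom), seqChar), path)
    path
}

# Raw BinProfile straight from vectors (for caller-level tests).
makeProfile <- function(rd, valid = !is.na(rd), lenBin = 2000L,
                        chrom = "chrT", mq = NULL, gc = NULL) {
    n <- length(rd)
    starts <- seq.int(1L, by = lenBin, length.out = n)
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts, starts + lenBin - 1L))
    if (is.null(mq)) mq <- rep(60, n)
    if (is.null(gc)) gc <- rep(0.5, n)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        rd = rd, mq = mq, gc = gc, valid = valid,
        rdSmooth = rd, mqSmooth = mq, mqNorm = mq)
    new("BinProfile", bins = gr, lenBin = as.integer(lenBin))
}
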