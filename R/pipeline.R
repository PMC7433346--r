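#' Tunable parameters of the TD-calling pipeline
#'
#' Central parameter object with the defaults used throughout:
#' \code{lenBin = 2000} (bin width, bp), \code{lam = 0.25} (TV
#' penalty), \code{eps = 0.7} (DBSCAN radius in the normalized feature
#' space), \code{minPts = 4} (twice the number of features),
#' \code{gcWindow = 0.001} (GC similarity half-width),
#' \code{searchPad} (split-read search half-width around each rough
#' boundary; defaults to one bin), \code{minClipLen = 10} (minimum
#' clip length of a usable split read), \code{dupFilter = FALSE}
#' (optional depth-direction filter), \code{bridgeInvalid = TRUE}
#' (merge noise runs across N-filtered bins), \code{leafSize = 16}
#' (k-d tree bucket size), \code{poolGenome = FALSE} (cluster all
#' chromosomes jointly instead of per chromosome).
#'
#' @param lenBin,lam,eps,minPts,gcWindow,searchPad,minClipLen,dupFilter,bridgeInvalid,leafSize,poolGenome
#'   see description.
#' @return a named list of validated parameters.
#' @export
tdParams <- function(lenBin = 2000L, lam = 0.25, eps = 0.7,
                     minPts = 4L, gcWindow = 0.001, searchPad = NULL,
                     minClipLen = 10L, dupFilter = FALSE,
                     bridgeInvalid = TRUE, leafSize = 16L,
                     poolGenome = FALSE) {
    if (is.null(searchPad))
        searchPad <- lenBin
    p <- list(lenBin = as.integer(lenBin), lam = lam, eps = eps,
              minPts = as.integer(minPts), gcWindow = gcWindow,
              searchPad = as.integer(searchPad),
              minClipLen = as.integer(minClipLen),
              dupFilter = isTRUE(dupFilter),
              bridgeInvalid = isTRUE(bridgeInvalid),
              leafSize = as.integer(leafSize),
              poolGenome = isTRUE(poolGenome))
    stopifnot(p$lenBin >= 1L, p$lam >= 0, p$eps > 0, p$minPts >= 1L,
              p$gcWindow > 0, p$searchPad >= 0L, p$minClipLen >= 0L)
    p
}

## One chromosome up to the (processed profile, splits) stage.
.profileChrom <- function(bamPath, fastaPath, chrom, params, verbose) {
    say <- function(...) if (verbose) message("[", chrom, "] ", ...)
    ref <- loadReference(fastaPath, chrom)
    say("reference loaded: ", seqLength(ref), " bp, ",
        sum(nMask(ref)), " N")
    ps <- extractPositionSignals(bamPath, chrom, ref)
    bp <- binSignals(ps, ref, params$lenBin)
    bp <- prepareProfile(bp, lam = params$lam,
                         gcWindow = params$gcWindow)
    mc <- S4Vectors::mcols(binRanges(bp))
    say("bins: ", length(binRanges(bp)), " total, ", sum(mc$valid),
        " valid")
    splits <- extractSplitSignals(bamPath, chrom, params$minClipLen)
    say("split signals: ", nrow(splits))
    list(profile = bp, splits = splits)
}

## Noise bins -> refined calls for one chromosome.
.callChrom <- function(profile, splits, noiseValidIdx, params,
                       verbose, chrom) {
    say <- function(...) if (verbose) message("[", chrom, "] ", ...)
    vIdx <- validBins(profile)
    noiseIdx <- vIdx[noiseValidIdx]
    say("noise bins: ", length(noiseIdx))
    rough <- mergeNoiseBins(noiseIdx, profile,
                            bridgeInvalid = params$bridgeInvalid)
    say("rough regions: ", length(rough))
    refined <- refineBreakpoints(rough, splits, params$searchPad)
    refined <- filterDuplicationLike(refined, profile,
                                     enabled = params$dupFilter)
    say("refined regions: ", length(refined))
    refined
}

#' Detect tandem duplications from a BAM + reference FASTA
#'
#' The full two-stage pipeline. Stage one builds the per-bin
#' (read-depth, mapping-quality) profile — pileup, binning,
#' GC-correction, TV denoising, scale normalization — and labels bins
#' whose feature points are DBSCAN noise as TD candidates; consecutive
#' noise bins are merged into rough regions. Stage two refines each
#' rough boundary to nucleotide resolution using clipped split reads.
#'
#' @param bamPath coordinate-sorted, indexed BAM.
#' @param fastaPath reference FASTA containing the chromosomes.
#' @param chroms chromosomes to process; default: all in the BAM
#'   header.
#' @param params parameter list from [tdParams()].
#' @param verbose log per-stage counts via [message()] (default TRUE).
#' @return list: \code{calls} (GRanges over all chromosomes),
#'   \code{profiles} (named list of processed [BinProfile-class]),
#'   \code{splits} (named list of split-signal tables) and
#'   \code{params}.
#' @examples
#' \dontrun{
#' sim <- simulateSample(tempfile(), refLength = 1e6, nTD = 3,
#'                       lenRange = c(5000, 10000), seed = 1)
#' res <- detectTandemDuplications(sim$bam, sim$ref)
#' res$calls
#' }
#' @export
detectTandemDuplications <- function(bamPath, fastaPath,
                                     chroms = NULL,
                                     params = tdParams(),
                                     verbose = TRUE) {
    if (!file.exists(bamPath))
        stop("alignment file not found: ", bamPath)
    if (!file.exists(fastaPath))
        stop("reference FASTA not found: ", fastaPath)
    hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]
    if (is.null(chroms))
        chroms <- names(hdr$targets)
    prof <- lapply(chroms, function(ch)
        .profileChrom(bamPath, fastaPath, ch, params, verbose))
    names(prof) <- chroms

    featuresOf <- function(p) {
        mc <- S4Vectors::mcols(binRanges(p$profile))
        v <- which(mc$valid)
        cbind(rd = mc$rdSmooth[v], mq = mc$mqNorm[v])
    }
    callsList <- if (params$poolGenome) {
        feats <- lapply(prof, featuresOf)
        all <- do.call(rbind, feats)
        lab <- if (nrow(all)) dbscanCluster(all, params$eps,
                                            params$minPts,
                                            params$leafSize)$labels
               else integer(0)
        offs <- cumsum(c(0L, vapply(feats, nrow, integer(1))))
        lapply(seq_along(chroms), function(i) {
            idx <- noiseBins(lab[(offs[i] + 1L):offs[i + 1L]])
            .callChrom(prof[[i]]$profile, prof[[i]]$splits, idx,
                       params, verbose, chroms[i])
        })
    } else {
        lapply(seq_along(chroms), function(i) {
            f <- featuresOf(prof[[i]])
            idx <- if (nrow(f))
                noiseBins(dbscanCluster(f, params$eps, params$minPts,
                                        params$leafSize))
            else integer(0)
            .callChrom(prof[[i]]$profile, prof[[i]]$splits, idx,
                       params, verbose, chroms[i])
        })
    }
    calls <- do.call(c, callsList)
    list(calls = sort(calls),
         profiles = lapply(prof, `[[`, "profile"),
         splits = lapply(prof, `[[`, "splits"),
         params = params)
}
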