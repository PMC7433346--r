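#' Match called regions against a truth set
#'
#' A truth region counts as a true positive when a single call covers
#' at least half of its length. Matching is one-to-one and greedy:
#' candidate (truth, call) pairs passing the half-coverage rule are
#' taken in order of decreasing overlap width (ties broken by truth
#' then call index), and each truth region / call is used at most once.
#' Unmatched calls are false positives; unmatched truths false
#' negatives.
#'
#' @param truth truth [GenomicRanges::GRanges].
#' @param calls called [GenomicRanges::GRanges].
#' @param minCoverage required covered fraction of the truth region
#'   (default 0.5).
#' @return list: counts \code{tp}, \code{fp}, \code{fn} and a
#'   data.frame \code{matching} with columns \code{truthIdx},
#'   \code{callIdx}, \code{overlap}.
#' @export
matchCalls <- function(truth, calls, minCoverage = 0.5) {
    matching <- data.frame(truthIdx = integer(0), callIdx = integer(0),
                           overlap = integer(0))
    if (length(truth) && length(calls)) {
        hits <- GenomicRanges::findOverlaps(truth, calls)
        if (length(hits)) {
            ti <- S4Vectors::queryHits(hits)
            ci <- S4Vectors::subjectHits(hits)
            ov <- IRanges::width(IRanges::pintersect(
                IRanges::ranges(truth)[ti], IRanges::ranges(calls)[ci]))
            pass <- ov >= minCoverage * IRanges::width(truth)[ti]
            ti <- ti[pass]; ci <- ci[pass]; ov <- ov[pass]
            ord <- order(-ov, ti, ci)
            usedT <- logical(length(truth))
            usedC <- logical(length(calls))
            for (j in ord) {
                if (!usedT[ti[j]] && !usedC[ci[j]]) {
                    usedT[ti[j]] <- TRUE
                    usedC[ci[j]] <- TRUE
                    matching <- rbind(matching, data.frame(
                        truthIdx = ti[j], callIdx = ci[j],
                        overlap = ov[j]))
                }
            }
        }
    }
    tp <- nrow(matching)
    list(tp = tp, fp = length(calls) - tp, fn = length(truth) - tp,
         matching = matching)
}

#' Sensitivity, precision and F1 from match counts
#'
#' Sensitivity = TP/(TP+FN), precision = TP/(TP+FP) and
#' F1 = 2PR/(P+R); a zero denominator yields 0 so that the metrics stay
#' plottable.
#'
#' @param tp,fp,fn counts from [matchCalls()].
#' @return list with \code{tp}, \code{fp}, \code{fn},
#'   \code{sensitivity}, \code{precision}, \code{f1}.
#' @export
computeMetrics <- function(tp, fp, fn) {
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
    list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
         precision = prec, f1 = f1)
}

#' Score a call set against a truth set
#'
#' Runs [matchCalls()] and [computeMetrics()] and adds the boundary
#' bias: over matched pairs, the mean of
#' \eqn{(|\Delta start| + |\Delta end|)/2} in bases — the average
#' nucleotide-level deviation of a called breakpoint from the true one.
#' \code{NA} when nothing matched.
#'
#' @inheritParams matchCalls
#' @return list with the [computeMetrics()] fields plus
#'   \code{boundaryBias} and the \code{matching} table.
#' @export
evaluateCalls <- function(truth, calls, minCoverage = 0.5) {
    m <- matchCalls(truth, calls, minCoverage)
    res <- computeMetrics(m$tp, m$fp, m$fn)
    bias <- NA_real_
    if (nrow(m$matching)) {
        ds <- abs(GenomicRanges::start(calls)[m$matching$callIdx] -
                  GenomicRanges::start(truth)[m$matching$truthIdx])
        de <- abs(GenomicRanges::end(calls)[m$matching$callIdx] -
                  GenomicRanges::end(truth)[m$matching$truthIdx])
        bias <- mean((ds + de) / 2)
    }
    c(res, list(boundaryBias = bias, matching = m$matching))
}

#' Overlap density score across methods
#'
#' Cross-method concordance without a truth set: for each method,
#' \eqn{M_{overlap}} is the mean over the other methods of the number
#' of its calls that are covered at least half by a call of the other
#' method, and \eqn{ODS = M_{overlap}^2 / N_{called}}. Higher is
#' better; a method with no calls scores 0 (with a warning).
#'
#' @param callSets named list (length >= 2) of call
#'   [GenomicRanges::GRanges], one per method.
#' @param minCoverage covered fraction required to count an overlap
#'   (default 0.5).
#' @return named numeric vector of ODS values.
#' @export
overlapDensityScore <- function(callSets, minCoverage = 0.5) {
    if (length(callSets) < 2L)
        stop("ODS needs at least two methods to compare")
    if (is.null(names(callSets)))
        names(callSets) <- paste0("method", seq_along(callSets))
    nMethods <- length(callSets)
    countOverlapped <- function(a, b) {
        if (!length(a) || !length(b))
            return(0L)
        hits <- GenomicRanges::findOverlaps(a, b)
        if (!length(hits))
            return(0L)
        ai <- S4Vectors::queryHits(hits)
        ov <- IRanges::width(IRanges::pintersect(
            IRanges::ranges(a)[ai],
            IRanges::ranges(b)[S4Vectors::subjectHits(hits)]))
        length(unique(ai[ov >= minCoverage * IRanges::width(a)[ai]]))
    }
    ods <- vapply(seq_len(nMethods), function(i) {
        n <- length(callSets[[i]])
        if (n == 0L) {
            warning("method '", names(callSets)[i],
                    "' has no calls; ODS set to 0")
            return(0)
        }
        mo <- mean(vapply(setdiff(seq_len(nMethods), i),
                          function(j) countOverlapped(callSets[[i]],
                                                      callSets[[j]]),
                          integer(1)))
        mo^2 / n
    }, numeric(1))
    names(ods) <- names(callSets)
    ods
}

#' Permutation test on the absolute difference of means
#'
#' Statistic \eqn{s = |\bar X - \bar Y|}. The group labels are permuted
#' \code{nPerm} times over the pooled values and the p-value is the
#' fraction of permuted statistics strictly larger than \eqn{s}.
#' Deterministic under \code{seed}.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with \code{statistic} and \code{pValue}.
#' @export
permutationTest <- function(x, y, nPerm = 10000L, seed = NULL) {
    stopifnot(length(x) >= 2L, length(y) >= 2L, nPerm >= 1L)
    s <- abs(mean(x) - mean(y))
    pooled <- c(x, y)
    nx <- length(x)
    nTot <- length(pooled)
    sumAll <- sum(pooled)
    .withSeed(seed, {
        exceed <- 0L
        for (i in seq_len(nPerm)) {
            idx <- sample.int(nTot, nx)
            mx <- sum(pooled[idx]) / nx
            my <- (sumAll - mx * nx) / (nTot - nx)
            if (abs(mx - my) > s)
                exceed <- exceed + 1L
        }
        list(statistic = s, pValue = exceed / nPerm)
    })
}
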