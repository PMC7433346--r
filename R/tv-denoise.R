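#' Total-variation denoising of a 1D signal (fused-lasso signal
#' approximator)
#'
#' Computes the exact global minimizer of
#' \deqn{\min_a \; \tfrac12 \lVert b - a \rVert_2^2 +
#'   \lambda \lVert D a \rVert_1,}
#' where \eqn{D} is the first-difference operator. The objective is
#' strictly convex, so the minimizer is unique; it smooths sampling noise
#' between adjacent bins while preserving the sharp depth/quality edges
#' at duplication boundaries. Solved with a direct single-pass
#' taut-string-family algorithm (no iterations, O(n) typical cost,
#' deterministic), not gradient descent.
#'
#' Limiting behaviour: \code{lam = 0} returns \code{b} unchanged; for
#' \code{lam} large enough the solution is constant at \code{mean(b)}.
#' The minimizer always preserves the mean of the input.
#'
#' @param b numeric vector, no NA (filtered bins must be removed first).
#' @param lam non-negative penalty; default 0.25.
#' @return numeric vector of the same length, the denoised signal.
#' @examples
#' tvDenoise(c(0, 0, 10, 10), lam = 0.25)  # 0.125 0.125 9.875 9.875
#' @export
tvDenoise <- function(b, lam = 0.25) {
    if (!is.numeric(b) || anyNA(b))
        stop("'b' must be numeric without NA")
    if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
        stop("'lam' must be a single non-negative number")
    y <- as.numeric(b)
    n <- length(y)
    if (n <= 1L || lam == 0)
        return(y)
    x <- numeric(n)
    # running tube bounds (vmin, vmax) and accumulated slacks
    # (umin, umax); km/kp are the last positions where the lower/upper
    # constraint was active; k0 is the start of the segment being built.
    k <- 1L; k0 <- 1L; km <- 1L; kp <- 1L
    umin <- lam; umax <- -lam
    vmin <- y[1L] - lam; vmax <- y[1L] + lam
    twolam <- 2 * lam
    repeat {
        while (k == n) {
            if (umin < 0) {            # lower tube violated at the end
                while (k0 <= km) { x[k0] <- vmin; k0 <- k0 + 1L }
                k <- k0; km <- k0
                vmin <- y[k]
                umin <- lam
                umax <- vmin + lam - vmax
            } else if (umax > 0) {     # upper tube violated at the end
                while (k0 <= kp) { x[k0] <- vmax; k0 <- k0 + 1L }
                k <- k0; kp <- k0
                vmax <- y[k]
                umax <- -lam
                umin <- vmax - lam - vmin
            } else {                   # flush the final segment
                vmin <- vmin + umin / (k - k0 + 1)
                while (k0 <= k) { x[k0] <- vmin; k0 <- k0 + 1L }
                return(x)
            }
        }
        umin <- umin + y[k + 1L] - vmin
        if (umin < -lam) {             # negative jump: emit at vmin
            while (k0 <= km) { x[k0] <- vmin; k0 <- k0 + 1L }
            k <- k0; km <- k0; kp <- k0
            vmin <- y[k]
            vmax <- vmin + twolam
            umin <- lam; umax <- -lam
        } else {
            umax <- umax + y[k + 1L] - vmax
            if (umax > lam) {          # positive jump: emit at vmax
                while (k0 <= kp) { x[k0] <- vmax; k0 <- k0 + 1L }
                k <- k0; km <- k0; kp <- k0
                vmax <- y[k]
                vmin <- vmax - twolam
                umin <- lam; umax <- -lam
            } else {                   # keep extending the segment
                k <- k + 1L
                if (umin >= lam) {
                    km <- k
                    vmin <- vmin + (umin - lam) / (k - k0 + 1)
                    umin <- lam
                }
                if (umax <= -lam) {
                    kp <- k
                    vmax <- vmax + (umax + lam) / (k - k0 + 1)
                    umax <- -lam
                }
            }
        }
    }
}

#' Objective value of the TV-denoising problem
#'
#' \eqn{\tfrac12\lVert b-a\rVert_2^2 + \lambda\lVert Da\rVert_1}; used by
#' tests to certify that a candidate solution does not beat the returned
#' minimizer.
#'
#' @param a candidate signal.
#' @param b observed signal.
#' @param lam penalty.
#' @return the scalar objective value.
#' @export
tvObjective <- function(a, b, lam) {
    0.5 * sum((b - a)^2) + lam * sum(abs(diff(a)))
}
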