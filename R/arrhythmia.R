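## Cutoff-based arrhythmic-event scoring: extreme R-R intervals, 2x2
## contingency tables, the Yates-corrected chi-square test, and Poincare
## return-map data.  The cutoff convention follows the two cell models:
## 3 s for hPSC-CM-type recordings, 1 s for the faster murine HL-1 line.

#' Count extreme (arrhythmic) R-R intervals
#'
#' An interval is an arrhythmic event when it strictly exceeds the cutoff.
#'
#' @param rr inter-beat intervals, seconds; nonempty, all positive.
#' @param cutoff cutoff in seconds (3 for hPSC-CM-type, 1 for HL-1-type).
#' @return Named numeric vector: \code{extreme} count, \code{total} count,
#'   \code{per1000} rate.
#' @examples
#' countExtremeRR(c(0.8, 0.9, 3.5, 0.7), cutoff = 3)
#' @export
countExtremeRR <- function(rr, cutoff = 3) {
    if (!length(rr)) {
        stop("'rr' must be nonempty")
    }
    if (any(!is.finite(rr)) || any(rr <= 0)) {
        stop("'rr' must be positive and finite")
    }
    if (cutoff <= 0) {
        stop("'cutoff' must be positive")
    }
    extreme <- sum(rr > cutoff)
    c(extreme = extreme, total = length(rr),
      per1000 = 1000 * extreme / length(rr))
}

#' Build a treatment-vs-control arrhythmia contingency table
#'
#' Pools extreme/normal interval counts across recordings within each arm
#' (the primary analysis) while retaining the per-recording breakdown for
#' sensitivity checks.
#'
#' @param treatmentExtreme,treatmentTotal per-recording extreme and total
#'   interval counts for the treatment arm (equal-length vectors).
#' @param controlExtreme,controlTotal same for the control arm.
#' @param cutoff cutoff (seconds) the counts were scored at, for the
#'   record.
#' @return An \linkS4class{ArrhythmiaTable}.
#' @examples
#' buildContingency(5, 1000, 1, 1000)
#' @export
buildContingency <- function(treatmentExtreme, treatmentTotal,
                             controlExtreme, controlTotal,
                             cutoff = NA_real_) {
    stopifnot(length(treatmentExtreme) == length(treatmentTotal),
              length(controlExtreme) == length(controlTotal))
    if (sum(treatmentTotal) <= 0 || sum(controlTotal) <= 0) {
        stop("both arms must have a positive interval total")
    }
    if (any(treatmentExtreme > treatmentTotal) ||
        any(controlExtreme > controlTotal)) {
        stop("extreme counts cannot exceed totals")
    }
    a <- sum(treatmentExtreme)
    b <- sum(treatmentTotal) - a
    c <- sum(controlExtreme)
    d <- sum(controlTotal) - c
    perRec <- data.frame(
        arm = rep(c("treatment", "control"),
                  c(length(treatmentExtreme), length(controlExtreme))),
        extreme = c(treatmentExtreme, controlExtreme),
        total = c(treatmentTotal, controlTotal))
    new("ArrhythmiaTable", a = as.integer(a), b = as.integer(b),
        c = as.integer(c), d = as.integer(d), cutoff = cutoff,
        perRecording = perRec)
}

#' Yates-corrected chi-square test on a 2x2 arrhythmia table
#'
#' Continuity-corrected Pearson chi-square for 2x2 tables:
#' \deqn{X^2 = N (\max(|ad - bc| - N/2,\ 0))^2 /
#'   ((a+b)(c+d)(a+c)(b+d)),}
#' with 1 degree of freedom.  The correction is clamped at zero so
#' near-homogeneous tables cannot produce a spurious positive statistic.
#'
#' @param table an \linkS4class{ArrhythmiaTable}, or a 2x2 numeric matrix
#'   of counts.
#' @return An object of class \code{"htest"} with the statistic, df = 1 and
#'   the p-value.
#' @examples
#' chiSquareYates(buildContingency(20, 1000, 5, 1000))
#' @export
chiSquareYates <- function(table) {
    if (is(table, "ArrhythmiaTable")) {
        a <- table@a; b <- table@b; c <- table@c; d <- table@d
    } else if (is.matrix(table) && all(dim(table) == 2L)) {
        a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
    } else {
        stop("'table' must be an ArrhythmiaTable or a 2x2 matrix")
    }
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    marg <- c(a + b, c + d, a + c, b + d)
    if (any(marg == 0)) {
        stop("all marginals must be positive")
    }
    stat <- n * max(abs(a * d - b * c) - n / 2, 0)^2 / prod(marg)
    structure(list(
        statistic = c(`X-squared` = stat),
        parameter = c(df = 1),
        p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
        method = "Chi-square test with Yates' continuity correction",
        data.name = sprintf("2x2 table (a=%g, b=%g, c=%g, d=%g)",
                            a, b, c, d)
    ), class = "htest")
}

#' Poincare (lag-1 return map) pairs of an R-R sequence
#'
#' Each interval is paired with the next; a pair is flagged when either
#' coordinate exceeds the cutoff, matching the cutoff lines drawn on the
#' published return maps.
#'
#' @param rr inter-beat intervals, seconds.
#' @param cutoff optional cutoff, seconds; without it no pair is flagged.
#' @return A \code{DataFrame} with columns \code{rr1}, \code{rr2},
#'   \code{flagged}; empty when fewer than 2 intervals are supplied.
#' @examples
#' poincarePairs(c(1, 2, 3), cutoff = 2.5)
#' @export
poincarePairs <- function(rr, cutoff = NULL) {
    if (length(rr) < 2L) {
        return(S4Vectors::DataFrame(rr1 = numeric(0), rr2 = numeric(0),
                                    flagged = logical(0)))
    }
    n <- length(rr)
    rr1 <- rr[-n]
    rr2 <- rr[-1L]
    flagged <- if (is.null(cutoff)) {
        rep(FALSE, n - 1L)
    } else {
        rr1 > cutoff | rr2 > cutoff
    }
    S4Vectors::DataFrame(rr1 = rr1, rr2 = rr2, flagged = flagged)
}
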