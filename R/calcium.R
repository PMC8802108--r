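## Calcium line-scan analysis: baseline normalization, transient kinetics
## (time to peak, decay time) and diastolic spark detection.

#' Normalize raw fluorescence to a diastolic baseline
#'
#' The baseline \eqn{F_0} is a low percentile of the raw trace (10th by
#' default), taken from the diastolic portion of the recording; the output
#' is \eqn{(F - F_0)/F_0}.
#'
#' @param raw raw fluorescence trace (numeric), or a matrix kymograph
#'   (positions x lines) that is first averaged over the spatial
#'   dimension.
#' @param lineRate line rate in Hz.
#' @param f0Quantile quantile used for the baseline estimate.
#' @param label profile label.
#' @return A \linkS4class{CalciumProfile}.
#' @examples
#' p <- normalizeF0(100 * (1 + c(0, 0, 1, 0.5, 0, 0, 0, 0, 0, 0)))
#' dff(p)
#' @export
normalizeF0 <- function(raw, lineRate = 100, f0Quantile = 0.1, label = "") {
    if (is.matrix(raw)) {
        raw <- colMeans(raw)
    }
    if (any(!is.finite(raw))) {
        stop("'raw' must be finite")
    }
    f0 <- stats::quantile(raw, f0Quantile, names = FALSE)
    if (f0 <= 0) {
        stop("baseline F0 estimate is not positive; cannot normalize")
    }
    new("CalciumProfile", raw = as.numeric(raw), dff = (raw - f0) / f0,
        lineRate = lineRate, f0 = f0, label = label)
}

#' Detect calcium transients and their kinetics
#'
#' Transients are local maxima of the \eqn{\Delta F/F_0} trace above a
#' threshold (by default 50\% of the robust maximum amplitude, with an
#' absolute floor), separated by at least \code{minSpacing}.  For each
#' transient, the onset is the last upward crossing of 10\% of the peak
#' amplitude before the peak, the time to peak is peak minus onset, and the
#' decay time is the (sample-interpolated) time from the peak to the
#' decline to 10\% of the peak amplitude - so a pure exponential decay of
#' time constant \eqn{\tau} has decay time \eqn{\tau \ln 10}.
#'
#' @param profile a \linkS4class{CalciumProfile} with >= 1 s of signal.
#' @param thresholdFraction transient threshold as a fraction of the
#'   robust maximum (99th percentile) amplitude.
#' @param minAmplitude absolute transient amplitude floor,
#'   \eqn{\Delta F/F_0}.
#' @param minSpacing minimum separation between transient peaks, seconds.
#' @param decayTo fractional level defining the decay time (0.1 = decay to
#'   10\% of peak; 0.5 gives a half-decay time instead).
#' @return A \code{DataFrame} with one row per transient: \code{onset},
#'   \code{peakTime}, \code{amplitude}, \code{timeToPeak},
#'   \code{decayTime} (NA when the trace ends before the decay level is
#'   reached).  Empty for traces without qualifying peaks.
#' @export
detectTransients <- function(profile, thresholdFraction = 0.5,
                             minAmplitude = 0.2, minSpacing = 0.5,
                             decayTo = 0.1) {
    stopifnot(is(profile, "CalciumProfile"))
    x <- dff(profile)
    fs <- lineRate(profile)
    if (length(x) < fs) {
        stop("at least 1 s of signal is required")
    }
    tvec <- (seq_along(x) - 1L) / fs
    emptyRes <- S4Vectors::DataFrame(
        onset = numeric(0), peakTime = numeric(0), amplitude = numeric(0),
        timeToPeak = numeric(0), decayTime = numeric(0))

    robustMax <- stats::quantile(x, 0.99, names = FALSE)
    threshold <- max(thresholdFraction * robustMax, minAmplitude)
    peaks <- localMaxima(x)
    peaks <- peaks[x[peaks] >= threshold]
    peaks <- enforceRefractory(peaks, x[peaks], minSpacing * fs)
    if (!length(peaks)) {
        return(emptyRes)
    }

    n <- length(x)
    onset <- peakT <- amp <- ttp <- dec <- numeric(length(peaks))
    prevPeak <- c(1L, peaks[-length(peaks)])
    nextBound <- c(peaks[-1L], n)
    for (i in seq_along(peaks)) {
        p <- peaks[i]
        amp[i] <- x[p]
        peakT[i] <- tvec[p]
        level <- decayTo * amp[i]
        onsetLevel <- 0.1 * amp[i]

        ## Onset: last sample at/below 10% of peak before the peak,
        ## crossing time interpolated.
        below <- which(x[prevPeak[i]:(p - 1L)] <= onsetLevel)
        if (length(below)) {
            j <- prevPeak[i] + max(below) - 1L
            onset[i] <- crossingTime(tvec, x, j, onsetLevel)
        } else {
            onset[i] <- tvec[prevPeak[i]]
        }
        ttp[i] <- peakT[i] - onset[i]

        ## Decay: first decline to `decayTo` of peak before the next
        ## transient takes over.
        searchEnd <- nextBound[i]
        seg <- x[p:searchEnd]
        hit <- which(seg <= level)
        if (length(hit)) {
            j <- p + min(hit) - 2L
            dec[i] <- crossingTime(tvec, x, j, level) - peakT[i]
        } else {
            dec[i] <- NA_real_
        }
    }
    S4Vectors::DataFrame(onset = onset, peakTime = peakT, amplitude = amp,
                         timeToPeak = ttp, decayTime = dec)
}

#' Detect calcium sparks in diastolic intervals
#'
#' Sparks are "extra events" between transients: the diastolic portion of
#' the trace (everything outside the transient spans, onset to peak plus
#' \code{maskFactor} decay times) is smoothed with a short moving average,
#' and local
#' maxima exceeding \code{k} times the MAD-based diastolic noise SD - but
#' staying below the transient threshold - are scored as sparks.  The
#' threshold is noise-relative, so the spark rate is invariant to scaling
#' the whole trace.
#'
#' @param profile a \linkS4class{CalciumProfile}.
#' @param transients transient table from \code{\link{detectTransients}}
#'   (detected on the fly when missing).
#' @param k detection threshold in diastolic noise-SD units (default 3.8).
#' @param smoothPoints moving-average width in lines (default 3).
#' @param maskFactor transient span extends to \code{peak + maskFactor *
#'   decayTime}; the default 1.3 reaches about 3 decay time constants
#'   past the peak.
#' @param minSeparation minimum separation between sparks, seconds.
#' @param thresholdFraction transient-classification ceiling, as in
#'   \code{\link{detectTransients}}.
#' @return A list: \code{sparks} (\code{DataFrame}: \code{time},
#'   \code{amplitude}, \code{width}), \code{rate} (sparks per second of
#'   diastolic time), \code{diastolicTime} (seconds), and
#'   \code{perSecond} (spark counts in 1-s bins over the recording).
#' @export
detectSparks <- function(profile, transients = NULL, k = 3.8,
                         smoothPoints = 3, maskFactor = 1.3,
                         minSeparation = 0.1, thresholdFraction = 0.5) {
    stopifnot(is(profile, "CalciumProfile"))
    if (is.null(transients)) {
        transients <- detectTransients(profile,
                                       thresholdFraction = thresholdFraction)
    }
    x <- dff(profile)
    fs <- lineRate(profile)
    n <- length(x)
    tvec <- (seq_len(n) - 1L) / fs

    diastolic <- rep(TRUE, n)
    if (nrow(transients) > 0L) {
        for (i in seq_len(nrow(transients))) {
            decWin <- transients$decayTime[i]
            if (is.na(decWin)) {
                decWin <- 3 / fs + (tvec[n] - transients$peakTime[i])
            }
            lo <- max(1L, floor(transients$onset[i] * fs) + 1L)
            hi <- min(n, ceiling((transients$peakTime[i] +
                                  maskFactor * decWin) * fs) + 1L)
            diastolic[lo:hi] <- FALSE
        }
    }
    diaTime <- sum(diastolic) / fs
    if (diaTime <= 0) {
        stop("no diastolic interval: spark rate undefined")
    }

    sm <- movingAverage(x, smoothPoints)
    ## Local-baseline subtraction: a running median (window several spark
    ## widths) flattens the residual shoulder of decaying transients, so
    ## the noise threshold is not fooled by elevated early-diastole signal.
    locWin <- min(oddWindow(0.35 * fs), oddWindow(n - 2L))
    det <- sm - stats::runmed(sm, locWin, endrule = "median")
    base <- stats::median(det[diastolic])
    noiseSd <- stats::mad(det[diastolic])
    robustMax <- stats::quantile(x, 0.99, names = FALSE)
    ceilingLevel <- thresholdFraction * robustMax
    if (noiseSd <= 0) {
        empty <- S4Vectors::DataFrame(time = numeric(0),
                                      amplitude = numeric(0),
                                      width = numeric(0))
        return(list(sparks = empty, rate = 0, diastolicTime = diaTime,
                    perSecond = tabulateSparkBins(numeric(0), tvec[n])))
    }

    cand <- localMaxima(det)
    cand <- cand[diastolic[cand]]
    cand <- cand[det[cand] - base > k * noiseSd]
    if (nrow(transients) > 0L) {
        ## Sub-transient ceiling: anything reaching the transient
        ## classification threshold is not a spark.
        cand <- cand[sm[cand] < ceilingLevel]
    }
    cand <- enforceRefractory(cand, det[cand], minSeparation * fs)

    times <- tvec[cand]
    amps <- det[cand] - base
    widths <- vapply(seq_along(cand), function(i) {
        p <- cand[i]
        half <- base + amps[i] / 2
        lo <- p
        while (lo > 1L && det[lo] > half && diastolic[lo]) lo <- lo - 1L
        hi <- p
        while (hi < n && det[hi] > half && diastolic[hi]) hi <- hi + 1L
        (hi - lo) / fs
    }, numeric(1))

    list(
        sparks = S4Vectors::DataFrame(time = times, amplitude = amps,
                                      width = widths),
        rate = length(cand) / diaTime,
        diastolicTime = diaTime,
        perSecond = tabulateSparkBins(times, tvec[n]))
}

## Spark counts per 1-s bin over [0, duration].
tabulateSparkBins <- function(times, duration) {
    nBin <- max(1L, ceiling(duration))
    bins <- findInterval(times, seq(0, nBin, by = 1),
                         rightmost.closed = TRUE)
    tabulate(bins, nbins = nBin)
}
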