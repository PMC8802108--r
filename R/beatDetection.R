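## R/S peak detection in mechanocardiogram force traces (shared detector
## core for MEA field potentials) and per-segment contraction metrics.

#' Beat detector configuration
#'
#' Bundles the tunable knobs of the R/S detector.  The prominence threshold
#' is adaptive: \code{max(minProminence, prominenceFraction * robust
#' amplitude range)}, where the robust range is a high quantile
#' (\code{rangeQuantile}) minus the median of the (processed) signal, so it
#' tracks the actual event
#' amplitude of each segment and tolerates drift and amplitude differences
#' across preparations.
#'
#' @param preset \code{"mcg"} (refractory 250 ms, suitable for hPSC-CM
#'   clusters) or \code{"mea"} (refractory 100 ms, murine HL-1 rates).
#' @param rangeQuantile upper quantile defining the robust amplitude range;
#'   high enough (99.95\%) that sparse events such as millisecond-scale
#'   field-potential spikes still dominate it.
#' @param refractory minimum separation between R peaks, seconds; overrides
#'   the preset default.
#' @param prominenceFraction fraction of the robust amplitude range an R
#'   peak's topographic prominence must reach.
#' @param minProminence absolute prominence floor, signal units.
#' @param detrend subtract a moving-median baseline before detection
#'   (window \code{detrendWindowFactor} times the median beat period,
#'   estimated by a first detection pass).  Off by default; enable for
#'   drifting recordings.
#' @param detrendWindowFactor moving-median window as a multiple of the
#'   median beat period.
#' @param smoothMs moving-average pre-smoothing width in milliseconds
#'   (0 disables).  Enable for noisy recordings.
#' @param channel channel index to analyse in multichannel segments.
#'
#' @return A list of class \code{"detectorConfig"}.
#' @examples
#' detectorConfig("mea")
#' @export
detectorConfig <- function(preset = c("mcg", "mea"), refractory = NULL,
                           prominenceFraction = 0.3, minProminence = 0,
                           rangeQuantile = 0.9995, detrend = FALSE,
                           detrendWindowFactor = 3, smoothMs = 0,
                           channel = 1L) {
    preset <- match.arg(preset)
    if (is.null(refractory)) {
        refractory <- if (preset == "mcg") 0.25 else 0.10
    }
    structure(list(
        preset = preset, refractory = refractory,
        prominenceFraction = prominenceFraction,
        minProminence = minProminence, rangeQuantile = rangeQuantile,
        detrend = detrend,
        detrendWindowFactor = detrendWindowFactor,
        smoothMs = smoothMs, channel = as.integer(channel)
    ), class = "detectorConfig")
}

#' Locate R and S peaks in a force or field-potential trace
#'
#' Finds one event per contraction: each R peak is a local maximum whose
#' topographic prominence exceeds an adaptive threshold (see
#' \code{\link{detectorConfig}}), peaks closer than the refractory period
#' are pruned keeping the larger one, and the paired S trough is the
#' minimum between that R and the next R (or the segment end).  Ties in
#' local extrema resolve to the earliest sample.  The detector is fully
#' deterministic for a fixed input and configuration.
#'
#' A flat or non-finite trace yields an empty \linkS4class{BeatSeries} with
#' a warning rather than an error, so batch pipelines can skip degenerate
#' recordings.
#'
#' @param segment a \linkS4class{RecordingSegment} (>= 2 s long).
#' @param config a \code{\link{detectorConfig}}.
#'
#' @return A \linkS4class{BeatSeries}.
#' @examples
#' gt <- generateBeatSchedule(duration = 30, baseRate = 60, rateJitterCV = 0)
#' seg <- renderMcgTrace(gt, contractionAmplitude = 100)
#' detectBeats(seg)
#' @export
detectBeats <- function(segment, config = detectorConfig()) {
    stopifnot(is(segment, "RecordingSegment"))
    fs <- samplingRate(segment)
    x <- signalMatrix(segment)[, config$channel]
    if (length(x) < 2 * fs) {
        stop("segment must be at least 2 s long")
    }
    emptySeries <- function(msg) {
        warning(msg, call. = FALSE)
        BeatSeries(units = segment@units, label = segmentLabel(segment))
    }
    if (any(!is.finite(x))) {
        return(emptySeries("non-finite samples in trace: no beats detected"))
    }
    if (max(x) == min(x)) {
        return(emptySeries("flat trace: no beats detected"))
    }

    y <- x
    if (config$detrend) {
        ## First pass without detrending estimates the beat period that
        ## sizes the moving-median window.
        cfg0 <- config
        cfg0$detrend <- FALSE
        first <- suppressWarnings(detectBeats(segment, cfg0))
        period <- if (nEvents(first) >= 3L) {
            stats::median(rrIntervals(first))
        } else {
            2
        }
        k <- oddWindow(config$detrendWindowFactor * period * fs)
        k <- min(k, oddWindow(length(y) - 2L))
        ## Constant-extend the interior baseline across the edge zones:
        ## shrinking edge windows would subtract boundary events away.
        base <- stats::runmed(y, k, endrule = "keep")
        h <- (k - 1L) %/% 2L
        if (h >= 1L && length(y) > 2L * h) {
            base[seq_len(h)] <- base[h + 1L]
            base[(length(y) - h + 1L):length(y)] <- base[length(y) - h]
        }
        y <- y - base
    }
    if (config$smoothMs > 0) {
        y <- movingAverage(y, config$smoothMs / 1000 * fs)
    }

    med <- stats::median(y)
    robustRange <- stats::quantile(y, config$rangeQuantile,
                                   names = FALSE) - med
    threshold <- max(config$minProminence,
                     config$prominenceFraction * robustRange)
    if (threshold <= 0) {
        return(emptySeries("degenerate amplitude range: no beats detected"))
    }

    peaks <- localMaxima(y)
    ## Events scheduled right at the segment start/end peak on the first or
    ## last sample; include boundary maxima so they are not lost.
    if (y[1L] > y[2L]) {
        peaks <- c(1L, peaks)
    }
    if (y[length(y)] > y[length(y) - 1L]) {
        peaks <- c(peaks, length(y))
    }
    peaks <- peaks[y[peaks] >= med + 0.5 * threshold]
    ## Refractory pruning first (cheap) caps the number of candidates the
    ## O(n)-per-peak prominence pass has to examine.
    peaks <- enforceRefractory(peaks, y[peaks], config$refractory * fs)
    if (length(peaks)) {
        prom <- peakProminence(y, peaks,
                               guard = floor(config$refractory * fs / 2))
        peaks <- peaks[prom >= threshold]
    }
    if (!length(peaks)) {
        return(BeatSeries(units = segment@units,
                          label = segmentLabel(segment)))
    }

    ## S trough: earliest minimum between each R and the next R (or end).
    tvec <- recordingTime(segment)
    nP <- length(peaks)
    sIdx <- integer(nP)
    keep <- logical(nP)
    bounds <- c(peaks, length(y) + 1L)
    for (i in seq_len(nP)) {
        lo <- peaks[i] + 1L
        hi <- bounds[i + 1L] - 1L
        if (lo > hi) next
        sIdx[i] <- lo + which.min(y[lo:hi]) - 1L
        keep[i] <- y[peaks[i]] > y[sIdx[i]]
    }
    peaks <- peaks[keep]
    sIdx <- sIdx[keep]
    ## With pre-smoothing on (noisy recordings), the extremal sample is
    ## biased by noise selection (max-of-noise at R, min-of-noise at S);
    ## the local mean around the extremum is a nearly unbiased deflection
    ## estimate.  Without smoothing, the raw sample is exact.
    deflAt <- function(idx) {
        if (config$smoothMs <= 0) {
            return(y[idx])
        }
        w <- max(1L, floor(config$smoothMs / 1000 * fs / 2))
        vapply(idx, function(i) {
            mean(y[max(1L, i - w):min(length(y), i + w)])
        }, numeric(1))
    }
    rd <- deflAt(peaks)
    sd <- deflAt(sIdx)
    ok <- rd > sd
    BeatSeries(
        rTime = tvec[peaks][ok], rDefl = rd[ok],
        sTime = tvec[sIdx][ok], sDefl = sd[ok],
        units = segment@units, label = segmentLabel(segment))
}

#' Beat rate of a detected series
#'
#' The primary definition is 60 divided by the mean inter-beat (R-R)
#' interval, which is insensitive to partial beats at the segment edges;
#' \code{method = "count"} instead divides the event count by the segment
#' duration.
#'
#' @param x a \linkS4class{BeatSeries} with at least 2 events.
#' @param method \code{"interval"} (default) or \code{"count"}.
#' @param duration segment duration in seconds, required for
#'   \code{method = "count"}.
#' @param ... unused.
#' @return Beat rate in beats per minute.
#' @examples
#' bs <- BeatSeries(rTime = 0:9, rDefl = 1, sTime = 0:9 + 0.1, sDefl = 0)
#' beatRate(bs) # 60
#' @rdname beatRate
#' @export
setMethod("beatRate", "BeatSeries",
    function(x, method = c("interval", "count"), duration = NULL, ...) {
        method <- match.arg(method)
        if (nEvents(x) < 2L) {
            stop("beat rate undefined: fewer than 2 events")
        }
        if (method == "interval") {
            60 / mean(rrIntervals(x))
        } else {
            if (is.null(duration)) {
                stop("'duration' is required for method = \"count\"")
            }
            60 * nEvents(x) / duration
        }
    })

#' Mean contraction force of a detected series
#'
#' Arithmetic mean of the per-event R-S amplitudes (R deflection minus S
#' deflection), the contraction-force readout of a mechanocardiogram.
#'
#' @param x a \linkS4class{BeatSeries} with at least 1 event.
#' @param ... unused.
#' @return Mean R-S amplitude in the series' signal units.
#' @rdname contractionForce
#' @export
setMethod("contractionForce", "BeatSeries", function(x, ...) {
    if (nEvents(x) < 1L) {
        stop("contraction force undefined: no events")
    }
    mean(rsAmplitudes(x))
})

#' Per-segment beat metrics
#'
#' @param series a \linkS4class{BeatSeries}.
#' @param duration optional segment duration (enables the count-based rate).
#' @return Named numeric vector with \code{nEvents}, \code{beatRate},
#'   \code{beatRateCount} (NA without \code{duration}), \code{meanRR} and
#'   \code{contractionForce}.
#' @export
beatMetrics <- function(series, duration = NULL) {
    n <- nEvents(series)
    c(nEvents = n,
      beatRate = if (n >= 2L) beatRate(series) else NA_real_,
      beatRateCount = if (!is.null(duration) && n >= 1L) {
          60 * n / duration
      } else {
          NA_real_
      },
      meanRR = if (n >= 2L) mean(rrIntervals(series)) else NA_real_,
      contractionForce = if (n >= 1L) contractionForce(series) else NA_real_)
}

#' Normalize treatment metrics to a baseline recording
#'
#' Computes relative responses: each treatment metric divided by the same
#' metric in the preparation's own baseline recording.  Optionally
#' re-normalizes by the mean ratio of a control group (second-stage
#' normalization), so a value of 1 means "no change beyond what untreated
#' controls show".
#'
#' @param treatment,baseline \linkS4class{BeatSeries} objects or named
#'   numeric vectors of metrics (as from \code{\link{beatMetrics}}).
#' @param metrics metric names to normalize.
#' @param controlRatios optional named numeric vector of control-group mean
#'   ratios for the same metrics.
#' @return A \code{DataFrame} with one row per metric: treatment mean,
#'   baseline mean, \code{ratio}, and \code{controlNormalized} when
#'   control ratios were supplied.
#' @examples
#' normalizeToBaseline(c(beatRate = 45), c(beatRate = 30))
#' @export
normalizeToBaseline <- function(treatment, baseline,
                                metrics = c("beatRate", "contractionForce"),
                                controlRatios = NULL) {
    asMetrics <- function(obj) {
        if (is(obj, "BeatSeries")) beatMetrics(obj) else obj
    }
    tm <- asMetrics(treatment)
    bm <- asMetrics(baseline)
    metrics <- intersect(metrics, intersect(names(tm), names(bm)))
    if (!length(metrics)) {
        stop("no shared metrics to normalize")
    }
    tv <- unname(tm[metrics])
    bv <- unname(bm[metrics])
    if (any(!is.finite(bv)) || any(bv <= 0)) {
        stop("baseline means must be positive and finite")
    }
    out <- S4Vectors::DataFrame(
        metric = metrics, treatmentMean = tv, baselineMean = bv,
        ratio = tv / bv)
    if (!is.null(controlRatios)) {
        cr <- controlRatios[metrics]
        if (any(!is.finite(cr)) || any(cr <= 0)) {
            stop("control ratios must be positive and finite")
        }
        out$controlNormalized <- out$ratio / unname(cr)
    }
    out
}
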