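## Accessors, constructors and show() methods for the core classes.

#' Construct a RecordingSegment
#'
#' @param signal numeric vector (one channel) or samples x channels matrix.
#' @param samplingRate sampling frequency, Hz.
#' @param startTime time of the first sample, seconds.
#' @param units signal units.
#' @param label free-text label.
#' @return A \linkS4class{RecordingSegment}.
#' @examples
#' seg <- RecordingSegment(sin(seq(0, 2 * pi, length.out = 100)),
#'     samplingRate = 50)
#' segmentDuration(seg)
#' @export
RecordingSegment <- function(signal, samplingRate, startTime = 0,
                             units = "nN", label = "") {
    if (!is.matrix(signal)) {
        signal <- matrix(as.numeric(signal), ncol = 1)
    }
    new("RecordingSegment",
        signal = signal, samplingRate = samplingRate,
        startTime = startTime, units = units, label = label)
}

#' @rdname RecordingSegment-class
#' @export
setMethod("signalMatrix", "RecordingSegment", function(x) x@signal)

#' @rdname RecordingSegment-class
#' @export
setMethod("samplingRate", "RecordingSegment", function(x) x@samplingRate)

#' @rdname RecordingSegment-class
#' @export
setMethod("recordingTime", "RecordingSegment", function(x) {
    x@startTime + (seq_len(nrow(x@signal)) - 1L) / x@samplingRate
})

#' @rdname RecordingSegment-class
#' @export
setMethod("nChannels", "RecordingSegment", function(x) ncol(x@signal))

#' @rdname RecordingSegment-class
#' @export
setMethod("segmentDuration", "RecordingSegment", function(x) {
    nrow(x@signal) / x@samplingRate
})

#' @rdname RecordingSegment-class
#' @export
setMethod("segmentLabel", "RecordingSegment", function(x) x@label)

setMethod("show", "RecordingSegment", function(object) {
    cat(sprintf(
        "RecordingSegment '%s': %d channel(s), %d samples @ %g Hz (%.1f s), units %s\n",
        object@label, ncol(object@signal), nrow(object@signal),
        object@samplingRate, nrow(object@signal) / object@samplingRate,
        object@units))
    invisible(NULL)
})

#' @rdname GroundTruth-class
#' @export
setMethod("beatTimes", "GroundTruth", function(x) x@beatTimes)

#' @rdname GroundTruth-class
#' @export
setMethod("pauseIndices", "GroundTruth", function(x) x@pauseIndices)

#' @rdname GroundTruth-class
#' @export
setMethod("sparkTimes", "GroundTruth", function(x) x@sparkTimes)

#' @rdname GroundTruth-class
#' @export
setMethod("transientTimes", "GroundTruth", function(x) x@transientTimes)

#' @rdname GroundTruth-class
#' @export
setMethod("badChannels", "GroundTruth", function(x) x@badChannels)

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(
        "GroundTruth: %d beats, %d pauses, %d transients, %d sparks, %d bad channels\n",
        length(object@beatTimes), length(object@pauseIndices),
        length(object@transientTimes), length(object@sparkTimes),
        length(object@badChannels)))
    invisible(NULL)
})

#' Construct a BeatSeries from parallel event vectors
#'
#' @param rTime,rDefl,sTime,sDefl per-event R/S times and deflections.
#' @param units,label metadata carried from the source segment.
#' @return A \linkS4class{BeatSeries}.
#' @export
BeatSeries <- function(rTime = numeric(0), rDefl = numeric(0),
                       sTime = numeric(0), sDefl = numeric(0),
                       units = "", label = "") {
    n <- length(rTime)
    new("BeatSeries",
        rTime = as.numeric(rTime),
        rDefl = rep_len(as.numeric(rDefl), n),
        sTime = rep_len(as.numeric(sTime), n),
        sDefl = rep_len(as.numeric(sDefl), n),
        units = units, label = label)
}

#' @rdname BeatSeries-class
#' @export
setMethod("nEvents", "BeatSeries", function(x) length(x@rTime))

#' @rdname BeatSeries-class
#' @export
setMethod("rrIntervals", "BeatSeries", function(x) diff(x@rTime))

#' @rdname BeatSeries-class
#' @export
setMethod("rsAmplitudes", "BeatSeries", function(x) x@rDefl - x@sDefl)

#' @rdname BeatSeries-class
#' @export
setMethod("beatEvents", "BeatSeries", function(x) {
    S4Vectors::DataFrame(
        rTime = x@rTime, rDefl = x@rDefl,
        sTime = x@sTime, sDefl = x@sDefl,
        rr = c(diff(x@rTime), NA_real_),
        rs = x@rDefl - x@sDefl)
})

setMethod("show", "BeatSeries", function(object) {
    n <- length(object@rTime)
    cat(sprintf("BeatSeries '%s': %d events", object@label, n))
    if (n >= 2L) {
        cat(sprintf(", BR %.1f bpm, mean R-S %.3g %s",
            60 / mean(diff(object@rTime)),
            mean(object@rDefl - object@sDefl), object@units))
    }
    cat("\n")
    invisible(NULL)
})

#' @rdname ArrhythmiaTable-class
#' @export
setMethod("contingencyCounts", "ArrhythmiaTable", function(x) {
    matrix(c(x@a, x@c, x@b, x@d), nrow = 2,
        dimnames = list(
            arm = c("treatment", "control"),
            interval = c("extreme", "normal")))
})

#' @rdname ArrhythmiaTable-class
#' @export
setMethod("ratePer1000", "ArrhythmiaTable", function(x) {
    c(treatment = 1000 * x@a / (x@a + x@b),
      control = 1000 * x@c / (x@c + x@d))
})

setMethod("show", "ArrhythmiaTable", function(object) {
    cat(sprintf("ArrhythmiaTable (cutoff %g s)\n", object@cutoff))
    print(contingencyCounts(object))
    r <- ratePer1000(object)
    cat(sprintf("per-1000 rates: treatment %.2f, control %.2f\n",
        r[["treatment"]], r[["control"]]))
    invisible(NULL)
})

#' @rdname CalciumProfile-class
#' @export
setMethod("dff", "CalciumProfile", function(x) x@dff)

#' @rdname CalciumProfile-class
#' @export
setMethod("lineRate", "CalciumProfile", function(x) x@lineRate)

#' @rdname CalciumProfile-class
#' @export
setMethod("recordingTime", "CalciumProfile", function(x) {
    (seq_along(x@dff) - 1L) / x@lineRate
})

setMethod("show", "CalciumProfile", function(object) {
    cat(sprintf(
        "CalciumProfile '%s': %d lines @ %g Hz (%.1f s), F0 = %s\n",
        object@label, length(object@dff), object@lineRate,
        length(object@dff) / object@lineRate,
        ifelse(is.na(object@f0), "unset", format(object@f0))))
    invisible(NULL)
})
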