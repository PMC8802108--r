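#' @import methods
NULL

#' Uniformly sampled single- or multi-channel recording
#'
#' Container for one raw recording segment: a mechanocardiogram force trace
#' (one channel, nN), a multielectrode-array field-potential recording
#' (many channels, uV), or any other uniformly sampled signal.  Time is
#' implicit: sample \code{i} sits at \code{startTime + (i-1)/samplingRate}.
#'
#' @slot signal numeric matrix, samples x channels.
#' @slot samplingRate sampling frequency in Hz.
#' @slot startTime time of the first sample in seconds.
#' @slot units physical units of the signal (e.g. \code{"nN"}, \code{"uV"}).
#' @slot label free-text segment label (e.g. \code{"baseline"},
#'   \code{"A 10 uM"}).
#'
#' @exportClass RecordingSegment
setClass("RecordingSegment",
    representation(
        signal = "matrix",
        samplingRate = "numeric",
        startTime = "numeric",
        units = "character",
        label = "character"
    ),
    prototype(
        signal = matrix(numeric(0), ncol = 1),
        samplingRate = 1000,
        startTime = 0,
        units = "nN",
        label = ""
    )
)

setValidity("RecordingSegment", function(object) {
    msg <- character(0)
    if (!is.numeric(object@signal)) {
        msg <- c(msg, "'signal' must be a numeric matrix")
    }
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0) {
        msg <- c(msg, "'samplingRate' must be a single positive number")
    }
    if (length(object@startTime) != 1L || !is.finite(object@startTime)) {
        msg <- c(msg, "'startTime' must be a single finite number")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated recording
#'
#' Bookkeeping object emitted by the signal simulator: the scheduled beat
#' times, per-beat contraction amplitudes, indices of inter-beat intervals
#' that were lengthened into arrhythmic pauses, calcium transient and spark
#' times, and the identity of deliberately unusable channels.  Every
#' detection stage is validated against this object in the test suite.
#'
#' @slot beatTimes scheduled beat times, seconds, sorted ascending.
#' @slot beatAmplitudes per-beat contraction amplitude (nN); may be empty.
#' @slot pauseIndices 1-based indices into the inter-beat-interval sequence
#'   that were replaced by an injected pause.
#' @slot transientTimes calcium transient onset times, seconds.
#' @slot sparkTimes calcium spark times, seconds.
#' @slot badChannels 1-based indices of simulated unusable channels.
#' @slot duration nominal recording duration in seconds.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        beatTimes = "numeric",
        beatAmplitudes = "numeric",
        pauseIndices = "integer",
        transientTimes = "numeric",
        sparkTimes = "numeric",
        badChannels = "integer",
        duration = "numeric"
    ),
    prototype(
        beatTimes = numeric(0),
        beatAmplitudes = numeric(0),
        pauseIndices = integer(0),
        transientTimes = numeric(0),
        sparkTimes = numeric(0),
        badChannels = integer(0),
        duration = NA_real_
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character(0)
    if (is.unsorted(object@beatTimes)) {
        msg <- c(msg, "'beatTimes' must be sorted ascending")
    }
    if (is.unsorted(object@sparkTimes)) {
        msg <- c(msg, "'sparkTimes' must be sorted ascending")
    }
    if (is.unsorted(object@transientTimes)) {
        msg <- c(msg, "'transientTimes' must be sorted ascending")
    }
    if (!is.na(object@duration)) {
        tt <- c(object@beatTimes, object@sparkTimes, object@transientTimes)
        if (length(tt) && (min(tt) < 0 || max(tt) > object@duration)) {
            msg <- c(msg, "all event times must lie within [0, duration]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Detected beat series
#'
#' Ordered R/S events detected in one recording segment.  Each contractile
#' (or electrical) event is summarised by the time and deflection of its R
#' peak and of the following S trough; inter-beat (R-R) intervals, R-S
#' amplitudes and the beat rate are derived quantities exposed through
#' accessors.
#'
#' @slot rTime R-peak times, seconds.
#' @slot rDefl R-peak deflections, signal units.
#' @slot sTime S-trough times, seconds.
#' @slot sDefl S-trough deflections, signal units.
#' @slot units signal units.
#' @slot label segment label the series was detected in.
#'
#' @exportClass BeatSeries
setClass("BeatSeries",
    representation(
        rTime = "numeric",
        rDefl = "numeric",
        sTime = "numeric",
        sDefl = "numeric",
        units = "character",
        label = "character"
    ),
    prototype(
        rTime = numeric(0), rDefl = numeric(0),
        sTime = numeric(0), sDefl = numeric(0),
        units = "", label = ""
    )
)

setValidity("BeatSeries", function(object) {
    n <- length(object@rTime)
    msg <- character(0)
    if (length(object@rDefl) != n || length(object@sTime) != n ||
        length(object@sDefl) != n) {
        msg <- c(msg, "event slots must have equal length")
    } else if (n > 0L) {
        if (is.unsorted(object@rTime, strictly = TRUE)) {
            msg <- c(msg, "'rTime' must be strictly increasing")
        }
        if (any(object@sTime <= object@rTime)) {
            msg <- c(msg, "each S trough must follow its R peak")
        }
        if (any(object@rDefl <= object@sDefl)) {
            msg <- c(msg, "R deflection must exceed S deflection")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Arrhythmic-event contingency table
#'
#' 2x2 table of extreme vs normal inter-beat intervals in a treatment arm
#' against a control arm.  An interval is "extreme" (an arrhythmic event)
#' when it exceeds a model-specific cutoff.  Counts may be pooled across
#' recordings within an arm; the per-recording breakdown is retained for
#' sensitivity checks.
#'
#' @slot a treatment extreme-interval count.
#' @slot b treatment normal-interval count.
#' @slot c control extreme-interval count.
#' @slot d control normal-interval count.
#' @slot cutoff cutoff in seconds that defined "extreme".
#' @slot perRecording data.frame with per-recording (arm, extreme, total).
#'
#' @exportClass ArrhythmiaTable
setClass("ArrhythmiaTable",
    representation(
        a = "integer", b = "integer", c = "integer", d = "integer",
        cutoff = "numeric",
        perRecording = "data.frame"
    ),
    prototype(
        a = 0L, b = 0L, c = 0L, d = 0L, cutoff = NA_real_,
        perRecording = data.frame()
    )
)

setValidity("ArrhythmiaTable", function(object) {
    cnt <- c(object@a, object@b, object@c, object@d)
    if (any(is.na(cnt)) || any(cnt < 0L)) {
        "counts must be nonnegative integers"
    } else {
        TRUE
    }
})

#' Calcium line-scan fluorescence profile
#'
#' One fluorescence-versus-time profile from confocal line-scan imaging
#' (100 Hz line rate by default), stored both as raw fluorescence and as the
#' baseline-normalized \eqn{\Delta F/F_0} trace used by the transient and
#' spark detectors.
#'
#' @slot raw raw fluorescence, arbitrary units.
#' @slot dff baseline-normalized fluorescence, \eqn{\Delta F/F_0}.
#' @slot lineRate line rate in Hz.
#' @slot f0 baseline fluorescence estimate used for normalization.
#' @slot label free-text label.
#'
#' @exportClass CalciumProfile
setClass("CalciumProfile",
    representation(
        raw = "numeric",
        dff = "numeric",
        lineRate = "numeric",
        f0 = "numeric",
        label = "character"
    ),
    prototype(
        raw = numeric(0), dff = numeric(0), lineRate = 100,
        f0 = NA_real_, label = ""
    )
)

setValidity("CalciumProfile", function(object) {
    msg <- character(0)
    if (length(object@lineRate) != 1L || !is.finite(object@lineRate) ||
        object@lineRate <= 0) {
        msg <- c(msg, "'lineRate' must be a single positive number")
    }
    if (length(object@dff) && length(object@raw) &&
        length(object@dff) != length(object@raw)) {
        msg <- c(msg, "'raw' and 'dff' must have equal length")
    }
    if (length(msg)) msg else TRUE
})
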