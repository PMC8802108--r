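#' @rdname RecordingSegment-class
#' @param x object.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname RecordingSegment-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname RecordingSegment-class
#' @export
setGeneric("recordingTime", function(x) standardGeneric("recordingTime"))

#' @rdname RecordingSegment-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname RecordingSegment-class
#' @export
setGeneric("segmentDuration", function(x) standardGeneric("segmentDuration"))

#' @rdname RecordingSegment-class
#' @export
setGeneric("segmentLabel", function(x) standardGeneric("segmentLabel"))

#' @rdname GroundTruth-class
#' @param x object.
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname GroundTruth-class
#' @export
setGeneric("pauseIndices", function(x) standardGeneric("pauseIndices"))

#' @rdname GroundTruth-class
#' @export
setGeneric("sparkTimes", function(x) standardGeneric("sparkTimes"))

#' @rdname GroundTruth-class
#' @export
setGeneric("transientTimes", function(x) standardGeneric("transientTimes"))

#' @rdname GroundTruth-class
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))

#' @rdname BeatSeries-class
#' @param x object.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname BeatSeries-class
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))

#' @rdname BeatSeries-class
#' @export
setGeneric("rsAmplitudes", function(x) standardGeneric("rsAmplitudes"))

#' @rdname BeatSeries-class
#' @export
setGeneric("beatEvents", function(x) standardGeneric("beatEvents"))

#' @rdname beatRate
#' @export
setGeneric("beatRate", function(x, ...) standardGeneric("beatRate"))

#' @rdname contractionForce
#' @export
setGeneric("contractionForce", function(x, ...) {
    standardGeneric("contractionForce")
})

#' @rdname ArrhythmiaTable-class
#' @param x object.
#' @export
setGeneric("contingencyCounts", function(x) {
    standardGeneric("contingencyCounts")
})

#' @rdname ArrhythmiaTable-class
#' @export
setGeneric("ratePer1000", function(x) standardGeneric("ratePer1000"))

#' @rdname CalciumProfile-class
#' @param x object.
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname CalciumProfile-class
#' @export
setGeneric("lineRate", function(x) standardGeneric("lineRate"))
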