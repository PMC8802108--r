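## Delimited-text I/O conventions: recordings as comma-separated
## (time, ch1..chN) tables with a '#'-commented header carrying units,
## sampling rate and label; ground truth as a JSON sidecar.

#' Write a recording segment as delimited text
#'
#' Format: '#'-commented header lines (\code{units}, \code{sampling_rate},
#' \code{label}), then comma-separated \code{time, ch1..chN} columns.
#'
#' @param segment a \linkS4class{RecordingSegment}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeRecording <- function(segment, file) {
    stopifnot(is(segment, "RecordingSegment"))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("# units: %s", segment@units),
        sprintf("# sampling_rate: %.10g", samplingRate(segment)),
        sprintf("# label: %s", segmentLabel(segment))
    ), con)
    sig <- signalMatrix(segment)
    df <- data.frame(time = recordingTime(segment), sig)
    names(df) <- c("time",
                   if (is.null(colnames(sig))) {
                       sprintf("ch%02d", seq_len(ncol(sig)))
                   } else {
                       colnames(sig)
                   })
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
    invisible(file)
}

#' Read a recording segment from delimited text
#'
#' Counterpart of \code{\link{writeRecording}}.  The time column must be
#' uniform to within one part in 10^6 of the sample period; non-uniform
#' sampling is an input error.
#'
#' @param file path to a recording written by \code{\link{writeRecording}}.
#' @return A \linkS4class{RecordingSegment}.
#' @export
readRecording <- function(file) {
    lines <- readLines(file)
    hdr <- grep("^#", lines, value = TRUE)
    pick <- function(key, default = "") {
        m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
        if (length(m)) trimws(sub(sprintf("^#\\s*%s:", key), "", m[1])) else default
    }
    units <- pick("units", "")
    fsHdr <- suppressWarnings(as.numeric(pick("sampling_rate", "")))
    label <- pick("label", "")
    df <- utils::read.csv(file, comment.char = "#")
    tvec <- df[[1]]
    if (length(tvec) >= 3L) {
        dt <- diff(tvec)
        if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
            stop("non-uniform sampling in '", file, "'")
        }
    }
    fs <- if (is.finite(fsHdr)) fsHdr else 1 / stats::median(diff(tvec))
    sig <- as.matrix(df[, -1, drop = FALSE])
    new("RecordingSegment", signal = sig, samplingRate = fs,
        startTime = tvec[1], units = units, label = label)
}

#' Write simulator ground truth as a JSON sidecar
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(truth, file) {
    stopifnot(is(truth, "GroundTruth"))
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
        stop("the 'jsonlite' package is required to write ground truth")
    }
    jsonlite::write_json(list(
        beat_times = truth@beatTimes,
        beat_amplitudes = truth@beatAmplitudes,
        pause_indices = truth@pauseIndices,
        transient_times = truth@transientTimes,
        spark_times = truth@sparkTimes,
        bad_channels = truth@badChannels,
        duration = truth@duration
    ), file, digits = NA)
    invisible(file)
}

#' Read a ground-truth sidecar written by \code{\link{writeGroundTruth}}
#'
#' @param file path.
#' @return A \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(file) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
        stop("the 'jsonlite' package is required to read ground truth")
    }
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    num <- function(v) if (length(v)) as.numeric(v) else numeric(0)
    int <- function(v) if (length(v)) as.integer(v) else integer(0)
    new("GroundTruth",
        beatTimes = num(x$beat_times),
        beatAmplitudes = num(x$beat_amplitudes),
        pauseIndices = int(x$pause_indices),
        transientTimes = num(x$transient_times),
        sparkTimes = num(x$spark_times),
        badChannels = int(x$bad_channels),
        duration = if (length(x$duration)) as.numeric(x$duration) else NA_real_)
}

#' Write a detected beat series as a per-event table
#'
#' Comma-separated columns \code{r_time, r_defl, s_time, s_defl, rr, rs};
#' the last row's \code{rr} is empty (n events give n - 1 intervals).
#'
#' @param series a \linkS4class{BeatSeries}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeBeatSeries <- function(series, file) {
    stopifnot(is(series, "BeatSeries"))
    ev <- as.data.frame(beatEvents(series))
    names(ev) <- c("r_time", "r_defl", "s_time", "s_defl", "rr", "rs")
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# label: %s", series@label), con)
    utils::write.table(ev, con, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(file)
}
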