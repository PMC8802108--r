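## Multichannel field-potential analysis: channel quality control and
## recording-level rate metrics.  Amplitudes are deliberately excluded from
## all MEA summaries: extracellular R-S spans do not track contraction
## force, so only R-R intervals and the beat rate propagate upstream.

#' Quality-control MEA channels
#'
#' A channel is rejected when its spike signal-to-noise ratio (median
#' detected spike amplitude over the MAD-based robust noise SD of the raw
#' channel) falls below \code{snrFloor}, or when its detected beat count
#' deviates from the across-channel median count by more than
#' \code{countTolerance} as a fraction (a "non-representative" channel).
#' The QC is deterministic.  A recording with fewer than 3 accepted
#' channels is rejected outright with an error.
#'
#' @param recording a multichannel \linkS4class{RecordingSegment} with at
#'   least 3 channels.
#' @param config a \code{\link{detectorConfig}}; defaults to the MEA
#'   preset.
#' @param snrFloor minimum acceptable SNR (default 5).
#' @param countTolerance maximum fractional deviation of a channel's beat
#'   count from the across-channel median (default 0.25).
#'
#' @return A \code{DataFrame} with one row per channel: \code{channel},
#'   \code{snr}, \code{nEvents}, \code{countConsistent}, \code{accepted}.
#' @export
qcChannels <- function(recording, config = detectorConfig("mea"),
                       snrFloor = 5, countTolerance = 0.25) {
    stopifnot(is(recording, "RecordingSegment"))
    nCh <- nChannels(recording)
    if (nCh < 3L) {
        stop("at least 3 channels are required")
    }
    snr <- numeric(nCh)
    counts <- integer(nCh)
    for (ch in seq_len(nCh)) {
        cfg <- config
        cfg$channel <- ch
        x <- signalMatrix(recording)[, ch]
        series <- suppressWarnings(detectBeats(recording, cfg))
        counts[ch] <- nEvents(series)
        noise <- stats::mad(x)
        snr[ch] <- if (counts[ch] >= 1L && noise > 0) {
            stats::median(series@rDefl) / noise
        } else {
            0
        }
    }
    medCount <- stats::median(counts)
    consistent <- if (medCount > 0) {
        abs(counts - medCount) <= countTolerance * medCount
    } else {
        rep(FALSE, nCh)
    }
    accepted <- snr >= snrFloor & consistent
    if (sum(accepted) < 3L) {
        stop("recording rejected: fewer than 3 channels passed quality ",
             "control (", sum(accepted), " accepted)")
    }
    S4Vectors::DataFrame(
        channel = seq_len(nCh), snr = snr, nEvents = counts,
        countConsistent = consistent, accepted = accepted)
}

#' Beat timing from an MEA recording
#'
#' Runs the shared R-peak detector (MEA refractory default) on every
#' accepted channel.  The recording-level beat rate is the mean of the
#' per-channel rates; the recording-level R-R interval sequence - the input
#' to arrhythmia scoring - is taken from the accepted channel with the
#' highest SNR, which avoids merging intervals across channels with
#' different conduction latencies.  No amplitude quantity is reported.
#'
#' @param recording a multichannel \linkS4class{RecordingSegment}.
#' @param qc optional precomputed \code{\link{qcChannels}} report.
#' @param config a \code{\link{detectorConfig}} (MEA preset by default).
#' @param ... passed to \code{\link{qcChannels}} when \code{qc} is NULL.
#'
#' @return A list: \code{beatRate} (bpm), \code{rrIntervals} (seconds, from
#'   the representative channel), \code{representativeChannel},
#'   \code{channelSummary} (\code{DataFrame}: channel, snr, nEvents,
#'   beatRate), \code{channelSeries} (per-channel
#'   \linkS4class{BeatSeries}), and \code{qc}.
#' @export
meaBeatSeries <- function(recording, qc = NULL,
                          config = detectorConfig("mea"), ...) {
    if (is.null(qc)) {
        qc <- qcChannels(recording, config = config, ...)
    }
    acc <- which(qc$accepted)
    if (length(acc) < 3L) {
        stop("recording rejected: fewer than 3 accepted channels")
    }
    seriesList <- list()
    rates <- numeric(length(acc))
    for (i in seq_along(acc)) {
        cfg <- config
        cfg$channel <- acc[i]
        s <- suppressWarnings(detectBeats(recording, cfg))
        if (nEvents(s) < 2L) {
            stop("accepted channel ", acc[i], " yielded fewer than 2 events")
        }
        seriesList[[sprintf("ch%02d", acc[i])]] <- s
        rates[i] <- beatRate(s)
    }
    rep <- acc[which.max(qc$snr[acc])]
    list(
        beatRate = mean(rates),
        rrIntervals = rrIntervals(seriesList[[sprintf("ch%02d", rep)]]),
        representativeChannel = rep,
        channelSummary = S4Vectors::DataFrame(
            channel = acc, snr = qc$snr[acc],
            nEvents = vapply(seriesList, nEvents, integer(1)),
            beatRate = rates),
        channelSeries = seriesList,
        qc = qc)
}
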