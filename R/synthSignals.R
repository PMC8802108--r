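## Phenomenological simulator for cardiomyocyte functional recordings.
## All stochastic functions take an explicit seed and restore the caller's
## RNG state, so identical parameters + seed give bit-identical output.

#' Generate a spontaneous beat schedule with optional arrhythmic events
#'
#' Draws a sequence of beat times for a spontaneously beating cardiomyocyte
#' preparation.  Inter-beat intervals are Gaussian around the base period
#' with coefficient of variation \code{rateJitterCV}.  Two arrhythmia
#' phenotypes can be injected: (i) stochastic extreme pauses, where a
#' Poisson-distributed number of randomly chosen inter-beat intervals is
#' replaced by a long pause drawn uniformly from \code{pauseDurationRange}
#' (so each injected pause maps one-to-one to an extreme R-R interval), and
#' (ii) tachy-brady alternation, a square-wave rate modulation that
#' multiplies the rate by \code{tachyBradyRateRatio} in the first half of
#' each period and divides it in the second half.
#'
#' @param duration recording duration in seconds (beats are generated on
#'   \code{[0, duration)}); ignored when \code{nBeats} is given.
#' @param baseRate base beat rate in beats per minute (> 0).
#' @param rateJitterCV coefficient of variation of inter-beat intervals
#'   (>= 0); intervals are truncated below at 10\% of their mean.
#' @param pauseRate expected injected pauses per 1000 beats.
#' @param pauseDurationRange length-2 numeric, seconds: range of injected
#'   pause durations.  Must exceed the arrhythmia cutoff the pauses are
#'   meant to trigger.
#' @param tachyBrady logical, enable square-wave tachy-brady alternation.
#' @param tachyBradyPeriod full alternation period, seconds.
#' @param tachyBradyRateRatio rate multiplier of the tachycardic half-period
#'   (the bradycardic half uses its reciprocal).
#' @param nBeats generate exactly this many beats instead of filling
#'   \code{duration}.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#'
#' @return A \linkS4class{GroundTruth} holding the beat times and the
#'   indices of intervals replaced by pauses.
#'
#' @examples
#' gt <- generateBeatSchedule(duration = 10, baseRate = 60, rateJitterCV = 0)
#' beatTimes(gt) # 0, 1, ..., 9
#' @export
generateBeatSchedule <- function(duration = NULL, baseRate = 60,
                                 rateJitterCV = 0.05, pauseRate = 0,
                                 pauseDurationRange = c(4, 5),
                                 tachyBrady = FALSE, tachyBradyPeriod = 10,
                                 tachyBradyRateRatio = 2,
                                 nBeats = NULL, seed = NULL) {
    if (is.null(duration) && is.null(nBeats)) {
        stop("one of 'duration' or 'nBeats' must be given")
    }
    if (!is.null(duration) && (!is.finite(duration) || duration <= 0)) {
        stop("'duration' must be a positive number")
    }
    if (!is.finite(baseRate) || baseRate <= 0) {
        stop("'baseRate' must be a positive number")
    }
    if (rateJitterCV < 0) {
        stop("'rateJitterCV' must be >= 0")
    }
    if (pauseRate < 0) {
        stop("'pauseRate' must be >= 0")
    }
    if (pauseRate > 0 &&
        (length(pauseDurationRange) != 2L ||
         any(pauseDurationRange <= 0) || diff(pauseDurationRange) < 0)) {
        stop("'pauseDurationRange' must be an increasing positive pair")
    }
    baseInterval <- 60 / baseRate

    withSeed(seed, {
        if (tachyBrady) {
            ## Rate depends on current time: generate sequentially.
            half <- tachyBradyPeriod / 2
            tEnd <- if (is.null(duration)) Inf else duration
            nMax <- if (is.null(nBeats)) Inf else nBeats
            times <- numeric(0)
            t <- 0
            while (t < tEnd && length(times) < nMax) {
                times <- c(times, t)
                ratio <- if ((t %% tachyBradyPeriod) < half) {
                    tachyBradyRateRatio
                } else {
                    1 / tachyBradyRateRatio
                }
                m <- baseInterval / ratio
                dt <- if (rateJitterCV > 0) {
                    max(0.1 * m, stats::rnorm(1L, m, rateJitterCV * m))
                } else {
                    m
                }
                t <- t + dt
            }
            intervals <- diff(times)
        } else {
            nDraw <- if (!is.null(nBeats)) {
                nBeats - 1L
            } else {
                ceiling(duration / baseInterval * (1 + 4 * rateJitterCV)) + 10L
            }
            intervals <- if (rateJitterCV > 0) {
                pmax(0.1 * baseInterval,
                     stats::rnorm(nDraw, baseInterval,
                                  rateJitterCV * baseInterval))
            } else {
                rep(baseInterval, nDraw)
            }
            if (!is.null(duration)) {
                while (sum(intervals) < duration) {
                    intervals <- c(intervals, pmax(
                        0.1 * baseInterval,
                        stats::rnorm(10L, baseInterval,
                                     rateJitterCV * baseInterval)))
                }
            }
        }

        nInt <- length(intervals)
        pauseIdx <- integer(0)
        if (pauseRate > 0 && nInt > 0L) {
            nPause <- min(stats::rpois(1L, pauseRate * (nInt + 1L) / 1000),
                          nInt)
            if (nPause > 0L) {
                pauseIdx <- sort(sample.int(nInt, nPause))
                intervals[pauseIdx] <- stats::runif(
                    nPause, pauseDurationRange[1L], pauseDurationRange[2L])
            }
        }

        times <- c(0, cumsum(intervals))
        if (!is.null(nBeats)) {
            times <- times[seq_len(min(nBeats, length(times)))]
        }
        if (!is.null(duration)) {
            keep <- times < duration
            times <- times[keep]
        }
        nKept <- length(times)
        pauseIdx <- pauseIdx[pauseIdx < nKept]

        new("GroundTruth",
            beatTimes = times,
            pauseIndices = as.integer(pauseIdx),
            duration = if (is.null(duration)) {
                if (nKept) max(times) else 0
            } else {
                duration
            })
    })
}

## Biphasic contraction template sampled at offsets tau (seconds, relative
## to the R peak).  Fast half-cosine upstroke over the quarter event width
## before the peak, fall to the S trough at +0.35 w, recovery to baseline
## at +0.75 w.  Smooth, so R and S are well-defined extrema.
mcgTemplate <- function(tau, amplitude, depthFraction, width) {
    y <- numeric(length(tau))
    rise <- 0.25 * width
    fall <- 0.35 * width
    rec <- 0.40 * width
    i <- tau >= -rise & tau <= 0
    y[i] <- amplitude * 0.5 * (1 + cos(pi * tau[i] / rise))
    i <- tau > 0 & tau <= fall
    y[i] <- -depthFraction * amplitude +
        (1 + depthFraction) * amplitude * 0.5 * (1 + cos(pi * tau[i] / fall))
    i <- tau > fall & tau <= fall + rec
    y[i] <- -depthFraction * amplitude * 0.5 *
        (1 + cos(pi * (tau[i] - fall) / rec))
    y
}

#' Render a mechanocardiogram force trace from a beat schedule
#'
#' Places one biphasic contraction event (upstroke to the R peak at the
#' scheduled beat time, undershoot to the S trough, return to baseline) at
#' every beat time, on top of optional sinusoidal drift and Gaussian noise.
#' The S trough sits at \code{relaxationDepthFraction * amplitude} below
#' baseline, so the configured R-S span is
#' \code{amplitude * (1 + relaxationDepthFraction)}.
#'
#' @param beatTimes sorted beat times, seconds (numeric vector or a
#'   \linkS4class{GroundTruth}).
#' @param contractionAmplitude R-peak amplitude in nN; a scalar or one value
#'   per beat.
#' @param relaxationDepthFraction S-trough depth as a fraction of the R
#'   amplitude (in (0, 1)).
#' @param eventWidth total width of one contraction event, seconds.  Events
#'   must not overlap: the shortest inter-beat interval must exceed it.
#' @param noiseSd Gaussian noise SD, nN.
#' @param driftAmplitude,driftPeriod sinusoidal baseline drift, nN / s.
#' @param samplingRate sampling rate, Hz (>= 50).
#' @param duration trace duration, seconds; defaults to covering the last
#'   event.
#' @param label segment label.
#' @param seed integer seed for the noise stream.
#'
#' @return A single-channel \linkS4class{RecordingSegment} in nN.
#' @examples
#' gt <- generateBeatSchedule(duration = 10, baseRate = 60, rateJitterCV = 0)
#' seg <- renderMcgTrace(gt, contractionAmplitude = 100)
#' @export
renderMcgTrace <- function(beatTimes, contractionAmplitude = 100,
                           relaxationDepthFraction = 0.25, eventWidth = 0.4,
                           noiseSd = 0, driftAmplitude = 0, driftPeriod = 60,
                           samplingRate = 1000, duration = NULL,
                           label = "mcg", seed = NULL) {
    if (is(beatTimes, "GroundTruth")) {
        beatTimes <- beatTimes(beatTimes)
    }
    if (is.unsorted(beatTimes)) {
        stop("'beatTimes' must be sorted")
    }
    if (any(contractionAmplitude <= 0)) {
        stop("'contractionAmplitude' must be positive")
    }
    if (relaxationDepthFraction <= 0 || relaxationDepthFraction >= 1) {
        stop("'relaxationDepthFraction' must be in (0, 1)")
    }
    if (samplingRate < 50) {
        stop("'samplingRate' must be >= 50 Hz")
    }
    nB <- length(beatTimes)
    if (nB >= 2L && min(diff(beatTimes)) <= eventWidth) {
        stop("overlapping events: shortest inter-beat interval must exceed ",
             "'eventWidth'")
    }
    amp <- rep_len(contractionAmplitude, nB)
    if (is.null(duration)) {
        duration <- if (nB) max(beatTimes) + eventWidth else 1
    }
    n <- round(duration * samplingRate)
    tvec <- (seq_len(n) - 1L) / samplingRate
    y <- numeric(n)
    for (b in seq_len(nB)) {
        lo <- max(1L, floor((beatTimes[b] - 0.25 * eventWidth) *
                            samplingRate) + 1L)
        hi <- min(n, ceiling((beatTimes[b] + 0.75 * eventWidth) *
                             samplingRate) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        y[idx] <- y[idx] + mcgTemplate(tvec[idx] - beatTimes[b], amp[b],
                                       relaxationDepthFraction, eventWidth)
    }
    if (driftAmplitude != 0) {
        y <- y + driftAmplitude * sin(2 * pi * tvec / driftPeriod)
    }
    if (noiseSd > 0) {
        y <- y + withSeed(seed, stats::rnorm(n, 0, noiseSd))
    }
    RecordingSegment(y, samplingRate = samplingRate, units = "nN",
                     label = label)
}

## Biphasic extracellular spike: derivative-of-Gaussian scaled so the
## positive lobe peaks at `amplitude` exactly `latency` after the beat.
meaSpikeTemplate <- function(tau, amplitude, sigma) {
    -amplitude * exp(0.5) * (tau / sigma) * exp(-tau^2 / (2 * sigma^2))
}

#' Render a multichannel field-potential (MEA) recording
#'
#' Good channels carry one biphasic extracellular spike per scheduled beat,
#' with a fixed channel-specific conduction latency below
#' \code{maxLatency}; bad channels carry noise only (at twice the nominal
#' noise SD, emulating a noisy, non-representative electrode).
#'
#' @param beatTimes sorted beat times, seconds, or a
#'   \linkS4class{GroundTruth}.
#' @param nChannels number of electrodes (>= 3).
#' @param nBadChannels number of unusable channels (< \code{nChannels}).
#' @param spikeAmplitude positive-lobe spike amplitude, uV.
#' @param spikeWidth lobe-to-lobe spike width, seconds.
#' @param noiseSd channel noise SD, uV.
#' @param maxLatency maximum channel latency, seconds.
#' @param samplingRate sampling rate, Hz.
#' @param duration trace duration, seconds.
#' @param label segment label.
#' @param seed integer seed.
#'
#' @return A list with \code{recording} (a multichannel
#'   \linkS4class{RecordingSegment} in uV) and \code{truth} (a
#'   \linkS4class{GroundTruth} whose \code{badChannels} marks the noise-only
#'   channels).
#' @export
renderMeaRecording <- function(beatTimes, nChannels = 6, nBadChannels = 0,
                               spikeAmplitude = 300, spikeWidth = 0.004,
                               noiseSd = 10, maxLatency = 0.01,
                               samplingRate = 10000, duration = NULL,
                               label = "mea", seed = NULL) {
    if (is(beatTimes, "GroundTruth")) {
        beatTimes <- beatTimes(beatTimes)
    }
    if (nChannels < 3) {
        stop("at least 3 channels are required")
    }
    if (nBadChannels >= nChannels) {
        stop("'nBadChannels' must be smaller than 'nChannels'")
    }
    if (is.unsorted(beatTimes)) {
        stop("'beatTimes' must be sorted")
    }
    if (is.null(duration)) {
        duration <- if (length(beatTimes)) {
            max(beatTimes) + 10 * spikeWidth + maxLatency
        } else {
            1
        }
    }
    n <- round(duration * samplingRate)
    tvec <- (seq_len(n) - 1L) / samplingRate
    sigma <- spikeWidth / 2

    withSeed(seed, {
        bad <- if (nBadChannels > 0) {
            sort(sample.int(nChannels, nBadChannels))
        } else {
            integer(0)
        }
        latency <- stats::runif(nChannels, 0, maxLatency)
        sig <- matrix(0, nrow = n, ncol = nChannels)
        for (ch in seq_len(nChannels)) {
            if (ch %in% bad) {
                sig[, ch] <- stats::rnorm(n, 0, 2 * noiseSd)
                next
            }
            y <- numeric(n)
            for (tb in beatTimes) {
                center <- tb + latency[ch] + sigma
                lo <- max(1L, floor((center - 4 * sigma) * samplingRate) + 1L)
                hi <- min(n, ceiling((center + 4 * sigma) * samplingRate) + 1L)
                if (lo > hi) next
                idx <- lo:hi
                y[idx] <- y[idx] +
                    meaSpikeTemplate(tvec[idx] - center, spikeAmplitude, sigma)
            }
            if (noiseSd > 0) {
                y <- y + stats::rnorm(n, 0, noiseSd)
            }
            sig[, ch] <- y
        }
        colnames(sig) <- sprintf("ch%02d", seq_len(nChannels))
        list(
            recording = new("RecordingSegment", signal = sig,
                samplingRate = samplingRate, startTime = 0,
                units = "uV", label = label),
            truth = new("GroundTruth", beatTimes = beatTimes,
                badChannels = as.integer(bad), duration = duration))
    })
}

## Calcium transient template: linear rise from 0 to `amplitude` over
## `riseTime`, then exponential decay with time constant `decayTau`.
calciumTemplate <- function(tau, amplitude, riseTime, decayTau) {
    y <- numeric(length(tau))
    i <- tau >= 0 & tau < riseTime
    y[i] <- amplitude * tau[i] / riseTime
    i <- tau >= riseTime
    y[i] <- amplitude * exp(-(tau[i] - riseTime) / decayTau)
    y
}

#' Render a calcium line-scan fluorescence profile
#'
#' Builds a \eqn{\Delta F/F_0} trace of periodic calcium transients (linear
#' rise over \code{riseTime}, exponential decay with time constant
#' \code{decayTau}) with low-amplitude calcium sparks (Gaussian bumps of
#' FWHM \code{sparkWidth}) inserted uniformly at random in the diastolic
#' intervals between transients, then converts it to raw fluorescence
#' around baseline \code{f0} with additive noise.
#'
#' @param transientTimes transient onset times, seconds.  Spacing must
#'   exceed \code{riseTime + 3 * decayTau} so transients do not overlap.
#' @param transientAmplitude transient peak amplitude, \eqn{\Delta F/F_0}.
#' @param riseTime rise duration, seconds.
#' @param decayTau exponential decay time constant, seconds.
#' @param sparkRate expected sparks per second of diastolic time.
#' @param sparkAmplitudeFraction spark amplitude as a fraction of the
#'   transient amplitude; must be in (0, 1) (sparks are sub-transient).
#' @param sparkWidth spark full width at half maximum, seconds.
#' @param lineRate line-scan rate, Hz (100 by default).
#' @param noiseSd additive noise SD in \eqn{\Delta F/F_0} units.
#' @param f0 baseline raw fluorescence (arbitrary units).
#' @param duration trace duration, seconds.
#' @param label profile label.
#' @param seed integer seed.
#'
#' @return A list with \code{profile} (a \linkS4class{CalciumProfile} whose
#'   \code{dff} slot holds the noisy normalized trace) and \code{truth}
#'   (a \linkS4class{GroundTruth} with transient and spark times).
#' @export
renderCalciumLinescan <- function(transientTimes, transientAmplitude = 2,
                                  riseTime = 0.05, decayTau = 0.2,
                                  sparkRate = 0,
                                  sparkAmplitudeFraction = 0.3,
                                  sparkWidth = 0.06, lineRate = 100,
                                  noiseSd = 0.02, f0 = 100,
                                  duration = NULL, label = "calcium",
                                  seed = NULL) {
    if (is(transientTimes, "GroundTruth")) {
        transientTimes <- beatTimes(transientTimes)
    }
    if (is.unsorted(transientTimes)) {
        stop("'transientTimes' must be sorted")
    }
    if (decayTau <= 0) {
        stop("'decayTau' must be positive")
    }
    if (sparkRate > 0 &&
        (sparkAmplitudeFraction <= 0 || sparkAmplitudeFraction >= 1)) {
        stop("'sparkAmplitudeFraction' must be in (0, 1): sparks are ",
             "sub-transient events")
    }
    span <- riseTime + 3 * decayTau
    if (length(transientTimes) >= 2L && min(diff(transientTimes)) <= span) {
        stop("transient spacing must exceed riseTime + 3 * decayTau")
    }
    if (is.null(duration)) {
        duration <- if (length(transientTimes)) {
            max(transientTimes) + span + 1
        } else {
            10
        }
    }
    n <- round(duration * lineRate)
    tvec <- (seq_len(n) - 1L) / lineRate
    y <- numeric(n)
    for (t0 in transientTimes) {
        lo <- max(1L, floor(t0 * lineRate) + 1L)
        hi <- min(n, ceiling((t0 + riseTime + 8 * decayTau) * lineRate) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        y[idx] <- y[idx] + calciumTemplate(tvec[idx] - t0, transientAmplitude,
                                           riseTime, decayTau)
    }

    withSeed(seed, {
        sparks <- numeric(0)
        if (sparkRate > 0) {
            ## Diastolic intervals: everything outside transient spans,
            ## shrunk by one spark width so sparks stay clear of transients.
            edges <- c(0, as.vector(rbind(transientTimes,
                                          transientTimes + span)), duration)
            starts <- edges[seq(1, length(edges), by = 2)] + sparkWidth
            ends <- edges[seq(2, length(edges), by = 2)] - sparkWidth
            ok <- ends > starts
            starts <- starts[ok]
            ends <- ends[ok]
            total <- sum(ends - starts)
            if (total > 0) {
                nSpark <- stats::rpois(1L, sparkRate * total)
                if (nSpark > 0) {
                    u <- stats::runif(nSpark, 0, total)
                    cum <- c(0, cumsum(ends - starts))
                    seg <- findInterval(u, cum, rightmost.closed = TRUE)
                    sparks <- sort(starts[seg] + (u - cum[seg]))
                    ## Enforce a resolvability spacing of two spark widths:
                    ## closer events would fuse into one bump at 100 Hz and
                    ## be indistinguishable from a single release event.
                    if (length(sparks) > 1L) {
                        keepS <- rep(TRUE, length(sparks))
                        last <- sparks[1L]
                        for (si in 2L:length(sparks)) {
                            if (sparks[si] - last < 2 * sparkWidth) {
                                keepS[si] <- FALSE
                            } else {
                                last <- sparks[si]
                            }
                        }
                        sparks <- sparks[keepS]
                    }
                }
            }
            sSigma <- sparkWidth / (2 * sqrt(2 * log(2)))
            sAmp <- sparkAmplitudeFraction * transientAmplitude
            for (ts in sparks) {
                lo <- max(1L, floor((ts - 4 * sSigma) * lineRate) + 1L)
                hi <- min(n, ceiling((ts + 4 * sSigma) * lineRate) + 1L)
                idx <- lo:hi
                y[idx] <- y[idx] +
                    sAmp * exp(-(tvec[idx] - ts)^2 / (2 * sSigma^2))
            }
        }
        noisy <- y
        if (noiseSd > 0) {
            noisy <- noisy + stats::rnorm(n, 0, noiseSd)
        }
        list(
            profile = new("CalciumProfile", raw = f0 * (1 + noisy),
                dff = noisy, lineRate = lineRate, f0 = f0, label = label),
            truth = new("GroundTruth", transientTimes = transientTimes,
                sparkTimes = sparks, duration = duration))
    })
}
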