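test_that("deterministic schedule limit: 60 bpm, no jitter, 10 s", {
    gt <- generateBeatSchedule(duration = 10, baseRate = 60,
                               rateJitterCV = 0)
    expect_equal(beatTimes(gt), 0:9)
    expect_length(pauseIndices(gt), 0)
})

test_that("schedules are reproducible and mean interval tracks the rate", {
    a <- generateBeatSchedule(duration = 120, baseRate = 45,
                              rateJitterCV = 0.08, pauseRate = 10,
                              seed = 77)
    b <- generateBeatSchedule(duration = 120, baseRate = 45,
                              rateJitterCV = 0.08, pauseRate = 10,
                              seed = 77)
    expect_identical(beatTimes(a), beatTimes(b))
    expect_identical(pauseIndices(a), pauseIndices(b))

    ## Mean interval (excluding injected pauses) within 3 CV standard
    ## errors of 60/baseRate.
    rr <- diff(beatTimes(a))
    normal <- rr[setdiff(seq_along(rr), pauseIndices(a))]
    se <- 0.08 * (60 / 45) / sqrt(length(normal))
    expect_lt(abs(mean(normal) - 60 / 45), 3 * se)
})

test_that("injected pause count follows the Poisson expectation", {
    gt <- generateBeatSchedule(nBeats = 1000, baseRate = 60,
                               rateJitterCV = 0.05, pauseRate = 50,
                               pauseDurationRange = c(4, 5), seed = 42)
    nPause <- length(pauseIndices(gt))
    expect_lt(abs(nPause - 50), 3 * sqrt(50))
    ## Every injected pause is an extreme interval above the 3 s cutoff.
    rr <- diff(beatTimes(gt))
    expect_true(all(rr[pauseIndices(gt)] > 3))
    expect_true(all(rr[pauseIndices(gt)] >= 4 & rr[pauseIndices(gt)] <= 5))
})

test_that("tachy-brady alternation gives two exact interval values", {
    gt <- generateBeatSchedule(duration = 40, baseRate = 60,
                               rateJitterCV = 0, tachyBrady = TRUE,
                               tachyBradyPeriod = 10,
                               tachyBradyRateRatio = 2)
    rr <- round(diff(beatTimes(gt)), 10)
    expect_setequal(unique(rr), c(0.5, 2))
})

test_that("schedule parameter validation", {
    expect_error(generateBeatSchedule(duration = -5), "positive")
    expect_error(generateBeatSchedule(duration = 10, baseRate = 0),
                 "positive")
    expect_error(generateBeatSchedule(), "duration")
})

test_that("MCG renderer: degenerate and single-event limits", {
    ## No beats, no noise, no drift: constant zero.
    seg <- renderMcgTrace(numeric(0), duration = 2)
    expect_true(all(signalMatrix(seg) == 0))

    ## One noiseless beat: global max equals the amplitude at the beat time.
    seg1 <- renderMcgTrace(5, contractionAmplitude = 100, duration = 10)
    x <- signalMatrix(seg1)[, 1]
    expect_equal(max(x), 100)
    tPeak <- recordingTime(seg1)[which.max(x)]
    expect_lt(abs(tPeak - 5), 0.2)

    expect_error(renderMcgTrace(c(1, 1.1), eventWidth = 0.4), "overlap")
})

test_that("MCG renderer conserves events and respects per-beat amplitude", {
    gt <- generateBeatSchedule(duration = 30, baseRate = 60,
                               rateJitterCV = 0)
    amps <- seq(80, 138, by = 2)
    seg <- renderMcgTrace(beatTimes(gt), contractionAmplitude = amps,
                          duration = 30)
    bs <- detectBeats(seg)
    expect_equal(nEvents(bs), length(beatTimes(gt)))
    expect_equal(bs@rDefl, amps, tolerance = 1e-6)
})

test_that("MEA renderer marks exactly the bad channels and QC finds them", {
    sched <- generateBeatSchedule(duration = 20, baseRate = 60,
                                  rateJitterCV = 0, seed = 1)
    m <- renderMeaRecording(sched, nChannels = 6, nBadChannels = 2,
                            duration = 20, seed = 2)
    expect_length(badChannels(m$truth), 2)
    qc <- qcChannels(m$recording)
    expect_identical(which(!qc$accepted), badChannels(m$truth))
})

test_that("MEA renderer: all-clean noiseless channels agree", {
    sched <- generateBeatSchedule(duration = 20, baseRate = 60,
                                  rateJitterCV = 0, seed = 1)
    m <- renderMeaRecording(sched, nChannels = 4, nBadChannels = 0,
                            noiseSd = 0, duration = 20, seed = 3)
    counts <- vapply(1:4, function(ch) {
        cfg <- detectorConfig("mea")
        cfg$channel <- ch
        nEvents(detectBeats(m$recording, cfg))
    }, integer(1))
    expect_true(all(counts == counts[1]))
    expect_equal(counts[1], length(beatTimes(sched)))
    expect_error(renderMeaRecording(sched, nChannels = 2), "3 channels")
})

test_that("calcium renderer matches its analytic template", {
    ## Noiseless, spark-free: exact template sum.
    sim <- renderCalciumLinescan(c(1, 3), transientAmplitude = 2,
                                 riseTime = 0.05, decayTau = 0.2,
                                 sparkRate = 0, noiseSd = 0, duration = 5)
    x <- dff(sim$profile)
    tvec <- recordingTime(sim$profile)
    ## Baseline exactly zero before the first transient.
    expect_true(all(x[tvec < 1] == 0))
    ## Peak value equals the amplitude at onset + riseTime.
    expect_equal(max(x), 2)
    ## Analytic decay identity: peak-to-10% time is tau * ln(10).
    iPeak <- which.max(x)
    i10 <- iPeak + min(which(x[iPeak:length(x)] <= 0.2)) - 1L
    expect_lt(abs((tvec[i10] - tvec[iPeak]) - 0.2 * log(10)), 0.015)

    expect_error(
        renderCalciumLinescan(c(1, 3), sparkRate = 1,
                              sparkAmplitudeFraction = 1.2),
        "sub-transient")
    expect_error(renderCalciumLinescan(c(1, 1.2)), "spacing")
})

test_that("renderers are bit-reproducible for identical seed + params", {
    s1 <- renderMcgTrace(0:9, noiseSd = 3, duration = 10, seed = 9)
    s2 <- renderMcgTrace(0:9, noiseSd = 3, duration = 10, seed = 9)
    expect_identical(signalMatrix(s1), signalMatrix(s2))
    c1 <- renderCalciumLinescan(c(1, 3), sparkRate = 2, duration = 5,
                                seed = 4)
    c2 <- renderCalciumLinescan(c(1, 3), sparkRate = 2, duration = 5,
                                seed = 4)
    expect_identical(dff(c1$profile), dff(c2$profile))
    expect_identical(sparkTimes(c1$truth), sparkTimes(c2$truth))
})
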