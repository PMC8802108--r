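test_that("noiseless trace: every scheduled beat recovered exactly", {
    fix <- cleanMcg(nBeats = 60, bpm = 60, amplitude = 100, fs = 1000)
    bs <- detectBeats(fix$segment)
    sched <- beatTimes(fix$truth)
    expect_equal(nEvents(bs), length(sched))
    ## R times equal scheduled times to within one sample period.
    expect_lte(max(abs(bs@rTime - sched)), 1 / 1000)
    expect_equal(rrIntervals(bs), rep(1, 59), tolerance = 1e-3)
    ## R-S span is amplitude * (1 + relaxation depth).
    expect_equal(rsAmplitudes(bs), rep(125, 60), tolerance = 1e-6)
})

test_that("degenerate traces yield an empty series with a warning", {
    flat <- RecordingSegment(rep(0, 5000), samplingRate = 1000)
    expect_warning(bs <- detectBeats(flat), "flat")
    expect_equal(nEvents(bs), 0)
    nas <- RecordingSegment(c(rep(0, 2500), NA, rep(0, 2499)),
                            samplingRate = 1000)
    expect_warning(bs2 <- detectBeats(nas), "non-finite")
    expect_equal(nEvents(bs2), 0)
    short <- RecordingSegment(rnorm(100), samplingRate = 1000)
    expect_error(detectBeats(short), "2 s")
})

test_that("noisy drifting trace: recall and precision at least 0.99", {
    gt <- generateBeatSchedule(duration = 60, baseRate = 60,
                               rateJitterCV = 0.05, seed = 21)
    seg <- renderMcgTrace(gt, contractionAmplitude = 100, noiseSd = 2,
                          driftAmplitude = 10, driftPeriod = 20,
                          duration = 60, seed = 22)
    bs <- detectBeats(seg, detectorConfig(detrend = TRUE, smoothMs = 6))
    m <- matchEvents(bs@rTime, beatTimes(gt), tol = 0.15)
    expect_gte(m$recall, 0.99)
    expect_gte(m$precision, 0.99)
})

test_that("time-shift invariance and amplitude-scale equivariance", {
    fix <- cleanMcg(nBeats = 20, bpm = 60)
    bs <- detectBeats(fix$segment)

    shifted <- fix$segment
    shifted@startTime <- 7.5
    bs2 <- detectBeats(shifted)
    expect_equal(bs2@rTime, bs@rTime + 7.5)
    expect_equal(rrIntervals(bs2), rrIntervals(bs))
    expect_equal(rsAmplitudes(bs2), rsAmplitudes(bs))
    expect_equal(beatRate(bs2), beatRate(bs))

    scaled <- RecordingSegment(3 * signalMatrix(fix$segment)[, 1],
                               samplingRate = samplingRate(fix$segment))
    bs3 <- detectBeats(scaled)
    expect_equal(bs3@rTime, bs@rTime)
    expect_equal(rsAmplitudes(bs3), 3 * rsAmplitudes(bs))
    expect_equal(beatRate(bs3), beatRate(bs))
})

test_that("count conservation: n-1 intervals for n events", {
    for (bpm in c(30, 60, 100)) {
        fix <- cleanMcg(nBeats = 15, bpm = bpm)
        bs <- detectBeats(fix$segment)
        expect_equal(length(rrIntervals(bs)), nEvents(bs) - 1L)
        expect_equal(length(rsAmplitudes(bs)), nEvents(bs))
    }
})

test_that("beat rate definitions", {
    bs <- BeatSeries(rTime = seq(0, 9, by = 1), rDefl = 1,
                     sTime = seq(0, 9, by = 1) + 0.1, sDefl = 0)
    expect_equal(beatRate(bs), 60)
    fast <- BeatSeries(rTime = seq(0, 4.5, by = 0.5), rDefl = 1,
                       sTime = seq(0, 4.5, by = 0.5) + 0.1, sDefl = 0)
    expect_equal(beatRate(fast), 120)
    expect_equal(beatRate(bs, method = "count", duration = 10), 60)
    one <- BeatSeries(rTime = 1, rDefl = 1, sTime = 1.1, sDefl = 0)
    expect_error(beatRate(one), "fewer than 2")

    ## Simulated 40 bpm with 5% jitter recovered within 2%.
    gt <- generateBeatSchedule(duration = 90, baseRate = 40,
                               rateJitterCV = 0.05, seed = 31)
    seg <- renderMcgTrace(gt, duration = 90, samplingRate = 500)
    br <- beatRate(detectBeats(seg))
    expect_lt(abs(br - 40) / 40, 0.02)
})

test_that("contraction force is the mean R-S span", {
    one <- BeatSeries(rTime = 1, rDefl = 100, sTime = 1.2, sDefl = -20)
    expect_equal(contractionForce(one), 120)
    same <- BeatSeries(rTime = 1:5, rDefl = 80, sTime = 1:5 + 0.2,
                       sDefl = -20)
    expect_equal(contractionForce(same), 100)
    expect_error(contractionForce(BeatSeries()), "no events")

    ## 100 noisy beats at amplitude 150: mean recovered within 1 nN.
    gt <- generateBeatSchedule(nBeats = 100, baseRate = 60,
                               rateJitterCV = 0.03, seed = 8)
    seg <- renderMcgTrace(gt, contractionAmplitude = 150,
                          relaxationDepthFraction = 0.25, noiseSd = 3,
                          seed = 9)
    f <- contractionForce(detectBeats(seg, detectorConfig(smoothMs = 6)))
    expect_lt(abs(f - 150 * 1.25), 1)
})

test_that("baseline normalization and control re-normalization", {
    r <- normalizeToBaseline(c(beatRate = 45), c(beatRate = 30))
    expect_equal(r$ratio, 1.5)

    fix <- cleanMcg(nBeats = 10)
    bs <- detectBeats(fix$segment)
    same <- normalizeToBaseline(bs, bs)
    expect_equal(same$ratio, c(1, 1))

    ctrl <- normalizeToBaseline(c(beatRate = 1.65), c(beatRate = 1),
                                metrics = "beatRate",
                                controlRatios = c(beatRate = 1.1))
    expect_equal(ctrl$controlNormalized, 1.5)

    expect_error(normalizeToBaseline(c(beatRate = 1), c(beatRate = 0)),
                 "positive")
})
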