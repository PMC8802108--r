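test_that("F0 normalization algebra", {
    const <- normalizeF0(rep(5, 200))
    expect_true(all(dff(const) == 0))
    expect_equal(const@f0, 5)

    ## raw = F0 * (1 + x) recovers x exactly when x has a 10% zero floor.
    x <- c(rep(0, 50), seq(0, 2, length.out = 150))
    p <- normalizeF0(80 * (1 + x))
    expect_equal(dff(p), x, tolerance = 1e-12)

    expect_error(normalizeF0(rep(-1, 100)), "not positive")

    ## Simulated trace: amplitude recovered within 5%.
    sim <- renderCalciumLinescan(c(1, 3, 5), transientAmplitude = 2,
                                 noiseSd = 0.02, duration = 7, seed = 2)
    p2 <- normalizeF0(sim$profile@raw)
    tr <- detectTransients(p2)
    expect_lt(max(abs(tr$amplitude - 2)) / 2, 0.05)

    ## Kymograph input is averaged over the spatial dimension.
    ky <- matrix(rep(80 * (1 + x), each = 8), nrow = 8) +
        matrix(rnorm(8 * length(x), sd = 0.6), nrow = 8)
    pk <- normalizeF0(ky)
    expect_equal(length(dff(pk)), length(x))
})

test_that("transient kinetics: rise and analytic exponential decay", {
    for (tau in c(0.05, 0.2, 1)) {
        sim <- renderCalciumLinescan(2, riseTime = 0.05, decayTau = tau,
                                     noiseSd = 0, sparkRate = 0,
                                     duration = 4 + 10 * tau)
        tr <- detectTransients(sim$profile)
        expect_equal(nrow(tr), 1L)
        ## 10%-to-peak rise time within one line period of the configured
        ## rise.
        expect_lt(abs(tr$timeToPeak - 0.05), 1 / 100)
        ## Pure exponential decay: peak-to-10% time is tau * ln(10).
        expect_lt(abs(tr$decayTime - tau * log(10)), 1 / 100)
    }
    flat <- new("CalciumProfile", raw = rep(1, 300), dff = rep(0, 300),
                lineRate = 100, f0 = 1, label = "")
    expect_equal(nrow(detectTransients(flat)), 0L)
})

test_that("transient detection recovers a periodic train under noise", {
    sim <- renderCalciumLinescan(seq(0.5, 18.5, by = 1.2), decayTau = 0.2,
                                 noiseSd = 0.02, sparkRate = 0,
                                 duration = 20, seed = 14)
    tr <- detectTransients(sim$profile)
    expect_equal(nrow(tr), length(transientTimes(sim$truth)))
})

test_that("spark detection: recall and precision against ground truth", {
    sim <- renderCalciumLinescan(seq(0.5, 28.5, by = 1.2), decayTau = 0.2,
                                 sparkRate = 2, sparkAmplitudeFraction = 0.3,
                                 noiseSd = 0.02, duration = 30, seed = 5)
    sp <- detectSparks(sim$profile)
    m <- matchEvents(sp$sparks$time, sparkTimes(sim$truth), tol = 0.08)
    expect_gte(m$recall, 0.9)
    expect_gte(m$precision, 0.9)
    ## Rate bookkeeping: count / diastolic time, and 1-s bins sum to the
    ## total count.
    expect_equal(sp$rate, nrow(sp$sparks) / sp$diastolicTime)
    expect_equal(sum(sp$perSecond), nrow(sp$sparks))
})

test_that("sparks and transients are disjoint in time", {
    for (seed in c(3, 8)) {
        sim <- renderCalciumLinescan(seq(0.5, 18.5, by = 1.2),
                                     decayTau = 0.2, sparkRate = 2,
                                     noiseSd = 0.02, duration = 20,
                                     seed = seed)
        tr <- detectTransients(sim$profile)
        sp <- detectSparks(sim$profile, tr)
        for (i in seq_len(nrow(tr))) {
            span <- c(tr$onset[i],
                      tr$peakTime[i] + 1.3 * tr$decayTime[i])
            expect_false(any(sp$sparks$time >= span[1] &
                             sp$sparks$time <= span[2]))
        }
    }
})

test_that("sub-threshold sparks are not detected", {
    sim <- renderCalciumLinescan(seq(0.5, 18.5, by = 1.2), decayTau = 0.2,
                                 sparkRate = 2,
                                 sparkAmplitudeFraction = 0.005,
                                 noiseSd = 0, duration = 20, seed = 6)
    sp <- detectSparks(sim$profile)
    expect_equal(nrow(sp$sparks), 0L)
    expect_equal(sp$rate, 0)
})

test_that("spark rate is invariant to a positive scaling of the trace", {
    sim <- renderCalciumLinescan(seq(0.5, 28.5, by = 1.2), decayTau = 0.2,
                                 sparkRate = 1, noiseSd = 0.02,
                                 duration = 30, seed = 3)
    base <- detectSparks(sim$profile)$rate
    for (k in c(0.5, 2, 10)) {
        scaled <- new("CalciumProfile", raw = sim$profile@raw,
                      dff = k * dff(sim$profile), lineRate = 100,
                      f0 = 1, label = "")
        expect_equal(detectSparks(scaled)$rate, base)
    }
})
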