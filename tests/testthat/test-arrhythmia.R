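test_that("extreme interval counting uses a strict cutoff", {
    r <- countExtremeRR(c(0.8, 0.9, 3.5, 0.7), cutoff = 3)
    expect_equal(unname(r), c(1, 4, 250))
    r0 <- countExtremeRR(rep(0.5, 20), cutoff = 3)
    expect_equal(unname(r0), c(0, 20, 0))
    ## Boundary: an interval exactly at the cutoff is not extreme.
    expect_equal(unname(countExtremeRR(c(3, 3.0001), 3)["extreme"]), 1)
    expect_error(countExtremeRR(numeric(0)), "nonempty")
    expect_error(countExtremeRR(c(1, -1)), "positive")
})

test_that("lowering the cutoff never decreases the extreme count", {
    set.seed(5)
    rr <- rexp(500, 1) + 0.3
    cuts <- seq(0.5, 5, by = 0.25)
    counts <- vapply(cuts, function(ct) countExtremeRR(rr, ct)[["extreme"]],
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("simulated pause rate is recovered through the scoring path", {
    gt <- generateBeatSchedule(nBeats = 2000, baseRate = 60,
                               rateJitterCV = 0.05, pauseRate = 20,
                               pauseDurationRange = c(4, 5), seed = 55)
    rr <- diff(beatTimes(gt))
    est <- countExtremeRR(rr, cutoff = 3)
    lambda <- 20 * 2000 / 1000
    se <- 1000 * sqrt(lambda) / length(rr)
    expect_lt(abs(est[["per1000"]] - 20), 3 * se)
    expect_equal(est[["extreme"]], length(pauseIndices(gt)))
})

test_that("contingency construction, pooling and symmetry", {
    tab <- buildContingency(5, 1000, 1, 1000)
    expect_equal(unname(contingencyCounts(tab)),
                 matrix(c(5, 1, 995, 999), nrow = 2))
    expect_equal(unname(ratePer1000(tab)), c(5, 1))

    same <- buildContingency(7, 500, 7, 500)
    expect_equal(same@a, same@c)
    expect_equal(same@b, same@d)

    pooled <- buildContingency(c(2, 3), c(500, 500), 1, 1000)
    expect_equal(pooled@a, 5L)
    expect_equal(pooled@b, 995L)
    expect_equal(nrow(pooled@perRecording), 3L)

    expect_error(buildContingency(0, 0, 1, 10), "positive")
    expect_error(buildContingency(5, 4, 1, 10), "exceed")
})

test_that("Yates statistic: homogeneous and clamped tables give zero", {
    h <- chiSquareYates(buildContingency(10, 20, 10, 20))
    expect_equal(unname(h$statistic), 0)
    expect_equal(h$p.value, 1)

    ## |ad - bc| <= N/2 clamps to exactly zero.
    cl <- chiSquareYates(matrix(c(5, 6, 5, 6), 2, byrow = TRUE))
    expect_equal(unname(cl$statistic), 0)

    expect_error(chiSquareYates(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "marginal")
})

test_that("Yates statistic equals the cell-wise oracle on random tables", {
    set.seed(11)
    for (i in 1:200) {
        a <- rpois(1, 8); b <- rpois(1, 400) + 1
        c <- rpois(1, 3); d <- rpois(1, 400) + 1
        if (a + c == 0) a <- 1
        got <- unname(chiSquareYates(matrix(c(a, b, c, d), 2,
                                            byrow = TRUE))$statistic)
        expect_equal(got, yatesOracle(a, b, c, d), tolerance = 1e-12)
    }
    ## Cross-check against the independent base-R implementation.
    ref <- stats::chisq.test(matrix(c(20, 980, 5, 995), 2, byrow = TRUE),
                             correct = TRUE)
    got <- chiSquareYates(matrix(c(20, 980, 5, 995), 2, byrow = TRUE))
    expect_equal(unname(got$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Yates statistic is arm-swap invariant and below Pearson", {
    set.seed(12)
    for (i in 1:100) {
        a <- rpois(1, 10) + 1; b <- rpois(1, 200) + 1
        c <- rpois(1, 10) + 1; d <- rpois(1, 200) + 1
        s1 <- unname(chiSquareYates(matrix(c(a, b, c, d), 2,
                                           byrow = TRUE))$statistic)
        s2 <- unname(chiSquareYates(matrix(c(c, d, a, b), 2,
                                           byrow = TRUE))$statistic)
        expect_equal(s1, s2, tolerance = 1e-12)
        pearson <- unname(suppressWarnings(
            stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                              correct = FALSE))$statistic)
        expect_lte(s1, pearson + 1e-12)
    }
})

test_that("Poincare pairs, identity diagonal, and flagging", {
    p <- poincarePairs(c(1, 2, 3))
    expect_equal(p$rr1, c(1, 2))
    expect_equal(p$rr2, c(2, 3))

    const <- poincarePairs(rep(0.8, 10))
    expect_true(all(const$rr1 == const$rr2))

    expect_equal(nrow(poincarePairs(1.5)), 0L)

    ## Flagged fraction tracks the injected extreme-interval fraction.
    gt <- generateBeatSchedule(nBeats = 2000, baseRate = 60,
                               rateJitterCV = 0.05, pauseRate = 30,
                               pauseDurationRange = c(4, 5), seed = 9)
    rr <- diff(beatTimes(gt))
    pc <- poincarePairs(rr, cutoff = 3)
    nExtreme <- length(pauseIndices(gt))
    ## Each isolated extreme interval flags two lag-1 pairs.
    expect_lt(abs(sum(pc$flagged) - 2 * nExtreme), 3 * sqrt(2 * nExtreme))
})
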