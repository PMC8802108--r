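test_that("outlier screening: clean, degenerate and gross-outlier cases", {
    set.seed(2)
    tight <- rnorm(20, 1, 0.05)
    expect_false(any(screenOutliers(tight)$flagged))

    expect_false(any(screenOutliers(rep(3, 10))$flagged))

    withGross <- c(rnorm(20, 1, 0.1), 10)
    scr <- screenOutliers(withGross)
    expect_identical(which(scr$flagged), 21L)

    expect_warning(out <- screenOutliers(c(1, 2)), "skipped")
    expect_equal(out$kept, c(1, 2))
})

test_that("outlier screening matches a brute-force BH oracle", {
    set.seed(33)
    for (i in 1:20) {
        x <- c(rnorm(15, 0, 1), rnorm(2, 8, 1))
        scr <- screenOutliers(x, Q = 1)
        ## Oracle: robust residual p-values through p.adjust().
        p <- 2 * pt(-abs(x - median(x)) / mad(x), df = length(x) - 1)
        oracle <- p.adjust(p, "BH") <= 0.01
        expect_identical(scr$flagged, oracle)
    }
})

test_that("Welch ANOVA matches oneway.test and the two-group t-test", {
    set.seed(7)
    g <- list(a = rnorm(10), b = rnorm(12, 0.5, 2), c = rnorm(9, 1, 0.5))
    w <- welchAnova(g)
    ref <- oneway.test(value ~ group,
                       data.frame(value = unlist(g),
                                  group = rep(names(g), lengths(g))))
    expect_equal(unname(w$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(w$parameter["df2"]),
                 unname(ref$parameter["denom df"]), tolerance = 1e-10)
    expect_equal(w$p.value, ref$p.value, tolerance = 1e-12)

    ## Two groups: Welch F is the square of the Welch t statistic.
    g2 <- list(x = rnorm(8), y = rnorm(11, 1, 3))
    w2 <- welchAnova(g2)
    tt <- t.test(g2$x, g2$y)
    expect_equal(unname(w2$statistic), unname(tt$statistic)^2,
                 tolerance = 1e-10)

    expect_error(welchAnova(list(a = rep(1, 5), b = rnorm(5))),
                 "zero variance")
    expect_error(welchAnova(list(a = 1, b = rnorm(5))), "at least 2")
})

test_that("Brown-Forsythe equals classical F for equal group sizes", {
    set.seed(8)
    g <- list(a = rnorm(9, 0, 1), b = rnorm(9, 1, 3), c = rnorm(9, 2, 0.3))
    bf <- brownForsytheAnova(g)
    f <- oneWayAnova(g)
    expect_equal(unname(bf$statistic), unname(f$statistic),
                 tolerance = 1e-12)
    ## Unequal sizes: statistics differ, p stays in range.
    g2 <- list(a = rnorm(5), b = rnorm(15, 1, 2), c = rnorm(8))
    bf2 <- brownForsytheAnova(g2)
    expect_true(bf2$p.value >= 0 && bf2$p.value <= 1)
})

test_that("classical one-way ANOVA matches anova(lm())", {
    set.seed(9)
    df <- data.frame(value = rnorm(30), group = rep(letters[1:3], 10))
    got <- oneWayAnova(df$value, df$group)
    ref <- anova(lm(value ~ group, df))
    expect_equal(unname(got$statistic), ref$`F value`[1], tolerance = 1e-12)
    expect_equal(got$p.value, ref$`Pr(>F)`[1], tolerance = 1e-12)
    expect_error(oneWayAnova(list(a = rep(1, 4), b = rep(2, 4))),
                 "zero within-group")
})

test_that("Games-Howell: identical groups, and the two-group identity", {
    gSame <- list(a = c(1.0, 1.1, 0.9, 1.05, 0.95),
                  b = c(1.0, 1.1, 0.9, 1.05, 0.95))
    gh <- gamesHowell(gSame)
    expect_gt(gh$p[1], 0.999)

    ## k = 2: the studentized-range p equals the two-sided Welch t p.
    set.seed(10)
    g2 <- list(x = rnorm(10), y = rnorm(12, 1, 2))
    gh2 <- gamesHowell(g2)
    tt <- t.test(g2$x, g2$y)
    expect_equal(unname(gh2$q[1]), abs(unname(tt$statistic)) * sqrt(2),
                 tolerance = 1e-10)
    expect_equal(unname(gh2$p[1]), tt$p.value, tolerance = 1e-5)

    set.seed(11)
    g4 <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8, 3))
    gh4 <- gamesHowell(g4)
    expect_equal(nrow(gh4), 6L)
    ## The separated group stands out; null pairs do not.
    dPairs <- gh4$group1 == "d" | gh4$group2 == "d"
    expect_true(all(gh4$p[dPairs] < 0.05))
})

test_that("Kruskal-Wallis H matches the explicit rank oracle", {
    groups <- list(a = c(2.1, 3.5, 3.5, 8), b = c(1, 2.1, 5),
                   c = c(4, 6, 7, 9, 10))
    got <- kruskalWallis(groups)
    expect_equal(unname(got$statistic), kruskalOracle(groups),
                 tolerance = 1e-12)

    ## k = 2 agrees with the normal-approximation Wilcoxon rank-sum:
    ## H equals the squared standardized W statistic.
    g2 <- list(x = c(1.2, 3.1, 4.5, 7, 8.2), y = c(2.2, 5.5, 6.1, 9.9))
    h <- unname(kruskalWallis(g2)$statistic)
    expect_equal(h, kruskalOracle(g2), tolerance = 1e-12)
    w <- wilcox.test(g2$x, g2$y, exact = FALSE, correct = FALSE)
    expect_equal(1 - pchisq(h, 1), w$p.value, tolerance = 1e-10)
})

test_that("location-shift and relabeling invariance", {
    set.seed(12)
    g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
    gShift <- lapply(g, function(v) v + 100)
    for (fn in list(welchAnova, brownForsytheAnova, oneWayAnova,
                    kruskalWallis)) {
        expect_equal(unname(fn(g)$statistic),
                     unname(fn(gShift)$statistic), tolerance = 1e-8)
        expect_equal(unname(fn(g)$statistic),
                     unname(fn(rev(g))$statistic), tolerance = 1e-8)
    }
})

test_that("dose-trend regression: exact line and permutation invariance", {
    conc <- rep(c(1e-5, 1e-4, 1e-3, 1e-2), each = 2)
    y <- 2 * log10(conc) + 1
    fit <- suppressWarnings(doseTrendRegression(conc, y))
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 1, tolerance = 1e-10)
    expect_equal(fit$r.squared, 1, tolerance = 1e-12)

    set.seed(13)
    yn <- y + rnorm(length(y), 0, 0.1)
    f1 <- doseTrendRegression(conc, yn)
    perm <- sample(length(conc))
    f2 <- doseTrendRegression(conc[perm], yn[perm])
    expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
    expect_equal(f1$p.value, f2$p.value, tolerance = 1e-12)

    expect_error(doseTrendRegression(c(1e-5, 1e-4), c(1, 2)), "3 distinct")
    expect_error(doseTrendRegression(c(-1, 1, 2), c(1, 2, 3)), "positive")
})
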