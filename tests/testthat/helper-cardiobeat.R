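## Shared helpers: event matching against ground truth and small fixtures.

## Recall/precision of detected event times against scheduled times.
matchEvents <- function(detected, truth, tol) {
    if (!length(truth)) {
        return(list(recall = NA_real_,
                    precision = if (length(detected)) 0 else NA_real_))
    }
    hits <- vapply(truth, function(t) any(abs(detected - t) <= tol),
                   logical(1))
    tp <- vapply(detected, function(t) any(abs(truth - t) <= tol),
                 logical(1))
    list(recall = mean(hits),
         precision = if (length(detected)) mean(tp) else NA_real_)
}

## A clean noiseless MCG fixture: n beats at given bpm, amplitude A.
cleanMcg <- function(nBeats = 60, bpm = 60, amplitude = 100,
                     depth = 0.25, fs = 1000) {
    gt <- generateBeatSchedule(duration = nBeats * 60 / bpm,
                               baseRate = bpm, rateJitterCV = 0)
    list(truth = gt,
         segment = renderMcgTrace(gt, contractionAmplitude = amplitude,
                                  relaxationDepthFraction = depth,
                                  samplingRate = fs,
                                  duration = nBeats * 60 / bpm))
}

## Independent cell-wise Yates oracle: sum over cells of
## (max(|O - E| - 1/2, 0))^2 / E with expected counts from the marginals.
yatesOracle <- function(a, b, c, d) {
    obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    n <- sum(obs)
    expd <- outer(rowSums(obs), colSums(obs)) / n
    sum(pmax(abs(obs - expd) - 0.5, 0)^2 / expd)
}

## Independent Kruskal-Wallis oracle by explicit rank computation with
## tie correction.
kruskalOracle <- function(groups) {
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    r <- rank(x)
    n <- length(x)
    h <- 12 / (n * (n + 1)) *
        sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
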