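## Internal helpers shared across modules.

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## The caller's .Random.seed is restored afterwards, so simulations
## are reproducible without clobbering the session RNG.
withSeed <- function(seed, code) {
    if (is.null(seed)) {
        return(force(code))
    }
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
        stop("'seed' must be a single finite number or NULL")
    }
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

## Derive a stream of child seeds from a master seed, each < 2^31.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Nearest odd integer >= 1 (for runmed / moving-average windows).
oddWindow <- function(k) {
    k <- max(1L, as.integer(round(k)))
    if (k %% 2L == 0L) k + 1L else k
}

## Centered moving average with reflection padding, so peaks at the very
## first or last sample are not flattened into monotone edges.
movingAverage <- function(x, k) {
    k <- oddWindow(k)
    n <- length(x)
    if (k <= 1L || n < 3L) {
        return(x)
    }
    h <- (k - 1L) %/% 2L
    h <- min(h, n - 1L)
    k <- 2L * h + 1L
    xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
    csum <- cumsum(c(0, xp))
    (csum[(k + 1L):(k + n)] - csum[seq_len(n)]) / k
}

## Indices of strict local maxima; plateaus resolve to the earliest sample.
localMaxima <- function(x) {
    n <- length(x)
    if (n < 3L) {
        return(integer(0))
    }
    i <- 2L:(n - 1L)
    which(x[i] > x[i - 1L] & x[i] >= x[i + 1L]) + 1L
}

## Topographic prominence of selected peaks: height above the higher of the
## two saddle minima separating the peak from the nearest higher terrain
## (or the signal edge when no higher point exists on that side).  Samples
## within `guard` of the peak belong to the same summit (noise can put a
## marginally higher sample right next to a peak) and are not treated as
## higher terrain.
peakProminence <- function(x, peaks, guard = 0L) {
    n <- length(x)
    vapply(peaks, function(i) {
        h <- x[i]
        endL <- i - 1L - guard
        baseL <- if (endL < 1L) {
            -Inf
        } else {
            left <- x[seq_len(endL)]
            higherL <- which(left > h)
            if (length(higherL)) {
                j <- max(higherL)
                ## Higher terrain flush against the guard band: no saddle,
                ## the candidate is a noise shoulder, not a peak.
                if (j >= endL) Inf else min(left[(j + 1L):endL])
            } else {
                min(left)
            }
        }
        startR <- i + 1L + guard
        baseR <- if (startR > n) {
            -Inf
        } else {
            right <- x[startR:n]
            higherR <- which(right > h)
            if (length(higherR)) {
                j <- min(higherR)
                if (j <= 1L) Inf else min(right[seq_len(j - 1L)])
            } else {
                min(right)
            }
        }
        h - max(baseL, baseR)
    }, numeric(1))
}

## Greedy refractory enforcement: keep the tallest peak of every cluster of
## peaks closer than `minGap` samples; ties resolve to the earlier peak.
enforceRefractory <- function(peaks, heights, minGap) {
    if (length(peaks) <= 1L) {
        return(peaks)
    }
    ord <- order(-heights, peaks)
    kept <- integer(0)
    for (p in peaks[ord]) {
        if (!length(kept) || all(abs(kept - p) >= minGap)) {
            kept <- c(kept, p)
        }
    }
    sort(kept)
}

## Linear interpolation of the time at which x crosses `level` between
## samples i and i+1 (assumes the level lies between the two samples).
crossingTime <- function(tvec, x, i, level) {
    x0 <- x[i]
    x1 <- x[i + 1L]
    if (x1 == x0) {
        return(tvec[i])
    }
    tvec[i] + (level - x0) / (x1 - x0) * (tvec[i + 1L] - tvec[i])
}
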