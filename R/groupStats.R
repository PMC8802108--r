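## Group-comparison layer: robust outlier screening, heteroscedasticity-
## robust ANOVA (Welch, Brown-Forsythe) with Games-Howell post hoc
## comparisons, classical one-way ANOVA, Kruskal-Wallis, and dose-trend
## regression on normalized metrics.  Parametric and rank-based results
## are always available side by side; nothing is gated on normality tests.

## Coerce list / data.frame / (values, group) input into a named list of
## numeric vectors.
asGroupList <- function(x, group = NULL) {
    if (is.data.frame(x) && all(c("value", "group") %in% names(x))) {
        return(split(x$value, x$group))
    }
    if (is.list(x)) {
        if (is.null(names(x))) {
            names(x) <- paste0("group", seq_along(x))
        }
        return(lapply(x, as.numeric))
    }
    if (is.numeric(x) && !is.null(group)) {
        return(split(as.numeric(x), group))
    }
    stop("supply a named list of numeric vectors, a data.frame with ",
         "'value' and 'group' columns, or (values, group)")
}

groupMoments <- function(groups, minN = 2L) {
    n <- vapply(groups, length, integer(1))
    if (length(groups) < 2L) {
        stop("at least 2 groups are required")
    }
    if (any(n < minN)) {
        stop("every group needs at least ", minN, " observations")
    }
    list(k = length(groups), n = n,
         mean = vapply(groups, mean, numeric(1)),
         var = vapply(groups, stats::var, numeric(1)))
}

testResult <- function(method, statistic, statName, df, p,
                       comparisons = NULL) {
    out <- structure(list(
        statistic = stats::setNames(statistic, statName),
        parameter = df, p.value = p, method = method,
        data.name = "grouped values"
    ), class = "htest")
    if (!is.null(comparisons)) {
        attr(out, "comparisons") <- comparisons
    }
    out
}

#' Robust outlier screening (ROUT-style)
#'
#' Robust location/scale residual screen with false-discovery-rate control:
#' residuals from the median are scaled by the MAD-based robust SD,
#' converted to two-sided t-tail probabilities, and screened by
#' Benjamini-Hochberg at rate \code{Q}.  This is the single-sample
#' degeneration of robust-regression-plus-FDR outlier removal, appropriate
#' for the scalar per-recording metrics this pipeline produces.  Flagged
#' points are excluded from downstream tests but always reported.
#'
#' @param values numeric vector (n >= 3; smaller inputs are returned
#'   unscreened with a warning).
#' @param Q target false discovery rate, percent (default 1).
#' @return A list: \code{kept}, \code{outliers}, \code{flagged} (logical
#'   mask over the input).
#' @examples
#' screenOutliers(c(rnorm(20, 1, 0.1), 10))
#' @export
screenOutliers <- function(values, Q = 1) {
    values <- as.numeric(values)
    n <- length(values)
    if (n < 3L) {
        warning("fewer than 3 values: outlier screening skipped")
        return(list(kept = values, outliers = numeric(0),
                    flagged = rep(FALSE, n)))
    }
    center <- stats::median(values)
    resid <- values - center
    s <- stats::mad(values)
    flagged <- if (s == 0) {
        resid != 0
    } else {
        p <- 2 * stats::pt(-abs(resid) / s, df = n - 1L)
        ord <- order(p)
        keepRank <- p[ord] <= (Q / 100) * seq_len(n) / n
        cut <- if (any(keepRank)) max(which(keepRank)) else 0L
        mask <- rep(FALSE, n)
        if (cut > 0L) {
            mask[ord[seq_len(cut)]] <- TRUE
        }
        mask
    }
    list(kept = values[!flagged], outliers = values[flagged],
         flagged = flagged)
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Welch's F with Satterthwaite denominator degrees of freedom; group
#' variances are not assumed equal.
#'
#' @param x groups: named list of numeric vectors, a data.frame with
#'   \code{value}/\code{group} columns, or a numeric vector with
#'   \code{group}.
#' @param group optional grouping factor when \code{x} is a numeric
#'   vector.
#' @return An \code{"htest"} with the F statistic, (df1, df2) and p-value.
#' @examples
#' welchAnova(list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10)))
#' @export
welchAnova <- function(x, group = NULL) {
    g <- asGroupList(x, group)
    m <- groupMoments(g)
    if (any(m$var == 0)) {
        stop("degenerate input: zero variance in at least one group")
    }
    w <- m$n / m$var
    W <- sum(w)
    mw <- sum(w * m$mean) / W
    k <- m$k
    A <- sum(w * (m$mean - mw)^2) / (k - 1)
    lambda <- sum((1 - w / W)^2 / (m$n - 1))
    Fstat <- A / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
    df2 <- (k^2 - 1) / (3 * lambda)
    p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
    testResult("Welch one-way ANOVA (unequal variances)", Fstat, "F",
               c(df1 = k - 1, df2 = df2), p)
}

#' Brown-Forsythe heteroscedasticity-robust one-way ANOVA
#'
#' The Brown-Forsythe F* test for equality of means: the classical
#' between-group sum of squares over the variance-weighted denominator
#' \eqn{\sum_j (1 - n_j/N) s_j^2}, with Satterthwaite denominator degrees
#' of freedom.  With equal group sizes the statistic coincides exactly
#' with the classical F.
#'
#' @inheritParams welchAnova
#' @return An \code{"htest"}.
#' @export
brownForsytheAnova <- function(x, group = NULL) {
    g <- asGroupList(x, group)
    m <- groupMoments(g)
    if (all(m$var == 0)) {
        stop("degenerate input: zero variance in every group")
    }
    N <- sum(m$n)
    grand <- sum(m$n * m$mean) / N
    num <- sum(m$n * (m$mean - grand)^2)
    denomTerms <- (1 - m$n / N) * m$var
    Fstat <- num / sum(denomTerms)
    cj <- denomTerms / sum(denomTerms)
    df2 <- 1 / sum(cj^2 / (m$n - 1))
    p <- stats::pf(Fstat, m$k - 1, df2, lower.tail = FALSE)
    testResult("Brown-Forsythe one-way ANOVA (unequal variances)", Fstat,
               "F", c(df1 = m$k - 1, df2 = df2), p)
}

#' Games-Howell multiple comparisons
#'
#' All pairwise comparisons after a heteroscedasticity-robust ANOVA:
#' Welch-type t statistics with Satterthwaite degrees of freedom, referred
#' to the studentized-range distribution via \eqn{q = |t|\sqrt{2}}, which
#' controls the family-wise error across all pairs without assuming equal
#' variances.
#'
#' @inheritParams welchAnova
#' @return A \code{DataFrame} with one row per pair: \code{group1},
#'   \code{group2}, \code{meanDiff}, \code{se}, \code{t}, \code{df},
#'   \code{q}, \code{p} (studentized-range adjusted).
#' @export
gamesHowell <- function(x, group = NULL) {
    g <- asGroupList(x, group)
    m <- groupMoments(g)
    k <- m$k
    pairs <- utils::combn(k, 2)
    res <- apply(pairs, 2, function(ij) {
        i <- ij[1]; j <- ij[2]
        vi <- unname(m$var[i] / m$n[i])
        vj <- unname(m$var[j] / m$n[j])
        md <- unname(m$mean[i] - m$mean[j])
        se <- sqrt(vi + vj)
        if (se == 0) {
            return(c(diff = md, se = 0, t = NA_real_,
                     df = NA_real_, q = NA_real_, p = NA_real_))
        }
        tstat <- md / se
        df <- (vi + vj)^2 / (vi^2 / (m$n[i] - 1) + vj^2 / (m$n[j] - 1))
        q <- abs(tstat) * sqrt(2)
        p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
        c(diff = md, se = se, t = tstat, df = unname(df), q = q, p = p)
    })
    nm <- names(g)
    S4Vectors::DataFrame(
        group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
        meanDiff = res["diff", ], se = res["se", ], t = res["t", ],
        df = res["df", ], q = res["q", ], p = res["p", ])
}

#' Classical one-way ANOVA (pooled variance)
#'
#' @inheritParams welchAnova
#' @return An \code{"htest"}.
#' @export
oneWayAnova <- function(x, group = NULL) {
    g <- asGroupList(x, group)
    m <- groupMoments(g)
    N <- sum(m$n)
    grand <- sum(m$n * m$mean) / N
    ssb <- sum(m$n * (m$mean - grand)^2)
    ssw <- sum((m$n - 1) * m$var)
    if (ssw == 0) {
        stop("degenerate input: zero within-group variance")
    }
    df1 <- m$k - 1
    df2 <- N - m$k
    Fstat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    testResult("Ordinary one-way ANOVA", Fstat, "F",
               c(df1 = df1, df2 = df2), p)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic (delegates to \code{stats::kruskal.test}).
#'
#' @inheritParams welchAnova
#' @return An \code{"htest"}.
#' @export
kruskalWallis <- function(x, group = NULL) {
    g <- asGroupList(x, group)
    kt <- stats::kruskal.test(g)
    testResult("Kruskal-Wallis rank sum test",
               unname(kt$statistic), "H",
               c(df = unname(kt$parameter)), kt$p.value)
}

#' Dose-trend regression of relative responses on log concentration
#'
#' Ordinary least squares of the relative response on
#' \eqn{\log_{10}}(concentration) - the natural covariate for ladders
#' spanning several decades - with a t-test on the slope.  A linear
#' concentration scale is available via \code{logScale = FALSE}.
#'
#' @param concentrations molar concentrations (> 0); at least 3 distinct
#'   values.
#' @param responses relative responses, same length.
#' @param logScale regress on log10(concentration) (default) or on the
#'   linear scale.
#' @return A list: \code{slope}, \code{intercept}, \code{r.squared},
#'   \code{p.value} (slope t-test), \code{fit} (the \code{lm} object).
#' @examples
#' doseTrendRegression(c(1e-5, 1e-4, 1e-3), c(1, 1.2, 1.4))
#' @export
doseTrendRegression <- function(concentrations, responses, logScale = TRUE) {
    if (length(concentrations) != length(responses)) {
        stop("'concentrations' and 'responses' must have equal length")
    }
    if (any(concentrations <= 0)) {
        stop("concentrations must be strictly positive")
    }
    if (length(unique(concentrations)) < 3L) {
        stop("at least 3 distinct concentrations are required")
    }
    xv <- if (logScale) log10(concentrations) else concentrations
    fit <- stats::lm(responses ~ xv)
    sm <- summary(fit)
    coefs <- stats::coef(sm)
    list(slope = coefs["xv", "Estimate"],
         intercept = coefs["(Intercept)", "Estimate"],
         r.squared = sm$r.squared,
         p.value = coefs["xv", "Pr(>|t|)"],
         fit = fit)
}
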