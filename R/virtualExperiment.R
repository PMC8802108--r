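## End-to-end "virtual experiment" runner: simulation -> beat detection ->
## baseline normalization -> arrhythmia scoring -> group statistics ->
## calcium kinetics, fully reproducible from a manifest of config + seed.

#' Configuration of a virtual drug-response experiment
#'
#' Captures the design of one concentration-ladder experiment on a
#' spontaneously beating cardiomyocyte model.  Model presets set the
#' cutoff for arrhythmic events (3 s for slow hPSC-CM-type clusters, 1 s
#' for the fast murine HL-1-type line), the base beat rate and the
#' concentration ladder; every value can be overridden.  Durations default
#' to a desk-scale 60 s of measurement per recording (the wet-lab protocol
#' records 5-10 min; the analysis is duration-agnostic).
#'
#' @param model \code{"hPSC-CM"} or \code{"HL-1"}.
#' @param concentrations molar ladder; defaults: 10 uM, 100 uM, 1 mM,
#'   10 mM (hPSC-CM) or 8-512 uM in doublings (HL-1).
#' @param recordingsPerArm recordings per arm (control and each
#'   concentration).
#' @param cutoff arrhythmia cutoff, seconds (model default when NULL).
#' @param baseRate mean spontaneous rate, bpm (model default when NULL).
#' @param rateJitterCV beat-to-beat interval CV.
#' @param chronotropySlope relative-BR increase per decade of
#'   concentration.
#' @param inotropyProfile relative-force multiplier per concentration
#'   (recycled; non-monotone allowed).
#' @param treatmentPauseRate,controlPauseRate injected extreme pauses per
#'   1000 beats in treated vs control recordings
#'   (concentration-independent by design).
#' @param pauseDurationRange injected pause duration range, seconds; must
#'   exceed the cutoff (model default when NULL).
#' @param measurementDuration,stabilizationDuration seconds; the
#'   stabilization phase is simulated but excluded from all metrics.
#' @param samplingRate MCG sampling rate, Hz.
#' @param contractionAmplitude nominal contraction amplitude, nN.
#' @param noiseSd,driftAmplitude,driftPeriod trace noise and drift.
#' @param prepRateCV,prepAmpCV between-preparation (EB-to-EB) lognormal CV
#'   of base rate and amplitude.
#' @param responseRateCV,responseForceCV lognormal CV of the per-recording
#'   drug response (biological variability of the relative response).
#' @param calcium logical: also simulate and analyse calcium line scans
#'   for the control arm and the top concentration.
#' @param calciumDecayTau named-length-2 numeric \code{c(control, treatment)}
#'   decay time constants, seconds.
#' @param calciumSparkRate length-2 numeric \code{c(control, treatment)}
#'   sparks per second.
#' @param seed master integer seed.
#' @return A list of class \code{"experimentConfig"}.
#' @export
experimentConfig <- function(model = c("hPSC-CM", "HL-1"),
                             concentrations = NULL, recordingsPerArm = 8,
                             cutoff = NULL, baseRate = NULL,
                             rateJitterCV = 0.05, chronotropySlope = 0.1,
                             inotropyProfile = c(1.25, 1.3, 1.25, 1.2),
                             treatmentPauseRate = 20, controlPauseRate = 2,
                             pauseDurationRange = NULL,
                             measurementDuration = 60,
                             stabilizationDuration = 0,
                             samplingRate = 500,
                             contractionAmplitude = 100, noiseSd = 2,
                             driftAmplitude = 5, driftPeriod = 30,
                             prepRateCV = 0.1, prepAmpCV = 0.15,
                             responseRateCV = 0.05, responseForceCV = 0.2,
                             calcium = TRUE,
                             calciumDecayTau = c(0.25, 0.18),
                             calciumSparkRate = c(0.1, 1.0),
                             seed = 1) {
    model <- match.arg(model)
    if (is.null(concentrations)) {
        concentrations <- if (model == "hPSC-CM") {
            c(1e-5, 1e-4, 1e-3, 1e-2)
        } else {
            c(8, 16, 32, 64, 128, 256, 512) * 1e-6
        }
    }
    if (is.null(cutoff)) {
        cutoff <- if (model == "hPSC-CM") 3 else 1
    }
    if (is.null(baseRate)) {
        baseRate <- if (model == "hPSC-CM") 40 else 120
    }
    if (is.null(pauseDurationRange)) {
        pauseDurationRange <- cutoff * c(4 / 3, 2)
    }
    if (any(pauseDurationRange <= cutoff)) {
        stop("'pauseDurationRange' must exceed the cutoff so injected ",
             "pauses register as arrhythmic events")
    }
    structure(list(
        model = model, concentrations = concentrations,
        recordingsPerArm = as.integer(recordingsPerArm), cutoff = cutoff,
        baseRate = baseRate, rateJitterCV = rateJitterCV,
        chronotropySlope = chronotropySlope,
        inotropyProfile = rep_len(inotropyProfile, length(concentrations)),
        treatmentPauseRate = treatmentPauseRate,
        controlPauseRate = controlPauseRate,
        pauseDurationRange = pauseDurationRange,
        measurementDuration = measurementDuration,
        stabilizationDuration = stabilizationDuration,
        samplingRate = samplingRate,
        contractionAmplitude = contractionAmplitude,
        noiseSd = noiseSd, driftAmplitude = driftAmplitude,
        driftPeriod = driftPeriod, prepRateCV = prepRateCV,
        prepAmpCV = prepAmpCV, responseRateCV = responseRateCV,
        responseForceCV = responseForceCV, calcium = calcium,
        calciumDecayTau = calciumDecayTau,
        calciumSparkRate = calciumSparkRate,
        seed = as.integer(seed)
    ), class = "experimentConfig")
}

## Simulate + analyse one recording (baseline then treatment) and return
## its summary row.
simulateRecordingPair <- function(cfg, armLabel, rateMult, forceMult,
                                  pauseRate, recSeed) {
    seeds <- deriveSeeds(recSeed, 8L)
    prep <- withSeed(seeds[1], c(
        rate = exp(stats::rnorm(1, 0, cfg$prepRateCV)),
        amp = exp(stats::rnorm(1, 0, cfg$prepAmpCV))))
    ebRate <- cfg$baseRate * prep["rate"]
    ebAmp <- cfg$contractionAmplitude * prep["amp"]
    totalDur <- cfg$stabilizationDuration + cfg$measurementDuration

    detCfg <- detectorConfig("mcg", detrend = cfg$driftAmplitude > 0,
                             smoothMs = if (cfg$noiseSd > 0) 6 else 0)
    analyse <- function(schedSeed, noiseSeed, rate, amp, pr) {
        gt <- generateBeatSchedule(
            duration = totalDur, baseRate = rate,
            rateJitterCV = cfg$rateJitterCV, pauseRate = pr,
            pauseDurationRange = cfg$pauseDurationRange, seed = schedSeed)
        seg <- renderMcgTrace(
            beatTimes(gt), contractionAmplitude = amp,
            eventWidth = min(0.4, 0.8 * 60 / rate / 2),
            noiseSd = cfg$noiseSd, driftAmplitude = cfg$driftAmplitude,
            driftPeriod = cfg$driftPeriod,
            samplingRate = cfg$samplingRate, duration = totalDur,
            seed = noiseSeed)
        series <- suppressWarnings(detectBeats(seg, detCfg))
        ## Stabilization-phase events are recorded but excluded.
        keep <- series@rTime >= cfg$stabilizationDuration
        BeatSeries(series@rTime[keep], series@rDefl[keep],
                   series@sTime[keep], series@sDefl[keep],
                   units = series@units, label = armLabel)
    }

    base <- analyse(seeds[2], seeds[3], ebRate, ebAmp,
                    cfg$controlPauseRate)
    treat <- analyse(seeds[4], seeds[5], ebRate * rateMult,
                     ebAmp * forceMult, pauseRate)
    if (nEvents(base) < 2L || nEvents(treat) < 2L) {
        return(NULL)
    }
    rel <- normalizeToBaseline(treat, base)
    rr <- rrIntervals(treat)
    ext <- countExtremeRR(rr, cfg$cutoff)
    data.frame(
        arm = armLabel, seed = recSeed,
        baselineBR = beatRate(base), treatmentBR = beatRate(treat),
        relBeatRate = rel$ratio[rel$metric == "beatRate"],
        baselineForce = contractionForce(base),
        treatmentForce = contractionForce(treat),
        relForce = rel$ratio[rel$metric == "contractionForce"],
        extreme = unname(ext["extreme"]),
        totalIntervals = unname(ext["total"]))
}

#' Run a full virtual drug-response experiment
#'
#' Deterministically (per config + seed) simulates a control arm and one
#' arm per concentration, each recording consisting of a baseline segment
#' and a treated segment from the same simulated preparation; detects
#' beats; normalizes beat rate and contraction force to baseline; screens
#' outliers; runs the heteroscedasticity-robust group comparisons and the
#' dose-trend regressions; scores extreme R-R intervals against the
#' model-specific cutoff and tests each treatment arm against control with
#' the Yates-corrected chi-square; and (optionally) simulates and analyses
#' calcium line scans for the control arm and the top concentration.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @return A list of class \code{"virtualExperiment"}: \code{recordings}
#'   (per-recording summary), \code{groupSummary}, \code{anova} (Welch +
#'   Brown-Forsythe + Games-Howell on relative BR), \code{arrhythmia}
#'   (per-arm and pooled \linkS4class{ArrhythmiaTable}s with test
#'   results), \code{doseRegression} (BR and force), \code{calcium}
#'   (per-cell kinetics and Kruskal-Wallis on spark rates, or NULL), and
#'   \code{manifest}.
#' @examples
#' cfg <- experimentConfig(recordingsPerArm = 3, measurementDuration = 30,
#'     calcium = FALSE, seed = 7)
#' \donttest{res <- runVirtualExperiment(cfg)}
#' @export
runVirtualExperiment <- function(config) {
    stopifnot(inherits(config, "experimentConfig"))
    cfg <- config
    conc <- cfg$concentrations
    refLog <- log10(min(conc))
    arms <- c("control", sprintf("%g uM", conc * 1e6))
    nArm <- length(arms)
    nRec <- cfg$recordingsPerArm
    armSeeds <- matrix(deriveSeeds(cfg$seed, nArm * nRec), nrow = nArm)

    rows <- list()
    for (ai in seq_len(nArm)) {
        isCtrl <- ai == 1L
        for (ri in seq_len(nRec)) {
            rSeed <- armSeeds[ai, ri]
            resp <- withSeed(rSeed + 1, c(
                br = exp(stats::rnorm(1, 0, cfg$responseRateCV)),
                f = exp(stats::rnorm(1, 0, cfg$responseForceCV))))
            rateMult <- if (isCtrl) {
                resp["br"]
            } else {
                (1 + cfg$chronotropySlope *
                     (log10(conc[ai - 1L]) - refLog)) * resp["br"]
            }
            forceMult <- if (isCtrl) {
                resp["f"]
            } else {
                cfg$inotropyProfile[ai - 1L] * resp["f"]
            }
            pr <- if (isCtrl) cfg$controlPauseRate else cfg$treatmentPauseRate
            row <- simulateRecordingPair(cfg, arms[ai], rateMult, forceMult,
                                         pr, rSeed)
            if (!is.null(row)) {
                row$recording <- ri
                rows[[length(rows) + 1L]] <- row
            }
        }
    }
    recordings <- do.call(rbind, rows)
    if (is.null(recordings) || !all(arms %in% recordings$arm)) {
        stop("an entire arm produced no usable recordings")
    }

    ## Outlier screening per arm, then group summaries.
    screenMetric <- function(metric) {
        keepIdx <- logical(nrow(recordings))
        for (a in arms) {
            idx <- which(recordings$arm == a)
            scr <- suppressWarnings(screenOutliers(recordings[[metric]][idx]))
            keepIdx[idx] <- !scr$flagged
        }
        keepIdx
    }
    keepBR <- screenMetric("relBeatRate")
    keepF <- screenMetric("relForce")

    armStats <- function(metric, keep) {
        do.call(rbind, lapply(arms, function(a) {
            v <- recordings[[metric]][recordings$arm == a & keep]
            data.frame(arm = a, n = length(v), mean = mean(v),
                       sd = stats::sd(v))
        }))
    }
    gBR <- armStats("relBeatRate", keepBR)
    gF <- armStats("relForce", keepF)
    ctrlBR <- gBR$mean[gBR$arm == "control"]
    ctrlF <- gF$mean[gF$arm == "control"]
    groupSummary <- data.frame(
        arm = arms,
        nBR = gBR$n, relBeatRate = gBR$mean, relBeatRateSD = gBR$sd,
        relBeatRateCtrlNorm = gBR$mean / ctrlBR,
        nForce = gF$n, relForce = gF$mean, relForceSD = gF$sd,
        relForceCtrlNorm = gF$mean / ctrlF)

    groupsBR <- lapply(arms, function(a) {
        recordings$relBeatRate[recordings$arm == a & keepBR]
    })
    names(groupsBR) <- arms
    anovaRes <- list(
        welch = welchAnova(groupsBR),
        brownForsythe = brownForsytheAnova(groupsBR),
        gamesHowell = gamesHowell(groupsBR))

    ## Arrhythmia: pooled contingency per treatment arm vs control, plus
    ## all treatments pooled.  Short runs can legitimately contain zero
    ## extreme intervals in both arms; that is "no evidence", not an
    ## error, so the test degenerates to statistic 0 / p 1.
    safeYates <- function(tab) {
        tryCatch(chiSquareYates(tab), error = function(e) {
            structure(list(
                statistic = c(`X-squared` = 0), parameter = c(df = 1),
                p.value = 1,
                method = "Chi-square test with Yates' continuity correction (degenerate: empty margin)",
                data.name = "2x2 table"), class = "htest")
        })
    }
    ctrlRows <- recordings$arm == "control"
    perArm <- lapply(arms[-1], function(a) {
        i <- recordings$arm == a
        tab <- buildContingency(
            recordings$extreme[i], recordings$totalIntervals[i],
            recordings$extreme[ctrlRows],
            recordings$totalIntervals[ctrlRows], cutoff = cfg$cutoff)
        list(table = tab, test = safeYates(tab))
    })
    names(perArm) <- arms[-1]
    pooledTab <- buildContingency(
        recordings$extreme[!ctrlRows], recordings$totalIntervals[!ctrlRows],
        recordings$extreme[ctrlRows], recordings$totalIntervals[ctrlRows],
        cutoff = cfg$cutoff)
    arrhythmia <- list(perArm = perArm, pooled = list(
        table = pooledTab, test = safeYates(pooledTab)))

    treatRows <- recordings[!ctrlRows, ]
    treatConc <- conc[match(treatRows$arm, arms[-1])]
    doseRegression <- list(
        beatRate = doseTrendRegression(treatConc, treatRows$relBeatRate),
        force = doseTrendRegression(treatConc, treatRows$relForce))

    calcium <- NULL
    if (isTRUE(cfg$calcium)) {
        calcium <- runCalciumArm(cfg, arms[nArm])
    }

    structure(list(
        recordings = recordings, groupSummary = groupSummary,
        anova = anovaRes, arrhythmia = arrhythmia,
        doseRegression = doseRegression, calcium = calcium,
        manifest = list(
            config = cfg,
            packageVersion = as.character(utils::packageVersion("cardiobeat")))
    ), class = "virtualExperiment")
}

## Calcium sub-experiment: control vs top-concentration cells.
runCalciumArm <- function(cfg, topArm) {
    nCell <- cfg$recordingsPerArm
    seeds <- deriveSeeds(cfg$seed + 1L, 2L * nCell)
    duration <- 20
    interval <- 1.2
    rows <- list()
    for (grp in 1:2) {
        armLabel <- if (grp == 1) "control" else topArm
        tau <- cfg$calciumDecayTau[grp]
        sRate <- cfg$calciumSparkRate[grp]
        for (ci in seq_len(nCell)) {
            sd <- seeds[(grp - 1L) * nCell + ci]
            tTimes <- seq(0.5, duration - 1.5, by = interval)
            sim <- renderCalciumLinescan(
                tTimes, decayTau = tau, sparkRate = sRate,
                duration = duration, seed = sd)
            tr <- detectTransients(sim$profile)
            sp <- detectSparks(sim$profile, tr)
            rows[[length(rows) + 1L]] <- data.frame(
                arm = armLabel, cell = ci, sparkRate = sp$rate,
                nTransients = nrow(tr),
                meanTimeToPeak = mean(tr$timeToPeak),
                meanDecayTime = mean(tr$decayTime, na.rm = TRUE))
        }
    }
    cells <- do.call(rbind, rows)
    list(cells = cells,
         kwSparks = kruskalWallis(split(cells$sparkRate, cells$arm)))
}

#' Write a virtual-experiment result bundle as delimited text
#'
#' One directory per run: per-recording table, group summary,
#' per-arm arrhythmia results, pairwise comparisons, calcium table and a
#' JSON manifest capturing config + seed + package version (a run can be
#' reproduced exactly from the manifest alone).
#'
#' @param result a \code{"virtualExperiment"} object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeExperiment <- function(result, dir) {
    stopifnot(inherits(result, "virtualExperiment"))
    if (!dir.exists(dir)) {
        dir.create(dir, recursive = TRUE)
    }
    wcsv <- function(df, name) {
        utils::write.table(
            format(df, digits = 12, trim = TRUE, scientific = FALSE),
            file.path(dir, name), sep = ",", row.names = FALSE,
            quote = FALSE)
    }
    wcsv(result$recordings, "recordings.csv")
    wcsv(result$groupSummary, "group_summary.csv")
    arr <- do.call(rbind, lapply(names(result$arrhythmia$perArm), function(a) {
        x <- result$arrhythmia$perArm[[a]]
        r <- ratePer1000(x$table)
        data.frame(arm = a, a = x$table@a, b = x$table@b, c = x$table@c,
                   d = x$table@d, ratePer1000 = r[["treatment"]],
                   controlRatePer1000 = r[["control"]],
                   statistic = unname(x$test$statistic),
                   p = x$test$p.value)
    }))
    wcsv(arr, "arrhythmia.csv")
    wcsv(as.data.frame(result$anova$gamesHowell), "comparisons.csv")
    if (!is.null(result$calcium)) {
        wcsv(result$calcium$cells, "calcium.csv")
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        mf <- result$manifest
        mf$config <- unclass(mf$config)
        jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}
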