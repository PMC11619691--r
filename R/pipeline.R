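## Orchestration: run the full synthetic study end to end and write a
## machine-readable report.

#' Crop a trace to a time window
#'
#' @param trace A [FluorescenceTrace].
#' @param t0,t1 Window bounds, seconds (inclusive).
#' @return A [FluorescenceTrace] restricted to `[t0, t1]`.
#' @export
cropTrace <- function(trace, t0 = -Inf, t1 = Inf) {
  stopifnot(is(trace, "FluorescenceTrace"))
  sel <- trace@times >= t0 & trace@times <= t1
  FluorescenceTrace(trace@times[sel], trace@values[sel],
                    roiId = trace@roiId,
                    stimulusTime = trace@stimulusTime,
                    ionomycinTime = trace@ionomycinTime)
}

#' Default configuration of the synthetic study
#'
#' All stage parameters of [runPipeline()], with defaults matching the
#' study conditions the generators emulate (see [GroundTruth]).  The
#' configuration is a plain named list and round-trips unchanged through
#' YAML ([writeRunConfig()] / [readRunConfig()]).
#'
#' @param seed Integer global seed; every stage derives its own stream
#'   from it.
#' @return A named list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    gcamp = list(nRois = 30L, frameInterval = 1.3, duration = 360,
                 stimulusTime = 10, ionomycinTime = 190, noiseSd = 1,
                 oscillationRate = 1, bleach = TRUE),
    truth = list(effectRatioCcl = 1.58, transientFold = 9,
                 ic50WT = 1e-8, ic50Mutant = 8e-8, hillH = 1,
                 atpFold = 4, bleachTau = 2000,
                 contactFractionWT = 0.79, contactFractionMutant = 0.19,
                 dapiSlopeTrue = 2),
    dose = list(concentrations = c(0, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6,
                                   5e-6),
                nBoot = 100L),
    dapi = list(nRois = 40L, duration = 300, frameInterval = 2,
                noiseSd = 2, deadCellOffset = 50),
    atp = list(nWells = 5L, baseline = 100, stimulusTime = 600,
               duration = 1800, sampleInterval = 30, noiseSd = 2,
               gapMask = c(22L, 23L)),
    qpcr = list(ddCt = -5.64, noiseSd = 0.1, nReplicates = 3L),
    fep = list(nWindows = 32L, complexTotal = 2.00, freeTotal = 0.68,
               workSd = 0.25, nSamples = 750L, temperature = 310,
               nBoot = 100L),
    contacts = list(nFrames = 100L, cutoff = 3.0)
  )
}

#' Read / write a run configuration as YAML
#'
#' `readRunConfig()` merges the YAML file over [defaultRunConfig()], so a
#' config file only needs the values it changes.
#'
#' @param path YAML file path.
#' @param config A configuration list (for writing).
#' @return The configuration list (read) or the path (write, invisibly).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- defaultRunConfig(seed = if (!is.null(user$seed)) user$seed else 1L)
  mergeList <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  mergeList(base, user)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Zero-noise configuration for ground-truth recovery checks
#'
#' The same study as [defaultRunConfig()] with every stochastic
#' component switched off (no measurement noise, no spontaneous
#' oscillations, no photobleaching, zero work spread): under these
#' conditions every downstream estimator must return the generator's
#' ground truth to numerical precision.
#'
#' @param seed Integer seed (retained for determinism of e.g. the
#'   contact-frame schedule).
#' @return A configuration list.
#' @export
zeroNoiseRunConfig <- function(seed = 1L) {
  cfg <- defaultRunConfig(seed)
  cfg$gcamp$noiseSd <- 0
  cfg$gcamp$oscillationRate <- 0
  cfg$gcamp$bleach <- FALSE
  cfg$dapi$noiseSd <- 0
  cfg$atp$noiseSd <- 0
  cfg$qpcr$noiseSd <- 0
  cfg$fep$workSd <- 0
  cfg$dose$nBoot <- 20L
  cfg$fep$nBoot <- 5L
  cfg
}

## Mean CCL of an ensemble after the full trace-preprocessing chain:
## optional bleach correction, dF/dFmax normalisation, per-ROI CCL,
## then the mean of per-ROI areas.
ensembleCcl <- function(ensemble, correctBleach = TRUE, t0 = 0,
                        t1 = 100) {
  traces <- ensemble@traces
  if (correctBleach) {
    traces <- lapply(traces, function(tr) fitBleach(tr)$corrected)
  }
  ens <- TraceEnsemble(traces, ensemble@meta, ensemble@groundTruth)
  norm <- normalizeEnsemble(ens)
  areas <- vapply(norm$normalized,
                  function(nt) computeCcl(nt, t0, t1)$area, numeric(1))
  list(areas = areas, meta = norm$meta, exclusions = norm$exclusions)
}

## Peak statistics (mean amplitude / FWHM) over an ensemble, measured on
## bleach-corrected traces cropped to the pre-ionomycin segment.
## `fitWindow` widens the bleach fit beyond the pre-stimulus default --
## legitimate for recordings without an evoked transient, where the whole
## pre-ionomycin segment is baseline plus sparse oscillations.
ensemblePeakStats <- function(ensemble, thresholdK = 3,
                              fitWindow = NULL, robust = FALSE,
                              baselineMode = c("median", "prestim"),
                              singlePeak = FALSE) {
  baselineMode <- match.arg(baselineMode)
  amp <- fw <- numeric()
  for (tr in ensemble@traces) {
    corr <- fitBleach(tr, fitWindow = fitWindow,
                      robust = robust)$corrected
    seg <- cropTrace(corr, t1 = if (is.na(tr@ionomycinTime)) Inf else
      tr@ionomycinTime - 1e-9)
    base <- if (baselineMode == "prestim") {
      mean(traceValues(seg)[traceTimes(seg) < tr@stimulusTime])
    } else NULL
    pk <- detectPeaks(seg, thresholdK = thresholdK, baseline = base)
    a <- peakAmplitudes(pk); f <- peakFwhms(pk)
    if (singlePeak && length(a)) {
      ## one stimulus per recording -> keep the dominant (evoked) peak
      i <- which.max(a); a <- a[i]; f <- f[i]
    }
    amp <- c(amp, a)
    fw <- c(fw, f)
  }
  list(meanAmplitude = mean(amp), meanFwhm = mean(fw, na.rm = TRUE),
       nPeaks = length(amp))
}

#' Run the full synthetic study end to end
#'
#' Generates every input with [GroundTruth]-anchored defaults, runs the
#' complete analysis chain (trace preprocessing, CCL and its
#' mutant/wild-type ratio, antibody dose-response fits, DAPI uptake
#' rates, ATP release, qPCR fold change, transient-vs-oscillation peak
#' statistics, BAR free-energy legs through the thermodynamic cycle to
#' the affinity fold change, trajectory contact fractions, and the
#' group-comparison statistics), and returns a single report.
#'
#' @param config A configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param outDir Optional directory; when given, per-stage CSVs and the
#'   JSON report are written there.
#' @param verbose Print stage progress to standard error.
#' @return The report, a nested named list (invisibly when `outDir` is
#'   given).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  g <- config$gcamp
  tr <- config$truth
  truth <- GroundTruth(
    effectRatioCcl = tr$effectRatioCcl, transientFold = tr$transientFold,
    ic50PerCondition = c(WT = tr$ic50WT, D178Y = tr$ic50Mutant),
    hillH = tr$hillH, atpFold = tr$atpFold, bleachTau = tr$bleachTau,
    perWindowDg = rep(config$fep$complexTotal / config$fep$nWindows,
                      config$fep$nWindows),
    contactFractionTrue = tr$contactFractionWT,
    dapiSlopeTrue = tr$dapiSlopeTrue, seed = seed)
  cfg <- SynthConfig(nRois = g$nRois, frameInterval = g$frameInterval,
                     duration = g$duration, stimulusTime = g$stimulusTime,
                     ionomycinTime = g$ionomycinTime, noiseSd = g$noiseSd,
                     oscillationRate = g$oscillationRate)

  ## --- Ca2+ uptake: control CCLs and the mutant/WT ratio ---------------
  say("simulating GCaMP ensembles and computing CCL")
  ensWT <- genGcampEnsemble(cfg, truth, condition = "WT",
                            bleach = g$bleach, seed = seed)
  ensMut <- genGcampEnsemble(cfg, truth, condition = "D178Y",
                             bleach = g$bleach, seed = seed)
  cclWT <- ensembleCcl(ensWT)
  cclMut <- ensembleCcl(ensMut)
  cclComparison <- compareGroups(
    c(cclWT$areas, cclMut$areas),
    c(rep("WT", length(cclWT$areas)), rep("D178Y", length(cclMut$areas))))

  ## --- antibody dose-response per condition ---------------------------
  say("fitting antibody dose-response")
  doseFits <- list()
  doseTables <- list()
  for (cond in c("WT", "D178Y")) {
    concAll <- cclAll <- numeric()
    for (conc in config$dose$concentrations) {
      e <- genGcampEnsemble(cfg, truth, condition = cond,
                            concentration = conc, bleach = g$bleach,
                            seed = seed)
      a <- ensembleCcl(e)$areas
      concAll <- c(concAll, rep(conc, length(a)))
      cclAll <- c(cclAll, a)
    }
    fit <- fitDoseResponse(concAll, cclAll, nBoot = config$dose$nBoot,
                           seed = subSeed(seed, paste0("dose-", cond)))
    doseFits[[cond]] <- fit
    doseTables[[cond]] <- data.frame(condition = cond,
                                     conc_molar = concAll, ccl = cclAll)
  }

  ## --- transient vs oscillation peak statistics -----------------------
  say("measuring evoked transients vs spontaneous oscillations")
  oscCfg <- cfg
  oscCfg@oscillationRate <- if (g$oscillationRate > 0)
    g$oscillationRate else 1
  ensOsc <- genGcampEnsemble(oscCfg, truth, condition = "WT",
                             transientAmplitude = 0, bleach = g$bleach,
                             seed = seed + 1L)
  evokedCfg <- cfg; evokedCfg@oscillationRate <- 0
  ensEvoked <- genGcampEnsemble(evokedCfg, truth, condition = "WT",
                                bleach = g$bleach, seed = seed + 2L)
  oscStats <- ensemblePeakStats(ensOsc,
                                fitWindow = c(0, g$ionomycinTime),
                                robust = TRUE)
  evokedStats <- ensemblePeakStats(ensEvoked, baselineMode = "prestim",
                                   singlePeak = TRUE)
  transients <- list(
    amplitudeFold = evokedStats$meanAmplitude / oscStats$meanAmplitude,
    fwhmFold = evokedStats$meanFwhm / oscStats$meanFwhm,
    nSpontaneous = oscStats$nPeaks, nEvoked = evokedStats$nPeaks)

  ## --- DAPI uptake -----------------------------------------------------
  say("computing DAPI uptake rates")
  d <- config$dapi
  ensDapi <- genDapiTraces(d$nRois, slope = tr$dapiSlopeTrue,
                           deadCellOffset = d$deadCellOffset,
                           duration = d$duration,
                           frameInterval = d$frameInterval,
                           noiseSd = d$noiseSd,
                           seed = subSeed(seed, "stage-dapi"))
  dapiRates <- vapply(ensDapi@traces, dapiRate, numeric(1))

  ## --- ATP release ------------------------------------------------------
  say("quantifying ATP release")
  a <- config$atp
  ensAtp <- genAtpTraces(a$nWells, baseline = a$baseline,
                         foldPeak = tr$atpFold,
                         stimulusTime = a$stimulusTime,
                         duration = a$duration,
                         sampleInterval = a$sampleInterval,
                         noiseSd = a$noiseSd, gapMask = a$gapMask,
                         seed = subSeed(seed, "stage-atp"))
  atpRes <- lapply(ensAtp@traces, atpRelease)
  atpPeakTimes <- vapply(ensAtp@traces, function(w)
    w@times[which.max(w@values)], numeric(1))

  ## --- qPCR -------------------------------------------------------------
  q <- config$qpcr
  set.seed(subSeed(seed, "stage-qpcr"))
  qm <- QpcrMeasurement(
    ctTargetTreated = stats::rnorm(q$nReplicates, 19, q$noiseSd),
    ctRefTreated = stats::rnorm(q$nReplicates, 22, q$noiseSd),
    ctTargetControl = stats::rnorm(q$nReplicates, 19 - q$ddCt, q$noiseSd),
    ctRefControl = stats::rnorm(q$nReplicates, 22, q$noiseSd))
  qpcrFold <- ddctFold(qm)

  ## --- free-energy arm --------------------------------------------------
  say("estimating free-energy legs (BAR)")
  f <- config$fep
  wComplex <- genFepSamples(rep(f$complexTotal / f$nWindows, f$nWindows),
                            workSd = f$workSd, nSamples = f$nSamples,
                            temperature = f$temperature,
                            seed = subSeed(seed, "fep-complex"))
  wFree <- genFepSamples(rep(f$freeTotal / f$nWindows, f$nWindows),
                         workSd = f$workSd, nSamples = f$nSamples,
                         temperature = f$temperature,
                         seed = subSeed(seed, "fep-free"))
  legComplex <- estimateLeg(wComplex, "complex", nBoot = f$nBoot,
                            seed = subSeed(seed, "leg-complex"))
  legFree <- estimateLeg(wFree, "free", nBoot = f$nBoot,
                         seed = subSeed(seed, "leg-free"))
  cyc <- thermoCycle(legComplex, legFree)
  ## the directly engaged protomer carries the computed ddG; the other
  ## five sites are modelled as non-contributing
  prot <- aggregateProtomers(c(cyc$ddg, 0, 0, 0, 0, 0),
                             se = c(cyc$se, 0, 0, 0, 0, 0),
                             temperature = f$temperature)

  ## --- trajectory contacts ----------------------------------------------
  say("computing trajectory contact fractions")
  ct <- config$contacts
  contactOf <- function(frac, stream) {
    nOn <- round(frac * ct$nFrames)
    sched <- rep(FALSE, ct$nFrames)
    set.seed(subSeed(seed, stream))
    sched[sample(ct$nFrames, nOn)] <- TRUE
    traj <- genToyTrajectory(sched, seed = subSeed(seed, stream))
    contactFraction(traj,
                    selectAtoms(traj, chain = "A"),
                    selectAtoms(traj, chain = "B"),
                    cutoff = ct$cutoff)
  }
  contactWT <- contactOf(tr$contactFractionWT, "contact-WT")
  contactMut <- contactOf(tr$contactFractionMutant, "contact-mut")

  report <- list(
    seed = seed,
    groundTruth = config$truth,
    ccl = list(
      meanWT = mean(cclWT$areas), meanMutant = mean(cclMut$areas),
      semWT = stats::sd(cclWT$areas) / sqrt(length(cclWT$areas)),
      semMutant = stats::sd(cclMut$areas) / sqrt(length(cclMut$areas)),
      ratioMutantWT = mean(cclMut$areas) / mean(cclWT$areas),
      nWT = length(cclWT$areas), nMutant = length(cclMut$areas),
      comparison = list(branch = cclComparison@branch,
                        test = cclComparison@omnibusTest,
                        p = cclComparison@omnibusP,
                        stars = starLabel(cclComparison@omnibusP)),
      exclusions = rbind(cclWT$exclusions, cclMut$exclusions)),
    dose = lapply(doseFits, function(fit) list(
      ic50Molar = fit@ic50, hill = fit@hill, floor = fit@floor,
      flagged = fit@flagged, ic50CI = fit@diagnostics$ic50CI,
      response = fit@response, concentrations = fit@concentrations)),
    transients = transients,
    dapi = list(meanRate = mean(dapiRates), semRate =
                  stats::sd(dapiRates) / sqrt(length(dapiRates)),
                n = length(dapiRates)),
    atp = list(
      meanAuc = mean(vapply(atpRes, function(x) x$auc, numeric(1))),
      meanPeakFold = mean(vapply(atpRes, function(x) x$peakFold,
                                 numeric(1))),
      meanPeakTime = mean(atpPeakTimes), nWells = length(atpRes)),
    qpcr = list(fold = qpcrFold, ddCtTrue = q$ddCt),
    energetics = list(
      dgComplex = legDg(legComplex), seComplex = legSe(legComplex),
      dgFree = legDg(legFree), seFree = legSe(legFree),
      ddg = cyc$ddg, ddgSe = cyc$se,
      totalDdg = totalDdg(prot), foldChange = affinityFold(prot),
      foldPowerOfTen = prot@foldPowerOfTen,
      contactFractionWT = contactFrac(contactWT),
      contactFractionMutant = contactFrac(contactMut)))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTraceCsv(ensWT, file.path(outDir, "gcamp_wt.csv"))
    writeTraceCsv(ensMut, file.path(outDir, "gcamp_mutant.csv"))
    utils::write.csv(do.call(rbind, doseTables),
                     file.path(outDir, "dose_response_ccl.csv"),
                     row.names = FALSE)
    writeTraceCsv(ensDapi, file.path(outDir, "dapi.csv"))
    writeTraceCsv(ensAtp, file.path(outDir, "atp.csv"))
    writeWorkCsv(wComplex, file.path(outDir, "fep_complex.csv"))
    writeWorkCsv(wFree, file.path(outDir, "fep_free.csv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(report))
  }
  report
}
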