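## Synthetic-data generators.  Every input the pipeline consumes can be
## generated here with a known ground truth, so all downstream estimators
## are testable without external recordings.

#' Stimulus-evoked transient waveform
#'
#' The evoked Ca2+ transient is modelled as a smooth unimodal
#' rise-and-decay `s(t) = (1 - exp(-t/rise)) * exp(-t/decay)` (t >= 0),
#' scaled so its peak equals `amplitude`.  The shape has an analytic
#' integral, which anchors the closed-form ground truth of the CCL
#' statistic.
#'
#' @param t Time since the stimulus, seconds (values < 0 give 0).
#' @param amplitude Peak amplitude, a.u.
#' @param rise,decay Time constants, seconds (defaults 10 and 40).
#' @return Numeric waveform values.
#' @export
transientShape <- function(t, amplitude = 1, rise = 10, decay = 40) {
  s <- ifelse(t >= 0, (1 - exp(-t / rise)) * exp(-t / decay), 0)
  tPeak <- rise * log(1 + decay / rise)
  gmax <- (1 - exp(-tPeak / rise)) * exp(-tPeak / decay)
  amplitude * s / gmax
}

#' Analytic area of the transient waveform
#'
#' Closed-form integral of [transientShape()] over `[0, upper]` seconds
#' since the stimulus.
#'
#' @param amplitude Peak amplitude, a.u.
#' @param rise,decay Time constants, seconds.
#' @param upper Upper integration limit, seconds (Inf allowed).
#' @return Numeric area (a.u. * s).
#' @export
transientArea <- function(amplitude = 1, rise = 10, decay = 40,
                          upper = 100) {
  tPeak <- rise * log(1 + decay / rise)
  gmax <- (1 - exp(-tPeak / rise)) * exp(-tPeak / decay)
  tc <- rise * decay / (rise + decay)
  up <- function(tau) if (is.infinite(upper)) tau else
    tau * (1 - exp(-upper / tau))
  amplitude * (up(decay) - up(tc)) / gmax
}

## FWHM of the transient waveform, found numerically (monotone rise and
## decay around the single peak).
transientFwhm <- function(rise = 10, decay = 40) {
  tPeak <- rise * log(1 + decay / rise)
  f <- function(t) transientShape(t, 1, rise, decay) - 0.5
  left <- stats::uniroot(f, c(0, tPeak), tol = 1e-10)$root
  hi <- tPeak
  while (f(hi) > 0) hi <- hi * 2
  right <- stats::uniroot(f, c(tPeak, hi), tol = 1e-10)$root
  right - left
}

#' Generate a synthetic GCaMP6s trace ensemble
#'
#' Each trace is the sum of (i) a baseline that photobleaches as
#' `F0 * exp(-t/bleachTau)`, (ii) Poisson-timed spontaneous Ca2+
#' oscillations with log-normal amplitudes (mean anchored so that evoked
#' transients are `transientFold` times larger in both amplitude and
#' FWHM), (iii) a stimulus-evoked transient whose amplitude carries the
#' condition effect (mutant CCL ratio) and the antibody inhibition
#' factor `1 / (1 + (c/IC50)^h)`, (iv) an ionomycin plateau giving the
#' per-ROI maximum used for dF/dFmax normalisation, and (v) additive
#' i.i.d. Gaussian noise.
#'
#' @param config A [SynthConfig].
#' @param truth A [GroundTruth]; condition effects, IC50s, transient
#'   fold, and bleach time constant are read from it.
#' @param condition `"WT"` or `"D178Y"` (must name an entry of
#'   `truth@ic50PerCondition`).
#' @param concentration Antibody concentration, molar (0 = no antibody).
#' @param baselineF0 Baseline fluorescence, a.u. (default 100).
#' @param ionomycinMax Ionomycin plateau above baseline, a.u.
#'   (default 400).
#' @param spontAmplitudeMean Mean spontaneous-oscillation amplitude,
#'   a.u. (default 20).  Spontaneous activity is independent of the
#'   stimulus; the evoked amplitude is anchored to it.
#' @param transientAmplitude Uninhibited WT evoked amplitude, a.u.
#'   (default `transientFold * spontAmplitudeMean`); set 0 for an
#'   oscillation-only recording.
#' @param bleach Apply photobleaching to the baseline (default TRUE).
#' @param rise,decay Transient time constants, seconds.
#' @param seed Integer; defaults to the truth's global seed.  The actual
#'   stream is sub-seeded per (condition, concentration).
#' @return A [TraceEnsemble] with the ground truth attached
#'   (`groundTruth(ens)`), including the analytic expected CCL.
#' @export
genGcampEnsemble <- function(config, truth, condition = "WT",
                             concentration = 0, baselineF0 = 100,
                             ionomycinMax = 400, spontAmplitudeMean = 20,
                             transientAmplitude =
                               truth@transientFold * spontAmplitudeMean,
                             bleach = TRUE, rise = 10, decay = 40,
                             seed = truth@seed) {
  stopifnot(is(config, "SynthConfig"), is(truth, "GroundTruth"))
  if (!condition %in% names(truth@ic50PerCondition))
    stop(sprintf("condition '%s' has no IC50 entry in the ground truth",
                 condition))
  set.seed(subSeed(seed, paste("gcamp", condition,
                               format(concentration, digits = 12))))
  t <- seq(0, config@duration, by = config@frameInterval)

  condFactor <- if (condition == "WT") 1 else truth@effectRatioCcl
  ic50 <- truth@ic50PerCondition[[condition]]
  inhib <- 1 / (1 + (concentration / ic50)^truth@hillH)
  amp <- transientAmplitude * condFactor * inhib

  ## spontaneous oscillations: amplitudes log-normal with arithmetic mean
  ## = evoked amplitude / transientFold; FWHM = evoked FWHM / fold
  fwhmEvoked <- transientFwhm(rise, decay)
  sigmaSpont <- (fwhmEvoked / truth@transientFold) / (2 * sqrt(2 * log(2)))
  sdlog <- 0.5
  meanlog <- log(spontAmplitudeMean) - sdlog^2 / 2

  baseTrend <- if (bleach) baselineF0 * exp(-t / truth@bleachTau) else
    rep(baselineF0, length(t))
  ionoRise <- 2  # s; effectively a step to the plateau
  traces <- vector("list", config@nRois)
  for (i in seq_len(config@nRois)) {
    v <- baseTrend +
      transientShape(t - config@stimulusTime, amp, rise, decay)
    nOsc <- stats::rpois(1, config@oscillationRate / 60 * config@duration)
    if (nOsc > 0) {
      tOsc <- stats::runif(nOsc, 0, config@duration)
      aOsc <- stats::rlnorm(nOsc, meanlog, sdlog)
      for (k in seq_len(nOsc)) {
        v <- v + aOsc[k] * exp(-(t - tOsc[k])^2 / (2 * sigmaSpont^2))
      }
    }
    ## ionomycin saturates the indicator: fluorescence rises to the
    ## per-ROI ceiling (baseline + plateau), overriding ongoing activity
    iono <- t >= config@ionomycinTime
    v[iono] <- baseTrend[iono] + ionomycinMax *
      (1 - exp(-(t[iono] - config@ionomycinTime) / ionoRise))
    if (config@noiseSd > 0) {
      v <- v + stats::rnorm(length(t), 0, config@noiseSd)
    }
    traces[[i]] <- FluorescenceTrace(
      t, v, roiId = sprintf("%s_c%g_roi%03d", condition, concentration, i),
      stimulusTime = config@stimulusTime,
      ionomycinTime = config@ionomycinTime)
  }
  meta <- data.frame(
    roi_id = vapply(traces, function(x) x@roiId, character(1)),
    condition = condition, conc_molar = concentration,
    stringsAsFactors = FALSE)
  gt <- list(truth = truth, condition = condition,
             concentration = concentration,
             evokedAmplitude = amp,
             expectedCcl = transientArea(amp, rise, decay, 100) /
               ionomycinMax,
             inhibitionFactor = inhib, rise = rise, decay = decay,
             ionomycinMax = ionomycinMax,
             evokedFwhm = fwhmEvoked,
             spontAmplitudeMean = spontAmplitudeMean,
             spontFwhm = fwhmEvoked / truth@transientFold)
  TraceEnsemble(traces, meta, groundTruth = gt)
}

#' Generate synthetic DAPI uptake traces
#'
#' Linear dye uptake on top of a constant per-ROI dead-cell offset:
#' `F(t) = offset + slope * t + noise`.
#'
#' @param n Number of ROIs.
#' @param slope True uptake rate, a.u./s (>= 0).
#' @param deadCellOffset Mean per-ROI offset, a.u.
#' @param duration Recording length, seconds.
#' @param frameInterval Seconds between frames (default 2).
#' @param noiseSd Additive Gaussian noise s.d., a.u.
#' @param seed Integer seed.
#' @return A [TraceEnsemble] (ground truth holds the slope).
#' @export
genDapiTraces <- function(n, slope, deadCellOffset = 50, duration = 300,
                          frameInterval = 2, noiseSd = 0, seed = 1L) {
  if (slope < 0) stop("slope must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  set.seed(subSeed(seed, "dapi"))
  t <- seq(0, duration, by = frameInterval)
  traces <- lapply(seq_len(n), function(i) {
    off <- deadCellOffset * stats::runif(1, 0.8, 1.2)
    v <- off + slope * t
    if (noiseSd > 0) v <- v + stats::rnorm(length(t), 0, noiseSd)
    FluorescenceTrace(t, v, roiId = sprintf("dapi_roi%03d", i))
  })
  meta <- data.frame(
    roi_id = vapply(traces, function(x) x@roiId, character(1)),
    condition = "dapi", conc_molar = NA_real_, stringsAsFactors = FALSE)
  TraceEnsemble(traces, meta,
                groundTruth = list(dapiSlopeTrue = slope,
                                   deadCellOffset = deadCellOffset))
}

#' Generate synthetic ATP-release luminescence series
#'
#' Plate-reader luminescence sampled every 30 s: a flat pre-stimulus
#' baseline, then a piecewise-linear rise to `foldPeak * baseline`
#' peaking 300 s after the stimulus, followed by a linear decay back to
#' baseline over `decayDuration`.  Samples listed in `gapMask` are
#' removed, emulating instrument gaps around reagent addition.
#'
#' @param nWells Number of wells.
#' @param baseline Baseline luminescence, a.u. (> 0).
#' @param foldPeak Peak/baseline ratio (>= 1).
#' @param stimulusTime Seconds (default 600).
#' @param duration Total recording, seconds (default 1800).
#' @param sampleInterval Seconds between samples (default 30).
#' @param peakDelay Seconds from stimulus to peak (default 300).
#' @param decayDuration Seconds from peak back to baseline (default 900).
#' @param noiseSd Additive Gaussian noise s.d., a.u.
#' @param gapMask Integer sample indices to drop.
#' @param seed Integer seed.
#' @return A [TraceEnsemble] of luminescence wells.
#' @export
genAtpTraces <- function(nWells, baseline = 100, foldPeak = 4,
                         stimulusTime = 600, duration = 1800,
                         sampleInterval = 30, peakDelay = 300,
                         decayDuration = 900, noiseSd = 0,
                         gapMask = integer(), seed = 1L) {
  if (foldPeak < 1) stop("foldPeak must be >= 1")
  if (baseline <= 0) stop("baseline must be positive")
  t <- seq(0, duration, by = sampleInterval)
  if (!any(t < stimulusTime)) stop("empty pre-stimulus window")
  set.seed(subSeed(seed, "atp"))
  rel <- t - stimulusTime
  shape <- ifelse(rel < 0, 0,
            ifelse(rel <= peakDelay, rel / peakDelay,
              pmax(0, 1 - (rel - peakDelay) / decayDuration)))
  keepIdx <- setdiff(seq_along(t), as.integer(gapMask))
  traces <- lapply(seq_len(nWells), function(i) {
    v <- baseline + (foldPeak - 1) * baseline * shape
    if (noiseSd > 0) v <- v + stats::rnorm(length(t), 0, noiseSd)
    FluorescenceTrace(t[keepIdx], v[keepIdx],
                      roiId = sprintf("well%02d", i),
                      stimulusTime = stimulusTime)
  })
  meta <- data.frame(
    roi_id = vapply(traces, function(x) x@roiId, character(1)),
    condition = "atp", conc_molar = NA_real_, stringsAsFactors = FALSE)
  TraceEnsemble(traces, meta,
                groundTruth = list(baseline = baseline,
                                   foldPeak = foldPeak,
                                   peakTime = stimulusTime + peakDelay))
}

#' Generate Crooks-consistent per-window work samples
#'
#' For each lambda window with true free energy `dg_i`, forward work is
#' drawn from `Normal(dg_i + sigma^2/(2RT), sigma^2)` and reverse work
#' from `Normal(-dg_i + sigma^2/(2RT), sigma^2)` (kcal/mol), the unique
#' Gaussian pair satisfying the Crooks fluctuation relation at the given
#' temperature.
#'
#' @param perWindowDg Numeric vector of true per-window free energies,
#'   kcal/mol.
#' @param workSd Work s.d. sigma, kcal/mol (>= 0).
#' @param nSamples Samples per direction per window (>= 2).
#' @param temperature Kelvin (default 310).
#' @param seed Integer seed.
#' @return A [WindowWorkSamples] with `trueDg` recorded.
#' @export
genFepSamples <- function(perWindowDg, workSd = 0.5, nSamples = 500L,
                          temperature = 310, seed = 1L) {
  if (workSd < 0) stop("workSd must be >= 0")
  if (nSamples < 2L) stop("need at least 2 samples per direction")
  set.seed(subSeed(seed, "fep"))
  rt <- RGAS * temperature
  bias <- workSd^2 / (2 * rt)
  fwd <- lapply(perWindowDg, function(dg)
    stats::rnorm(nSamples, dg + bias, workSd))
  rev <- lapply(perWindowDg, function(dg)
    stats::rnorm(nSamples, -dg + bias, workSd))
  WindowWorkSamples(fwd, rev, temperature = temperature,
                    trueDg = perWindowDg)
}

#' Generate a toy two-residue trajectory with a prescribed contact schedule
#'
#' Two residues of a few heavy atoms each (plus one hydrogen, placed
#' nearer than any heavy atom so that heavy-atom-only selections are
#' exercised).  On frames where `contactSchedule` is TRUE the minimum
#' heavy-atom inter-residue distance is `contactDist` (< 3 A); on other
#' frames it is `apartDist` (>= 4 A).
#'
#' @param contactSchedule Logical vector, one entry per frame.
#' @param contactDist Distance on contact frames, Angstrom (default 2.5).
#' @param apartDist Distance on non-contact frames, Angstrom
#'   (default 4.5).
#' @param jitterSd Gaussian positional jitter orthogonal to the contact
#'   axis, Angstrom (default 0: exact geometry).
#' @param seed Integer seed (used only when `jitterSd > 0`).
#' @return A [TrajectoryFrames] with chains "A" and "B".
#' @export
genToyTrajectory <- function(contactSchedule, contactDist = 2.5,
                             apartDist = 4.5, jitterSd = 0, seed = 1L) {
  nFrames <- length(contactSchedule)
  if (nFrames < 1L) stop("contactSchedule must have at least one frame")
  if (contactDist <= 0 || apartDist <= 0)
    stop("degenerate geometry: distances must be positive")
  if (contactDist >= 3 || apartDist < 4)
    stop("contactDist must be < 3 A and apartDist >= 4 A")
  set.seed(subSeed(seed, "trajectory"))
  ## residue A: heavy atoms at (0, 0) and (-1.5, 0.5); residue B: heavy
  ## atoms at (d, 0) and (d + 1.5, 0.5); one hydrogen on B at
  ## (d - 0.8, 0.3), nearer than any heavy atom so heavy-atom-only
  ## selections are exercised.  The closest heavy pair is always the two
  ## CA atoms at distance d; the y offsets keep the roster non-collinear
  ## for superposition.
  atoms <- data.frame(
    chain = c("A", "A", "B", "B", "B"),
    resno = c(1L, 1L, 2L, 2L, 2L),
    resname = c("ASP", "ASP", "SER", "SER", "SER"),
    atomName = c("CA", "CB", "CA", "CB", "HB"),
    isHydrogen = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  coords <- array(0, dim = c(nFrames, nrow(atoms), 3))
  for (f in seq_len(nFrames)) {
    d <- if (contactSchedule[f]) contactDist else apartDist
    x <- c(0, -1.5, d, d + 1.5, d - 0.8)
    y <- c(0, 0.5, 0, 0.5, 0.3)
    if (jitterSd > 0) y <- y + stats::rnorm(5, 0, jitterSd)
    coords[f, , ] <- cbind(x, y, 0)
  }
  TrajectoryFrames(coords, atoms)
}
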