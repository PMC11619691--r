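#' @import methods
NULL

## ---------------------------------------------------------------------------
## Fluorescence / luminescence time series
## ---------------------------------------------------------------------------

#' FluorescenceTrace: one ROI's raw time series
#'
#' A single region-of-interest (ROI) fluorescence or luminescence time
#' series with its experimental landmarks: the time of the depolarising /
#' Ca2+ stimulus and, for calcium-imaging recordings, the time at which
#' ionomycin was applied to saturate the indicator.
#'
#' @slot times Numeric, seconds, strictly increasing.
#' @slot values Numeric, fluorescence or luminescence in arbitrary units.
#' @slot roiId Character scalar identifying the ROI (or well).
#' @slot stimulusTime Numeric scalar, seconds (NA when no stimulus).
#' @slot ionomycinTime Numeric scalar, seconds (NA when not applicable).
#'
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
  representation(times = "numeric", values = "numeric", roiId = "character",
                 stimulusTime = "numeric", ionomycinTime = "numeric"),
  prototype(stimulusTime = NA_real_, ionomycinTime = NA_real_))

setValidity("FluorescenceTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 4L)
    msg <- c(msg, "a trace needs at least 4 samples")
  if (anyNA(object@times) || any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@roiId) != 1L)
    msg <- c(msg, "roiId must be a single string")
  st <- object@stimulusTime; it <- object@ionomycinTime
  if (!is.na(st) && !is.na(it) && it <= st)
    msg <- c(msg, "ionomycinTime must be after stimulusTime")
  if (length(msg)) msg else TRUE
})

#' @rdname FluorescenceTrace-class
#' @param times,values,roiId,stimulusTime,ionomycinTime See slots.
#' @return A `FluorescenceTrace` object.
#' @examples
#' tr <- FluorescenceTrace(0:9, rnorm(10, 100), roiId = "roi1",
#'                         stimulusTime = 3)
#' @export
FluorescenceTrace <- function(times, values, roiId = "roi",
                              stimulusTime = NA_real_,
                              ionomycinTime = NA_real_) {
  new("FluorescenceTrace", times = as.numeric(times),
      values = as.numeric(values), roiId = as.character(roiId),
      stimulusTime = as.numeric(stimulusTime),
      ionomycinTime = as.numeric(ionomycinTime))
}

#' NormalizedTrace: a dF/dFmax trace
#'
#' Baseline-subtracted fluorescence normalised to the maximum response
#' evoked by ionomycin (dF/dFmax), the scale on which cytosolic Ca2+
#' load is integrated.
#'
#' @slot times Numeric, seconds.
#' @slot dff Numeric, dimensionless dF/dFmax.
#' @slot dfMax Numeric scalar, the ionomycin-evoked maximum dF (a.u.), > 0.
#' @slot f0 Numeric scalar, the pre-stimulus baseline estimate (a.u.).
#' @slot roiId Character scalar.
#' @slot stimulusTime Numeric scalar, seconds.
#'
#' @exportClass NormalizedTrace
setClass("NormalizedTrace",
  representation(times = "numeric", dff = "numeric", dfMax = "numeric",
                 f0 = "numeric", roiId = "character",
                 stimulusTime = "numeric"))

setValidity("NormalizedTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@dff))
    msg <- c(msg, "times and dff must have equal length")
  if (length(object@dfMax) != 1L || !is.finite(object@dfMax) ||
      object@dfMax <= 0)
    msg <- c(msg, "dfMax must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' PeakSet: detected peaks of a trace
#'
#' Peak times, amplitudes (above local baseline), full widths at half
#' maximum (FWHM) and inter-peak intervals, as used to characterise
#' spontaneous Ca2+ oscillations versus stimulus-evoked transients.
#'
#' @slot peakTimes Numeric, seconds.
#' @slot amplitudes Numeric, same units as the input trace.
#' @slot fwhms Numeric, seconds (NA when a half-maximum crossing falls
#'   outside the recording).
#'
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peakTimes = "numeric", amplitudes = "numeric",
                 fwhms = "numeric"))

setValidity("PeakSet", function(object) {
  n <- length(object@peakTimes)
  msg <- character()
  if (length(object@amplitudes) != n || length(object@fwhms) != n)
    msg <- c(msg, "peakTimes, amplitudes and fwhms must have equal length")
  if (any(object@fwhms <= 0, na.rm = TRUE))
    msg <- c(msg, "fwhms must be positive")
  if (length(msg)) msg else TRUE
})

#' BleachModel: fitted photobleaching decay
#'
#' Parameters of the exponential decay a*exp(-t/tau) + c fitted to the
#' pre-stimulus baseline; `degenerate` marks traces where no decay could
#' be fitted (constant input, or fall-back linear detrend).
#'
#' @slot amplitude,tau,offset Numeric scalars (a.u., s, a.u.).
#' @slot degenerate Logical scalar.
#' @slot method Character scalar, "exponential" or "linear".
#'
#' @exportClass BleachModel
setClass("BleachModel",
  representation(amplitude = "numeric", tau = "numeric", offset = "numeric",
                 degenerate = "logical", method = "character"))

setValidity("BleachModel", function(object) {
  if (!object@degenerate && (!is.finite(object@tau) || object@tau <= 0))
    "tau must be positive unless the fit is flagged degenerate" else TRUE
})

#' TraceEnsemble: grouped traces for one condition
#'
#' An ordered collection of [FluorescenceTrace] objects with per-trace
#' metadata (condition label, antibody concentration) and, for synthetic
#' ensembles, the generator's ground-truth record.
#'
#' @slot traces List of `FluorescenceTrace`.
#' @slot meta `data.frame` with one row per trace; columns `roi_id`,
#'   `condition`, `conc_molar`.
#' @slot groundTruth List; empty for real data.
#'
#' @exportClass TraceEnsemble
setClass("TraceEnsemble",
  representation(traces = "list", meta = "data.frame", groundTruth = "list"))

setValidity("TraceEnsemble", function(object) {
  msg <- character()
  if (!all(vapply(object@traces, is, logical(1), "FluorescenceTrace")))
    msg <- c(msg, "all elements must be FluorescenceTrace objects")
  if (nrow(object@meta) != length(object@traces))
    msg <- c(msg, "meta must have one row per trace")
  if (!all(c("roi_id", "condition", "conc_molar") %in% names(object@meta)))
    msg <- c(msg, "meta needs columns roi_id, condition, conc_molar")
  if (length(msg)) msg else TRUE
})

#' @rdname TraceEnsemble-class
#' @param traces,meta,groundTruth See slots.
#' @export
TraceEnsemble <- function(traces, meta = NULL, groundTruth = list()) {
  if (is.null(meta)) {
    meta <- data.frame(
      roi_id = vapply(traces, function(x) x@roiId, character(1)),
      condition = "unknown", conc_molar = NA_real_,
      stringsAsFactors = FALSE)
  }
  new("TraceEnsemble", traces = traces, meta = meta,
      groundTruth = groundTruth)
}

## ---------------------------------------------------------------------------
## Assay results
## ---------------------------------------------------------------------------

#' DoseResponsePanel: antibody dose-response with Hill fit
#'
#' Mean cytosolic Ca2+ load (CCL) per antibody concentration, normalised
#' to the antibody-free control, together with the fitted inhibitory Hill
#' curve `R(c) = floor + (1 - floor) / (1 + (c/IC50)^h)`.
#'
#' @slot concentrations Numeric, molar (the control 0 M is included in the
#'   data but excluded from the log-concentration fit).
#' @slot meanCcl Numeric, mean CCL per concentration (dimensionless * s).
#' @slot response Numeric, fraction of the control CCL.
#' @slot ic50 Numeric scalar, molar.
#' @slot hill Numeric scalar, Hill coefficient.
#' @slot floor Numeric scalar, residual response at saturating antibody.
#' @slot flagged Logical scalar; TRUE when the data defeat the fit
#'   (no inhibition, non-convergence).
#' @slot diagnostics List: bootstrap confidence intervals, messages.
#'
#' @exportClass DoseResponsePanel
setClass("DoseResponsePanel",
  representation(concentrations = "numeric", meanCcl = "numeric",
                 response = "numeric", ic50 = "numeric", hill = "numeric",
                 floor = "numeric", flagged = "logical",
                 diagnostics = "list"))

setValidity("DoseResponsePanel", function(object) {
  msg <- character()
  if (!object@flagged) {
    if (!is.finite(object@ic50) || object@ic50 <= 0)
      msg <- c(msg, "ic50 must be positive")
    if (object@hill < 0.3 - 1e-9 || object@hill > 4 + 1e-9)
      msg <- c(msg, "hill coefficient must lie in [0.3, 4]")
  }
  if (length(msg)) msg else TRUE
})

#' QpcrMeasurement: Ct replicates for a 2^-ddCt quantification
#'
#' Threshold-cycle replicates for the target and reference genes in the
#' treated and control conditions.
#'
#' @slot ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl Numeric
#'   replicate vectors of PCR cycles, each in (0, 45) with >= 1 replicate.
#'
#' @exportClass QpcrMeasurement
setClass("QpcrMeasurement",
  representation(ctTargetTreated = "numeric", ctRefTreated = "numeric",
                 ctTargetControl = "numeric", ctRefControl = "numeric"))

setValidity("QpcrMeasurement", function(object) {
  vals <- c(object@ctTargetTreated, object@ctRefTreated,
            object@ctTargetControl, object@ctRefControl)
  ns <- c(length(object@ctTargetTreated), length(object@ctRefTreated),
          length(object@ctTargetControl), length(object@ctRefControl))
  msg <- character()
  if (any(ns < 1L)) msg <- c(msg, "each condition needs >= 1 Ct replicate")
  if (any(vals <= 0 | vals >= 45))
    msg <- c(msg, "all Ct values must lie in (0, 45) cycles")
  if (length(msg)) msg else TRUE
})

#' @rdname QpcrMeasurement-class
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl See slots.
#' @export
QpcrMeasurement <- function(ctTargetTreated, ctRefTreated,
                            ctTargetControl, ctRefControl) {
  new("QpcrMeasurement",
      ctTargetTreated = as.numeric(ctTargetTreated),
      ctRefTreated = as.numeric(ctRefTreated),
      ctTargetControl = as.numeric(ctTargetControl),
      ctRefControl = as.numeric(ctRefControl))
}

## ---------------------------------------------------------------------------
## Energetics
## ---------------------------------------------------------------------------

#' TrajectoryFrames: a multi-frame coordinate set
#'
#' An ordered stack of coordinate frames over a constant atom roster, as
#' read from a multi-model PDB; the substrate for RMSD and residue-contact
#' statistics.
#'
#' @slot coords Numeric array `[nFrames, nAtoms, 3]`, Angstrom.
#' @slot atoms `data.frame` with columns `chain`, `resno`, `resname`,
#'   `atomName`, `isHydrogen`.
#'
#' @exportClass TrajectoryFrames
setClass("TrajectoryFrames",
  representation(coords = "array", atoms = "data.frame"))

setValidity("TrajectoryFrames", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an [nFrames, nAtoms, 3] array")
  if (!is.null(d) && length(d) == 3L && d[2] != nrow(object@atoms))
    msg <- c(msg, "atom table must match the coordinate roster")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  need <- c("chain", "resno", "resname", "atomName", "isHydrogen")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms needs columns", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname TrajectoryFrames-class
#' @param coords,atoms See slots.
#' @export
TrajectoryFrames <- function(coords, atoms) {
  new("TrajectoryFrames", coords = coords, atoms = atoms)
}

#' WindowWorkSamples: per-lambda-window work values
#'
#' Forward and reverse work samples (kcal/mol) for each lambda window of
#' an alchemical transformation, the input to the free-energy estimators.
#'
#' @slot forward,reverse Lists of numeric vectors, one per window, each
#'   with >= 2 samples.
#' @slot temperature Numeric scalar, Kelvin.
#' @slot trueDg Numeric; the generator's per-window free energies for
#'   synthetic samples (length 0 for real data).
#'
#' @exportClass WindowWorkSamples
setClass("WindowWorkSamples",
  representation(forward = "list", reverse = "list",
                 temperature = "numeric", trueDg = "numeric"),
  prototype(trueDg = numeric()))

setValidity("WindowWorkSamples", function(object) {
  msg <- character()
  if (length(object@forward) != length(object@reverse))
    msg <- c(msg, "forward and reverse must have one entry per window")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a positive scalar (K)")
  ok <- function(l) all(vapply(l, function(x) length(x) >= 2L, logical(1)))
  if (length(object@forward) && (!ok(object@forward) || !ok(object@reverse)))
    msg <- c(msg, "each window needs >= 2 samples per direction")
  if (length(msg)) msg else TRUE
})

#' @rdname WindowWorkSamples-class
#' @param forward,reverse,temperature,trueDg See slots.
#' @export
WindowWorkSamples <- function(forward, reverse, temperature = 310,
                              trueDg = numeric()) {
  new("WindowWorkSamples", forward = forward, reverse = reverse,
      temperature = as.numeric(temperature), trueDg = as.numeric(trueDg))
}

#' FreeEnergyLeg: one leg of the thermodynamic cycle
#'
#' The summed free-energy change of one alchemical leg (the antibody-bound
#' complex or the free hemichannel), with per-window estimates.
#'
#' @slot label Character scalar, e.g. "complex" or "free".
#' @slot dg Numeric scalar, kcal/mol (= sum of per-window dg).
#' @slot se Numeric scalar, kcal/mol (windows combined in quadrature).
#' @slot perWindow `data.frame` with columns `window`, `dg`, `se`.
#'
#' @exportClass FreeEnergyLeg
setClass("FreeEnergyLeg",
  representation(label = "character", dg = "numeric", se = "numeric",
                 perWindow = "data.frame"))

setValidity("FreeEnergyLeg", function(object) {
  msg <- character()
  if (nrow(object@perWindow) < 1L)
    msg <- c(msg, "a leg needs at least one window")
  if (abs(object@dg - sum(object@perWindow$dg)) >
      1e-8 * max(1, abs(object@dg)))
    msg <- c(msg, "dg must equal the sum of per-window contributions")
  if (object@se < 0) msg <- c(msg, "se must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ProtomerContributions: per-protomer ddG and affinity fold change
#'
#' The six per-protomer binding free-energy differences of the hexameric
#' connexon, their sum, and the implied multiplicative change in binding
#' affinity exp(total/RT).
#'
#' @slot ddgPerProtomer Numeric length 6, kcal/mol.
#' @slot se Numeric length 6, kcal/mol.
#' @slot totalDdg Numeric scalar, kcal/mol.
#' @slot foldChange Numeric scalar, exp(totalDdg / RT).
#' @slot foldPowerOfTen Numeric scalar, nearest power of ten of foldChange.
#' @slot temperature Numeric scalar, Kelvin.
#'
#' @exportClass ProtomerContributions
setClass("ProtomerContributions",
  representation(ddgPerProtomer = "numeric", se = "numeric",
                 totalDdg = "numeric", foldChange = "numeric",
                 foldPowerOfTen = "numeric", temperature = "numeric"))

setValidity("ProtomerContributions", function(object) {
  msg <- character()
  if (length(object@ddgPerProtomer) != 6L)
    msg <- c(msg, "exactly six per-protomer values are required")
  if (abs(object@totalDdg - sum(object@ddgPerProtomer)) > 1e-9)
    msg <- c(msg, "totalDdg must equal the sum of the six contributions")
  rt <- RGAS * object@temperature
  if (abs(object@foldChange - exp(object@totalDdg / rt)) >
      1e-9 * object@foldChange)
    msg <- c(msg, "foldChange must equal exp(totalDdg/RT)")
  if (length(msg)) msg else TRUE
})

#' ContactResult: residue-contact statistics of a trajectory
#'
#' Per-frame contact indicator between two atom selections (contact =
#' minimum heavy-atom distance strictly below the cutoff) and the fraction
#' of frames in contact.
#'
#' @slot selectionA,selectionB Character descriptions of the selections.
#' @slot cutoff Numeric scalar, Angstrom.
#' @slot fraction Numeric scalar in `[0, 1]`.
#' @slot perFrame Logical vector, one entry per frame.
#' @slot minDistances Numeric vector, per-frame minimum distances (A).
#'
#' @exportClass ContactResult
setClass("ContactResult",
  representation(selectionA = "character", selectionB = "character",
                 cutoff = "numeric", fraction = "numeric",
                 perFrame = "logical", minDistances = "numeric"))

setValidity("ContactResult", function(object) {
  if (length(object@perFrame) &&
      abs(object@fraction - mean(object@perFrame)) > 1e-12)
    "fraction must equal mean(perFrame)" else TRUE
})

## ---------------------------------------------------------------------------
## Statistics
## ---------------------------------------------------------------------------

#' ComparisonResult: normality-gated group comparison
#'
#' Result of the comparison decision tree: Shapiro-Wilk normality per
#' group; one-way ANOVA with Bonferroni pairwise tests (or a two-sided t
#' test for two groups) when every group passes; Kruskal-Wallis with
#' Dunn-Sidak pairwise tests otherwise.  Summaries are mean +/- s.e.m.
#'
#' @slot branch Character, "parametric" or "nonparametric".
#' @slot omnibusTest Character, test name.
#' @slot omnibusStatistic,omnibusP Numeric scalars.
#' @slot shapiroP Named numeric, per-group Shapiro-Wilk p values.
#' @slot pairwise `data.frame`: `group1`, `group2`, `p`, `pAdjusted`,
#'   `stars`.
#' @slot groupSummary `data.frame`: `group`, `mean`, `sem`, `n`.
#'
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(branch = "character", omnibusTest = "character",
                 omnibusStatistic = "numeric", omnibusP = "numeric",
                 shapiroP = "numeric", pairwise = "data.frame",
                 groupSummary = "data.frame"))

setValidity("ComparisonResult", function(object) {
  p <- object@pairwise$pAdjusted
  if (length(p) && (any(p < 0 - 1e-12) || any(p > 1 + 1e-12)))
    "adjusted p values must lie in [0, 1]" else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-data configuration and ground truth
## ---------------------------------------------------------------------------

#' SynthConfig: acquisition parameters for synthetic recordings
#'
#' Frame timing and stimulus landmarks for synthetic GCaMP recordings.
#' Defaults follow the imaging protocol the package emulates: 1.3 s frame
#' interval over a 6 min recording, a 10 s baseline before the Ca2+
#' stimulus, and ionomycin at 190 s.
#'
#' @slot nRois Integer, number of ROIs per ensemble.
#' @slot frameInterval Numeric, seconds (default 1.3).
#' @slot duration Numeric, seconds (default 360).
#' @slot stimulusTime Numeric, seconds (default 10).
#' @slot ionomycinTime Numeric, seconds (default 190).
#' @slot noiseSd Numeric, additive Gaussian noise s.d. in a.u.
#' @slot oscillationRate Numeric, spontaneous Ca2+ events per minute.
#' @slot gapMask Integer sample indices excluded from luminescence series.
#'
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nRois = "integer", frameInterval = "numeric",
                 duration = "numeric", stimulusTime = "numeric",
                 ionomycinTime = "numeric", noiseSd = "numeric",
                 oscillationRate = "numeric", gapMask = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be positive")
  if (!(object@stimulusTime > 0 &&
        object@stimulusTime < object@ionomycinTime &&
        object@ionomycinTime < object@duration))
    msg <- c(msg, "need 0 < stimulusTime < ionomycinTime < duration")
  if (object@nRois < 1L) msg <- c(msg, "nRois must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@oscillationRate < 0)
    msg <- c(msg, "oscillationRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SynthConfig-class
#' @param nRois,frameInterval,duration,stimulusTime,ionomycinTime See slots.
#' @param noiseSd,oscillationRate,gapMask See slots.
#' @export
SynthConfig <- function(nRois = 30L, frameInterval = 1.3, duration = 360,
                        stimulusTime = 10, ionomycinTime = 190,
                        noiseSd = 1, oscillationRate = 1,
                        gapMask = integer()) {
  new("SynthConfig", nRois = as.integer(nRois),
      frameInterval = frameInterval, duration = duration,
      stimulusTime = stimulusTime, ionomycinTime = ionomycinTime,
      noiseSd = noiseSd, oscillationRate = oscillationRate,
      gapMask = as.integer(gapMask))
}

#' GroundTruth: the generator's known parameters
#'
#' The study conditions the synthetic-data generators emulate, recorded so
#' that every downstream estimator can be checked against known truth:
#' the mutant/wild-type CCL ratio (1.58, i.e. a 58% increase), the 9-fold
#' amplitude/FWHM ratio of evoked transients over spontaneous
#' oscillations, per-condition antibody IC50 (10 nM wild type, 80 nM
#' mutant), the 4-fold ATP luminescence peak, photobleaching time
#' constant, per-window alchemical free energies, the true contact
#' fraction and the DAPI uptake slope.
#'
#' @slot effectRatioCcl Numeric scalar > 0, mutant/WT CCL ratio.
#' @slot transientFold Numeric scalar > 0, evoked vs spontaneous fold.
#' @slot ic50PerCondition Named numeric, molar.
#' @slot hillH Numeric scalar, Hill coefficient.
#' @slot atpFold Numeric scalar > 0, peak/baseline luminescence.
#' @slot bleachTau Numeric scalar, seconds.
#' @slot perWindowDg Numeric, kcal/mol per lambda window.
#' @slot contactFractionTrue Numeric in `[0, 1]`.
#' @slot dapiSlopeTrue Numeric, a.u./s.
#' @slot seed Integer global seed.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(effectRatioCcl = "numeric", transientFold = "numeric",
                 ic50PerCondition = "numeric", hillH = "numeric",
                 atpFold = "numeric", bleachTau = "numeric",
                 perWindowDg = "numeric", contactFractionTrue = "numeric",
                 dapiSlopeTrue = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  pos <- c(effectRatioCcl = object@effectRatioCcl,
           transientFold = object@transientFold,
           hillH = object@hillH, atpFold = object@atpFold,
           bleachTau = object@bleachTau)
  if (any(pos <= 0))
    msg <- c(msg, "folds, ratios and time constants must be > 0")
  if (any(object@ic50PerCondition <= 0))
    msg <- c(msg, "IC50 values must be > 0")
  if (object@contactFractionTrue < 0 || object@contactFractionTrue > 1)
    msg <- c(msg, "contactFractionTrue must lie in [0, 1]")
  if (any(!is.finite(object@perWindowDg)))
    msg <- c(msg, "perWindowDg must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname GroundTruth-class
#' @param effectRatioCcl,transientFold,ic50PerCondition,hillH See slots.
#' @param atpFold,bleachTau,perWindowDg,contactFractionTrue See slots.
#' @param dapiSlopeTrue,seed See slots.
#' @export
GroundTruth <- function(effectRatioCcl = 1.58, transientFold = 9,
                        ic50PerCondition = c(WT = 1e-8, D178Y = 8e-8),
                        hillH = 1, atpFold = 4, bleachTau = 2000,
                        perWindowDg = rep(2.00 / 32, 32),
                        contactFractionTrue = 0.79, dapiSlopeTrue = 2,
                        seed = 1L) {
  new("GroundTruth", effectRatioCcl = effectRatioCcl,
      transientFold = transientFold,
      ic50PerCondition = ic50PerCondition, hillH = hillH,
      atpFold = atpFold, bleachTau = bleachTau,
      perWindowDg = perWindowDg,
      contactFractionTrue = contactFractionTrue,
      dapiSlopeTrue = dapiSlopeTrue, seed = as.integer(seed))
}
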