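## Hemichannel activity statistics: cytosolic Ca2+ load, DAPI uptake rate,
## ATP release, qPCR fold change, antibody dose-response.

#' Cytosolic Ca2+ load: area under a dF/dFmax trace
#'
#' Trapezoidal integral of the normalised trace over a fixed
#' post-stimulus window (default 0-100 s with t = 0 at the stimulus),
#' the study statistic for Ca2+ uptake through open hemichannels.
#' Off-grid window endpoints are included by linear interpolation.
#'
#' @param norm A [NormalizedTrace].
#' @param t0,t1 Window in seconds relative to the stimulus
#'   (defaults 0 and 100).
#' @return A list with `roiId`, `area` (dimensionless * s) and `window`.
#' @examples
#' tt <- seq(-10, 150, by = 0.5)
#' tri <- pmax(0, 1 - abs(tt - 50) / 50)  # unit triangle on [0, 100]
#' nt <- new("NormalizedTrace", times = tt + 10, dff = tri, dfMax = 1,
#'           f0 = 0, roiId = "r", stimulusTime = 10)
#' computeCcl(nt)$area  # 50
#' @export
computeCcl <- function(norm, t0 = 0, t1 = 100) {
  stopifnot(is(norm, "NormalizedTrace"))
  tRel <- norm@times - norm@stimulusTime
  area <- trapzWindow(tRel, norm@dff, t0, t1)
  list(roiId = norm@roiId, area = area, window = c(t0, t1))
}

#' DAPI uptake rate: origin-constrained slope
#'
#' Implements the dye-uptake quantification: the first sample is
#' subtracted from the trace (removing dead-cell signal already present
#' at t = 0), time is re-zeroed to the first frame, and the uptake rate
#' is the least-squares slope of a straight line through the origin,
#' `slope = sum(t * F) / sum(t^2)`.
#'
#' @param trace A [FluorescenceTrace] of nuclear DAPI fluorescence.
#' @return Numeric scalar, a.u./s.
#' @examples
#' tr <- FluorescenceTrace(0:3, c(0, 2, 4, 6) + 50)
#' dapiRate(tr)  # 2
#' @export
dapiRate <- function(trace) {
  stopifnot(is(trace, "FluorescenceTrace"))
  t <- trace@times - trace@times[1]
  f <- trace@values - trace@values[1]
  if (length(t) < 3L) stop("dapiRate needs at least 3 samples")
  st2 <- sum(t^2)
  if (st2 == 0) stop("all times are zero after re-zeroing")
  sum(t * f) / st2
}

#' ATP release: baseline-subtracted luminescence AUC
#'
#' Baseline is the mean of the pre-stimulus samples; the area under the
#' baseline-subtracted luminescence curve is integrated by trapezoids
#' over `[stimulusTime, stimulusTime + horizon]`, interpolating linearly
#' across instrument gaps.  The peak fold is `max(L) / baseline`.
#'
#' @param lum A [FluorescenceTrace] holding a well's luminescence series.
#' @param stimulusTime Seconds; default the trace's own `stimulusTime`.
#' @param horizon Integration horizon after the stimulus, seconds
#'   (default 600).
#' @return A list with `wellId`, `baseline` (a.u.), `auc` (a.u.*s) and
#'   `peakFold`.
#' @export
atpRelease <- function(lum, stimulusTime = lum@stimulusTime,
                       horizon = 600) {
  stopifnot(is(lum, "FluorescenceTrace"))
  if (is.na(stimulusTime)) stop("stimulusTime is required")
  t <- lum@times; v <- lum@values
  pre <- t < stimulusTime
  if (sum(pre) < 2L) stop("need at least 2 pre-stimulus samples")
  if (!any(t >= stimulusTime)) stop("empty post-stimulus window")
  baseline <- mean(v[pre])
  t1 <- min(stimulusTime + horizon, max(t))
  auc <- trapzWindow(t, v - baseline, stimulusTime, t1)
  list(wellId = lum@roiId, baseline = baseline, auc = auc,
       peakFold = max(v) / baseline)
}

#' Relative gene expression by the 2^-ddCt method
#'
#' `dCt = mean(Ct_target) - mean(Ct_ref)` per condition;
#' `ddCt = dCt_treated - dCt_control`; fold change `2^(-ddCt)`.
#'
#' @param m A [QpcrMeasurement].
#' @return Numeric scalar fold change (dimensionless).
#' @examples
#' m <- QpcrMeasurement(c(20, 18), c(20, 20), c(26, 18), c(20, 20))
#' ddctFold(m)  # 64
#' @export
ddctFold <- function(m) {
  stopifnot(is(m, "QpcrMeasurement"))
  dctTreated <- mean(m@ctTargetTreated) - mean(m@ctRefTreated)
  dctControl <- mean(m@ctTargetControl) - mean(m@ctRefControl)
  2^(-(dctTreated - dctControl))
}

## Inhibitory Hill response on the log10-concentration scale.
hillResponse <- function(logc, logIc50, h, floor) {
  floor + (1 - floor) / (1 + 10^(h * (logc - logIc50)))
}

#' Fit an antibody dose-response curve
#'
#' Normalises the mean CCL at each antibody concentration to the
#' antibody-free control (concentration 0, which is the normaliser and
#' not a fitted point) and fits the inhibitory Hill model
#' `R(c) = floor + (1 - floor) / (1 + (c/IC50)^h)` by least squares in
#' log10 concentration.  The free `floor` accommodates incomplete
#' inhibition at saturating antibody.  Confidence intervals for IC50 and
#' h come from a seeded bootstrap over ROIs within each concentration.
#'
#' Panels that defeat the fit (no inhibition, non-convergence) return a
#' flagged panel with diagnostics rather than raising an error.
#'
#' @param concentrations Numeric vector, molar, one entry per ROI
#'   measurement; must include 0 (control) and at least 4 distinct
#'   non-zero concentrations.
#' @param ccl Numeric vector of per-ROI CCL values, same length.
#' @param nBoot Bootstrap resamples for the CIs (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return A [DoseResponsePanel].
#' @export
fitDoseResponse <- function(concentrations, ccl, nBoot = 200L, seed = 1L) {
  stopifnot(length(concentrations) == length(ccl))
  concs <- sort(unique(concentrations))
  if (!0 %in% concs) stop("a control at concentration 0 is required")
  if (sum(concs > 0) < 4L)
    stop("need at least 4 distinct non-zero concentrations")

  meanAt <- function(cc, vals, conc) {
    vapply(concs, function(k) mean(vals[conc == k]), numeric(1))
  }
  fitOnce <- function(meanCcl) {
    resp <- meanCcl / meanCcl[concs == 0]
    x <- log10(concs[concs > 0])
    y <- resp[concs > 0]
    floor0 <- max(0, min(min(y), 0.9))
    p0 <- x[which.min(abs(y - (1 + floor0) / 2))]
    ## Levenberg-Marquardt on the residual function directly; parameter
    ## uncertainty comes from the bootstrap, so no nls model object is
    ## needed (and exact-fit data cannot trip its construction).
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(p = p0, h = 1, fl = floor0),
        lower = c(p = min(x) - 3, h = 0.3, fl = 0),
        upper = c(p = max(x) + 3, h = 4, fl = 0.95),
        fn = function(par)
          y - hillResponse(x, par[["p"]], par[["h"]], par[["fl"]]),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
    cf <- fit$par
    list(ic50 = 10^cf[["p"]], h = cf[["h"]], floor = cf[["fl"]],
         response = resp, resid = fit$fvec)
  }

  meanCcl <- meanAt(concs, ccl, concentrations)
  main <- fitOnce(meanCcl)
  resp <- meanCcl / meanCcl[concs == 0]

  inhibitionRange <- max(resp) - min(resp)
  flagged <- is.null(main) || inhibitionRange < 0.05
  diag <- list(messages = character(), ic50CI = c(NA_real_, NA_real_),
               hillCI = c(NA_real_, NA_real_), nBoot = nBoot)

  if (flagged) {
    diag$messages <- c(diag$messages,
      if (is.null(main)) "Hill fit did not converge" else
        sprintf("no usable inhibition (response range %.3g); IC50 unidentified",
                inhibitionRange))
    diag$ic50CI <- c(0, Inf)
    return(new("DoseResponsePanel", concentrations = concs,
               meanCcl = meanCcl, response = resp, ic50 = NA_real_,
               hill = NA_real_, floor = NA_real_, flagged = TRUE,
               diagnostics = diag))
  }

  ## bootstrap over ROIs within concentration
  set.seed(subSeed(seed, "dose-response-bootstrap"))
  bootIc <- bootH <- rep(NA_real_, nBoot)
  byConc <- split(ccl, match(concentrations, concs))
  for (b in seq_len(nBoot)) {
    mc <- vapply(byConc, function(v) mean(sample(v, replace = TRUE)),
                 numeric(1))
    fb <- fitOnce(mc)
    if (!is.null(fb)) { bootIc[b] <- fb$ic50; bootH[b] <- fb$h }
  }
  diag$ic50CI <- unname(stats::quantile(bootIc, c(0.025, 0.975),
                                        na.rm = TRUE))
  diag$hillCI <- unname(stats::quantile(bootH, c(0.025, 0.975),
                                        na.rm = TRUE))
  diag$bootstrapFailures <- sum(is.na(bootIc))

  new("DoseResponsePanel", concentrations = concs, meanCcl = meanCcl,
      response = main$response, ic50 = main$ic50, hill = main$h,
      floor = main$floor, flagged = FALSE, diagnostics = diag)
}
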