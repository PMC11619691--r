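## Fluorescence trace preprocessing: background subtraction, photobleach
## correction, dF/dFmax normalisation, peak statistics.

#' Subtract a cell-free background trace
#'
#' Pointwise subtraction of a background ROI recorded on the same time
#' grid.  Negative values are preserved (no clamping) so that downstream
#' area integrals stay linear.
#'
#' @param trace,background [FluorescenceTrace] objects on identical grids.
#' @return A background-subtracted [FluorescenceTrace].
#' @examples
#' tr <- FluorescenceTrace(0:4, c(10, 12, 11, 10, 10))
#' bg <- FluorescenceTrace(0:4, rep(5, 5))
#' traceValues(subtractBackground(tr, bg))
#' @export
subtractBackground <- function(trace, background) {
  stopifnot(is(trace, "FluorescenceTrace"),
            is(background, "FluorescenceTrace"))
  if (length(trace@times) != length(background@times) ||
      any(trace@times != background@times)) {
    stop("trace and background must share an identical time grid")
  }
  FluorescenceTrace(trace@times, trace@values - background@values,
                    roiId = trace@roiId,
                    stimulusTime = trace@stimulusTime,
                    ionomycinTime = trace@ionomycinTime)
}

#' Fit and remove an exponential photobleaching trend
#'
#' Fits `a * exp(-t/tau) + c` to the baseline samples by nonlinear least
#' squares and removes the fitted trend from the whole trace, retaining
#' the offset: `corrected = F - (a*exp(-t/tau) + c) + c`.  The fit uses
#' the pre-stimulus window only (when a stimulus is set), so that evoked
#' signal cannot bias the decay estimate; the correction is extrapolated
#' over the full recording.  The amplitude is constrained non-negative
#' (photobleaching is a decay): without the constraint, a short noisy
#' baseline window can support a spurious rising exponential whose
#' extrapolation corrupts the rest of the trace.
#'
#' A constant input yields a degenerate model (`a = 0`, trace returned
#' unchanged).  If the exponential fit fails to converge the function
#' falls back to a linear detrend of the window, flagged in the returned
#' model's `method`.
#'
#' @param trace A [FluorescenceTrace].
#' @param fitWindow Numeric length-2 `[t_lo, t_hi)` of the fit window,
#'   seconds.  Default: `[0, stimulusTime)` when a stimulus is set,
#'   otherwise the whole trace.
#' @param robust Iteratively refit excluding positive outliers (residual
#'   > 2 robust s.d.), so that sparse Ca2+ events riding on the baseline
#'   do not bias the decay estimate.  Useful when the fit window spans a
#'   recording with spontaneous activity; default FALSE.
#' @return A list with elements `model` ([BleachModel]) and `corrected`
#'   ([FluorescenceTrace]).
#' @export
fitBleach <- function(trace, fitWindow = NULL, robust = FALSE) {
  stopifnot(is(trace, "FluorescenceTrace"))
  t <- trace@times; v <- trace@values
  if (is.null(fitWindow)) {
    fitWindow <- if (!is.na(trace@stimulusTime)) {
      c(min(t), trace@stimulusTime)
    } else c(min(t), max(t) + 1)
  }
  sel <- t >= fitWindow[1] & t < fitWindow[2]
  if (sum(sel) < 4L) stop("fit window must contain at least 4 samples")
  tw <- t[sel]; vw <- v[sel]

  rebuild <- function(corr) {
    FluorescenceTrace(t, corr, roiId = trace@roiId,
                      stimulusTime = trace@stimulusTime,
                      ionomycinTime = trace@ionomycinTime)
  }

  if (stats::sd(vw) < .Machine$double.eps^0.5 * max(1, abs(mean(vw)))) {
    model <- new("BleachModel", amplitude = 0, tau = NA_real_,
                 offset = mean(vw), degenerate = TRUE,
                 method = "constant")
    return(list(model = model, corrected = rebuild(v)))
  }

  span <- diff(range(tw))
  expFit <- function(tt, vv) {
    c0 <- min(vv) - 0.05 * diff(range(vv))
    a0 <- max(vv[1] - c0, 0.2 * stats::sd(vv))  # strictly positive start:
                                                # a = 0 leaves tau unidentified
    tryCatch(
      minpack.lm::nlsLM(
        vv ~ a * exp(-tt / tau) + cc,
        start = list(a = a0, tau = span / 2, cc = c0),
        lower = c(a = 0, tau = span * 1e-4, cc = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
  }
  fit <- expFit(tw, vw)
  if (robust && !is.null(fit)) {
    tk <- tw; vk <- vw
    for (it in 1:3) {
      p <- stats::coef(fit)
      resid <- vk - (p[["a"]] * exp(-tk / p[["tau"]]) + p[["cc"]])
      s <- stats::mad(resid)
      if (s < .Machine$double.eps^0.25 * max(1, abs(mean(vk)))) break
      keep <- resid < 2 * s        # drop positive outliers (events) only
      if (sum(keep) < 4L || all(keep)) break
      tk <- tk[keep]; vk <- vk[keep]
      refit <- expFit(tk, vk)
      if (is.null(refit)) break
      fit <- refit
    }
  }

  if (is.null(fit)) {
    ## Non-convergence.  A linear detrend is a sensible stand-in inside
    ## the fitted window, but extrapolating a straight line far beyond a
    ## short window is not: in that regime the trace is returned
    ## uncorrected (flagged "constant").
    if (max(t) > max(tw) + span) {
      model <- new("BleachModel", amplitude = 0, tau = NA_real_,
                   offset = mean(vw), degenerate = TRUE,
                   method = "constant")
      return(list(model = model, corrected = rebuild(v)))
    }
    lf <- stats::lm(vw ~ tw)
    trend <- stats::coef(lf)[1] + stats::coef(lf)[2] * t
    corr <- v - trend + mean(vw)
    model <- new("BleachModel", amplitude = unname(stats::coef(lf)[2]),
                 tau = NA_real_, offset = mean(vw), degenerate = TRUE,
                 method = "linear")
    return(list(model = model, corrected = rebuild(corr)))
  }

  p <- stats::coef(fit)
  trend <- p[["a"]] * exp(-t / p[["tau"]]) + p[["cc"]]
  corr <- v - trend + p[["cc"]]
  model <- new("BleachModel", amplitude = p[["a"]], tau = p[["tau"]],
               offset = p[["cc"]], degenerate = FALSE,
               method = "exponential")
  list(model = model, corrected = rebuild(corr))
}

#' Normalise a trace to its ionomycin-evoked maximum (dF/dFmax)
#'
#' Computes `dF(t) = F(t) - F0` with `F0` the mean of the pre-stimulus
#' samples, and `dFmax` the maximum `dF` within the ionomycin window
#' (from `ionomycinTime` to the end of the recording).  The returned
#' trace is `dF/dFmax`.
#'
#' ROIs in which the ionomycin response is not positive carry no usable
#' normalisation and are excluded: the function signals a classed error
#' (`hcq_exclusion`) carrying the exclusion reason, which ensemble-level
#' wrappers collect into an exclusion log.
#'
#' @param trace A [FluorescenceTrace] with `stimulusTime` and
#'   `ionomycinTime` set.
#' @return A [NormalizedTrace].
#' @export
normalizeDff <- function(trace) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (is.na(trace@stimulusTime) || is.na(trace@ionomycinTime))
    stop("normalizeDff requires stimulusTime and ionomycinTime")
  t <- trace@times; v <- trace@values
  pre <- t < trace@stimulusTime
  if (!any(pre)) stop("no pre-stimulus samples to estimate F0 from")
  f0 <- mean(v[pre])
  df <- v - f0
  iono <- t >= trace@ionomycinTime
  if (!any(iono)) stop("no samples in the ionomycin window")
  dfmax <- max(df[iono])
  if (!is.finite(dfmax) || dfmax <= 0) {
    cond <- structure(
      class = c("hcq_exclusion", "error", "condition"),
      list(message = sprintf(
             "ROI '%s' excluded: non-positive ionomycin response (dFmax = %.3g)",
             trace@roiId, dfmax),
           call = sys.call(-1), roiId = trace@roiId, dfMax = dfmax))
    stop(cond)
  }
  new("NormalizedTrace", times = t, dff = df / dfmax, dfMax = dfmax,
      f0 = f0, roiId = trace@roiId, stimulusTime = trace@stimulusTime)
}

#' Normalise every trace of an ensemble, logging exclusions
#'
#' Applies [normalizeDff()] to each trace; ROIs that fail the ionomycin
#' criterion are dropped and recorded.
#'
#' @param ensemble A [TraceEnsemble].
#' @return A list with `normalized` (list of [NormalizedTrace]), `meta`
#'   (metadata rows of the retained traces) and `exclusions`
#'   (`data.frame` of `roi_id`, `reason`).
#' @export
normalizeEnsemble <- function(ensemble) {
  stopifnot(is(ensemble, "TraceEnsemble"))
  out <- vector("list", length(ensemble))
  keep <- logical(length(ensemble))
  excl <- list()
  for (i in seq_along(ensemble@traces)) {
    res <- tryCatch(normalizeDff(ensemble@traces[[i]]),
                    hcq_exclusion = function(e) e)
    if (inherits(res, "hcq_exclusion")) {
      excl[[length(excl) + 1L]] <- data.frame(
        roi_id = res$roiId, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      out[[i]] <- res; keep[i] <- TRUE
    }
  }
  list(normalized = out[keep],
       meta = ensemble@meta[keep, , drop = FALSE],
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(roi_id = character(), reason = character()))
}

#' Detect peaks and their widths in a trace
#'
#' Local maxima exceeding `baseline + k * (1.4826 * MAD)` are reported,
#' where the baseline is the trace median and the MAD is taken over the
#' residuals from it.  The amplitude is the peak value minus the
#' baseline; the FWHM is obtained by linear interpolation of the
#' half-amplitude crossings on either side of the peak (NA when a
#' crossing falls outside the recording).  Peaks closer than
#' `mergeWithin` samples are merged, keeping the highest (earliest on
#' ties).
#'
#' @param x A [FluorescenceTrace] or [NormalizedTrace].
#' @param thresholdK Dimensionless detection threshold multiplier
#'   (default 3).
#' @param mergeWithin Minimum separation in samples (default 3).
#' @param baseline Optional numeric baseline level.  Default (NULL) is
#'   the trace median, appropriate when activity is sparse; pass the
#'   pre-stimulus mean for traces dominated by a broad evoked transient,
#'   where the median itself is elevated.
#' @return A [PeakSet] (possibly empty).
#' @export
detectPeaks <- function(x, thresholdK = 3, mergeWithin = 3L,
                        baseline = NULL) {
  t <- traceTimes(x); v <- traceValues(x)
  if (length(v) < 8L) stop("peak detection needs at least 8 samples")
  base <- if (is.null(baseline)) stats::median(v) else baseline
  sigma <- stats::mad(v, center = base)   # 1.4826 * median |v - base|
  thr <- base + thresholdK * sigma
  n <- length(v)
  ## strict rise into the peak, non-strict fall out: earliest sample of a
  ## plateau wins
  cand <- which(v > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] > v[cand - 1L] & v[cand] >= v[cand + 1L]]
  if (length(cand) > 1L) {
    merged <- integer()
    i <- 1L
    while (i <= length(cand)) {
      grp <- cand[i]
      j <- i
      while (j < length(cand) && cand[j + 1L] - cand[j] < mergeWithin) {
        j <- j + 1L
        grp <- c(grp, cand[j])
      }
      best <- grp[which.max(v[grp])]    # which.max: earliest on ties
      merged <- c(merged, best)
      i <- j + 1L
    }
    cand <- merged
  }
  if (!length(cand)) {
    return(new("PeakSet", peakTimes = numeric(), amplitudes = numeric(),
               fwhms = numeric()))
  }
  amp <- v[cand] - base
  fw <- vapply(cand, function(ix) {
    half <- base + (v[ix] - base) / 2
    ## walk left
    l <- ix
    while (l > 1L && v[l - 1L] > half) l <- l - 1L
    tl <- if (l == 1L && v[1L] > half) NA_real_ else
      crossingTime(t[l - 1L], v[l - 1L], t[l], v[l], half)
    ## walk right
    r <- ix
    while (r < n && v[r + 1L] > half) r <- r + 1L
    tr <- if (r == n && v[n] > half) NA_real_ else
      crossingTime(t[r], v[r], t[r + 1L], v[r + 1L], half)
    tr - tl
  }, numeric(1))
  new("PeakSet", peakTimes = t[cand], amplitudes = amp, fwhms = fw)
}
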