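## Generics and accessors.  Slot access everywhere else in the package and
## in user code goes through these.

#' @name accessors
#' @title Accessors for hcquant classes
#' @description Small accessor generics: trace times/values, dF/dFmax
#'   values, peak statistics, trajectory dimensions and free-energy
#'   summaries.
#' @param x An object of the relevant class.
#' @return The slot value (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))
#' @rdname accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))
#' @rdname accessors
#' @export
setGeneric("dfMax", function(x) standardGeneric("dfMax"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("peakAmplitudes", function(x) standardGeneric("peakAmplitudes"))
#' @rdname accessors
#' @export
setGeneric("peakFwhms", function(x) standardGeneric("peakFwhms"))
#' @rdname accessors
#' @export
setGeneric("interPeakIntervals",
           function(x) standardGeneric("interPeakIntervals"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("legDg", function(x) standardGeneric("legDg"))
#' @rdname accessors
#' @export
setGeneric("legSe", function(x) standardGeneric("legSe"))
#' @rdname accessors
#' @export
setGeneric("totalDdg", function(x) standardGeneric("totalDdg"))
#' @rdname accessors
#' @export
setGeneric("affinityFold", function(x) standardGeneric("affinityFold"))
#' @rdname accessors
#' @export
setGeneric("contactFrac", function(x) standardGeneric("contactFrac"))
#' @rdname accessors
#' @export
setGeneric("ensembleMeta", function(x) standardGeneric("ensembleMeta"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
setMethod("traceTimes", "FluorescenceTrace", function(x) x@times)
#' @rdname accessors
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)
#' @rdname accessors
setMethod("roiId", "FluorescenceTrace", function(x) x@roiId)
#' @rdname accessors
setMethod("traceTimes", "NormalizedTrace", function(x) x@times)
#' @rdname accessors
setMethod("traceValues", "NormalizedTrace", function(x) x@dff)
#' @rdname accessors
setMethod("roiId", "NormalizedTrace", function(x) x@roiId)
#' @rdname accessors
setMethod("dff", "NormalizedTrace", function(x) x@dff)
#' @rdname accessors
setMethod("dfMax", "NormalizedTrace", function(x) x@dfMax)

#' @rdname accessors
setMethod("peakTimes", "PeakSet", function(x) x@peakTimes)
#' @rdname accessors
setMethod("peakAmplitudes", "PeakSet", function(x) x@amplitudes)
#' @rdname accessors
setMethod("peakFwhms", "PeakSet", function(x) x@fwhms)
#' @rdname accessors
setMethod("interPeakIntervals", "PeakSet", function(x) {
  if (length(x@peakTimes) < 2L) numeric() else diff(x@peakTimes)
})

#' @rdname accessors
setMethod("nFrames", "TrajectoryFrames", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("atomTable", "TrajectoryFrames", function(x) x@atoms)
#' @rdname accessors
setMethod("frameCoords", "TrajectoryFrames", function(x) x@coords)

#' @rdname accessors
setMethod("legDg", "FreeEnergyLeg", function(x) x@dg)
#' @rdname accessors
setMethod("legSe", "FreeEnergyLeg", function(x) x@se)
#' @rdname accessors
setMethod("totalDdg", "ProtomerContributions", function(x) x@totalDdg)
#' @rdname accessors
setMethod("affinityFold", "ProtomerContributions", function(x) x@foldChange)
#' @rdname accessors
setMethod("contactFrac", "ContactResult", function(x) x@fraction)

#' @rdname accessors
setMethod("ensembleMeta", "TraceEnsemble", function(x) x@meta)
#' @rdname accessors
setMethod("groundTruth", "TraceEnsemble", function(x) x@groundTruth)

#' @describeIn TraceEnsemble-class Number of traces.
#' @param x A `TraceEnsemble`.
#' @export
setMethod("length", "TraceEnsemble", function(x) length(x@traces))

#' @describeIn TraceEnsemble-class Extract one trace.
#' @param i Index.
#' @export
setMethod("[[", "TraceEnsemble", function(x, i) x@traces[[i]])

## -- show methods -----------------------------------------------------------

setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("FluorescenceTrace '%s': %d samples, %.1f-%.1f s",
              object@roiId, length(object@times),
              min(object@times), max(object@times)))
  if (!is.na(object@stimulusTime))
    cat(sprintf(", stimulus %.1f s", object@stimulusTime))
  if (!is.na(object@ionomycinTime))
    cat(sprintf(", ionomycin %.1f s", object@ionomycinTime))
  cat("\n")
})

setMethod("show", "NormalizedTrace", function(object) {
  cat(sprintf(
    "NormalizedTrace '%s': %d samples, dFmax = %.3g a.u., max dF/dFmax = %.3g\n",
    object@roiId, length(object@times), object@dfMax, max(object@dff)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peak(s)", length(object@peakTimes)))
  if (length(object@peakTimes)) {
    cat(sprintf("; mean amplitude %.3g, mean FWHM %.3g s",
                mean(object@amplitudes), mean(object@fwhms, na.rm = TRUE)))
  }
  cat("\n")
})

setMethod("show", "TraceEnsemble", function(object) {
  conds <- unique(object@meta$condition)
  cat(sprintf("TraceEnsemble: %d traces, condition(s): %s\n",
              length(object@traces), paste(conds, collapse = ", ")))
  if (length(object@groundTruth))
    cat("  (synthetic; ground truth attached)\n")
})

setMethod("show", "BleachModel", function(object) {
  if (object@degenerate) {
    cat(sprintf("BleachModel: degenerate (%s), offset %.4g\n",
                object@method, object@offset))
  } else {
    cat(sprintf("BleachModel: %.4g * exp(-t/%.4g s) + %.4g\n",
                object@amplitude, object@tau, object@offset))
  }
})

setMethod("show", "WindowWorkSamples", function(object) {
  cat(sprintf(
    "WindowWorkSamples: %d lambda windows at %.1f K, %d/%d fwd/rev samples in window 1\n",
    length(object@forward), object@temperature,
    length(object@forward[[1]]), length(object@reverse[[1]])))
})

setMethod("show", "FreeEnergyLeg", function(object) {
  cat(sprintf("FreeEnergyLeg '%s': dG = %.4g +/- %.3g kcal/mol over %d windows\n",
              object@label, object@dg, object@se, nrow(object@perWindow)))
})

setMethod("show", "ProtomerContributions", function(object) {
  cat(sprintf(
    "ProtomerContributions: total ddG = %.3g kcal/mol at %.0f K -> %.3g-fold (~%g)\n",
    object@totalDdg, object@temperature, object@foldChange,
    object@foldPowerOfTen))
})

setMethod("show", "ContactResult", function(object) {
  cat(sprintf(
    "ContactResult: %s vs %s, cutoff %.2f A: contact on %d/%d frames (%.1f%%)\n",
    object@selectionA, object@selectionB, object@cutoff,
    sum(object@perFrame), length(object@perFrame), 100 * object@fraction))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult (%s): %s, p = %.3g\n", object@branch,
              object@omnibusTest, object@omnibusP))
  if (nrow(object@pairwise)) {
    cat("Pairwise (adjusted):\n")
    print(object@pairwise, row.names = FALSE)
  }
})

setMethod("show", "DoseResponsePanel", function(object) {
  if (object@flagged) {
    cat("DoseResponsePanel: flagged fit (see @diagnostics)\n")
  } else {
    cat(sprintf(
      "DoseResponsePanel: IC50 = %.3g M, h = %.3g, floor = %.3g (%d concentrations)\n",
      object@ic50, object@hill, object@floor,
      length(object@concentrations)))
  }
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: CCL ratio %.3g, transient fold %.3g, ATP fold %.3g, contact %.2f, seed %d\n",
    object@effectRatioCcl, object@transientFold, object@atpFold,
    object@contactFractionTrue, object@seed))
})
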