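#' Accessors for the imaging and trace classes
#'
#' \code{timeStamps} returns the frame times in seconds; \code{pixelData} the
#' raw count array; \code{frameData} the 2-D frame array of a
#' \linkS4class{FrameSeries}; \code{irradiationTime} the time of laser
#' irradiation (time point A); \code{normalizedTrace} /
#' \code{correctedTrace} the normalised and background-corrected intensity
#' series of an \linkS4class{IntensityTrace}.
#'
#' @param object a \linkS4class{TimeLapseStack}, \linkS4class{FrameSeries} or
#'   \linkS4class{IntensityTrace}.
#' @return the requested component.
#' @name accessors
#' @aliases timeStamps pixelData frameData irradiationTime normalizedTrace
#'   correctedTrace
#' @examples
#' tb <- buildTimebase(3, 1, 5, 5)
#' stk <- TimeLapseStack(array(0, c(5, 1, 4, 4)), tb, irradiationTimeS = 2)
#' timeStamps(stk)
#' irradiationTime(stk)
NULL

#' @rdname accessors
#' @export
setGeneric("timeStamps", function(object) standardGeneric("timeStamps"))

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname accessors
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))

#' @rdname accessors
#' @export
setGeneric("irradiationTime", function(object) standardGeneric("irradiationTime"))

#' @rdname accessors
#' @export
setGeneric("normalizedTrace", function(object) standardGeneric("normalizedTrace"))

#' @rdname accessors
#' @export
setGeneric("correctedTrace", function(object) standardGeneric("correctedTrace"))

#' @rdname accessors
setMethod("timeStamps", "TimeLapseStack", function(object) object@timestamps)
#' @rdname accessors
setMethod("timeStamps", "FrameSeries", function(object) object@timestamps)
#' @rdname accessors
setMethod("timeStamps", "IntensityTrace", function(object) object@timestamps)
#' @rdname accessors
setMethod("pixelData", "TimeLapseStack", function(object) object@pixels)
#' @rdname accessors
setMethod("frameData", "FrameSeries", function(object) object@frames)
#' @rdname accessors
setMethod("irradiationTime", "TimeLapseStack", function(object) object@irradiationTimeS)
#' @rdname accessors
setMethod("irradiationTime", "FrameSeries", function(object) object@irradiationTimeS)
#' @rdname accessors
setMethod("irradiationTime", "IntensityTrace", function(object) object@irradiationTimeS)
#' @rdname accessors
setMethod("normalizedTrace", "IntensityTrace", function(object) object@normalized)
#' @rdname accessors
setMethod("correctedTrace", "IntensityTrace", function(object) object@corrected)

setMethod("show", "TimeLapseStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "TimeLapseStack: T=%d Z=%d %dx%d px | %.4g um/px | %d-bit | t = %.3g..%.3g s | irradiation at %.3g s\n",
    d[1], d[2], d[3], d[4], object@pixelSizeUm, object@bitDepth,
    object@timestamps[1], object@timestamps[length(object@timestamps)],
    object@irradiationTimeS
  ))
})

setMethod("show", "FrameSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameSeries (%s): T=%d %dx%d px | t = %.3g..%.3g s\n",
    object@provenance, d[1], d[2], d[3],
    object@timestamps[1], object@timestamps[length(object@timestamps)]
  ))
})

setMethod("show", "IntensityTrace", function(object) {
  n <- length(object@timestamps)
  pre <- sum(object@timestamps < object@irradiationTimeS)
  cat(sprintf(
    "IntensityTrace: %d time points (%d pre-irradiation) | peak normalised %.4g\n",
    n, pre, max(object@normalized)
  ))
})

setMethod("show", "PhasePoints", function(object) {
  cat(sprintf(
    "PhasePoints: A=%.4g B=%.4g C=%.4g D=%.4g E=%s s%s%s\n",
    object@tA, object@tB, object@tC, object@tD,
    if (is.na(object@tE)) "NA" else sprintf("%.4g", object@tE),
    if (isTRUE(object@tEExtrapolated)) " (E extrapolated)" else "",
    if (isTRUE(object@plateauPresent)) " [plateau]" else ""
  ))
})

setMethod("show", "TraceModel", function(object) {
  cat(sprintf(
    "TraceModel: deltaMax=%.4g kOn=%.4g/s kOff=%.4g/s tB=%.4g s tD=%.4g s\n",
    object@deltaMax, object@kOn, object@kOff, object@tB, object@tD
  ))
})

setMethod("show", "KineticParameters", function(object) {
  cat(sprintf(
    paste0("KineticParameters: lag=%.4g assoc=%.4g plateau=%.4g diss=%.4g ",
           "duration=%.4g s | kOn=%.4g kOff=%.4g /s | fold=%.4g%s\n"),
    object@lagTimeS, object@associationTimeS, object@plateauTimeS,
    object@dissociationTimeS, object@durationS, object@kOn, object@kOff,
    object@foldChange,
    if (length(object@flags)) paste0(" | flags: ", paste(object@flags, collapse = ",")) else ""
  ))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): F(%g, %g) = %.4g, p = %.4g\n",
              object@parameter, object@dfBetween, object@dfWithin,
              object@fStatistic, object@pValue))
  print(object@pairwise)
})
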