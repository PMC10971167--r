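#' @import methods
NULL

#' TimeLapseStack: a raw T x Z x Y x X acquisition
#'
#' Container for one laser micro-irradiation movie: camera counts indexed
#' \code{[t, z, y, x]}, per-frame timestamps in seconds (t = 0 at acquisition
#' start), the pixel size in micrometres, the camera bit depth, and the time
#' of laser irradiation (time point A of the kinetic analysis).
#'
#' @slot pixels numeric 4-D array \code{[t, z, y, x]} of camera counts.
#' @slot timestamps numeric vector of frame times in seconds, strictly
#'   increasing, one per time point.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot bitDepth camera bit depth; counts must lie in
#'   \code{[0, 2^bitDepth - 1]}.
#' @slot irradiationTimeS time of irradiation (seconds), inside the
#'   timestamp range.
#' @exportClass TimeLapseStack
setClass("TimeLapseStack",
  slots = c(
    pixels = "array",
    timestamps = "numeric",
    pixelSizeUm = "numeric",
    bitDepth = "integer",
    irradiationTimeS = "numeric"
  )
)

setValidity("TimeLapseStack", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 4L)
    msg <- c(msg, "pixels must be a 4-D [t, z, y, x] array")
  tt <- object@timestamps
  if (length(d) == 4L && length(tt) != d[1L])
    msg <- c(msg, "length(timestamps) must equal the number of time points")
  if (length(tt) > 1L && any(diff(tt) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  maxv <- 2^object@bitDepth - 1
  if (any(object@pixels < 0) || any(object@pixels > maxv))
    msg <- c(msg, sprintf("intensities must lie in [0, %d]", maxv))
  it <- object@irradiationTimeS
  if (length(tt) > 0L && (it < tt[1L] || it > tt[length(tt)]))
    msg <- c(msg, "irradiationTimeS must lie within the timestamp range")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})

#' FrameSeries: a 2-D frame sequence derived from a stack
#'
#' A T x Y x X series (for example the maximum-intensity projection of a
#' \linkS4class{TimeLapseStack}), carrying the source timestamps unchanged
#' and a provenance tag recording which corrections have been applied.
#'
#' @slot frames numeric 3-D array \code{[t, y, x]}.
#' @slot timestamps numeric vector, seconds, one per frame.
#' @slot provenance character tag, e.g. \code{"raw-MIP"}, \code{"registered"},
#'   \code{"bleach-corrected"}.
#' @slot irradiationTimeS irradiation time in seconds, carried along from the
#'   source stack.
#' @exportClass FrameSeries
setClass("FrameSeries",
  slots = c(
    frames = "array",
    timestamps = "numeric",
    provenance = "character",
    irradiationTimeS = "numeric"
  )
)

setValidity("FrameSeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D [t, y, x] array")
  if (length(d) == 3L && length(object@timestamps) != d[1L])
    msg <- c(msg, "length(timestamps) must equal the number of frames")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' DriftModel: per-frame lateral shifts from stack registration
#'
#' @slot shifts T x 2 matrix of (dy, dx) corrections in pixels; translating
#'   frame t by \code{shifts[t, ]} aligns it with the reference frame. The
#'   reference row is (0, 0).
#' @slot referenceIndex index of the reference frame.
#' @slot flagged logical vector; TRUE where the estimated shift exceeded
#'   \code{maxShiftPx} and was clamped.
#' @slot maxShiftPx the configured shift bound in pixels.
#' @exportClass DriftModel
setClass("DriftModel",
  slots = c(
    shifts = "matrix",
    referenceIndex = "integer",
    flagged = "logical",
    maxShiftPx = "numeric"
  )
)

setValidity("DriftModel", function(object) {
  msg <- character()
  if (ncol(object@shifts) != 2L)
    msg <- c(msg, "shifts must have two columns (dy, dx)")
  ri <- object@referenceIndex
  if (ri < 1L || ri > nrow(object@shifts))
    msg <- c(msg, "referenceIndex out of range")
  else if (any(object@shifts[ri, ] != 0))
    msg <- c(msg, "shift of the reference frame must be (0, 0)")
  if (any(abs(object@shifts) > object@maxShiftPx + 1e-9))
    msg <- c(msg, "shifts exceed maxShiftPx")
  if (length(object@flagged) != nrow(object@shifts))
    msg <- c(msg, "flagged must have one entry per frame")
  if (length(msg)) msg else TRUE
})

#' BleachModel: per-frame photobleaching normalisation
#'
#' Mono-exponential-plus-offset fit to the mean intensity of a control region
#' (nucleus excluding stripe and ring), or, as a fallback, per-frame ratio
#' factors. Dividing frame t by \code{factors[t]} undoes the bleaching.
#'
#' @slot form \code{"exponential"} or \code{"ratio"}.
#' @slot params named numeric (amplitude, rate, offset) for the exponential
#'   form; empty for ratio form.
#' @slot factors per-frame normalisation factors; \code{factors[1] == 1},
#'   all strictly positive.
#' @exportClass BleachModel
setClass("BleachModel",
  slots = c(
    form = "character",
    params = "numeric",
    factors = "numeric"
  )
)

setValidity("BleachModel", function(object) {
  msg <- character()
  if (!object@form %in% c("exponential", "ratio"))
    msg <- c(msg, "form must be 'exponential' or 'ratio'")
  f <- object@factors
  if (length(f) && abs(f[1L] - 1) > 1e-9)
    msg <- c(msg, "normalisation factor at the first frame must equal 1")
  if (any(f <= 0))
    msg <- c(msg, "factors must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' NucleusROI: one segmented nucleus
#'
#' @slot label integer id, stable across the movie.
#' @slot mask logical Y x X matrix.
#' @slot centroid numeric (y, x) in pixels.
#' @slot areaPx pixel count of the mask.
#' @exportClass NucleusROI
setClass("NucleusROI",
  slots = c(
    label = "integer",
    mask = "matrix",
    centroid = "numeric",
    areaPx = "integer"
  )
)

setValidity("NucleusROI", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (object@areaPx != sum(object@mask))
    msg <- c(msg, "areaPx must equal sum(mask)")
  if (length(msg)) msg else TRUE
})

#' DamageSiteROI: the laser stripe and its two-pixel background ring
#'
#' The stripe mask is the detected damage site within one nucleus; the ring
#' mask is the surrounding shell (default two pixels wide) clipped to the
#' nucleus, used as the local background estimate.
#'
#' @slot nucleusLabel label of the parent nucleus.
#' @slot siteMask logical Y x X matrix, subset of the nucleus mask.
#' @slot ringMask logical Y x X matrix, disjoint from the site, subset of the
#'   nucleus mask.
#' @slot stripeAxis unit vector (y, x) along the stripe's major axis.
#' @exportClass DamageSiteROI
setClass("DamageSiteROI",
  slots = c(
    nucleusLabel = "integer",
    siteMask = "matrix",
    ringMask = "matrix",
    stripeAxis = "numeric"
  )
)

setValidity("DamageSiteROI", function(object) {
  msg <- character()
  if (any(object@siteMask & object@ringMask))
    msg <- c(msg, "ring and site masks must be disjoint")
  if (!any(object@siteMask))
    msg <- c(msg, "site mask must be non-empty")
  if (!any(object@ringMask))
    msg <- c(msg, "ring mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' IntensityTrace: per-timepoint site and background intensities
#'
#' For one laser-irradiated cell: the mean intensity over the damage-site
#' mask and over the background ring per time point, the background-corrected
#' trace (site minus ring) and the normalised trace (corrected minus its
#' pre-irradiation mean, so the pre-irradiation baseline is zero).
#'
#' @slot timestamps seconds, strictly increasing.
#' @slot siteMean mean site intensity per time point.
#' @slot ringMean mean ring intensity per time point.
#' @slot corrected \code{siteMean - ringMean}.
#' @slot normalized \code{corrected} minus its pre-irradiation mean.
#' @slot irradiationTimeS irradiation time (time point A) in seconds.
#' @exportClass IntensityTrace
setClass("IntensityTrace",
  slots = c(
    timestamps = "numeric",
    siteMean = "numeric",
    ringMean = "numeric",
    corrected = "numeric",
    normalized = "numeric",
    irradiationTimeS = "numeric"
  )
)

setValidity("IntensityTrace", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (length(object@siteMean) != n || length(object@ringMean) != n ||
      length(object@corrected) != n || length(object@normalized) != n)
    msg <- c(msg, "all series must share the timestamp length")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  pre <- object@timestamps < object@irradiationTimeS
  if (any(pre)) {
    if (abs(mean(object@normalized[pre])) > 1e-9 * max(1, max(abs(object@corrected))))
      msg <- c(msg, "normalized trace must average to zero before irradiation")
  }
  if (length(msg)) msg else TRUE
})

#' PhasePoints: the five time points A-E of a recruitment trace
#'
#' A = irradiation, B = recruitment onset, C = end of recruitment,
#' D = dissociation onset, E = return to a pre-irradiation-like level.
#' Phase I (lag) = [A,B], II (association) = [B,C], III (plateau) = [C,D],
#' IV (dissociation) = [D,E]. \code{tE} may be NA with
#' \code{tEExtrapolated = TRUE} when E lies beyond the measured window and
#' must be extrapolated from the fitted dissociation rate.
#'
#' @slot tA,tB,tC,tD,tE seconds; ordered tA <= tB <= tC <= tD <= tE.
#' @slot tEExtrapolated TRUE when E was (or must be) extrapolated as the time
#'   at which 95\% of the dissociation has occurred.
#' @slot plateauPresent TRUE when the plateau phase [C,D] lasted at least the
#'   configured minimum duration.
#' @exportClass PhasePoints
setClass("PhasePoints",
  slots = c(
    tA = "numeric", tB = "numeric", tC = "numeric",
    tD = "numeric", tE = "numeric",
    tEExtrapolated = "logical",
    plateauPresent = "logical"
  )
)

setValidity("PhasePoints", function(object) {
  v <- c(object@tA, object@tB, object@tC, object@tD, object@tE)
  v <- v[!is.na(v)]
  if (length(v) > 1L && any(diff(v) < -1e-9))
    "phase points must be ordered tA <= tB <= tC <= tD <= tE"
  else TRUE
})

#' TraceModel: first-order association/dissociation recruitment model
#'
#' The normalised trace is modelled as 0 before onset tB, a mono-exponential
#' association \code{deltaMax * (1 - exp(-kOn (t - tB)))} until dissociation
#' onset tD, and a mono-exponential dissociation from the level reached at tD
#' with rate kOff afterwards. The curve is continuous at tB and tD.
#'
#' @slot baseline pre-onset level of the normalised trace (about 0).
#' @slot deltaMax association amplitude (normalised units), > 0.
#' @slot kOn association rate constant, 1/s.
#' @slot kOff dissociation rate constant, 1/s.
#' @slot tB recruitment onset, seconds.
#' @slot tD dissociation onset, seconds.
#' @slot plateauPresent whether the trace exhibits a plateau phase.
#' @exportClass TraceModel
setClass("TraceModel",
  slots = c(
    baseline = "numeric",
    deltaMax = "numeric",
    kOn = "numeric",
    kOff = "numeric",
    tB = "numeric",
    tD = "numeric",
    plateauPresent = "logical"
  ),
  prototype = prototype(baseline = 0, plateauPresent = TRUE)
)

setValidity("TraceModel", function(object) {
  msg <- character()
  if (!is.na(object@deltaMax) && object@deltaMax <= 0)
    msg <- c(msg, "deltaMax must be > 0")
  if (!is.na(object@kOn) && object@kOn <= 0)
    msg <- c(msg, "kOn must be > 0")
  if (!is.na(object@kOff) && object@kOff <= 0)
    msg <- c(msg, "kOff must be > 0")
  if (!any(is.na(c(object@tB, object@tD))) && object@tD < object@tB)
    msg <- c(msg, "tD must be >= tB")
  if (length(msg)) msg else TRUE
})

#' KineticParameters: the nine per-cell kinetic parameters
#'
#' Phase durations derived from the empirical phase points, rate constants
#' from the robust fit, and the intensity fold change at the damage site.
#' Duration (B to E) equals association + plateau + dissociation.
#'
#' @slot lagTimeS recruitment lag, A to B (s).
#' @slot associationTimeS association phase, B to C (s).
#' @slot plateauTimeS plateau phase, C to D (s).
#' @slot dissociationTimeS dissociation phase, D to E (s); NA when E is
#'   undefined (non-converged fit with E outside the window).
#' @slot durationS total engagement, B to E (s).
#' @slot kOn,kOff fitted rate constants (1/s); NA when the fit failed.
#' @slot foldChange (maximum site intensity - pre-irradiation site intensity)
#'   / pre-irradiation site intensity.
#' @slot plateauPresent whether a plateau phase was detected.
#' @slot flags character vector of quality flags (e.g. "fit-not-converged",
#'   "tE-extrapolated").
#' @exportClass KineticParameters
setClass("KineticParameters",
  slots = c(
    lagTimeS = "numeric",
    associationTimeS = "numeric",
    plateauTimeS = "numeric",
    dissociationTimeS = "numeric",
    durationS = "numeric",
    kOn = "numeric",
    kOff = "numeric",
    foldChange = "numeric",
    plateauPresent = "logical",
    flags = "character"
  )
)

setValidity("KineticParameters", function(object) {
  msg <- character()
  parts <- c(object@associationTimeS, object@plateauTimeS, object@dissociationTimeS)
  if (!any(is.na(parts)) && !is.na(object@durationS)) {
    if (abs(object@durationS - sum(parts)) > 1e-6)
      msg <- c(msg, "durationS must equal association + plateau + dissociation")
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: outcome of the robust non-linear trace fit
#'
#' @slot model the fitted \linkS4class{TraceModel}.
#' @slot residualScale robust residual scale (1.345 x MAD of the
#'   pre-irradiation noise) used for the Huber weights.
#' @slot converged TRUE when the optimiser reported convergence with all rate
#'   parameters inside the configured bounds.
#' @slot weights final per-point robust weights.
#' @exportClass FitResult
setClass("FitResult",
  slots = c(
    model = "TraceModel",
    residualScale = "numeric",
    converged = "logical",
    weights = "numeric"
  )
)

#' GroupComparison: one-way ANOVA with Tukey post hoc tests
#'
#' @slot parameter name of the compared kinetic parameter.
#' @slot fStatistic one-way ANOVA F.
#' @slot pValue ANOVA p value.
#' @slot dfBetween,dfWithin ANOVA degrees of freedom.
#' @slot pairwise data.frame with one row per group pair: difference of
#'   means, 95\% interval, Tukey-adjusted p value and a significance tier
#'   ("", "*", "**", "***" at 0.05 / 0.01 / 0.001).
#' @exportClass GroupComparison
setClass("GroupComparison",
  slots = c(
    parameter = "character",
    fStatistic = "numeric",
    pValue = "numeric",
    dfBetween = "numeric",
    dfWithin = "numeric",
    pairwise = "data.frame"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (nrow(object@pairwise)) {
    p <- object@pairwise$pAdjusted
    if (any(p < 0 | p > 1, na.rm = TRUE))
      msg <- c(msg, "Tukey adjusted p values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: forward-model parameters for synthetic movies
#'
#' Defaults mirror the acquisition geometry of the assay: 512 x 512 field at
#' 229.55 nm/pixel, 12-bit counts, a 12 um laser stripe (24 shots at 0.5 um
#' steps), a 1 fps then 0.2 fps frame schedule, and recruitment kinetics
#' with a 12.77 s lag, kOn = 0.05/s and kOff = 0.01/s. The irradiation time
#' defaults to 11 s so that the baseline holds eleven 1-fps frames, enough to
#' estimate the pre-irradiation noise level.
#'
#' @slot imageSizePx field edge length in pixels (square field).
#' @slot pixelSizeUm micrometres per pixel.
#' @slot bitDepth camera bit depth.
#' @slot nZ number of z planes per time point.
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusRadiusUm nucleus radius in micrometres.
#' @slot nucleusIntensity nuclear fluorescence above background (counts).
#' @slot backgroundIntensity camera background level (counts).
#' @slot stripeLengthUm laser cut length in micrometres.
#' @slot stripeWidthPx stripe width in pixels (Gaussian cross profile,
#'   sigma = width/2).
#' @slot nShots,shotStepUm discrete laser shot count and spacing, used when
#'   \code{discreteShots} is TRUE.
#' @slot discreteShots render the stripe as discrete shots instead of a
#'   continuous rectangle.
#' @slot lagS,kOn,kOff,tDAfterAS per-cell recruitment kinetics: lag (B - A,
#'   s), association and dissociation rates (1/s), dissociation onset
#'   relative to irradiation (s).
#' @slot foldChangeRange range of the per-cell intensity fold change at the
#'   stripe (uniformly sampled).
#' @slot recruitingProbability probability that a nucleus recruits.
#' @slot bleachRatePerS global photobleaching rate (1/s).
#' @slot driftPerFramePx per-frame (dy, dx) lateral drift in pixels.
#' @slot noiseGain scaled-Poisson gain (counts per photoelectron).
#' @slot readNoiseSd Gaussian read noise (counts).
#' @slot nFast,fastDtS,slowDtS,totalFrames frame schedule: number of fast
#'   intervals, fast and slow intervals (s), total frame count.
#' @slot irradiationTimeS irradiation time (s).
#' @slot seed RNG seed; identical seed + config give bit-identical output.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    imageSizePx = "integer",
    pixelSizeUm = "numeric",
    bitDepth = "integer",
    nZ = "integer",
    nNuclei = "integer",
    nucleusRadiusUm = "numeric",
    nucleusIntensity = "numeric",
    backgroundIntensity = "numeric",
    stripeLengthUm = "numeric",
    stripeWidthPx = "numeric",
    nShots = "integer",
    shotStepUm = "numeric",
    discreteShots = "logical",
    lagS = "numeric",
    kOn = "numeric",
    kOff = "numeric",
    tDAfterAS = "numeric",
    foldChangeRange = "numeric",
    recruitingProbability = "numeric",
    bleachRatePerS = "numeric",
    driftPerFramePx = "numeric",
    noiseGain = "numeric",
    readNoiseSd = "numeric",
    nFast = "integer",
    fastDtS = "numeric",
    slowDtS = "numeric",
    totalFrames = "integer",
    irradiationTimeS = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p <- object@recruitingProbability
  if (p < 0 || p > 1)
    msg <- c(msg, "recruitingProbability must lie in [0, 1]")
  pos <- c(
    imageSizePx = object@imageSizePx, pixelSizeUm = object@pixelSizeUm,
    nucleusRadiusUm = object@nucleusRadiusUm,
    stripeLengthUm = object@stripeLengthUm,
    stripeWidthPx = object@stripeWidthPx,
    fastDtS = object@fastDtS, slowDtS = object@slowDtS,
    kOn = object@kOn, kOff = object@kOff
  )
  bad <- names(pos)[pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("must be positive: ", paste(bad, collapse = ", ")))
  if (any(object@foldChangeRange < 0) || diff(object@foldChangeRange) < 0)
    msg <- c(msg, "foldChangeRange must be a non-decreasing non-negative pair")
  if (object@bleachRatePerS < 0)
    msg <- c(msg, "bleachRatePerS must be >= 0")
  if (length(msg)) msg else TRUE
})
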