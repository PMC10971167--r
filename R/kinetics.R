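## Four-phase kinetic analysis of a recruiting trace: empirical phase points
## A-E from the smoothed trace, robust non-linear fit of the first-order
## association/dissociation model, and the nine per-cell parameters.

#' Construct a TraceModel
#'
#' @param deltaMax association amplitude (normalised units).
#' @param kOn,kOff association and dissociation rate constants (1/s).
#' @param tB recruitment onset (s).
#' @param tD dissociation onset (s).
#' @param baseline pre-onset level (default 0).
#' @param plateauPresent plateau flag (default TRUE).
#' @return a validated \linkS4class{TraceModel}.
#' @export
#' @examples
#' m <- TraceModel(deltaMax = 1, kOn = 0.05, kOff = 0.01, tB = 13, tD = 200)
#' plot(defaultTimebase(), modelCurve(m, defaultTimebase()), type = "l")
TraceModel <- function(deltaMax, kOn, kOff, tB, tD, baseline = 0,
                       plateauPresent = TRUE) {
  new("TraceModel", baseline = baseline, deltaMax = deltaMax, kOn = kOn,
      kOff = kOff, tB = tB, tD = tD, plateauPresent = plateauPresent)
}

#' Evaluate the recruitment model curve
#'
#' Piecewise first-order kinetics: 0 before onset tB, mono-exponential
#' association towards \code{deltaMax} until dissociation onset tD,
#' mono-exponential decay of the level reached at tD afterwards. The curve
#' is continuous at tB and tD.
#'
#' @param model a \linkS4class{TraceModel}.
#' @param timestamps evaluation times (seconds).
#' @return normalised intensities, one per timestamp.
#' @export
modelCurve <- function(model, timestamps) {
  stopifnot(is(model, "TraceModel"))
  .modelCurve(timestamps, model@tB, model@tD, model@deltaMax, model@kOn,
              model@kOff, model@baseline)
}

.modelCurve <- function(tt, tB, tD, deltaMax, kOn, kOff, baseline = 0) {
  y <- numeric(length(tt))
  rise <- tt >= tB & tt < tD
  y[rise] <- deltaMax * (1 - exp(-kOn * (tt[rise] - tB)))
  ampD <- deltaMax * (1 - exp(-kOn * (tD - tB)))
  fall <- tt >= tD
  y[fall] <- ampD * exp(-kOff * (tt[fall] - tD))
  y + baseline
}

#' Centred moving average
#'
#' Index-space smoothing used by the phase-point detector; window edges use
#' the available samples, so the output has the input length.
#'
#' @param x numeric vector.
#' @param window odd window length in samples (default 5).
#' @return smoothed vector of the same length.
#' @export
movingAverage <- function(x, window = 5L) {
  n <- length(x)
  h <- (as.integer(window) - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect the phase points A-E of a recruiting trace
#'
#' Empirical changepoint detection on the smoothed normalised trace:
#' \itemize{
#'   \item \strong{A}: the configured irradiation time.
#'   \item \strong{B} (onset): the first post-A run of at least 3
#'     consecutive smoothed samples above \code{kSigma} pre-irradiation SDs
#'     marks the detection; the onset itself is then refined by backtracking
#'     to where the smoothed trace last sat at the baseline noise level, so
#'     that the reported lag is not biased by the rise time to threshold.
#'   \item Plateau level P: median of the smoothed trace over the interval
#'     where a doubly smoothed copy stays within 2\% of its maximum.
#'   \item \strong{C}: first time the monotone (isotonic) fit of the rising
#'     segment reaches \code{peakFraction} of P (linearly interpolated).
#'   \item \strong{D}: last time the antitonic fit of the falling segment
#'     still holds \code{peakFraction} of P.
#'   \item Plateau: present when D - C >= \code{plateauMinS}; otherwise C
#'     and D collapse to the peak time.
#'   \item \strong{E}: first time after D below \code{1 - peakFraction} of
#'     P; if the trace never returns that far within the window, tE is NA
#'     with \code{tEExtrapolated = TRUE} and is later filled in from the
#'     fitted dissociation rate (see \code{\link{extrapolateE}}).
#' }
#'
#' @param trace an \linkS4class{IntensityTrace} classified as recruiting,
#'   with at least 5 pre-irradiation samples.
#' @param smoothWindow moving-average window in samples (default 5).
#' @param kSigma onset detection threshold in pre-irradiation SDs
#'   (default 3).
#' @param peakFraction fraction of the plateau level defining C and D, and
#'   (as \code{1 - peakFraction}) the return level defining E
#'   (default 0.95).
#' @param plateauMinS minimum plateau duration in seconds (default 10).
#' @return a \linkS4class{PhasePoints}. Signals a condition of class
#'   \code{"notRecruitingError"} when no onset is found.
#' @export
detectPhasePoints <- function(trace, smoothWindow = 5L, kSigma = 3,
                              peakFraction = 0.95, plateauMinS = 10,
                              onsetBacktrackSigma = 1.5) {
  stopifnot(is(trace, "IntensityTrace"))
  tt <- trace@timestamps
  tA <- trace@irradiationTimeS
  pre <- tt < tA
  if (sum(pre) < 5L)
    stop("phase detection requires at least 5 pre-irradiation samples")
  y <- trace@normalized
  s <- movingAverage(y, smoothWindow)
  ds <- movingAverage(s, smoothWindow)
  sigmaPre <- stats::sd(y[pre])
  sigmaPreSm <- stats::sd(s[pre])

  ## --- B: threshold crossing (run of 3), then backtrack to baseline ---
  postIdx <- which(!pre)
  above <- s[postIdx] > kSigma * sigmaPre
  runStart <- .firstRunStart(above, 3L)
  if (is.na(runStart)) {
    cond <- structure(
      class = c("notRecruitingError", "error", "condition"),
      list(message = "no recruitment onset found", call = sys.call(-1)))
    stop(cond)
  }
  cross <- postIdx[runStart]
  j <- cross
  while (j > 1L && s[j - 1L] > onsetBacktrackSigma * sigmaPreSm) j <- j - 1L
  tB <- max(tA, tt[min(j, length(tt))])

  ## --- plateau level P ---
  ## Top band: contiguous interval where the doubly smoothed trace stays
  ## within 2% of its maximum. P is the mean of the singly smoothed trace
  ## over the second half of that interval: the first half still carries
  ## the tail of the rise, while a mean over the interior is unbiased under
  ## noise (a max- or quantile-based level would inflate with noise and
  ## push the 95% crossing late).
  peakIdx <- which.max(ds)
  band <- which(ds >= 0.98 * ds[peakIdx])
  bandIdx <- seq(min(band), max(band))
  half <- bandIdx[bandIdx >= bandIdx[1L] + (length(bandIdx) - 1L) / 2]
  P <- mean(s[half])
  if (!is.finite(P) || P <= 0)
    P <- max(ds)
  thrC <- peakFraction * P

  ## --- C: rise to peakFraction * P ---
  ## The trace approaches its plateau asymptotically, so the direct 95%
  ## crossing sits where the slope is almost zero and any level noise
  ## translates into tens of seconds. Instead the 50% and 75% crossings of
  ## the isotonic (monotone) fit of the rising segment - where the trace is
  ## steep and the crossings well conditioned - are located and mapped to
  ## the 95% time under first-order association kinetics:
  ## t95 = t50 + ln(10)/k with k = ln(2)/(t75 - t50). On a noiseless
  ## first-order trace this is exact.
  idxB <- which(tt >= tB)[1L]
  riseIdx <- idxB:peakIdx
  tC <- tt[peakIdx]
  if (length(riseIdx) >= 2L) {
    iso <- stats::isoreg(tt[riseIdx], y[riseIdx])$yf
    t50 <- .firstCrossingUp(tt[riseIdx], iso, 0.50 * P, fallback = NA_real_)
    t75 <- .firstCrossingUp(tt[riseIdx], iso, 0.75 * P, fallback = NA_real_)
    if (is.finite(t50) && is.finite(t75) && t75 > t50) {
      kHat <- log(2) / (t75 - t50)
      ## t_p - t50 = (log(1/(1-p)) - log(2))/k; log(10)/k for p = 0.95
      tC <- t50 + (log(1 / (1 - peakFraction)) - log(2)) / kHat
    } else {
      tC <- .firstCrossingUp(tt[riseIdx], iso, thrC, fallback = tt[peakIdx])
    }
  }
  tC <- min(max(tC, tB), tt[peakIdx])

  ## --- D: antitonic decay still holding peakFraction * P ---
  fallIdx <- peakIdx:length(tt)
  tD <- tt[peakIdx]
  anti <- NULL
  if (length(fallIdx) >= 2L) {
    anti <- rev(stats::isoreg(seq_along(fallIdx), rev(y[fallIdx]))$yf)
    tD <- .lastCrossingDown(tt[fallIdx], anti, thrC, fallback = tt[length(tt)])
  }
  tD <- max(tD, tC)

  plateauPresent <- (tD - tC) >= plateauMinS
  if (!plateauPresent) {
    tC <- tD <- tt[peakIdx]
    tC <- max(tB, tC)
    tD <- max(tB, tD)
  }

  ## --- E: first return below (1 - peakFraction) * P after D ---
  thrE <- (1 - peakFraction) * P
  tE <- NA_real_
  extrapolated <- TRUE
  if (!is.null(anti)) {
    after <- which(tt[fallIdx] > tD & anti < thrE)
    if (length(after)) {
      tE <- tt[fallIdx][after[1L]]
      extrapolated <- FALSE
    }
  }
  new("PhasePoints", tA = tA, tB = tB, tC = tC, tD = tD, tE = tE,
      tEExtrapolated = extrapolated, plateauPresent = plateauPresent)
}

## index of the first element starting a run of `len` TRUEs, or NA
.firstRunStart <- function(x, len) {
  if (length(x) < len) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

## linearly interpolated first upward crossing of a non-decreasing curve
.firstCrossingUp <- function(tt, yy, thr, fallback) {
  k <- which(yy >= thr)
  if (!length(k)) return(fallback)
  k <- k[1L]
  if (k == 1L) return(tt[1L])
  dy <- yy[k] - yy[k - 1L]
  if (dy <= 0) return(tt[k])
  tt[k - 1L] + (thr - yy[k - 1L]) / dy * (tt[k] - tt[k - 1L])
}

## linearly interpolated last time a non-increasing curve is still >= thr
.lastCrossingDown <- function(tt, yy, thr, fallback) {
  k <- which(yy >= thr)
  if (!length(k)) return(tt[1L])
  k <- k[length(k)]
  if (k == length(yy)) return(fallback)
  dy <- yy[k + 1L] - yy[k]
  if (dy >= 0) return(tt[k])
  tt[k] + (thr - yy[k]) / dy * (tt[k + 1L] - tt[k])
}

#' Robust non-linear fit of the recruitment model
#'
#' Fits the \linkS4class{TraceModel} to the normalised trace by
#' Levenberg-Marquardt least squares with iteratively reweighted Huber
#' weights (a soft-L1 loss); the residual scale is 1.345 times the MAD of
#' the pre-irradiation noise. Start values come from the empirical phase
#' points: tB and tD as detected, kOn = 3/(tC - tB), kOff = 3/(dissociation
#' span), deltaMax = observed peak. Rates are bounded to [1e-5, 10] 1/s.
#' Non-convergence is reported, not raised: downstream parameters then rely
#' on the empirical points alone.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param points the trace's \linkS4class{PhasePoints}.
#' @param rateBounds lower/upper bounds for both rates (1/s).
#' @param maxIrwls number of reweighting iterations (default 3).
#' @return a \linkS4class{FitResult}.
#' @export
fitKinetics <- function(trace, points, rateBounds = c(1e-5, 10),
                        maxIrwls = 3L) {
  stopifnot(is(trace, "IntensityTrace"), is(points, "PhasePoints"))
  tt <- trace@timestamps
  y <- trace@normalized
  pre <- tt < trace@irradiationTimeS
  scale <- 1.345 * stats::mad(y[pre])

  tA <- points@tA
  tEnd <- tt[length(tt)]
  assoc <- max(points@tC - points@tB, tt[2L] - tt[1L])
  dissSpan <- if (!is.na(points@tE)) points@tE - points@tD else tEnd - points@tD
  dissSpan <- max(dissSpan, diff(range(tt)) / (length(tt) - 1L))
  start <- c(
    tB = points@tB,
    tD = max(points@tD, points@tB + 1e-3),
    deltaMax = max(max(y), 1e-6),
    kOn = min(max(3 / assoc, rateBounds[1L]), rateBounds[2L]),
    kOff = min(max(3 / dissSpan, rateBounds[1L]), rateBounds[2L])
  )
  lower <- c(tB = tA, tD = points@tB, deltaMax = 1e-8,
             kOn = rateBounds[1L], kOff = rateBounds[1L])
  upper <- c(tB = points@tC + 1e-6, tD = tEnd, deltaMax = 4 * max(abs(y)),
             kOn = rateBounds[2L], kOff = rateBounds[2L])
  start <- pmin(pmax(start, lower), upper)

  w <- rep(1, length(y))
  fitPar <- start
  converged <- FALSE
  for (it in seq_len(max(1L, maxIrwls))) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = fitPar,
        fn = function(p) {
          sqrt(w) * (y - .modelCurve(tt, p[["tB"]], p[["tD"]], p[["deltaMax"]],
                                     p[["kOn"]], p[["kOff"]]))
        },
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) break
    fitPar <- stats::coef(res)
    converged <- res$info %in% c(1L, 2L, 3L, 4L)
    if (scale > 0) {
      r <- y - .modelCurve(tt, fitPar[["tB"]], fitPar[["tD"]],
                           fitPar[["deltaMax"]], fitPar[["kOn"]],
                           fitPar[["kOff"]])
      u <- abs(r) / scale
      w <- ifelse(u <= 1, 1, 1 / u)  # Huber psi(u)/u
    } else {
      break  # noiseless: plain least squares, no reweighting needed
    }
  }
  converged <- converged &&
    all(fitPar[c("kOn", "kOff")] >= rateBounds[1L]) &&
    all(fitPar[c("kOn", "kOff")] <= rateBounds[2L]) &&
    fitPar[["deltaMax"]] > 0
  model <- new("TraceModel", baseline = 0,
               deltaMax = unname(fitPar[["deltaMax"]]),
               kOn = unname(fitPar[["kOn"]]), kOff = unname(fitPar[["kOff"]]),
               tB = unname(fitPar[["tB"]]), tD = unname(fitPar[["tD"]]),
               plateauPresent = points@plateauPresent)
  new("FitResult", model = model, residualScale = scale,
      converged = converged, weights = w)
}

#' Extrapolate the end of dissociation (point E)
#'
#' When the trace has not returned to a pre-irradiation-like level within
#' the measured window, E is extrapolated as the time at which 95\% of the
#' dissociation has occurred under the fitted exponential decay:
#' \code{tE = tD + ln(20)/kOff}.
#'
#' @param fit a converged \linkS4class{FitResult}.
#' @param points the trace's \linkS4class{PhasePoints}.
#' @return tE in seconds, or NA when the fit did not converge or kOff is
#'   not positive.
#' @export
#' @examples
#' # kOff = 0.01/s, tD = 200 s -> tE about 499.57 s
#' log(20) / 0.01 + 200
extrapolateE <- function(fit, points) {
  stopifnot(is(fit, "FitResult"), is(points, "PhasePoints"))
  if (!is.na(points@tE) && !points@tEExtrapolated)
    return(points@tE)  # observed within the window; keep it
  if (!isTRUE(fit@converged) || !is.finite(fit@model@kOff) ||
      fit@model@kOff <= 0)
    return(NA_real_)
  points@tD + log(20) / fit@model@kOff
}

#' Compute the nine kinetic parameters of a recruiting cell
#'
#' Phase durations from the empirical points (lag = B - A, association =
#' C - B, plateau = D - C, dissociation = E - D, duration = E - B), rate
#' constants from the robust fit, and the intensity fold change at the
#' damage site. When E lies outside the window it is extrapolated from the
#' fitted kOff; if that is impossible (non-converged fit), the
#' dissociation-dependent parameters are NA and flagged.
#'
#' @param trace the \linkS4class{IntensityTrace}.
#' @param points the \linkS4class{PhasePoints}.
#' @param fit the \linkS4class{FitResult} (may be non-converged).
#' @param intensityMode fold-change intensity mode, see
#'   \code{\link{foldChange}}.
#' @return a \linkS4class{KineticParameters}.
#' @export
computeParameters <- function(trace, points, fit,
                              intensityMode = c("raw", "corrected")) {
  stopifnot(is(trace, "IntensityTrace"), is(points, "PhasePoints"),
            is(fit, "FitResult"))
  intensityMode <- match.arg(intensityMode)
  flags <- character()
  tE <- points@tE
  if (is.na(tE) || points@tEExtrapolated) {
    tE <- extrapolateE(fit, points)
    if (is.na(tE))
      flags <- c(flags, "tE-undefined")
    else
      flags <- c(flags, "tE-extrapolated")
  }
  if (!isTRUE(fit@converged))
    flags <- c(flags, "fit-not-converged")
  fc <- foldChange(trace, intensityMode = intensityMode)
  if (is.na(fc))
    flags <- c(flags, "fold-change-undefined")
  diss <- if (is.na(tE)) NA_real_ else tE - points@tD
  dur <- if (is.na(tE)) NA_real_ else tE - points@tB
  kOn <- if (isTRUE(fit@converged)) fit@model@kOn else NA_real_
  kOff <- if (isTRUE(fit@converged)) fit@model@kOff else NA_real_
  new("KineticParameters",
      lagTimeS = points@tB - points@tA,
      associationTimeS = points@tC - points@tB,
      plateauTimeS = points@tD - points@tC,
      dissociationTimeS = diss,
      durationS = dur,
      kOn = kOn, kOff = kOff, foldChange = fc,
      plateauPresent = points@plateauPresent,
      flags = flags)
}
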