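## Translation-only drift registration and photobleaching correction.
## Registration uses FFT cross-correlation against a reference frame with
## parabolic sub-pixel refinement; applied shifts are rounded to whole
## pixels, out-of-field pixels are filled with the frame's median.

#' Register frames against a reference (drift correction)
#'
#' Estimates a per-frame lateral translation by cross-correlating each frame
#' with the reference frame (FFT phase space, parabolic sub-pixel peak
#' refinement) and translates each frame so the image content aligns with
#' the reference. Rotation and scaling are not modelled; the assay only
#' requires compensation of lateral stage/cell movement. Estimated shifts
#' larger than \code{maxShiftPx} (e.g. on structureless noise frames) are
#' clamped and flagged.
#'
#' @param series a \linkS4class{FrameSeries} with at least 2 frames.
#' @param referenceIndex index of the reference frame (default 1, the first
#'   pre-irradiation frame).
#' @param maxShiftPx maximum plausible |shift| per axis in pixels
#'   (default 20).
#' @return a list with \code{series} (the registered
#'   \linkS4class{FrameSeries}, provenance \code{"registered"}) and
#'   \code{drift} (a \linkS4class{DriftModel} whose rows are the applied
#'   (dy, dx) corrections).
#' @export
#' @examples
#' f <- array(rep(matrix(rnorm(64 * 64), 64), 3), c(64, 64, 3))
#' f <- aperm(f, c(3, 1, 2))
#' s <- FrameSeries(f, 0:2, irradiationTimeS = 1)
#' registerFrames(s)$drift@shifts
registerFrames <- function(series, referenceIndex = 1L, maxShiftPx = 20) {
  stopifnot(is(series, "FrameSeries"))
  d <- dim(series@frames)
  nT <- d[1L]
  if (nT < 2L)
    stop("registration requires at least 2 frames")
  referenceIndex <- as.integer(referenceIndex)
  if (referenceIndex < 1L || referenceIndex > nT)
    stop("referenceIndex out of range")

  ref <- matrix(series@frames[referenceIndex, , ], d[2L], d[3L])
  refC <- ref - mean(ref)
  fRef <- stats::fft(refC)

  shifts <- matrix(0, nT, 2L, dimnames = list(NULL, c("dy", "dx")))
  flagged <- logical(nT)
  out <- series@frames
  for (t in seq_len(nT)) {
    if (t == referenceIndex) next
    fr <- matrix(series@frames[t, , ], d[2L], d[3L])
    est <- .xcorrShift(fRef, fr - mean(fr))
    corr <- -est  # translate the frame by the negated displacement
    if (any(abs(corr) > maxShiftPx)) {
      flagged[t] <- TRUE
      corr <- pmin(pmax(corr, -maxShiftPx), maxShiftPx)
    }
    shifts[t, ] <- corr
    ci <- round(corr)
    if (any(ci != 0))
      out[t, , ] <- .translate(fr, ci[1L], ci[2L], fill = stats::median(fr))
  }
  list(
    series = FrameSeries(out, series@timestamps, provenance = "registered",
                         irradiationTimeS = series@irradiationTimeS),
    drift = new("DriftModel", shifts = shifts,
                referenceIndex = referenceIndex, flagged = flagged,
                maxShiftPx = maxShiftPx)
  )
}

## Displacement (dy, dx) of `frame` relative to the reference whose FFT is
## fRef, via the cross-correlation peak with parabolic sub-pixel refinement.
.xcorrShift <- function(fRef, frame) {
  ny <- nrow(frame); nx <- ncol(frame)
  cc <- Re(stats::fft(fRef * Conj(stats::fft(frame)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  ## circular lag at the peak, mapped to the symmetric range
  lag <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- lag(pk[1L], ny)
  dx <- lag(pk[2L], nx)
  ## parabolic refinement on the wrapped neighbours
  refine <- function(i, n, at) {
    c0 <- cc[at(i)]
    cm <- cc[at((i - 2) %% n + 1)]
    cp <- cc[at(i %% n + 1)]
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  dy <- dy + refine(pk[1L], ny, function(i) cbind(i, pk[2L]))
  dx <- dx + refine(pk[2L], nx, function(j) cbind(pk[1L], j))
  ## fft-based correlation finds the shift of ref relative to frame with
  ## this conjugation order; negate to report frame-relative-to-ref
  -c(dy, dx)
}

## Integer translation with constant fill.
.translate <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  okY <- ys >= 1 & ys <= ny
  okX <- xs >= 1 & xs <= nx
  out[which(okY), which(okX)] <- m[ys[okY], xs[okX]]
  out
}

#' Estimate photobleaching from a control region
#'
#' Fits the mean intensity of an undamaged control region (typically the
#' nucleus excluding the stripe and its background ring) over time with a
#' mono-exponential plus offset, \eqn{I(t) = A e^{-kt} + C}, the standard
#' photophysics model for slow acquisition bleaching. Per-frame
#' normalisation factors are \code{fitted(t)/fitted(t0)}. If the fit fails
#' or fewer than 5 frames are available, the model falls back to ratio
#' normalisation (observed control mean over its first-frame value).
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param controlMask logical Y x X matrix selecting control pixels
#'   (non-empty, excluding the damage stripe).
#' @return a \linkS4class{BleachModel}.
#' @export
estimateBleaching <- function(series, controlMask) {
  stopifnot(is(series, "FrameSeries"))
  if (!any(controlMask))
    stop("control mask is empty")
  d <- dim(series@frames)
  idx <- which(controlMask)
  y <- vapply(seq_len(d[1L]), function(t)
    mean(matrix(series@frames[t, , ], d[2L], d[3L])[idx]), numeric(1))
  if (any(y <= 0) || mean(y) <= 0)
    stop("control region mean must be positive to estimate bleaching")
  tt <- series@timestamps

  ratioModel <- function() {
    new("BleachModel", form = "ratio", params = numeric(),
        factors = y / y[1L])
  }
  if (length(y) < 5L)
    return(ratioModel())

  span <- max(tt) - min(tt)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = max(y[1L] - min(y), 1e-3 * y[1L]), k = 1 / span,
              C = min(y)),
      fn = function(p) y - (p[["A"]] * exp(-p[["k"]] * tt) + p[["C"]]),
      lower = c(A = 0, k = 0, C = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% c(1L, 2L, 3L, 4L))
    return(ratioModel())
  p <- stats::coef(fit)
  fitted0 <- p[["A"]] * exp(-p[["k"]] * tt) + p[["C"]]
  if (any(fitted0 <= 0))
    return(ratioModel())
  new("BleachModel", form = "exponential",
      params = c(amplitude = p[["A"]], rate = p[["k"]], offset = p[["C"]]),
      factors = fitted0 / fitted0[1L])
}

#' Apply a bleaching correction to a frame series
#'
#' Divides frame t by the model's normalisation factor for frame t; the
#' first frame is unchanged (its factor is 1 by construction).
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param model a \linkS4class{BleachModel} with one factor per frame.
#' @return the corrected \linkS4class{FrameSeries}, provenance
#'   \code{"bleach-corrected"}.
#' @export
correctBleaching <- function(series, model) {
  stopifnot(is(series, "FrameSeries"), is(model, "BleachModel"))
  d <- dim(series@frames)
  if (length(model@factors) != d[1L])
    stop("model must define one factor per frame")
  out <- series@frames / model@factors  # recycles over t (first dimension)
  FrameSeries(out, series@timestamps, provenance = "bleach-corrected",
              irradiationTimeS = series@irradiationTimeS)
}
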