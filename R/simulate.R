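## Forward model: synthetic traces and synthetic movies with full ground
## truth. Scene geometry mirrors the acquisition: nuclear-localised
## fluorescence, a 12 um linear irradiation stripe, global exponential
## photobleaching, rigid lateral drift, scaled-Poisson + Gaussian camera
## noise, and quantisation to the camera bit depth.

#' Construct a simulation configuration
#'
#' All arguments default to the study conditions of the assay; see
#' \linkS4class{SimulationConfig} for the meaning and defaults of each
#' field. Identical configuration and seed give bit-identical output.
#'
#' @param imageSizePx field edge length (default 512).
#' @param pixelSizeUm micrometres per pixel (default 0.22955).
#' @param bitDepth camera bit depth (default 12).
#' @param nZ z planes per time point (default 1).
#' @param nNuclei nuclei to place (default 5).
#' @param nucleusRadiusUm nucleus radius (default 7 um).
#' @param nucleusIntensity nuclear fluorescence above background
#'   (default 300 counts).
#' @param backgroundIntensity camera background (default 50 counts).
#' @param stripeLengthUm stripe length (default 12 um).
#' @param stripeWidthPx stripe width (default 3 px).
#' @param nShots,shotStepUm,discreteShots discrete-shot rendering
#'   (default 24 shots at 0.5 um, off).
#' @param lagS recruitment lag B - A (default 12.77 s).
#' @param kOn association rate (default 0.05 /s).
#' @param kOff dissociation rate (default 0.01 /s).
#' @param tDAfterAS dissociation onset after irradiation (default 199 s).
#' @param foldChangeRange per-cell fold-change range (default c(1, 1)).
#' @param recruitingProbability per-cell recruitment probability
#'   (default 0.72).
#' @param bleachRatePerS photobleaching rate (default 2e-4 /s).
#' @param driftPerFramePx per-frame (dy, dx) drift (default c(0.02, 0.01)).
#' @param noiseGain scaled-Poisson gain (default 1 count/e-).
#' @param readNoiseSd Gaussian read noise (default 3 counts).
#' @param nFast,fastDtS,slowDtS,totalFrames frame schedule (default 120
#'   fast 1 s intervals then 5 s intervals, 217 frames: 0-600 s).
#' @param irradiationTimeS irradiation time (default 11 s, leaving eleven
#'   1-fps baseline frames).
#' @param seed RNG seed (default 1).
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(imageSizePx = 512L, pixelSizeUm = 0.22955,
                             bitDepth = 12L, nZ = 1L, nNuclei = 5L,
                             nucleusRadiusUm = 7, nucleusIntensity = 300,
                             backgroundIntensity = 50, stripeLengthUm = 12,
                             stripeWidthPx = 3, nShots = 24L,
                             shotStepUm = 0.5, discreteShots = FALSE,
                             lagS = 12.77, kOn = 0.05, kOff = 0.01,
                             tDAfterAS = 199, foldChangeRange = c(1, 1),
                             recruitingProbability = 0.72,
                             bleachRatePerS = 2e-4,
                             driftPerFramePx = c(0.02, 0.01),
                             noiseGain = 1, readNoiseSd = 3,
                             nFast = 120L, fastDtS = 1, slowDtS = 5,
                             totalFrames = 217L, irradiationTimeS = 11,
                             seed = 1L) {
  new("SimulationConfig",
      imageSizePx = as.integer(imageSizePx), pixelSizeUm = pixelSizeUm,
      bitDepth = as.integer(bitDepth), nZ = as.integer(nZ),
      nNuclei = as.integer(nNuclei), nucleusRadiusUm = nucleusRadiusUm,
      nucleusIntensity = nucleusIntensity,
      backgroundIntensity = backgroundIntensity,
      stripeLengthUm = stripeLengthUm, stripeWidthPx = stripeWidthPx,
      nShots = as.integer(nShots), shotStepUm = shotStepUm,
      discreteShots = discreteShots, lagS = lagS, kOn = kOn, kOff = kOff,
      tDAfterAS = tDAfterAS, foldChangeRange = foldChangeRange,
      recruitingProbability = recruitingProbability,
      bleachRatePerS = bleachRatePerS, driftPerFramePx = driftPerFramePx,
      noiseGain = noiseGain, readNoiseSd = readNoiseSd,
      nFast = as.integer(nFast), fastDtS = fastDtS, slowDtS = slowDtS,
      totalFrames = as.integer(totalFrames),
      irradiationTimeS = irradiationTimeS, seed = as.integer(seed))
}

#' Single-nucleus configuration for per-cell simulations
#'
#' Convenience wrapper: one centred nucleus on a small field, used for
#' per-cell benchmark movies where only one cell is irradiated per movie.
#'
#' @param imageSizePx field edge length (default 128).
#' @param ... further arguments to \code{\link{simulationConfig}}.
#' @return a \linkS4class{SimulationConfig}.
#' @export
singleNucleusConfig <- function(imageSizePx = 128L, ...) {
  simulationConfig(imageSizePx = imageSizePx, nNuclei = 1L, ...)
}

#' Simulate an intensity trace with known kinetics
#'
#' Synthesises the site and ring channels of one recruiting cell: the ring
#' holds the constant nucleoplasm level, the site holds that level plus the
#' model curve scaled to the requested intensity fold change, plus i.i.d.
#' Gaussian noise. The returned normalised trace equals
#' \code{modelCurve + noise} (re-centred on the pre-irradiation mean, as in
#' measurement); with \code{noiseSigma = 0} it equals the model curve
#' exactly.
#'
#' @param model a \linkS4class{TraceModel} (the ground truth).
#' @param timestamps frame times in seconds.
#' @param noiseSigma Gaussian noise SD in normalised units (default 0.05).
#' @param seed RNG seed, or NULL to use the current RNG state.
#' @param irradiationTimeS irradiation time (default 11 s); must not exceed
#'   the model's tB.
#' @param foldChange target intensity fold change at the site (default 1).
#' @return an \linkS4class{IntensityTrace}.
#' @export
#' @examples
#' m <- TraceModel(deltaMax = 1, kOn = 0.05, kOff = 0.01,
#'                 tB = 11 + 12.77, tD = 11 + 199)
#' tr <- simulateTrace(m, defaultTimebase(), noiseSigma = 0.05, seed = 1)
#' tr
simulateTrace <- function(model, timestamps, noiseSigma = 0.05, seed = NULL,
                          irradiationTimeS = 11, foldChange = 1) {
  stopifnot(is(model, "TraceModel"))
  if (model@tB < irradiationTimeS)
    stop("model onset tB precedes the irradiation time")
  if (!is.null(seed))
    set.seed(seed)
  curve <- modelCurve(model, timestamps)
  siteBase <- model@deltaMax / foldChange  # nucleoplasm level at the site
  noise <- if (noiseSigma > 0)
    stats::rnorm(length(timestamps), 0, noiseSigma) else 0
  site <- siteBase + curve + noise
  ring <- rep(siteBase, length(timestamps))
  newIntensityTrace(as.numeric(timestamps), site, ring, irradiationTimeS)
}

#' Simulate a full time-lapse movie with ground truth
#'
#' Renders disk nuclei with nuclear fluorescence on a dark background,
#' injects a linear recruitment stripe (Gaussian cross profile, or discrete
#' laser shots) into each recruiting nucleus with intensity following that
#' cell's \linkS4class{TraceModel}, applies global exponential bleaching,
#' cumulative rigid drift, scaled-Poisson plus Gaussian read noise, and
#' quantises to the camera bit depth.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a list with \code{stack} (a \linkS4class{TimeLapseStack}) and
#'   \code{truth}: per-nucleus recruiting flags, ground-truth
#'   \linkS4class{TraceModel}s, nucleus and stripe masks (unshifted scene
#'   coordinates), stripe amplitudes in counts, target fold changes, the
#'   fraction of clipped (saturated) pixels, and the echoed configuration.
#' @export
simulateStack <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  n <- config@imageSizePx
  tt <- buildTimebase(config@nFast, config@fastDtS, config@slowDtS,
                      config@totalFrames)
  tA <- config@irradiationTimeS
  rPx <- config@nucleusRadiusUm / config@pixelSizeUm

  ## --- nucleus placement (bounded retries, non-overlapping) ---
  margin <- rPx + 2
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < config@nNuclei && tries < 200L * config@nNuclei) {
    tries <- tries + 1L
    if (config@nNuclei == 1L) {
      cand <- c(n / 2, n / 2)  # single-nucleus movies: centred cell
    } else {
      cand <- stats::runif(2, margin, n - margin)
    }
    if (margin > n - margin)
      break
    if (!nrow(centers) ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2))) > 2 * rPx + 4)
      centers <- rbind(centers, cand)
  }
  nNuc <- nrow(centers)
  if (nNuc < config@nNuclei)
    message("simulateStack: placed ", nNuc, " of ", config@nNuclei, " nuclei")

  ys <- matrix(seq_len(n), n, n)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)

  ## --- static scene maps ---
  nucMaps <- vector("list", nNuc)
  stripeProfiles <- vector("list", nNuc)
  stripeMasks <- vector("list", nNuc)
  models <- vector("list", nNuc)
  recruiting <- logical(nNuc)
  folds <- numeric(nNuc)
  amps <- numeric(nNuc)
  preSiteLevel <- config@backgroundIntensity + config@nucleusIntensity
  lenPx <- config@stripeLengthUm / config@pixelSizeUm
  sigma <- config@stripeWidthPx / 2

  for (i in seq_len(nNuc)) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]
    dist <- sqrt((ys - cy)^2 + (xs - cx)^2)
    nucMaps[[i]] <- pmin(pmax(rPx - dist + 0.5, 0), 1)  # 1-px soft edge
    recruiting[i] <- stats::runif(1) < config@recruitingProbability
    folds[i] <- stats::runif(1, config@foldChangeRange[1L],
                             config@foldChangeRange[2L])
    theta <- stats::runif(1, 0, pi)
    u <- (ys - cy) * sin(theta) + (xs - cx) * cos(theta)
    v <- -(ys - cy) * cos(theta) + (xs - cx) * sin(theta)
    if (config@discreteShots) {
      stepPx <- config@shotStepUm / config@pixelSizeUm
      offs <- (seq_len(config@nShots) - (config@nShots + 1) / 2) * stepPx
      prof <- 0
      for (o in offs)
        prof <- pmax(prof, exp(-((u - o)^2 + v^2) / (2 * sigma^2)))
    } else {
      prof <- exp(-v^2 / (2 * sigma^2)) * (abs(u) <= lenPx / 2)
    }
    stripeProfiles[[i]] <- prof
    stripeMasks[[i]] <- prof >= 0.5
    models[[i]] <- TraceModel(deltaMax = 1, kOn = config@kOn,
                              kOff = config@kOff, tB = tA + config@lagS,
                              tD = tA + config@tDAfterAS)
    meanProf <- mean(prof[stripeMasks[[i]]])
    amps[i] <- if (recruiting[i]) folds[i] * preSiteLevel / meanProf else 0
  }

  curves <- vapply(models, modelCurve, numeric(length(tt)),
                   timestamps = tt)  # T x nNuc

  ## --- per-frame rendering ---
  maxCount <- 2^config@bitDepth - 1
  zmid <- (config@nZ + 1) / 2
  zw <- if (config@nZ == 1L) 1 else
    exp(-((seq_len(config@nZ) - zmid) / max(config@nZ / 4, 0.5))^2 / 2)
  px <- array(0, dim = c(length(tt), config@nZ, n, n))
  clipped <- 0
  for (t in seq_along(tt)) {
    fluor <- matrix(0, n, n)
    for (i in seq_len(nNuc)) {
      fluor <- fluor + config@nucleusIntensity * nucMaps[[i]]
      if (recruiting[i] && curves[t, i] > 0)
        fluor <- fluor + amps[i] * curves[t, i] * stripeProfiles[[i]] *
          (nucMaps[[i]] > 0)
    }
    fluor <- fluor * exp(-config@bleachRatePerS * tt[t])
    shift <- (t - 1L) * config@driftPerFramePx
    if (any(shift != 0))
      fluor <- .shiftBilinear(fluor, shift[1L], shift[2L], fill = 0)
    for (z in seq_len(config@nZ)) {
      lambda <- config@backgroundIntensity + zw[z] * fluor
      counts <- config@noiseGain *
        stats::rpois(n * n, lambda / config@noiseGain) +
        stats::rnorm(n * n, 0, config@readNoiseSd)
      counts <- round(counts)
      clipped <- clipped + sum(counts > maxCount)
      px[t, z, , ] <- matrix(pmin(pmax(counts, 0), maxCount), n, n)
    }
  }

  stack <- TimeLapseStack(px, tt, pixelSizeUm = config@pixelSizeUm,
                          bitDepth = config@bitDepth,
                          irradiationTimeS = tA)
  truth <- list(
    recruiting = recruiting,
    models = models,
    nucleusCenters = centers,
    nucleusMasks = lapply(nucMaps, function(m) m >= 0.5),
    stripeMasks = stripeMasks,
    stripeAmplitudes = amps,
    foldChanges = folds,
    clippedFraction = clipped / (length(tt) * config@nZ * n * n),
    config = config
  )
  list(stack = stack, truth = truth)
}

## bilinear shift of a matrix by (dy, dx); out-of-field pixels get `fill`
.shiftBilinear <- function(m, dy, dx, fill = 0) {
  iy <- floor(dy); fy <- dy - iy
  ix <- floor(dx); fx <- dx - ix
  s <- function(a, b) .translate(m, a, b, fill = fill)
  (1 - fy) * (1 - fx) * s(iy, ix) +
    (1 - fy) * fx * s(iy, ix + 1) +
    fy * (1 - fx) * s(iy + 1, ix) +
    fy * fx * s(iy + 1, ix + 1)
}

#' Serialise simulation ground truth to JSON
#'
#' Writes the scalar and per-nucleus ground truth (recruiting flags, model
#' parameters, amplitudes, fold changes, clipped fraction) next to a
#' simulated stack for audit; masks are summarised by their pixel counts.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{simulateStack}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  models <- lapply(truth$models, function(m)
    list(deltaMax = m@deltaMax, kOn = m@kOn, kOff = m@kOff,
         tB = m@tB, tD = m@tD))
  jsonlite::write_json(list(
    recruiting = truth$recruiting,
    models = models,
    nucleusCenters = truth$nucleusCenters,
    stripeAreasPx = vapply(truth$stripeMasks, sum, numeric(1)),
    stripeAmplitudes = truth$stripeAmplitudes,
    foldChanges = truth$foldChanges,
    clippedFraction = truth$clippedFraction
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
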