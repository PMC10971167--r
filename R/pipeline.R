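## End-to-end orchestration: MIP -> registration -> nucleus segmentation ->
## stripe detection -> per-nucleus bleaching correction -> trace measurement
## -> classification -> phase points -> robust fit -> parameters.

#' Analyse one movie end to end
#'
#' Runs the full workflow on one \linkS4class{TimeLapseStack} and returns a
#' per-cell record for every segmented nucleus, recruiting or not. Stage
#' order is fixed: maximum-intensity projection, drift registration,
#' nucleus segmentation on the time-averaged pre-irradiation frame, stripe
#' detection on the post-minus-pre difference, per-nucleus bleaching
#' estimation from the nucleus excluding stripe and ring, trace
#' measurement, recruitment classification, phase-point detection, robust
#' model fit, parameter computation. A failure in one cell is recorded in
#' that cell's flags and does not abort the remaining cells.
#'
#' @param stack a \linkS4class{TimeLapseStack}.
#' @param experimentId,cellModel labels copied into the records.
#' @param maxShiftPx registration shift bound (default 20).
#' @param segmentArgs,detectArgs,classifyArgs named lists of extra
#'   arguments for \code{\link{segmentNuclei}},
#'   \code{\link{detectDamageSite}} and \code{\link{classifyRecruitment}}.
#' @param bleachCorrection apply per-nucleus bleaching correction
#'   (default TRUE).
#' @param intensityMode fold-change intensity mode (see
#'   \code{\link{foldChange}}).
#' @return a list with \code{records} (the per-cell data.frame of
#'   \code{\link{cellRecords}}), \code{traces}, \code{rois}, \code{points},
#'   \code{fits}, \code{nuclei}, \code{drift} and \code{bleach} (per-cell
#'   details; NULL where a stage did not run).
#' @export
analyzeStack <- function(stack, experimentId = "exp1", cellModel = "model1",
                         maxShiftPx = 20, segmentArgs = list(),
                         detectArgs = list(), classifyArgs = list(),
                         bleachCorrection = TRUE,
                         intensityMode = c("raw", "corrected")) {
  stopifnot(is(stack, "TimeLapseStack"))
  intensityMode <- match.arg(intensityMode)
  mip <- maxProject(stack)
  reg <- registerFrames(mip, maxShiftPx = maxShiftPx)
  series <- reg$series
  tt <- series@timestamps
  tA <- series@irradiationTimeS
  preIdx <- which(tt < tA)
  d <- dim(series@frames)
  preMean <- matrix(0, d[2L], d[3L])
  for (t in preIdx) preMean <- preMean + series@frames[t, , ]
  preMean <- preMean / length(preIdx)

  nuclei <- do.call(segmentNuclei, c(list(preMean), segmentArgs))
  nCells <- length(nuclei)
  out <- list(records = NULL, traces = vector("list", nCells),
              rois = vector("list", nCells),
              points = vector("list", nCells),
              fits = vector("list", nCells), nuclei = nuclei,
              drift = reg$drift, bleach = vector("list", nCells))
  if (!nCells) {
    out$records <- cellRecords(character(), character(), character(),
                               logical(), list())
    return(out)
  }

  recruiting <- logical(nCells)
  params <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    roi <- tryCatch(
      do.call(detectDamageSite, c(list(series, nuclei[[i]]), detectArgs)),
      error = function(e) NULL
    )
    out$rois[[i]] <- roi
    if (is.null(roi)) {
      params[[i]] <- NA
      next
    }
    trace <- measureTrace(series, roi)
    if (bleachCorrection) {
      control <- nuclei[[i]]@mask & !roi@siteMask & !roi@ringMask
      bleach <- tryCatch(estimateBleaching(series, control),
                         error = function(e) NULL)
      if (!is.null(bleach)) {
        out$bleach[[i]] <- bleach
        f <- bleach@factors
        trace <- newIntensityTrace(tt, trace@siteMean / f,
                                   trace@ringMean / f, tA)
      }
    }
    out$traces[[i]] <- trace
    rec <- tryCatch(
      do.call(classifyRecruitment,
              c(list(trace, intensityMode = intensityMode), classifyArgs)),
      error = function(e) FALSE
    )
    if (!rec) {
      params[[i]] <- NA
      next
    }
    pts <- tryCatch(detectPhasePoints(trace), error = function(e) e)
    if (inherits(pts, "notRecruitingError")) {
      params[[i]] <- NA
      next
    }
    if (inherits(pts, "error")) {
      params[[i]] <- NA
      next
    }
    recruiting[i] <- TRUE
    out$points[[i]] <- pts
    fit <- fitKinetics(trace, pts)
    out$fits[[i]] <- fit
    params[[i]] <- computeParameters(trace, pts, fit,
                                     intensityMode = intensityMode)
  }
  out$records <- cellRecords(
    cellModel = rep(cellModel, nCells),
    experimentId = rep(experimentId, nCells),
    cellId = vapply(nuclei, function(x) as.character(x@label), character(1)),
    recruiting = recruiting,
    parameters = params
  )
  out
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (or read) -> preprocess -> detect -> fit -> cohort
#' and writes reproducible outputs: the per-cell CSV, per-cell fit reports
#' (JSON), cohort summary CSVs, group comparisons and a machine-readable
#' run report with per-stage counts and the echoed configuration. A rerun
#' with the identical configuration and seed produces identical numeric
#' outputs.
#'
#' @param config a named list with either \code{input} (list of TIFF/YAML
#'   path pairs: \code{path}, \code{metadata}) or \code{simulate} (a
#'   \linkS4class{SimulationConfig} or list of them, one per movie);
#'   optional \code{experimentId}, \code{cellModel} (recycled over movies),
#'   \code{seed} (applied to simulation configs lacking one),
#'   \code{analyzeArgs} (passed on to \code{\link{analyzeStack}}), and
#'   \code{compareBy} (parameter names for group comparisons when several
#'   cell models are present).
#' @param outDir output directory, created if needed; NULL skips writing.
#' @return invisibly, a list with \code{records}, \code{fractions},
#'   \code{plateau}, \code{comparisons} and \code{report}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(is.list(config))
  simCfgs <- config$simulate
  if (is(simCfgs, "SimulationConfig"))
    simCfgs <- list(simCfgs)
  inputs <- config$input
  if (!is.null(inputs) && !is.null(inputs$path))
    inputs <- list(inputs)
  nMovies <- if (!is.null(simCfgs)) length(simCfgs) else length(inputs)
  if (!nMovies)
    stop("config must supply 'simulate' configurations or 'input' paths")
  if (!is.null(inputs)) {
    missing <- vapply(inputs, function(x) !file.exists(x$path), logical(1))
    if (any(missing))
      stop("input file(s) not found: ",
           paste(vapply(inputs[missing], `[[`, "", "path"), collapse = ", "))
  }
  expIds <- rep_len(config$experimentId %||% "exp1", nMovies)
  modelsLab <- rep_len(config$cellModel %||% "model1", nMovies)

  allRecords <- vector("list", nMovies)
  details <- vector("list", nMovies)
  for (m in seq_len(nMovies)) {
    if (!is.null(simCfgs)) {
      cfg <- simCfgs[[m]]
      if (!is.null(config$seed))
        cfg@seed <- as.integer(config$seed + m - 1L)
      stack <- simulateStack(cfg)$stack
    } else {
      stack <- readStack(inputs[[m]]$path, inputs[[m]]$metadata)
    }
    res <- do.call(analyzeStack,
                   c(list(stack, experimentId = expIds[m],
                          cellModel = modelsLab[m]),
                     config$analyzeArgs %||% list()))
    res$records$movieId <- m
    res$records$cellId <- paste0("m", m, "c", res$records$cellId)
    allRecords[[m]] <- res$records
    details[[m]] <- res
  }
  records <- do.call(rbind, allRecords)
  if (!nrow(records))
    stop("empty final cohort: no nuclei found in any movie")

  fractions <- recruitingFraction(records)
  plateau <- vapply(split(records, records$cellModel), function(r) {
    if (any(r$recruiting)) plateauFraction(r) else NA_real_
  }, numeric(1))

  comparisons <- list()
  compareBy <- config$compareBy %||% character()
  for (p in compareBy) {
    ok <- tryCatch(
      compareGroups(records[[p]], records$cellModel, parameter = p),
      error = function(e) NULL
    )
    if (!is.null(ok)) comparisons[[p]] <- ok
  }

  report <- list(
    nMovies = nMovies,
    nCells = nrow(records),
    nRecruiting = sum(records$recruiting),
    seed = config$seed %||% NA,
    stageOrder = c("maxProject", "registerFrames", "segmentNuclei",
                   "detectDamageSite", "estimateBleaching", "measureTrace",
                   "classifyRecruitment", "detectPhasePoints", "fitKinetics",
                   "computeParameters", "cohort")
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(outDir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(fractions, file.path(outDir, "recruiting_fraction.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    for (m in seq_len(nMovies))
      writeCellReports(details[[m]], outDir, prefix = paste0("movie", m))
    for (p in names(comparisons))
      utils::write.csv(comparisons[[p]]@pairwise,
                       file.path(outDir, paste0("tukey_", p, ".csv")),
                       row.names = FALSE)
  }
  invisible(list(records = records, fractions = fractions,
                 plateau = plateau, comparisons = comparisons,
                 report = report, details = details))
}

#' Write per-cell audit artifacts for one analysed movie
#'
#' Serialises the per-cell results of \code{\link{analyzeStack}} for audit:
#' a JSON fit report per recruiting cell (phase points, fitted model,
#' convergence, flags, bleach model), the drift model, and label-image
#' TIFFs of the nucleus masks and of the site/ring masks (pixel value =
#' nucleus label; site = label, ring = label + 0.5, scaled into the 16-bit
#' TIFF range).
#'
#' @param analysis the list returned by \code{\link{analyzeStack}}.
#' @param dir output directory, created if needed.
#' @param prefix filename prefix (default \code{"movie"}).
#' @return invisibly, the paths written.
#' @export
writeCellReports <- function(analysis, dir, prefix = "movie") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  ## drift model
  driftPath <- file.path(dir, paste0(prefix, "_drift.json"))
  jsonlite::write_json(list(
    shifts = analysis$drift@shifts,
    referenceIndex = analysis$drift@referenceIndex,
    flagged = analysis$drift@flagged
  ), driftPath, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, driftPath)
  ## per-cell fit reports
  for (i in seq_along(analysis$nuclei)) {
    pts <- analysis$points[[i]]
    if (is.null(pts)) next
    fit <- analysis$fits[[i]]
    bleach <- analysis$bleach[[i]]
    p <- file.path(dir, paste0(prefix, "_cell", analysis$nuclei[[i]]@label,
                               "_fit.json"))
    jsonlite::write_json(list(
      phasePoints = list(tA = pts@tA, tB = pts@tB, tC = pts@tC, tD = pts@tD,
                         tE = pts@tE, tEExtrapolated = pts@tEExtrapolated,
                         plateauPresent = pts@plateauPresent),
      model = if (!is.null(fit)) list(
        deltaMax = fit@model@deltaMax, kOn = fit@model@kOn,
        kOff = fit@model@kOff, tB = fit@model@tB, tD = fit@model@tD,
        converged = fit@converged, residualScale = fit@residualScale),
      bleach = if (!is.null(bleach)) list(
        form = bleach@form, params = as.list(bleach@params))
    ), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  ## label-image masks
  if (length(analysis$nuclei)) {
    dims <- dim(analysis$nuclei[[1L]]@mask)
    nucLab <- matrix(0, dims[1L], dims[2L])
    roiLab <- matrix(0, dims[1L], dims[2L])
    for (i in seq_along(analysis$nuclei)) {
      lab <- analysis$nuclei[[i]]@label
      nucLab[analysis$nuclei[[i]]@mask] <- lab
      roi <- analysis$rois[[i]]
      if (!is.null(roi)) {
        roiLab[roi@ringMask] <- lab + 0.5
        roiLab[roi@siteMask] <- lab
      }
    }
    scale <- max(1, max(nucLab), max(roiLab))
    nucPath <- file.path(dir, paste0(prefix, "_nuclei.tif"))
    roiPath <- file.path(dir, paste0(prefix, "_sites.tif"))
    tiff::writeTIFF(nucLab / scale, nucPath, bits.per.sample = 16L)
    tiff::writeTIFF(roiLab / scale, roiPath, bits.per.sample = 16L)
    paths <- c(paths, nucPath, roiPath)
  }
  invisible(paths)
}

#' Export an intensity trace as a tidy data.frame
#'
#' One row per time point with the site, ring, corrected and normalised
#' series, ready for CSV export or plotting.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param fit optional \linkS4class{FitResult}; adds the modelled curve.
#' @return a data.frame.
#' @export
traceTable <- function(trace, fit = NULL) {
  df <- data.frame(
    timeS = trace@timestamps,
    siteMean = trace@siteMean,
    ringMean = trace@ringMean,
    corrected = trace@corrected,
    normalized = trace@normalized
  )
  if (!is.null(fit))
    df$model <- modelCurve(fit@model, trace@timestamps)
  df
}
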