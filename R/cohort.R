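## Cohort aggregation: per-cell records -> per-model summaries and one-way
## ANOVA with Tukey post hoc comparisons. Records are plain data.frames
## with one row per irradiated cell (see cellRecords()).

#' Assemble a per-cell record table
#'
#' Builds the tidy per-cell table the cohort statistics operate on: one row
#' per irradiated cell with its cell model, experiment (replicate) id,
#' recruiting flag and, for recruiting cells, the nine kinetic parameters.
#'
#' @param cellModel character vector, e.g. "hiPSC", "NPC", "MN".
#' @param experimentId replicate tag.
#' @param cellId per-cell identifier.
#' @param recruiting logical.
#' @param parameters list of \linkS4class{KineticParameters} or NA for
#'   non-recruiting cells.
#' @return data.frame with columns cellModel, experimentId, cellId,
#'   recruiting, plateauPresent, lagTimeS, associationTimeS, plateauTimeS,
#'   dissociationTimeS, durationS, kOn, kOff, foldChange, flags.
#' @export
cellRecords <- function(cellModel, experimentId, cellId, recruiting,
                        parameters) {
  n <- length(cellModel)
  stopifnot(length(experimentId) == n, length(cellId) == n,
            length(recruiting) == n, length(parameters) == n)
  num <- function(get) vapply(seq_len(n), function(i) {
    p <- parameters[[i]]
    if (is(p, "KineticParameters")) get(p) else NA_real_
  }, numeric(1))
  data.frame(
    cellModel = as.character(cellModel),
    experimentId = as.character(experimentId),
    cellId = as.character(cellId),
    recruiting = as.logical(recruiting),
    plateauPresent = vapply(seq_len(n), function(i) {
      p <- parameters[[i]]
      if (is(p, "KineticParameters")) p@plateauPresent else NA
    }, logical(1)),
    lagTimeS = num(function(p) p@lagTimeS),
    associationTimeS = num(function(p) p@associationTimeS),
    plateauTimeS = num(function(p) p@plateauTimeS),
    dissociationTimeS = num(function(p) p@dissociationTimeS),
    durationS = num(function(p) p@durationS),
    kOn = num(function(p) p@kOn),
    kOff = num(function(p) p@kOff),
    foldChange = num(function(p) p@foldChange),
    flags = vapply(seq_len(n), function(i) {
      p <- parameters[[i]]
      if (is(p, "KineticParameters")) paste(p@flags, collapse = ";") else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Recruiting fraction per cell model
#'
#' Within each experiment, the fraction of irradiated cells classified as
#' recruiting (in percent); per model, the mean and SEM of those per-
#' experiment fractions. Experiments without irradiated cells are excluded
#' with a warning. With a single experiment the SEM is reported as 0.
#'
#' @param records a per-cell data.frame with columns \code{cellModel},
#'   \code{experimentId} and \code{recruiting} (see \code{\link{cellRecords}}).
#' @return data.frame with columns cellModel, nExperiments, nCells,
#'   meanPct, semPct.
#' @export
#' @examples
#' rec <- data.frame(cellModel = "hiPSC",
#'                   experimentId = rep(c("e1", "e2", "e3"), each = 100),
#'                   recruiting = c(rep(c(TRUE, FALSE), c(65, 35)),
#'                                  rep(c(TRUE, FALSE), c(72, 28)),
#'                                  rep(c(TRUE, FALSE), c(79, 21))))
#' recruitingFraction(rec)  # mean 72, SEM 4.04
recruitingFraction <- function(records) {
  stopifnot(all(c("cellModel", "experimentId", "recruiting") %in%
                names(records)))
  if (!nrow(records)) {
    warning("no records; nothing to summarise")
    return(data.frame(cellModel = character(), nExperiments = integer(),
                      nCells = integer(), meanPct = numeric(),
                      semPct = numeric()))
  }
  split1 <- split(records, records$cellModel)
  out <- lapply(names(split1), function(modelName) {
    rm <- split1[[modelName]]
    fr <- vapply(split(rm$recruiting, rm$experimentId), function(x) {
      if (!length(x)) NA_real_ else 100 * mean(x)
    }, numeric(1))
    fr <- fr[!is.na(fr)]
    if (!length(fr)) {
      warning("cell model ", modelName, " has no usable experiments; excluded")
      return(NULL)
    }
    sem <- if (length(fr) > 1L) stats::sd(fr) / sqrt(length(fr)) else 0
    data.frame(cellModel = modelName, nExperiments = length(fr),
               nCells = nrow(rm), meanPct = mean(fr), semPct = sem,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Plateaued fraction among recruiting cells
#'
#' Percentage of recruiting cells that exhibited a plateau phase; the
#' denominator is the number of recruiting cells, not of all irradiated
#' cells.
#'
#' @param records per-cell data.frame with columns \code{recruiting} and
#'   \code{plateauPresent}.
#' @return percentage in [0, 100], or NA (with a warning) when no cell
#'   recruited.
#' @export
plateauFraction <- function(records) {
  stopifnot(all(c("recruiting", "plateauPresent") %in% names(records)))
  rec <- records[records$recruiting %in% TRUE, , drop = FALSE]
  if (!nrow(rec)) {
    warning("no recruiting cells; plateaued fraction undefined")
    return(NA_real_)
  }
  100 * mean(rec$plateauPresent %in% TRUE)
}

#' Per-model parameter summary
#'
#' Mean, SEM and n of each kinetic parameter per cell model, over recruiting
#' cells; missing values (non-converged fits, undefined tE) are excluded
#' pairwise per parameter and the remaining counts reported.
#'
#' @param records per-cell data.frame (see \code{\link{cellRecords}}).
#' @param parameters which parameter columns to summarise.
#' @return data.frame with columns cellModel, parameter, n, mean, sem.
#' @export
summarizeParameters <- function(records,
                                parameters = c("lagTimeS", "associationTimeS",
                                               "plateauTimeS",
                                               "dissociationTimeS",
                                               "durationS", "kOn", "kOff",
                                               "foldChange")) {
  rec <- records[records$recruiting %in% TRUE, , drop = FALSE]
  out <- expand.grid(cellModel = unique(rec$cellModel),
                     parameter = parameters, stringsAsFactors = FALSE)
  stat <- t(mapply(function(m, p) {
    v <- rec[[p]][rec$cellModel == m]
    v <- v[is.finite(v)]
    n <- length(v)
    c(n = n, mean = if (n) mean(v) else NA_real_,
      sem = if (n > 1L) stats::sd(v) / sqrt(n) else if (n == 1L) 0 else NA_real_)
  }, out$cellModel, out$parameter))
  cbind(out, as.data.frame(stat))
}

#' Compare a kinetic parameter across cell models
#'
#' Classical one-way ANOVA followed by Tukey honestly-significant-difference
#' post hoc tests on all group pairs (Tukey-Kramer for unbalanced groups),
#' with significance tiers *, **, *** at adjusted p < 0.05, 0.01, 0.001.
#' When every group is constant and all means coincide, F is reported as 0
#' and all pairwise adjusted p as 1 (no difference).
#'
#' @param values numeric vector of per-cell parameter values.
#' @param groups factor or character vector of cell-model labels, same
#'   length as \code{values}.
#' @param parameter name used for reporting (default
#'   \code{"parameter"}).
#' @param alpha family-wise level for the Tukey intervals (default 0.05).
#' @return a \linkS4class{GroupComparison}.
#' @export
#' @examples
#' cmp <- compareGroups(c(1, 2, 3, 1, 2, 3, 11, 12, 13),
#'                      rep(c("a", "b", "c"), each = 3))
#' cmp
compareGroups <- function(values, groups, parameter = "parameter",
                          alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  counts <- table(groups)
  if (nlevels(groups) < 2L)
    stop("group comparison requires at least 2 groups")
  if (any(counts < 2L))
    stop("every group needs at least 2 values")

  tiers <- function(p) {
    ifelse(is.na(p), "",
           ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                  ifelse(p < 0.05, "*", ""))))
  }
  pairNames <- utils::combn(levels(groups), 2L,
                            function(x) paste(x[2L], x[1L], sep = "-"))

  if (stats::var(values) < .Machine$double.eps * max(1, mean(values)^2)) {
    pw <- data.frame(pair = pairNames, difference = 0, lower = 0, upper = 0,
                     pAdjusted = 1, significance = "",
                     stringsAsFactors = FALSE)
    return(new("GroupComparison", parameter = parameter, fStatistic = 0,
               pValue = 1, dfBetween = nlevels(groups) - 1,
               dfWithin = length(values) - nlevels(groups), pairwise = pw))
  }

  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  fStat <- an$`F value`[1L]
  pVal <- an$`Pr(>F)`[1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pw <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                   lower = tk[, "lwr"], upper = tk[, "upr"],
                   pAdjusted = tk[, "p adj"],
                   significance = tiers(tk[, "p adj"]),
                   stringsAsFactors = FALSE, row.names = NULL)
  new("GroupComparison", parameter = parameter, fStatistic = fStat,
      pValue = pVal, dfBetween = an$Df[1L], dfWithin = an$Df[2L],
      pairwise = pw)
}
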