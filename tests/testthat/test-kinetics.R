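test_that("model curve is piecewise exponential and continuous", {
  m <- TraceModel(deltaMax = 1.3, kOn = 0.05, kOff = 0.01, tB = 24, tD = 210)
  ## pre-onset: identically zero
  expect_equal(modelCurve(m, seq(0, 23.9, by = 0.5)),
               rep(0, length(seq(0, 23.9, by = 0.5))))
  ## full dissociation limit
  expect_lt(modelCurve(m, 1e5), 1e-12)
  ## continuity at tB and tD (one-sided limits)
  eps <- 1e-9
  expect_lt(abs(modelCurve(m, 24 - eps) - modelCurve(m, 24 + eps)), 1e-9)
  expect_lt(abs(modelCurve(m, 210 - eps) - modelCurve(m, 210 + eps)), 1e-9)
})

test_that("phase points on a noiseless trace match the closed-form curve", {
  ## generated with tA = 11, tB = 23, kOn = 0.05, tD = 210, kOff = 0.01
  tr <- makeTrace(lagS = 12, kOn = 0.05, kOff = 0.01, tDAfterAS = 199,
                  noiseSigma = 0)
  p <- detectPhasePoints(tr)
  expect_equal(p@tA, 11)
  expect_lte(abs(p@tB - 23), 1)                       # within one sample
  expect_lte(abs(p@tC - (23 + log(20) / 0.05)), 1)    # 95%-of-peak time
  expect_true(p@plateauPresent)
  expect_lte(abs(p@tD - (210 + log(0.9999 / 0.95) / 0.01)), 5.5)
  expect_false(p@tEExtrapolated)
  expect_lte(abs(p@tE - (210 + log(20) / 0.01)), 6)
})

test_that("a triangular rise-fall trace has no plateau and tC = tD", {
  tb <- defaultTimebase()
  ## fast dissociation right after the peak: no flat top
  tr <- makeTrace(kOn = 0.08, kOff = 0.05, tDAfterAS = 40, noiseSigma = 0)
  p <- detectPhasePoints(tr)
  expect_false(p@plateauPresent)
  expect_identical(p@tC, p@tD)
})

test_that("a trace still high at the window end is flagged for extrapolation", {
  ## kOff so slow that the trace sits near peak at 600 s
  tr <- makeTrace(kOn = 0.05, kOff = 1e-4, tDAfterAS = 300, noiseSigma = 0)
  p <- detectPhasePoints(tr)
  expect_true(p@tEExtrapolated)
  expect_true(is.na(p@tE))
  f <- fitKinetics(tr, p)
  tE <- extrapolateE(f, p)
  expect_true(is.finite(tE))
  expect_gt(tE, 600)
})

test_that("a non-recruiting trace signals notRecruitingError", {
  tr <- makeTrace(deltaMax = 1e-6, noiseSigma = 0.05, seed = 9)
  expect_error(detectPhasePoints(tr), class = "notRecruitingError")
})

test_that("robust fit recovers noiseless generative parameters to 1e-3", {
  tr <- makeTrace(lagS = 12, kOn = 0.05, kOff = 0.01, tDAfterAS = 199,
                  noiseSigma = 0)
  p <- detectPhasePoints(tr)
  f <- fitKinetics(tr, p)
  expect_true(f@converged)
  expect_equal(f@model@kOn, 0.05, tolerance = 1e-3)
  expect_equal(f@model@kOff, 0.01, tolerance = 1e-3)
  expect_equal(f@model@deltaMax, 1, tolerance = 1e-3)
  expect_equal(f@model@tB, 23, tolerance = 1e-3)
  expect_equal(f@model@tD, 210, tolerance = 1e-3)
})

test_that("mean fitted kOn over noisy replicates is within 10% of truth", {
  kOns <- vapply(1:20, function(i) {
    tr <- makeTrace(noiseSigma = 0.05, seed = 100 + i)
    p <- detectPhasePoints(tr)
    fitKinetics(tr, p)@model@kOn
  }, numeric(1))
  expect_equal(mean(kOns), 0.05, tolerance = 0.1)
})

test_that("the robust loss keeps outlier frames from distorting the fit", {
  tr <- makeTrace(noiseSigma = 0.05, seed = 42)
  p <- detectPhasePoints(tr)
  clean <- fitKinetics(tr, p)
  ## inject two 10x-amplitude outliers after onset
  dirty <- tr
  dirty@normalized[c(60, 140)] <- 10
  dirtyFit <- fitKinetics(dirty, p)
  relShift <- function(f) abs(f@model@kOn - clean@model@kOn) / clean@model@kOn
  expect_lt(relShift(dirtyFit), 0.05)
  ## an ordinary least-squares fit shifts more than the robust one
  olsPar <- function(trace) {
    tt <- trace@timestamps; y <- trace@normalized
    res <- minpack.lm::nls.lm(
      par = c(tB = p@tB, tD = p@tD, deltaMax = 1, kOn = 0.05, kOff = 0.01),
      fn = function(q) y - RecruitKinetics:::.modelCurve(
        tt, q[["tB"]], q[["tD"]], q[["deltaMax"]], q[["kOn"]], q[["kOff"]]),
      lower = c(11, p@tB, 1e-8, 1e-5, 1e-5), upper = c(p@tC, 600, 4, 10, 10))
    stats::coef(res)[["deltaMax"]]
  }
  olsShift <- abs(olsPar(dirty) - olsPar(tr)) / olsPar(tr)
  robShift <- abs(dirtyFit@model@deltaMax - clean@model@deltaMax) /
    clean@model@deltaMax
  expect_lt(robShift, olsShift)
})

test_that("extrapolated E follows the 95%-dissociation closed form", {
  p <- new("PhasePoints", tA = 1, tB = 13, tC = 73, tD = 200, tE = NA_real_,
           tEExtrapolated = TRUE, plateauPresent = TRUE)
  mkFit <- function(kOff, converged = TRUE)
    new("FitResult",
        model = TraceModel(deltaMax = 1, kOn = 0.05, kOff = kOff,
                           tB = 13, tD = 200),
        residualScale = 0, converged = converged, weights = numeric())
  expect_equal(extrapolateE(mkFit(0.01), p), 200 + log(20) / 0.01,
               tolerance = 1e-12)
  ## independently: locate the 5% residual amplitude on the model curve
  m <- mkFit(0.01)@model
  ampD <- modelCurve(m, 200)
  root <- uniroot(function(t) modelCurve(m, t) - 0.05 * ampD,
                  c(200, 2000), tol = 1e-10)$root
  expect_equal(extrapolateE(mkFit(0.01), p), root, tolerance = 1e-9)
  ## constructed inverse: kOff = ln(20)/100 gives tE - tD = 100 exactly
  expect_equal(extrapolateE(mkFit(log(20) / 100), p) - 200, 100,
               tolerance = 1e-9)
  ## non-converged fit: E undefined
  expect_true(is.na(extrapolateE(mkFit(0.01, converged = FALSE), p)))
  ## observed E inside the window is kept, not extrapolated
  pObs <- new("PhasePoints", tA = 1, tB = 13, tC = 73, tD = 200, tE = 480,
              tEExtrapolated = FALSE, plateauPresent = TRUE)
  expect_equal(extrapolateE(mkFit(0.01), pObs), 480)
})

test_that("the nine parameters follow the phase-point arithmetic", {
  tr <- makeTrace(noiseSigma = 0, tA = 1, lagS = 12, timestamps = 0:600)
  p <- new("PhasePoints", tA = 1, tB = 13, tC = 73, tD = 200, tE = 499.57,
           tEExtrapolated = FALSE, plateauPresent = TRUE)
  f <- fitKinetics(tr, p)
  kp <- computeParameters(tr, p, f)
  expect_equal(kp@lagTimeS, 12)
  expect_equal(kp@associationTimeS, 60)
  expect_equal(kp@plateauTimeS, 127)
  expect_equal(kp@dissociationTimeS, 299.57)
  expect_equal(kp@durationS, 486.57)
  expect_equal(kp@durationS,
               kp@associationTimeS + kp@plateauTimeS + kp@dissociationTimeS)
})

test_that("fold change follows its defining ratio", {
  tt <- 0:20
  mkTr <- function(site) RecruitKinetics:::newIntensityTrace(
    tt, site, rep(40, length(tt)), irradiationTimeS = 10)
  ## IntensityA = 100, IntensityC = 250 -> 1.5
  site <- rep(100, length(tt)); site[15] <- 250
  expect_equal(foldChange(mkTr(site)), 1.5)
  ## no recruitment: fold change 0
  expect_equal(foldChange(mkTr(rep(100, length(tt)))), 0)
  ## non-positive baseline: undefined
  expect_true(is.na(foldChange(mkTr(rep(0, length(tt))))))
})

test_that("phase ordering and duration identity hold over random traces", {
  set.seed(2024)
  n <- 200
  for (i in seq_len(n)) {
    tr <- makeTrace(
      lagS = runif(1, 3, 40),
      kOn = runif(1, 0.02, 0.12),
      kOff = runif(1, 0.004, 0.05),
      tDAfterAS = runif(1, 60, 400),
      deltaMax = runif(1, 0.5, 2),
      noiseSigma = runif(1, 0, 0.08),
      seed = 5000 + i
    )
    p <- tryCatch(detectPhasePoints(tr), error = function(e) NULL)
    if (is.null(p)) next
    v <- c(p@tA, p@tB, p@tC, p@tD, p@tE)
    v <- v[!is.na(v)]
    expect_true(all(diff(v) >= -1e-9))
    f <- fitKinetics(tr, p)
    kp <- computeParameters(tr, p, f)
    if (!is.na(kp@durationS))
      expect_equal(kp@durationS, kp@associationTimeS + kp@plateauTimeS +
                     kp@dissociationTimeS, tolerance = 1e-6)
  }
})
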