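test_that("simulated traces are exact in the noiseless limit and seeded", {
  tb <- defaultTimebase()
  m <- TraceModel(deltaMax = 1, kOn = 0.05, kOff = 0.01, tB = 23.77, tD = 210)
  tr0 <- simulateTrace(m, tb, noiseSigma = 0, irradiationTimeS = 11)
  expect_equal(normalizedTrace(tr0), modelCurve(m, tb), tolerance = 1e-12)
  ## determinism under a fixed seed
  trA <- simulateTrace(m, tb, noiseSigma = 0.05, seed = 77, irradiationTimeS = 11)
  trB <- simulateTrace(m, tb, noiseSigma = 0.05, seed = 77, irradiationTimeS = 11)
  expect_identical(trA@siteMean, trB@siteMean)
  ## onset before irradiation is rejected
  expect_error(simulateTrace(m, tb, irradiationTimeS = 30), "precedes")
})

test_that("the injected noise level is reproduced (Monte Carlo)", {
  ## long pre-irradiation baseline: 1000 samples before A
  tb <- 0:1100
  m <- TraceModel(deltaMax = 1, kOn = 0.05, kOff = 0.01, tB = 1010, tD = 1080)
  tr <- simulateTrace(m, tb, noiseSigma = 0.05, seed = 12,
                      irradiationTimeS = 1000.5)
  sdPre <- sd(normalizedTrace(tr)[tb < 1000])
  expect_equal(sdPre, 0.05, tolerance = 0.05)
})

test_that("the simulated trace carries the requested fold change", {
  tr <- makeTrace(noiseSigma = 0, foldChange = 0.8)
  expect_equal(foldChange(tr), 0.8 * max(modelCurve(
    TraceModel(deltaMax = 1, kOn = 0.05, kOff = 0.01, tB = 23.77, tD = 210),
    timeStamps(tr))), tolerance = 1e-6)
})

test_that("stack simulation is deterministic and geometrically faithful", {
  cfg <- singleNucleusConfig(seed = 10L)
  simA <- simulateStack(cfg)
  simB <- simulateStack(cfg)
  expect_identical(simA$stack@pixels, simB$stack@pixels)
  ## stripe mask length within 1 px of 12 um / pixel size
  lenPx <- 12 / cfg@pixelSizeUm
  st <- simA$truth$stripeMasks[[1]]
  idx <- which(st, arr.ind = TRUE)
  ## extent along the stripe's major axis (principal component of the mask)
  pc1 <- prcomp(idx)$x[, 1]
  expect_lt(abs(diff(range(pc1)) - lenPx), 1.5)
  ## saturation is rare under the default configuration
  expect_lt(simA$truth$clippedFraction, 0.001)
})

test_that("a clean movie round-trips the injected kinetics end to end", {
  cfg <- singleNucleusConfig(readNoiseSd = 0, noiseGain = 1e-6,
                             bleachRatePerS = 0, driftPerFramePx = c(0, 0),
                             recruitingProbability = 1, seed = 2L)
  ## noiseGain -> 0 makes the Poisson term nearly deterministic
  sim <- simulateStack(cfg)
  res <- analyzeStack(sim$stack, bleachCorrection = FALSE)
  expect_true(res$records$recruiting[1])
  tr <- res$traces[[1]]
  truth <- modelCurve(sim$truth$models[[1]], timeStamps(tr))
  amp <- max(normalizedTrace(tr))
  expect_lt(sqrt(mean((normalizedTrace(tr) / amp - truth)^2)), 0.01)
})

test_that("a null scene yields no damage sites", {
  cfg <- simulationConfig(imageSizePx = 160L, nNuclei = 3L,
                          recruitingProbability = 0, seed = 14L)
  sim <- simulateStack(cfg)
  res <- analyzeStack(sim$stack)
  expect_gt(nrow(res$records), 0)
  expect_true(all(vapply(res$rois, is.null, logical(1))))
  expect_false(any(res$records$recruiting))
})

test_that("discrete-shot stripes resemble the continuous rendering", {
  cfgC <- singleNucleusConfig(seed = 4L)
  cfgD <- singleNucleusConfig(seed = 4L, discreteShots = TRUE)
  mC <- simulateStack(cfgC)$truth$stripeMasks[[1]]
  mD <- simulateStack(cfgD)$truth$stripeMasks[[1]]
  ## 24 shots at 0.5 um steps tile the same 12 um line
  expect_gt(sum(mC & mD) / sum(mC | mD), 0.6)
})

test_that("ground truth serialises to JSON", {
  cfg <- singleNucleusConfig(imageSizePx = 64L, nucleusRadiusUm = 4,
                             stripeLengthUm = 6, totalFrames = 40L,
                             nFast = 30L, seed = 6L)
  sim <- simulateStack(cfg)
  f <- tempfile(fileext = ".json")
  writeGroundTruth(sim$truth, f)
  gt <- jsonlite::read_json(f)
  expect_identical(length(gt$recruiting), 1L)
  expect_equal(gt$models[[1]]$kOn, cfg@kOn)
})
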