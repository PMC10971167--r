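## Frame-series builder: a nucleus disk with optional post-irradiation
## shapes added inside it. tA = 6 s with 6 pre and 8 post frames.
makeDetectSeries <- function(n = 64, r = 25, nucLevel = 300, bg = 50,
                             addPost = NULL, noiseSd = 0, seed = 1) {
  set.seed(seed)
  ys <- matrix(seq_len(n), n, n)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  nuc <- (ys - n / 2)^2 + (xs - n / 2)^2 <= r^2
  base <- matrix(bg, n, n) + nucLevel * nuc
  tt <- 0:13
  f <- array(0, c(length(tt), n, n))
  for (t in seq_along(tt)) {
    fr <- base
    if (tt[t] >= 6 && !is.null(addPost)) fr <- fr + addPost
    if (noiseSd > 0) fr <- fr + matrix(rnorm(n * n, 0, noiseSd), n, n)
    f[t, , ] <- fr
  }
  list(series = FrameSeries(f, tt, irradiationTimeS = 6), nucleus = nuc)
}

diskMask <- function(n, cy, cx, r) {
  ys <- matrix(seq_len(n), n, n)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  (ys - cy)^2 + (xs - cx)^2 <= r^2
}

stripeMask <- function(n, cy, halfLen, halfWidth) {
  ys <- matrix(seq_len(n), n, n)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  abs(ys - cy) <= halfWidth & abs(xs - n / 2) <= halfLen
}

test_that("nucleus segmentation finds synthetic disks and applies filters", {
  expect_message(out0 <- segmentNuclei(matrix(0, 64, 64)), "no nuclei")
  expect_length(out0, 0)
  ## two disks r = 20 on background
  n <- 128
  fr <- matrix(100, n, n)
  fr[diskMask(n, 35, 35, 20)] <- 1000
  fr[diskMask(n, 90, 90, 20)] <- 1000
  rois <- segmentNuclei(fr)
  expect_length(rois, 2)
  cents <- t(vapply(rois, function(x) x@centroid, numeric(2)))
  cents <- cents[order(cents[, 1]), ]
  expect_true(all(abs(cents - rbind(c(35, 35), c(90, 90))) <= 2))
  ## a border-touching disk is excluded
  frB <- matrix(100, n, n)
  frB[diskMask(n, 10, 64, 20)] <- 1000
  expect_message(outB <- segmentNuclei(frB), "filters")
  expect_length(outB, 0)
})

test_that("stripe detection overlaps the generated stripe and rejects nulls", {
  ## no intensity change: no site
  quiet <- makeDetectSeries()
  expect_null(detectDamageSite(quiet$series, new("NucleusROI", label = 1L,
    mask = quiet$nucleus, centroid = c(32, 32),
    areaPx = as.integer(sum(quiet$nucleus)))))
  ## +50% stripe after irradiation
  n <- 64
  truthStripe <- stripeMask(n, n / 2, 20, 1)
  withStripe <- makeDetectSeries(addPost = 150 * truthStripe, noiseSd = 5)
  nuc <- new("NucleusROI", label = 1L, mask = withStripe$nucleus,
             centroid = c(32, 32), areaPx = as.integer(sum(withStripe$nucleus)))
  roi <- detectDamageSite(withStripe$series, nuc)
  expect_false(is.null(roi))
  truthInNuc <- truthStripe & withStripe$nucleus
  overlap <- sum(roi@siteMask & truthInNuc) / sum(truthInNuc)
  expect_gte(overlap, 0.8)
  ## ring properties: disjoint, inside nucleus
  expect_false(any(roi@siteMask & roi@ringMask))
  expect_true(all(roi@ringMask <= nuc@mask))
})

test_that("an elongated stripe is preferred over a larger circular blob", {
  n <- 64
  blob <- diskMask(n, 26, 22, 11)          # area ~380, eccentricity ~0
  stripe <- stripeMask(n, 44, 18, 1)       # area ~111, elongated
  both <- makeDetectSeries(addPost = 150 * (blob | stripe), noiseSd = 3)
  nuc <- new("NucleusROI", label = 1L, mask = both$nucleus,
             centroid = c(32, 32), areaPx = as.integer(sum(both$nucleus)))
  roi <- detectDamageSite(both$series, nuc)
  expect_false(is.null(roi))
  stripeIn <- stripe & both$nucleus
  blobIn <- blob & both$nucleus
  expect_gt(sum(roi@siteMask & stripeIn) / sum(stripeIn), 0.5)
  expect_lt(sum(roi@siteMask & blobIn) / sum(blobIn), 0.2)
})

test_that("background ring matches the brute-force morphological oracle", {
  nuc <- matrix(TRUE, 9, 9)
  site <- matrix(FALSE, 9, 9); site[5, 5] <- TRUE
  ring <- makeBackgroundRing(site, nuc, widthPx = 2)
  expect_identical(sum(ring), 24L)  # 5x5 shell minus the centre pixel
  expect_identical(ring, bruteRing(site, nuc, 2))
  ## random sites against the oracle, including nucleus clipping
  set.seed(3)
  for (i in 1:10) {
    n <- 21
    nucR <- diskMask(n, 11, 11, 9)
    st <- matrix(FALSE, n, n)
    st[sample(which(nucR), 12)] <- TRUE
    w <- sample(1:3, 1)
    expect_identical(makeBackgroundRing(st, nucR, w), bruteRing(st, nucR, w))
  }
  ## site at the nucleus edge: ring clipped but valid
  nucE <- diskMask(21, 11, 11, 8)
  stE <- matrix(FALSE, 21, 21); stE[11, 18:19] <- TRUE
  rE <- makeBackgroundRing(stE, nucE, 2)
  expect_false(any(rE & stE))
  expect_true(all(rE <= nucE))
  ## degenerate: site fills the nucleus
  expect_error(makeBackgroundRing(nucE, nucE, 2), "empty")
})

test_that("trace measurement cancels shared background and centres baseline", {
  n <- 32
  nuc <- diskMask(n, 16, 16, 12)
  site <- matrix(FALSE, n, n); site[15:17, 10:22] <- TRUE
  ring <- makeBackgroundRing(site, nuc, 2)
  roi <- new("DamageSiteROI", nucleusLabel = 1L, siteMask = site,
             ringMask = ring, stripeAxis = c(0, 1))
  tt <- 0:9
  mk <- function(siteVal, ringVal) {
    f <- array(0, c(length(tt), n, n))
    for (t in seq_along(tt)) {
      fr <- matrix(0, n, n)
      fr[ring] <- ringVal
      fr[site] <- siteVal
      f[t, , ] <- fr
    }
    FrameSeries(f, tt, irradiationTimeS = 5)
  }
  ## shared constant value: corrected and normalised identically zero
  trSame <- measureTrace(mk(80, 80), roi)
  expect_equal(correctedTrace(trSame), rep(0, 10))
  expect_equal(normalizedTrace(trSame), rep(0, 10))
  ## constant offset: corrected = 50, normalised = 0
  trOff <- measureTrace(mk(200, 150), roi)
  expect_equal(correctedTrace(trOff), rep(50, 10))
  expect_equal(normalizedTrace(trOff), rep(0, 10))
})

test_that("measured traces follow the injected recruitment profile", {
  cfg <- singleNucleusConfig(noiseGain = 1, readNoiseSd = 2,
                             bleachRatePerS = 0, driftPerFramePx = c(0, 0),
                             recruitingProbability = 1, seed = 21L)
  sim <- simulateStack(cfg)
  res <- analyzeStack(sim$stack, bleachCorrection = FALSE)
  expect_true(res$records$recruiting[1])
  tr <- res$traces[[1]]
  truthCurve <- modelCurve(sim$truth$models[[1]], timeStamps(tr))
  ## scale the measured normalised trace by its fitted amplitude to compare
  amp <- max(normalizedTrace(tr))
  resid <- normalizedTrace(tr) / amp - truthCurve
  expect_lt(sqrt(mean(resid^2)), 0.1)
})

test_that("recruitment classification requires a sustained supra-noise rise", {
  tb <- defaultTimebase()
  ## pure noise (vanishing amplitude): not recruiting
  expect_false(classifyRecruitment(makeTrace(noiseSigma = 0.05,
                                             deltaMax = 1e-6, seed = 2)))
  ## unambiguous step to +10 sigma
  expect_true(classifyRecruitment(makeTrace(noiseSigma = 0.05, seed = 3)))
  ## a single-frame spike does not qualify (consecutive-frame rule)
  sigma <- 0.05
  set.seed(4)
  noise <- rnorm(length(tb), 0, sigma)
  site <- 1 + noise
  site[150] <- site[150] + 10 * sigma
  spike <- RecruitKinetics:::newIntensityTrace(tb, site, rep(1, length(tb)), 11)
  expect_false(classifyRecruitment(spike))
})

test_that("normalised trace is offset-invariant; fold change is gain-invariant", {
  tr <- makeTrace(noiseSigma = 0.02, seed = 6)
  offset <- RecruitKinetics:::newIntensityTrace(
    timeStamps(tr), tr@siteMean + 500, tr@ringMean + 500, irradiationTime(tr))
  expect_equal(normalizedTrace(offset), normalizedTrace(tr), tolerance = 1e-12)
  gain <- RecruitKinetics:::newIntensityTrace(
    timeStamps(tr), tr@siteMean * 3.7, tr@ringMean * 3.7, irradiationTime(tr))
  expect_equal(foldChange(gain), foldChange(tr), tolerance = 1e-12)
  expect_identical(classifyRecruitment(gain), classifyRecruitment(tr))
})
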