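test_that("recruiting fraction aggregates per experiment, then per model", {
  ## one experiment, complete recruitment: 100% +/- 0
  one <- data.frame(cellModel = "m", experimentId = "e1",
                    recruiting = rep(TRUE, 10))
  r1 <- recruitingFraction(one)
  expect_equal(r1$meanPct, 100)
  expect_equal(r1$semPct, 0)
  ## three experiments at 65/72/79%: mean 72, SEM sd/sqrt(3)
  three <- data.frame(
    cellModel = "hiPSC",
    experimentId = rep(c("e1", "e2", "e3"), each = 100),
    recruiting = c(rep(c(TRUE, FALSE), c(65, 35)),
                   rep(c(TRUE, FALSE), c(72, 28)),
                   rep(c(TRUE, FALSE), c(79, 21))))
  r3 <- recruitingFraction(three)
  expect_equal(r3$meanPct, 72)
  expect_equal(r3$semPct, sd(c(65, 72, 79)) / sqrt(3), tolerance = 1e-9)
  expect_equal(r3$semPct, 4.04, tolerance = 0.002)
})

test_that("plateaued fraction uses recruiting cells as denominator", {
  mk <- function(rec, plat) data.frame(recruiting = rec, plateauPresent = plat)
  ## 4 of 8 recruiting cells plateaued
  expect_equal(plateauFraction(mk(rep(TRUE, 8), rep(c(TRUE, FALSE), 4))), 50)
  ## all recruiting cells plateaued
  expect_equal(plateauFraction(mk(rep(TRUE, 5), rep(TRUE, 5))), 100)
  ## 3 plateaued of 7 recruiting among 10 irradiated: denominator is 7
  rec <- c(rep(TRUE, 7), rep(FALSE, 3))
  plat <- c(rep(TRUE, 3), rep(FALSE, 4), rep(NA, 3))
  expect_equal(plateauFraction(mk(rec, plat)), 100 * 3 / 7, tolerance = 1e-9)
  ## zero recruiting cells: undefined
  expect_warning(out <- plateauFraction(mk(rep(FALSE, 4), rep(NA, 4))),
                 "undefined")
  expect_true(is.na(out))
})

test_that("identical groups give F = 0 and all adjusted p = 1", {
  cmp <- compareGroups(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(cmp@fStatistic, 0)
  expect_equal(cmp@pValue, 1)
  expect_true(all(cmp@pairwise$pAdjusted == 1))
  expect_true(all(cmp@pairwise$significance == ""))
})

test_that("ANOVA + Tukey match the studentized-range numeric oracle", {
  vals <- c(1, 2, 3, 1, 2, 3, 11, 12, 13)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  cmp <- compareGroups(vals, grp)
  pw <- cmp@pairwise
  sig <- setNames(pw$pAdjusted < 0.05, pw$pair)
  expect_false(sig[["g2-g1"]])
  expect_true(sig[["g3-g1"]])
  expect_true(sig[["g3-g2"]])
  ## adjusted p values vs direct numerical integration of the studentized
  ## range distribution (independent of R's ptukey)
  mse <- 1  # within-group variance of each group is 1 here
  for (i in seq_len(nrow(pw))) {
    pNum <- tukeyPNumeric(pw$difference[i], mse, 3, 3, k = 3, df = 6)
    expect_equal(pw$pAdjusted[i], pNum, tolerance = 1e-3)
  }
})

test_that("with two groups Tukey reduces to the pooled t-test (q = t sqrt 2)", {
  set.seed(8)
  x <- rnorm(7, 10, 2); y <- rnorm(9, 12, 2)
  cmp <- compareGroups(c(x, y), rep(c("a", "b"), c(7, 9)))
  pT <- t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(cmp@pairwise$pAdjusted, pT, tolerance = 1e-6)
})

test_that("F is invariant to label permutation and global shifts", {
  set.seed(10)
  vals <- rnorm(18, rep(c(5, 6, 9), each = 6))
  grp <- rep(c("a", "b", "c"), each = 6)
  f0 <- compareGroups(vals, grp)@fStatistic
  ## permuting which label names which group leaves F unchanged
  relabel <- c(a = "c", b = "a", c = "b")[grp]
  expect_equal(compareGroups(vals, relabel)@fStatistic, f0, tolerance = 1e-12)
  ## adding a constant to every value changes nothing
  shifted <- compareGroups(vals + 123.4, grp)
  expect_equal(shifted@fStatistic, f0, tolerance = 1e-9)
  expect_equal(shifted@pairwise$pAdjusted,
               compareGroups(vals, grp)@pairwise$pAdjusted, tolerance = 1e-9)
  ## adjusted p >= unadjusted pairwise p (same pooled variance) for 3 groups
  pw <- compareGroups(vals, grp)@pairwise
  mse <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2))) / (18 - 3)
  for (i in seq_len(nrow(pw))) {
    tStat <- abs(pw$difference[i]) / sqrt(mse * (2 / 6))
    pUnadj <- 2 * pt(-tStat, df = 15)
    expect_gte(pw$pAdjusted[i] + 1e-12, pUnadj)
  }
})

test_that("group comparison rejects degenerate designs", {
  expect_error(compareGroups(1:5, rep("a", 5)), "at least 2 groups")
  expect_error(compareGroups(c(1, 2, 3), c("a", "a", "b")), "at least 2 values")
})

test_that("summarizeParameters excludes missing values pairwise", {
  rec <- data.frame(
    cellModel = rep("m", 4), experimentId = "e", cellId = as.character(1:4),
    recruiting = TRUE, plateauPresent = TRUE,
    lagTimeS = c(10, 12, 14, NA), kOn = c(0.05, NA, NA, NA))
  s <- summarizeParameters(rec, parameters = c("lagTimeS", "kOn"))
  expect_equal(s$n[s$parameter == "lagTimeS"], 3)
  expect_equal(s$mean[s$parameter == "lagTimeS"], 12)
  expect_equal(s$n[s$parameter == "kOn"], 1)
})
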