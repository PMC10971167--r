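## Independent oracles used by the tests. These deliberately avoid the code
## paths they check: brute-force loops, closed forms, exhaustive search and
## direct numerical integration.

## --- brute-force morphology: Chebyshev (8-connected) dilation ---
bruteDilate <- function(mask, width) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  on <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(on))) {
    ys <- max(1, on[k, 1] - width):min(ny, on[k, 1] + width)
    xs <- max(1, on[k, 2] - width):min(nx, on[k, 2] + width)
    out[ys, xs] <- TRUE
  }
  out
}

bruteRing <- function(site, nucleus, width) {
  bruteDilate(site, width) & !site & nucleus
}

## --- brute-force per-pixel max projection ---
bruteMaxProject <- function(px) {
  d <- dim(px)
  out <- array(0, d[-2L])
  for (t in seq_len(d[1]))
    for (y in seq_len(d[3]))
      for (x in seq_len(d[4]))
        out[t, y, x] <- max(px[t, , y, x])
  out
}

## --- exhaustive grid search for the noiseless trace fit ---
gridSearchFit <- function(trace, tB, tD,
                          kOnGrid = seq(0.02, 0.1, by = 0.005),
                          kOffGrid = seq(0.004, 0.03, by = 0.002),
                          deltaGrid = seq(0.6, 1.6, by = 0.02)) {
  tt <- trace@timestamps
  y <- trace@normalized
  best <- c(kOn = NA, kOff = NA, deltaMax = NA)
  bestSse <- Inf
  for (kOn in kOnGrid) for (kOff in kOffGrid) for (delta in deltaGrid) {
    r <- y - RecruitKinetics:::.modelCurve(tt, tB, tD, delta, kOn, kOff)
    sse <- sum(r * r)
    if (sse < bestSse) {
      bestSse <- sse
      best <- c(kOn = kOn, kOff = kOff, deltaMax = delta)
    }
  }
  best
}

## --- studentized range distribution by direct numerical integration ---
## P(Q <= q) for k groups and df error degrees of freedom:
## integrate over the pooled scale s ~ sqrt(chi2_df/df) and the smallest
## group mean z. Independent of R's ptukey.
ptukeyNumeric <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z)
      stats::dnorm(z) * (stats::pnorm(z + q * s) - stats::pnorm(z))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  dS <- function(s)  # density of sqrt(chi2_df / df)
    2 * s * df * stats::dchisq(df * s^2, df)
  stats::integrate(function(ss) vapply(ss, function(s) dS(s) * inner(s),
                                       numeric(1)),
                   0, Inf, rel.tol = 1e-8)$value
}

## Tukey-Kramer adjusted p for one pair, via the numeric CDF above.
tukeyPNumeric <- function(diff, mse, ni, nj, k, df) {
  q <- abs(diff) / sqrt(mse / 2 * (1 / ni + 1 / nj))
  1 - ptukeyNumeric(q, k, df)
}

## --- shared fixtures ---
## A synthetic trace from known kinetics on the default timebase.
makeTrace <- function(lagS = 12.77, kOn = 0.05, kOff = 0.01,
                      tDAfterAS = 199, deltaMax = 1, noiseSigma = 0,
                      seed = NULL, tA = 11, timestamps = defaultTimebase(),
                      foldChange = 1) {
  m <- TraceModel(deltaMax = deltaMax, kOn = kOn, kOff = kOff,
                  tB = tA + lagS, tD = tA + tDAfterAS)
  simulateTrace(m, timestamps, noiseSigma = noiseSigma, seed = seed,
                irradiationTimeS = tA, foldChange = foldChange)
}

## A static frame series with a bright block, for registration tests.
makeStructuredSeries <- function(nT = 4, n = 64, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n * n, 100, 3), n, n)
  base[20:40, 15:45] <- base[20:40, 15:45] + 400
  f <- array(0, c(nT, n, n))
  for (t in seq_len(nT)) f[t, , ] <- base
  FrameSeries(f, seq_len(nT) - 1, irradiationTimeS = 0.5)
}
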