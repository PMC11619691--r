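## Independent brute-force oracles used across the suite.  These are kept
## deliberately naive (nested loops, direct formulas) and never share code
## with the implementation they check.

## temperature at which RT = 1 kcal/mol, so work is in kT units
kTUnitsTemperature <- function() 1 / gasConstantKcal()

## all-pairs heavy-atom minimum distance, frame by frame
bruteContactFraction <- function(traj, selA, selB, cutoff) {
  co <- frameCoords(traj)
  at <- atomTable(traj)
  selA <- selA[!at$isHydrogen[selA]]
  selB <- selB[!at$isHydrogen[selB]]
  hits <- logical(dim(co)[1])
  for (f in seq_len(dim(co)[1])) {
    dmin <- Inf
    for (i in selA) for (j in selB) {
      d <- sqrt(sum((co[f, i, ] - co[f, j, ])^2))
      if (d < dmin) dmin <- d
    }
    hits[f] <- dmin < cutoff
  }
  mean(hits)
}

## Kruskal-Wallis H with tie correction, from the textbook formula
bruteKruskalH <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  rbar <- mean(r)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(x) length(x) * (mean(x) - rbar)^2))
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

## Bennett self-consistency solved by successive grid refinement
## (independent of the package's bracketed root-finder)
barGridOracle <- function(wf, wr, temperature) {
  beta <- 1 / (gasConstantKcal() * temperature)
  M <- log(length(wf) / length(wr))
  resid <- function(dg) {
    sum(1 / (1 + exp(beta * (wf - dg) + M))) -
      sum(1 / (1 + exp(beta * (wr + dg) - M)))
  }
  lo <- min(c(wf, -wr)) - 1
  hi <- max(c(wf, -wr)) + 1
  for (round in 1:4) {
    grid <- seq(lo, hi, length.out = 2001)
    vals <- vapply(grid, resid, numeric(1))
    i <- which(vals >= 0)[1]
    if (is.na(i) || i == 1L) return(NA_real_)
    lo <- grid[i - 1L]; hi <- grid[i]
  }
  (lo + hi) / 2
}

## a Gaussian bump trace on a flat baseline
gaussianBumpTrace <- function(frameInterval = 1, duration = 400,
                              center = 200, sigma = 10, amplitude = 0.5,
                              baseline = 0, noiseSd = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration, by = frameInterval)
  v <- baseline + amplitude * exp(-(t - center)^2 / (2 * sigma^2))
  if (noiseSd > 0) v <- v + rnorm(length(t), 0, noiseSd)
  FluorescenceTrace(t, v, roiId = "bump")
}

## small scaled-down pipeline configuration for fast end-to-end tests
smallRunConfig <- function(seed = 1L) {
  cfg <- defaultRunConfig(seed)
  cfg$gcamp$nRois <- 6L
  cfg$dose$nBoot <- 15L
  cfg$dapi$nRois <- 8L
  cfg$fep$nWindows <- 6L
  cfg$fep$nSamples <- 80L
  cfg$fep$nBoot <- 10L
  cfg$contacts$nFrames <- 20L
  cfg
}
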