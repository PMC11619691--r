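## Trace preprocessing: background subtraction, photobleach correction,
## dF/dFmax normalisation, peak statistics.

test_that("background subtraction is pointwise and keeps negatives", {
  tr <- FluorescenceTrace(0:3, c(10, 12, 11, 10))
  bg <- FluorescenceTrace(0:3, c(5, 5, 5, 5))
  expect_equal(traceValues(subtractBackground(tr, bg))[1:3], c(5, 7, 6))

  zero <- FluorescenceTrace(0:3, rep(0, 4))
  expect_equal(traceValues(subtractBackground(tr, zero)),
               traceValues(tr))
  expect_equal(traceValues(subtractBackground(tr, tr)), rep(0, 4))

  ## larger background gives negative values, preserved
  big <- FluorescenceTrace(0:3, rep(20, 4))
  expect_equal(traceValues(subtractBackground(tr, big))[1], -10)

  shifted <- FluorescenceTrace(0:3 + 0.5, rep(5, 4))
  expect_error(subtractBackground(tr, shifted), "time grid")
})

test_that("exponential bleach fit recovers exact decay parameters", {
  t <- seq(0, 600, by = 1.5)
  tr <- FluorescenceTrace(t, 100 * exp(-t / 300) + 10)
  fb <- fitBleach(tr)
  expect_false(fb$model@degenerate)
  expect_equal(fb$model@amplitude, 100, tolerance = 1e-6)
  expect_equal(fb$model@tau, 300, tolerance = 1e-6)
  expect_equal(fb$model@offset, 10, tolerance = 1e-6)
  expect_equal(traceValues(fb$corrected),
               rep(10, length(t)), tolerance = 1e-5)
})

test_that("constant input yields a degenerate no-op bleach model", {
  tr <- FluorescenceTrace(0:20, rep(42, 21))
  fb <- fitBleach(tr)
  expect_true(fb$model@degenerate)
  expect_equal(fb$model@amplitude, 0)
  expect_identical(traceValues(fb$corrected), traceValues(tr))
})

test_that("bleach tau is recovered within 10% from a noisy decay", {
  set.seed(101)
  t <- seq(0, 600, by = 1.5)
  tr <- FluorescenceTrace(t, 100 * exp(-t / 300) + 10 +
                            rnorm(length(t), 0, 1))
  fb <- fitBleach(tr)
  expect_false(fb$model@degenerate)
  expect_lt(abs(fb$model@tau / 300 - 1), 0.1)
})

test_that("bleach correction of bleach-free noisy input is bounded", {
  set.seed(77)
  t <- seq(0, 300, by = 2)
  v <- 50 + rnorm(length(t), 0, 1)
  tr <- FluorescenceTrace(t, v)
  fb <- fitBleach(tr)
  expect_lt(max(abs(traceValues(fb$corrected) - v)), 3)
})

test_that("robust bleach fit ignores sparse positive events", {
  t <- seq(0, 300, by = 2)
  base <- 80 * exp(-t / 400) + 20
  bumps <- 30 * exp(-(t - 60)^2 / 18) + 25 * exp(-(t - 200)^2 / 18)
  tr <- FluorescenceTrace(t, base + bumps)
  plain <- fitBleach(tr)
  robust <- fitBleach(tr, robust = TRUE)
  errPlain <- abs(plain$model@tau - 400)
  errRobust <- abs(robust$model@tau - 400)
  expect_lt(errRobust, errPlain)
  expect_lt(abs(robust$model@tau / 400 - 1), 0.05)
})

test_that("dF/dFmax normalisation follows the ionomycin convention", {
  ## F0 = 2, evoked peak F = 4 (dF 2), ionomycin max dF = 8
  t <- seq(0, 100, by = 1)
  v <- rep(2, length(t))
  v[t >= 20 & t < 25] <- 4
  v[t >= 80] <- 10
  tr <- FluorescenceTrace(t, v, stimulusTime = 10, ionomycinTime = 80)
  nt <- normalizeDff(tr)
  expect_equal(dfMax(nt), 8)
  expect_equal(max(dff(nt)[t >= 20 & t < 25]), 0.25)
  ## global max inside the ionomycin window normalises to exactly 1
  expect_equal(max(dff(nt)), 1)
})

test_that("normalisation is invariant under multiplicative rescaling", {
  cfg <- SynthConfig(nRois = 1L, noiseSd = 0, oscillationRate = 0)
  tr <- genGcampEnsemble(cfg, GroundTruth(), bleach = FALSE)[[1]]
  scaled <- FluorescenceTrace(traceTimes(tr), 3.7 * traceValues(tr),
                              stimulusTime = tr@stimulusTime,
                              ionomycinTime = tr@ionomycinTime)
  expect_equal(dff(normalizeDff(scaled)), dff(normalizeDff(tr)),
               tolerance = 1e-12)
})

test_that("ROIs without a positive ionomycin response are excluded", {
  t <- seq(0, 100, by = 1)
  flat <- FluorescenceTrace(t, rep(5, length(t)), roiId = "flat",
                            stimulusTime = 10, ionomycinTime = 80)
  expect_error(normalizeDff(flat), class = "hcq_exclusion")

  cfg <- SynthConfig(nRois = 2L, noiseSd = 0, oscillationRate = 0)
  good <- genGcampEnsemble(cfg, GroundTruth(), bleach = FALSE)
  mix <- TraceEnsemble(c(good@traces, flat),
                       rbind(good@meta,
                             data.frame(roi_id = "flat", condition = "WT",
                                        conc_molar = 0)))
  res <- normalizeEnsemble(mix)
  expect_length(res$normalized, 2L)
  expect_equal(res$exclusions$roi_id, "flat")
  expect_match(res$exclusions$reason, "non-positive")
})

test_that("a sampled Gaussian bump yields its closed-form peak metrics", {
  sigma <- 10
  expected <- 2 * sqrt(2 * log(2)) * sigma   # ~23.55 s
  for (dt in c(1, 0.25)) {
    tr <- gaussianBumpTrace(frameInterval = dt, sigma = sigma,
                            amplitude = 0.5)
    pk <- detectPeaks(tr, thresholdK = 3)
    expect_length(peakTimes(pk), 1L)
    expect_equal(peakAmplitudes(pk), 0.5, tolerance = 0.01)
    expect_lte(abs(peakFwhms(pk) - expected), dt)
  }
  ## FWHM error shrinks with the sampling interval
  fwAt <- function(dt) peakFwhms(detectPeaks(
    gaussianBumpTrace(frameInterval = dt, sigma = sigma,
                      amplitude = 0.5)))
  expect_lt(abs(fwAt(0.1) - expected), abs(fwAt(2) - expected))
})

test_that("inter-peak intervals and merging behave as specified", {
  t <- seq(0, 400, by = 1)
  v <- 0.5 * exp(-(t - 100)^2 / 200) + 0.5 * exp(-(t - 160)^2 / 200)
  pk <- detectPeaks(FluorescenceTrace(t, v))
  expect_length(peakTimes(pk), 2L)
  expect_equal(interPeakIntervals(pk), 60, tolerance = 1)

  ## flat noise below threshold: empty peak set
  set.seed(3)
  noise <- FluorescenceTrace(t, rnorm(length(t), 0, 0.05))
  expect_length(peakTimes(detectPeaks(noise, thresholdK = 6)), 0L)
})

test_that("peak count is monotone non-increasing in the threshold", {
  set.seed(11)
  t <- seq(0, 500, by = 1)
  v <- rnorm(length(t), 0, 0.3)
  for (ctr in c(60, 150, 260, 300, 420)) {
    v <- v + runif(1, 0.5, 3) * exp(-(t - ctr)^2 / 50)
  }
  tr <- FluorescenceTrace(t, v)
  counts <- vapply(c(0.5, 1, 2, 3, 5, 8),
                   function(k) length(peakTimes(detectPeaks(tr, k))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})
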