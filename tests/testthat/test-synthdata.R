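## Synthetic-data generators: determinism, closed-form ground truth,
## and the fidelity guarantees the downstream recovery tests rely on.

test_that("generators are deterministic given (config, seed)", {
  cfg <- SynthConfig(nRois = 4L)
  truth <- GroundTruth(seed = 7L)
  e1 <- genGcampEnsemble(cfg, truth)
  e2 <- genGcampEnsemble(cfg, truth)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))

  d1 <- genDapiTraces(3, slope = 2, noiseSd = 1, seed = 5)
  d2 <- genDapiTraces(3, slope = 2, noiseSd = 1, seed = 5)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))

  a1 <- genAtpTraces(2, noiseSd = 2, seed = 3)
  a2 <- genAtpTraces(2, noiseSd = 2, seed = 3)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))

  w1 <- genFepSamples(c(0.1, 0.2), workSd = 0.5, nSamples = 10, seed = 2)
  w2 <- genFepSamples(c(0.1, 0.2), workSd = 0.5, nSamples = 10, seed = 2)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))

  ## distinct seeds give distinct draws
  e3 <- genGcampEnsemble(cfg, truth, seed = 8L)
  expect_false(identical(traceValues(e1[[1]]), traceValues(e3[[1]])))
})

test_that("sub-seed streams are independent of one another", {
  s1 <- subSeed(42L, "alpha")
  expect_identical(s1, subSeed(42L, "alpha"))
  expect_false(s1 == subSeed(42L, "beta"))
  expect_false(s1 == subSeed(43L, "alpha"))
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("noise-free evoked CCL matches the analytic transient area", {
  ## fine sampling so the trapezoid is numerically close to the integral
  cfg <- SynthConfig(nRois = 1L, frameInterval = 0.02, noiseSd = 0,
                     oscillationRate = 0)
  truth <- GroundTruth(seed = 1L)
  ens <- genGcampEnsemble(cfg, truth, bleach = FALSE)
  gt <- groundTruth(ens)
  area <- computeCcl(normalizeDff(ens[[1]]))$area
  expect_equal(area, gt$expectedCcl, tolerance = 1e-5)
  ## at the experimental frame interval the discretisation error is the
  ## only error
  cfg2 <- SynthConfig(nRois = 1L, frameInterval = 1.3, noiseSd = 0,
                      oscillationRate = 0)
  ens2 <- genGcampEnsemble(cfg2, truth, bleach = FALSE)
  area2 <- computeCcl(normalizeDff(ens2[[1]]))$area
  expect_equal(area2, groundTruth(ens2)$expectedCcl, tolerance = 5e-3)
})

test_that("antibody at c = IC50 with h = 1 halves the evoked amplitude", {
  cfg <- SynthConfig(nRois = 1L, noiseSd = 0, oscillationRate = 0)
  truth <- GroundTruth(seed = 1L)
  e0 <- genGcampEnsemble(cfg, truth, bleach = FALSE)
  eH <- genGcampEnsemble(cfg, truth, concentration = 1e-8,
                         bleach = FALSE)
  expect_equal(groundTruth(eH)$inhibitionFactor, 0.5)
  ## the generated waveforms themselves scale by exactly one half
  dev0 <- traceValues(e0[[1]]) - 100
  devH <- traceValues(eH[[1]]) - 100
  pre <- traceTimes(e0[[1]]) < 190
  expect_equal(devH[pre], dev0[pre] / 2, tolerance = 1e-12)
})

test_that("mutant condition scales the evoked transient by the CCL ratio", {
  cfg <- SynthConfig(nRois = 2L, noiseSd = 0, oscillationRate = 0)
  truth <- GroundTruth(seed = 1L)
  eW <- genGcampEnsemble(cfg, truth, "WT", bleach = FALSE)
  eM <- genGcampEnsemble(cfg, truth, "D178Y", bleach = FALSE)
  cW <- computeCcl(normalizeDff(eW[[1]]))$area
  cM <- computeCcl(normalizeDff(eM[[1]]))$area
  expect_equal(cM / cW, 1.58, tolerance = 1e-9)
})

test_that("invalid acquisition configurations are rejected", {
  expect_error(SynthConfig(frameInterval = 0), "frameInterval")
  expect_error(SynthConfig(stimulusTime = 200, ionomycinTime = 100),
               "stimulusTime")
  expect_error(genGcampEnsemble(SynthConfig(nRois = 1L),
                                GroundTruth(), condition = "nope"),
               "IC50")
})

test_that("DAPI generator produces the prescribed linear uptake", {
  flat <- genDapiTraces(2, slope = 0, deadCellOffset = 50, noiseSd = 0,
                        seed = 1)
  v <- traceValues(flat[[1]])
  expect_equal(v, rep(v[1], length(v)))
  expect_gt(v[1], 0)

  lin <- genDapiTraces(3, slope = 2, deadCellOffset = 50, noiseSd = 0,
                       seed = 1)
  expect_equal(dapiRate(lin[[1]]), 2, tolerance = 1e-12)
  expect_error(genDapiTraces(2, slope = -1), "slope")
  expect_error(genDapiTraces(2, slope = 1, duration = -5), "duration")
})

test_that("ATP generator peak location and gaps behave as designed", {
  ## no stimulus response: baseline-subtracted AUC is zero downstream
  flat <- genAtpTraces(1, baseline = 100, foldPeak = 1, noiseSd = 0)
  r <- atpRelease(flat[[1]])
  expect_equal(r$auc, 0, tolerance = 1e-9)
  expect_equal(r$peakFold, 1, tolerance = 1e-12)

  ## peak at stimulus + 300 s, amplitude fold 4
  atp <- genAtpTraces(1, baseline = 100, foldPeak = 4,
                      stimulusTime = 600, noiseSd = 0)
  tr <- atp[[1]]
  tPeak <- traceTimes(tr)[which.max(traceValues(tr))]
  expect_lte(abs(tPeak - groundTruth(atp)$peakTime), 30)
  expect_equal(max(traceValues(tr)), 400, tolerance = 1e-12)

  ## gap on the linear rise: trapezoid interpolation across the gap is
  ## exact, so the AUC is unchanged
  gap <- genAtpTraces(1, baseline = 100, foldPeak = 4,
                      stimulusTime = 600, noiseSd = 0,
                      gapMask = c(22L, 23L))
  expect_lt(length(traceTimes(gap[[1]])), length(traceTimes(tr)))
  expect_equal(atpRelease(gap[[1]])$auc, atpRelease(tr)$auc,
               tolerance = 1e-9)
  expect_error(genAtpTraces(1, foldPeak = 0.5), "foldPeak")
  expect_error(genAtpTraces(1, stimulusTime = -10),
               "pre-stimulus")
})

test_that("FEP work samples honour the Crooks construction", {
  ## zero spread: forward work is exactly the window free energy
  w0 <- genFepSamples(c(0.3, -0.1), workSd = 0, nSamples = 5)
  expect_equal(w0@forward[[1]], rep(0.3, 5))
  expect_equal(w0@reverse[[2]], rep(0.1, 5))

  ## 32 equal windows of 0.05 sum to a 1.6 kcal/mol leg
  w <- genFepSamples(rep(0.05, 32), workSd = 0, nSamples = 3)
  expect_equal(sum(w@trueDg), 1.6)
  leg <- estimateLeg(w, "leg", nBoot = 2L)
  expect_equal(legDg(leg), 1.6, tolerance = 1e-9)

  ## Gaussian forward/reverse means sit at +/-dg + sigma^2/(2RT)
  set.seed(1)
  wg <- genFepSamples(0.5, workSd = 0.4, nSamples = 20000,
                      temperature = 310, seed = 11)
  bias <- 0.4^2 / (2 * gasConstantKcal() * 310)
  expect_equal(mean(wg@forward[[1]]), 0.5 + bias, tolerance = 0.02)
  expect_equal(mean(wg@reverse[[1]]), -0.5 + bias, tolerance = 0.02)
  expect_error(genFepSamples(0.5, workSd = -1), "workSd")
  expect_error(genFepSamples(0.5, nSamples = 1), "samples")
})

test_that("toy trajectory realises its contact schedule exactly", {
  sched <- c(rep(TRUE, 7), rep(FALSE, 3))
  traj <- genToyTrajectory(sched)
  a <- selectAtoms(traj, chain = "A")
  b <- selectAtoms(traj, chain = "B")
  cf <- contactFraction(traj, a, b)
  expect_equal(contactFrac(cf), 0.7)
  expect_identical(cf@perFrame, sched)
  ## min heavy-atom distances are the prescribed geometry
  expect_equal(cf@minDistances, ifelse(sched, 2.5, 4.5))

  expect_equal(contactFrac(contactFraction(
    genToyTrajectory(rep(FALSE, 5)), a, b)), 0)
  expect_equal(contactFrac(contactFraction(
    genToyTrajectory(rep(TRUE, 5)), a, b)), 1)
  expect_error(genToyTrajectory(logical(0)), "frame")
  expect_error(genToyTrajectory(c(TRUE), contactDist = 0), "degenerate")
})

test_that("noisy recovery error shrinks as the ensemble grows", {
  ## mean DAPI rate over n ROIs: averaged absolute error across seeds
  ## must drop when n increases tenfold
  errAt <- function(n, seed) {
    ens <- genDapiTraces(n, slope = 2, noiseSd = 8, seed = seed)
    abs(mean(vapply(ens@traces, dapiRate, numeric(1))) - 2)
  }
  small <- mean(vapply(1:6, function(s) errAt(4L, s), numeric(1)))
  large <- mean(vapply(1:6, function(s) errAt(80L, s), numeric(1)))
  expect_lt(large, small)
})
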