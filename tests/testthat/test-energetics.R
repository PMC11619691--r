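## Trajectory statistics and free-energy estimation.

test_that("contact fraction equals the brute-force all-pairs oracle", {
  set.seed(21)
  for (rep in 1:5) {
    sched <- runif(12) < runif(1)
    traj <- genToyTrajectory(sched, jitterSd = 0.15, seed = rep)
    a <- selectAtoms(traj, chain = "A")
    b <- selectAtoms(traj, chain = "B")
    for (cut in c(1, 2.6, 3, 4.6)) {
      expect_equal(contactFrac(contactFraction(traj, a, b, cut)),
                   bruteContactFraction(traj, a, b, cut))
    }
  }
})

test_that("contact fraction is monotone in the cutoff and strict at ties", {
  traj <- genToyTrajectory(c(TRUE, TRUE, FALSE, FALSE, FALSE))
  a <- selectAtoms(traj, chain = "A")
  b <- selectAtoms(traj, chain = "B")
  fr <- vapply(c(0, 1, 2.5, 2.6, 4.5, 4.6, 10),
               function(cut)
                 contactFrac(contactFraction(traj, a, b, cut)),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  ## cutoff 0: nothing is strictly below it
  expect_equal(fr[1], 0)
  ## distances exactly at the cutoff do not count as contacts
  expect_equal(fr[3], 0)    # cutoff 2.5 = contact distance
  expect_equal(fr[4], 0.4)  # just above
  expect_equal(fr[5], 0.4)  # cutoff 4.5 = apart distance
  expect_equal(fr[7], 1)
})

test_that("coincident selections are always in contact", {
  atoms <- data.frame(chain = c("A", "B"), resno = c(1L, 2L),
                      resname = "GLY", atomName = "CA",
                      isHydrogen = FALSE)
  co <- array(0, dim = c(3, 2, 3))   # both atoms at the origin, 3 frames
  traj <- TrajectoryFrames(co, atoms)
  expect_equal(contactFrac(contactFraction(traj, 1L, 2L, 3.0)), 1)
})

test_that("invalid contact selections are rejected", {
  traj <- genToyTrajectory(c(TRUE, FALSE))
  expect_error(contactFraction(traj, integer(), 3:4), "heavy atom")
  expect_error(contactFraction(traj, 1:2, 2:4), "disjoint")
  ## hydrogen-only selection has no heavy atoms
  expect_error(contactFraction(traj, 5L, 1:2), "heavy atom")
})

test_that("hydrogens are excluded from contact distances", {
  traj <- genToyTrajectory(rep(FALSE, 4))  # H sits at 3.7 A, heavies 4.5
  a <- selectAtoms(traj, chain = "A", heavyOnly = FALSE)
  b <- selectAtoms(traj, chain = "B", heavyOnly = FALSE)
  cf <- contactFraction(traj, a, b, cutoff = 4.0)
  expect_equal(contactFrac(cf), 0)           # heavy min 4.5, H ignored
  expect_equal(cf@minDistances, rep(4.5, 4))
})

test_that("RMSD is zero for identical frames and rigid copies", {
  traj <- genToyTrajectory(c(FALSE, FALSE, FALSE))
  expect_equal(rmsdSeries(traj, align = FALSE), rep(0, 3))

  ## rotate + translate every frame rigidly: aligned RMSD stays zero
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  co <- frameCoords(traj)
  for (f in 2:3) {
    co[f, , ] <- co[f, , ] %*% R +
      matrix(rep(c(4, -2, 7), each = dim(co)[2]), ncol = 3)
  }
  moved <- TrajectoryFrames(co, atomTable(traj))
  expect_equal(rmsdSeries(moved, align = TRUE), rep(0, 3),
               tolerance = 1e-9)
  expect_gt(max(rmsdSeries(moved, align = FALSE)), 1)
})

test_that("RMSD of a known displacement matches hand computation", {
  atoms <- data.frame(chain = "A", resno = 1L, resname = "GLY",
                      atomName = paste0("C", 1:4), isHydrogen = FALSE)
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  co <- array(0, dim = c(2, 4, 3))
  co[1, , ] <- base
  co[2, , ] <- base
  co[2, 1, 1] <- 2   # one atom displaced by 2 A
  traj <- TrajectoryFrames(co, atoms)
  expect_equal(rmsdSeries(traj, align = FALSE)[2], 2 / sqrt(4))
})

test_that("aligned RMSD series is invariant under a global rigid motion", {
  set.seed(31)
  nA <- 6
  co <- array(rnorm(3 * nA * 3, sd = 2), dim = c(3, nA, 3))
  atoms <- data.frame(chain = "A", resno = 1L, resname = "GLY",
                      atomName = paste0("C", 1:nA), isHydrogen = FALSE)
  traj <- TrajectoryFrames(co, atoms)
  r0 <- rmsdSeries(traj, align = TRUE)
  th <- -0.4
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  co2 <- co
  for (f in 1:3) {
    co2[f, , ] <- co[f, , ] %*% R +
      matrix(rep(c(-3, 5, 1), each = nA), ncol = 3)
  }
  r1 <- rmsdSeries(TrajectoryFrames(co2, atoms), align = TRUE)
  expect_equal(r1, r0, tolerance = 1e-9)
  ## cross-check against the reference superposition in bio3d
  ref <- matrix(co[1, , ], ncol = 3)
  for (f in 2:3) {
    fit <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                          mobile = as.numeric(t(matrix(co[f, , ],
                                                       ncol = 3))),
                          fixed.inds = 1:(3 * nA),
                          mobile.inds = 1:(3 * nA))
    expect_equal(r0[f],
                 sqrt(mean(colSums((matrix(fit, nrow = 3) -
                                      t(ref))^2))),
                 tolerance = 1e-6)
  }
})

test_that("exponential estimator matches closed forms", {
  expect_equal(expEstimator(rep(1.5, 6), 310), 1.5)
  expect_equal(expEstimator(2.34, 310), 2.34)   # single sample
  ## Gaussian work in kT units: dG -> mu - sigma^2/2
  kT <- kTUnitsTemperature()
  set.seed(41)
  w <- rnorm(2e5, 2, 1)
  est <- expEstimator(w, kT)
  ## large-n Monte Carlo: agree with mu - 0.5 within a generous 3 s.e.
  expect_lt(abs(est - 1.5), 0.03)
  expect_error(expEstimator(numeric(), 310), "samples")
})

test_that("BAR solves symmetric and antisymmetric cases exactly", {
  kT <- kTUnitsTemperature()
  b <- barEstimator(rep(1, 10), rep(-1, 10), temperature = kT,
                    nBoot = 10)
  expect_equal(b$dg, 1, tolerance = 1e-9)
  expect_false(b$flagged)

  set.seed(51)
  wf <- rnorm(300, 1.5, 1); wr <- rnorm(300, -0.5, 1)
  d1 <- barEstimator(wf, wr, temperature = kT, nBoot = 5)$dg
  d2 <- barEstimator(-wr, -wf, temperature = kT, nBoot = 5)$dg
  expect_equal(d2, -(-d1), tolerance = 1e-9)  # swap + negate flips sign
})

test_that("BAR recovers the free energy of Crooks-consistent samples", {
  kT <- kTUnitsTemperature()
  w <- genFepSamples(1, workSd = 1, nSamples = 10000,
                     temperature = kT, seed = 97)
  b <- barEstimator(w@forward[[1]], w@reverse[[1]], temperature = kT,
                    nBoot = 100, seed = 7)
  expect_lt(abs(b$dg - 1), 3 * b$se)
  ## and agrees with the independent grid-search oracle to 1e-6
  oracle <- barGridOracle(w@forward[[1]], w@reverse[[1]], kT)
  expect_lt(abs(b$dg - oracle), 1e-6)
})

test_that("BAR is no worse than exponential averaging at equal n", {
  kT <- kTUnitsTemperature()
  bar <- expw <- numeric(20)
  for (s in 1:20) {
    w <- genFepSamples(1, workSd = 1.5, nSamples = 150,
                       temperature = kT, seed = 1000 + s)
    bar[s] <- barEstimator(w@forward[[1]], w@reverse[[1]],
                           temperature = kT, nBoot = 2)$dg
    expw[s] <- expEstimator(w@forward[[1]], kT)
  }
  expect_lte(abs(mean(bar) - 1), abs(mean(expw) - 1))
  expect_lte(var(bar), var(expw))
})

test_that("window combination and the thermodynamic cycle are exact", {
  per <- replicate(32, list(dg = 0.05, se = 0.01), simplify = FALSE)
  leg <- combineLeg(per, "complex")
  expect_equal(legDg(leg), 1.6)
  expect_equal(legSe(leg), sqrt(32 * 0.01^2))

  single <- combineLeg(list(list(dg = 0.42, se = 0.2)))
  expect_equal(legDg(single), 0.42)
  expect_equal(legSe(single), 0.2)

  mixed <- combineLeg(data.frame(dg = c(0.5, -0.2, 0.1), se = 0))
  expect_equal(legDg(mixed), 0.4)
  expect_error(combineLeg(list()), "empty")

  cl <- combineLeg(data.frame(dg = 2.00, se = 0.1), "complex")
  fr <- combineLeg(data.frame(dg = 0.68, se = 0.1), "free")
  expect_equal(thermoCycle(cl, fr)$ddg, 1.32)
  expect_equal(thermoCycle(cl, cl)$ddg, 0)
  expect_equal(thermoCycle(combineLeg(data.frame(dg = 0.5, se = 0)),
                           combineLeg(data.frame(dg = 1.0, se = 0)))$ddg,
               -0.5)
})

test_that("protomer aggregation reproduces the hexamer bookkeeping", {
  ## per-site values of the directly engaged protomer and its two
  ## neighbours; the remaining three contribute nothing
  pc <- aggregateProtomers(c(1.43, 0.50, -0.37, 0, 0, 0))
  expect_equal(totalDdg(pc), 1.56)

  z <- aggregateProtomers(rep(0, 6))
  expect_equal(totalDdg(z), 0)
  expect_equal(affinityFold(z), 1)

  ## permutation invariance
  set.seed(61)
  v <- rnorm(6)
  expect_equal(totalDdg(aggregateProtomers(v)),
               totalDdg(aggregateProtomers(sample(v))))
  expect_error(aggregateProtomers(1:5), "six")
})

test_that("affinity fold change converts ddG at body temperature", {
  expect_equal(foldChange(0, 310), 1)
  expect_equal(foldChange(0, 298), 1)
  expect_equal(foldChange(-1.1, 310), 1 / foldChange(1.1, 310))
  ## a 1.32 kcal/mol penalty at 310 K is an ~order-of-magnitude loss
  expect_equal(foldChange(1.32, 310), 8.52, tolerance = 0.01 / 8.52)
  pc <- aggregateProtomers(c(1.32, 0, 0, 0, 0, 0), temperature = 310)
  expect_equal(pc@foldPowerOfTen, 10)
})

test_that("work-sample CSV and trajectory PDB round-trip", {
  w <- genFepSamples(c(0.1, -0.3), workSd = 0.2, nSamples = 6, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeWorkCsv(w, path)
  w2 <- readWorkCsv(path)
  expect_equal(w2@forward, w@forward, tolerance = 1e-12)
  expect_equal(w2@reverse, w@reverse, tolerance = 1e-12)
  expect_equal(w2@temperature, w@temperature)

  traj <- genToyTrajectory(c(TRUE, FALSE, TRUE))
  pdb <- tempfile(fileext = ".pdb")
  writeTrajectoryPdb(traj, pdb)
  back <- readTrajectoryPdb(pdb)
  expect_equal(nFrames(back), 3L)
  expect_equal(frameCoords(back), frameCoords(traj), tolerance = 1e-3)
  expect_equal(atomTable(back)$isHydrogen, atomTable(traj)$isHydrogen)
  ## contact statistics survive the round-trip unchanged
  a <- selectAtoms(back, chain = "A"); b <- selectAtoms(back, chain = "B")
  expect_equal(contactFrac(contactFraction(back, a, b)), 2 / 3)
})
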