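test_that("generators are deterministic given a seed", {
  p <- kineticPreset("zld_like", nMolecules = 200L, seed = 11L)
  a <- simulateTrajectories(p)
  b <- simulateTrajectories(p)
  expect_identical(trackData(a$tracks), trackData(b$tracks))
  expect_identical(a$truth, b$truth)
  f1 <- simulateFrap(frapSimParams(nSpots = 3L, nPost = 40L, seed = 5L))
  f2 <- simulateFrap(frapSimParams(nSpots = 3L, nPost = 40L, seed = 5L))
  expect_identical(f1@bleach, f2@bleach)
  m1 <- simulateMs2Volumes(locusSimParams(nTimepoints = 2L, seed = 3L))
  m2 <- simulateMs2Volumes(locusSimParams(nTimepoints = 2L, seed = 3L))
  expect_identical(m1$path, m2$path)
  expect_identical(frames(m1$mcp)[[1]], frames(m2$mcp)[[1]])
})

test_that("with every motion source off, trajectories are constant points", {
  p <- twoStateSimParams(nMolecules = 20L, fBound = 1, dBound = 0,
                         sigmaLoc = 0, kOffSpecific = 0,
                         kOffNonspecific = 0, kBleach = 0, nFrames = 12L,
                         seed = 2L)
  sim <- simulateTrajectories(p)
  expect_true(all(trackLengths(sim$tracks) == 12L))
  d <- trackData(sim$tracks)
  spread <- tapply(d$x, d$id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("steady-state bound fraction matches the requested one", {
  p <- twoStateSimParams(nMolecules = 10000L, fBound = 0.5, seed = 7L)
  sim <- simulateTrajectories(p)
  fb <- mean(sim$truth$state != "free")
  expect_lt(abs(fb - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("specific unbinding times average 1/k_off", {
  # k = 0.18/s gives a 5.56 s mean bound duration
  p <- twoStateSimParams(nMolecules = 20000L, fBound = 1, fSpecific = 1,
                         kOffSpecific = 0.18, kBleach = 0,
                         frameInterval = 0.5, exposure = 0.5,
                         nFrames = 200L, seed = 8L)
  sim <- simulateTrajectories(p)
  m <- mean(sim$truth$tUnbind)
  expect_lt(abs(m - 1 / 0.18) / (1 / 0.18), 0.03)
})

test_that("histone control track durations are bleaching-limited", {
  p <- kineticPreset("his2b_like", nMolecules = 5000L, fBound = 1,
                     fSpecific = 1, kBleach = 0.15, frameInterval = 0.5,
                     exposure = 0.5, nFrames = 2000L, seed = 9L)
  tracks <- simulateHis2bControl(p)
  # durations are exponential(0.15) discretized to frames: compare the
  # empirical duration CDF with the analytic geometric law
  len <- trackLengths(tracks)
  surv <- vapply(1:20, function(j) mean(len >= j), 0)
  expected <- exp(-0.15 * 0.5 * (0:19))
  expect_lt(max(abs(surv - expected)), 0.02)
  # and the preset immobile fraction is 88%
  sim <- simulateTrajectories(kineticPreset("his2b_like",
                                            nMolecules = 20000L, seed = 1L))
  expect_lt(abs(mean(sim$truth$state != "free") - 0.88), 0.01)
})

test_that("long exposures blur free molecules into the background", {
  p <- twoStateSimParams(nMolecules = 2000L, fBound = 0.5,
                         frameInterval = 0.5, exposure = 0.5,
                         nFrames = 20L, seed = 4L)
  sim <- simulateTrajectories(p)
  rendered <- sim$truth$id[sim$truth$nLoc > 0]
  expect_true(all(sim$truth$state[sim$truth$id %in% rendered] != "free"))
})

test_that("hub placement reproduces the requested density ratio", {
  sim <- simulateNucleusMovie(nucleusSimParams(seed = 3L))
  for (fold in c(1, 4)) {
    tr <- simulateBoundMoleculesInHubs(sim$hubMask, sim$nucleusLabels,
                                       fold = fold, n = 20000L,
                                       trackLength = 1L, jitterSd = 0,
                                       seed = 10L + fold)
    d <- trackData(tr)
    row <- floor(d$y / 0.1) + 1L
    col <- floor(d$x / 0.1) + 1L
    inHub <- sim$hubMask[cbind(row, col)]
    aIn <- sum(sim$hubMask & sim$nucleusLabels > 0)
    aOut <- sum(!sim$hubMask & sim$nucleusLabels > 0)
    ratio <- (sum(inHub) / aIn) / (sum(!inHub) / aOut)
    expect_lt(abs(ratio - fold) / fold, 0.1)
  }
})

test_that("FRAP generator obeys its closed forms", {
  # no corruption: the corrected curve is the model curve itself
  p <- frapSimParams(noiseSd = 0, controlDrift = 1, darkLevel = 0,
                     nSpots = 2L, nPost = 100L, seed = 1L)
  exp <- simulateFrap(p)
  t <- (seq_len(100L) - 1L) * p$frameInterval
  model <- 1 - p$aAmp * exp(-p$kA * t) - p$bAmp * exp(-p$kB * t)
  expect_equal(exp@bleach[-(1:10), 1], model, tolerance = 1e-12)
  # a = b = 0 keeps the trace flat at unity
  flat <- simulateFrap(frapSimParams(aAmp = 0, bAmp = 0, noiseSd = 0,
                                     nSpots = 1L, nPost = 20L, seed = 1L))
  expect_true(all(flat@bleach == 1))
  # slow-component half time is ln(2)/kB
  kB <- log(2) / 5
  tHalf <- log(2) / kB
  expect_equal(tHalf, 5)
})
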