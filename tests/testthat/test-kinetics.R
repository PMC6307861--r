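test_that("displacement compilation respects the per-trajectory jump cap", {
  # 9 localizations, timepoints 8, jumps 4: exactly 4 jumps per frameshift
  d <- data.frame(id = 1L, frame = 0:8, x = (0:8) * 0.1, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = 0.01, exposure = 0.01)
  ds <- compileDisplacements(tr, timepoints = 8L, jumpsPerTraj = 4L)
  # 9 - k pairs exist at frameshift k; the cap limits them to 4
  expect_identical(vapply(ds@displacements, length, 0L),
                   pmin(4L, 9L - 1:7))
  expect_equal(ds@displacements[[1]], rep(0.1, 4), tolerance = 1e-12)
  expect_equal(ds@displacements[[3]], rep(0.3, 4), tolerance = 1e-12)
})

test_that("an immobile noiseless trajectory yields zero displacements", {
  d <- data.frame(id = 1L, frame = 0:9, x = 0.5, y = 0.5)
  tr <- new("TrackSet", data = d, frameInterval = 0.01, exposure = 0.01)
  ds <- compileDisplacements(tr)
  expect_true(all(unlist(ds@displacements) == 0))
})

test_that("a gap-spanning displacement lands in the longer frameshift group", {
  # hand-enumerated 4-point track with frame 2 missing:
  # pairs at k=1: (0,1), (3,4); k=2: (1,3); k=3: (0,3), (1,4)
  d <- data.frame(id = 1L, frame = c(0L, 1L, 3L, 4L),
                  x = c(0, 1, 3, 4) * 0.1, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = 0.01, exposure = 0.01)
  ds <- compileDisplacements(tr, timepoints = 5L)
  expect_equal(lengths(ds@displacements), c(2L, 1L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(ds@displacements[[2]], 0.2, tolerance = 1e-12)
})

test_that("defocalization survival has the right limits", {
  expect_equal(defocalizationSurvival(0, 0.05, 0.8), 1)
  expect_lt(defocalizationSurvival(3, 1e4, 0.8), 1e-12)
  expect_equal(defocalizationSurvival(3, 0, 0.8), 1)
  s <- defocalizationSurvival(3, c(0.01, 0.02, 0.05), 0.8)
  expect_true(all(diff(s) < 0))
})

test_that("defocalization survival matches a Monte-Carlo walker oracle", {
  set.seed(101)
  for (case in list(c(3, 0.03), c(1, 0.05), c(6, 0.02))) {
    mc <- mcSlabSurvival(200000L, case[1], case[2], 0.8)
    expect_lt(abs(mc - defocalizationSurvival(case[1], case[2], 0.8)),
              3e-3)
  }
})

test_that("single-population data drives the bound fraction to its boundary", {
  p <- twoStateSimParams(nMolecules = 8000L, fBound = 1, dBound = 0.05,
                         kOffSpecific = 0, kOffNonspecific = 0, seed = 3L)
  sim <- simulateTrajectories(p)
  fit <- fitTwoState(compileDisplacements(sim$tracks), sliceDepth = 0.8)
  expect_gte(fBound(fit), 0.97)
})

test_that("the two-state fit recovers a mixed population", {
  p <- kineticPreset("zld_like", nMolecules = 15000L, seed = 21L)
  sim <- simulateTrajectories(p)
  ds <- compileDisplacements(sim$tracks)
  fit <- fitTwoState(ds, sliceDepth = 0.8)
  expect_lt(abs(fBound(fit) - 0.5), 0.04)
  expect_lt(abs(dFree(fit) - 3.5) / 3.5, 0.25)
})

test_that("the fit is invariant to trajectory order and translation", {
  p <- kineticPreset("zld_like", nMolecules = 4000L, seed = 22L)
  sim <- simulateTrajectories(p)
  d <- trackData(sim$tracks)
  fit1 <- fitTwoState(compileDisplacements(sim$tracks), sliceDepth = 0.8)
  # translate and reverse trajectory block order
  d2 <- d[order(-d$id, d$frame), ]
  d2$x <- d2$x + 5; d2$y <- d2$y - 3
  tr2 <- new("TrackSet", data = d2, frameInterval = 0.01, exposure = 0.01)
  fit2 <- fitTwoState(compileDisplacements(tr2), sliceDepth = 0.8)
  expect_equal(fBound(fit1), fBound(fit2), tolerance = 1e-8)
  expect_equal(dFree(fit1), dFree(fit2), tolerance = 1e-8)
})
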