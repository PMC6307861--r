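test_that("a drift-free noiseless experiment corrects to the exact model", {
  p <- frapSimParams(noiseSd = 0, controlDrift = 1, darkLevel = 0,
                     nSpots = 3L, nPost = 200L, seed = 1L)
  cc <- bleachCorrect(simulateFrap(p), outlierFactor = Inf)
  model <- 1 - p$aAmp * exp(-p$kA * cc$time) - p$bAmp * exp(-p$kB * cc$time)
  expect_equal(cc$curve, model, tolerance = 1e-12)
})

test_that("shared acquisition drift cancels in the correction", {
  base <- frapSimParams(noiseSd = 0, controlDrift = 1, darkLevel = 0,
                        nSpots = 3L, nPost = 200L, seed = 2L)
  drifted <- frapSimParams(noiseSd = 0, controlDrift = 0.999,
                           darkLevel = 0, nSpots = 3L, nPost = 200L,
                           seed = 2L)
  c1 <- bleachCorrect(simulateFrap(base), outlierFactor = Inf)
  c2 <- bleachCorrect(simulateFrap(drifted), outlierFactor = Inf)
  expect_equal(c1$curve, c2$curve, tolerance = 1e-10)
})

test_that("an additive dark offset cancels in the correction", {
  base <- frapSimParams(noiseSd = 0, controlDrift = 1, darkLevel = 0,
                        nSpots = 3L, nPost = 200L, seed = 3L)
  offset <- frapSimParams(noiseSd = 0, controlDrift = 1, darkLevel = 50,
                          nSpots = 3L, nPost = 200L, seed = 3L)
  c1 <- bleachCorrect(simulateFrap(base), outlierFactor = Inf)
  c2 <- bleachCorrect(simulateFrap(offset), outlierFactor = Inf)
  expect_equal(c1$curve, c2$curve, tolerance = 1e-10)
})

test_that("control traces darker than the dark spots are an error", {
  p <- frapSimParams(noiseSd = 0, controlDrift = 1, darkLevel = 0,
                     nSpots = 2L, nPost = 20L, seed = 4L)
  exp <- simulateFrap(p)
  exp@dark <- exp@dark + 5  # dark exceeds the unit-level control
  expect_error(bleachCorrect(exp), "control mean")
})

test_that("the single-exponential limit gives tHalf = ln2/kA", {
  p <- frapSimParams(aAmp = 0.5, bAmp = 0, kA = 1, noiseSd = 0.002,
                     nSpots = 20L, nPost = 600L, seed = 5L)
  fit <- suppressWarnings(fitReactionDominant(bleachCorrect(simulateFrap(p))))
  expect_lt(abs(tHalfSlow(fit) - log(2)) / log(2), 0.1)
})

test_that("parameters are recovered across an amplitude/rate grid", {
  # estimates averaged over three replicate experiments, as recovery
  # curves are averaged over embryo replicates in practice
  for (case in list(c(0.2, 0.4, 0.1), c(0.4, 0.2, 0.7), c(0.3, 0.4, 0.2))) {
    a <- case[1]; b <- case[2]; kSlow <- case[3]
    fits <- lapply(1:3, function(r) {
      p <- frapSimParams(aAmp = a, bAmp = b, kA = 3, kB = kSlow,
                         noiseSd = 0.02, nSpots = 50L, seed = 6L + r,
                         controlDrift = 0.9998, darkLevel = 10)
      fitReactionDominant(bleachCorrect(simulateFrap(p)))
    })
    est <- function(f) mean(vapply(fits, f, 0))
    expect_lt(abs(est(function(f) f@kB) - kSlow) / kSlow, 0.15)
    expect_lt(abs(est(function(f) f@bAmp) - b) / b, 0.15)
    expect_lt(abs(est(function(f) f@aAmp) - a) / a, 0.15)
  }
})

test_that("outlier spots are culled by the residual rule", {
  p <- frapSimParams(noiseSd = 0.01, nSpots = 20L, nPost = 300L, seed = 7L)
  exp <- simulateFrap(p)
  # corrupt two spots with a large drifting artefact
  exp@bleach[, 1] <- exp@bleach[, 1] +
    seq(0, 0.8, length.out = nrow(exp@bleach))
  exp@bleach[, 2] <- exp@bleach[, 2] +
    0.5 * sin(seq(0, 20, length.out = nrow(exp@bleach)))
  cc <- bleachCorrect(exp)
  expect_identical(cc$nSpotsUsed, 18L)
})
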