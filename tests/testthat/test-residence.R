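test_that("survival probability is the complement CDF of track durations", {
  d <- data.frame(id = rep(1:4, each = 10), frame = rep(0:9, 4),
                  x = 0, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = 0.5, exposure = 0.5)
  sp <- survivalProbability(tr)
  expect_equal(sp@prob, rep(1, 10))
  expect_equal(sp@time, (1:10) * 0.5)
  # mixed lengths: SP drops at the right duration
  d2 <- rbind(d, data.frame(id = 5L, frame = 0:4, x = 0, y = 0))
  tr2 <- new("TrackSet", data = d2, frameInterval = 0.5, exposure = 0.5)
  sp2 <- survivalProbability(tr2)
  expect_equal(sp2@prob[5], 1)
  expect_equal(sp2@prob[6], 0.8)
})

test_that("survival of exponential durations matches the analytic law", {
  set.seed(33)
  dt <- 0.5
  n <- 8000L
  len <- pmax(1L, ceiling(rexp(n, 1) / dt))
  d <- data.frame(id = rep(seq_len(n), len),
                  frame = sequence(len) - 1L, x = 0, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = dt, exposure = dt)
  sp <- survivalProbability(tr)
  j <- 1:10
  expect_lt(max(abs(sp@prob[j] - exp(-1 * (j - 1) * dt))), 0.02)
})

test_that("a pure single exponential drives the fast amplitude to zero", {
  set.seed(34)
  dt <- 0.5
  n <- 20000L
  len <- pmax(1L, ceiling(rexp(n, 0.33) / dt))
  d <- data.frame(id = rep(seq_len(n), len),
                  frame = sequence(len) - 1L, x = 0, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = dt, exposure = dt)
  fit <- suppressWarnings(fitDoubleExponential(survivalProbability(tr)))
  kSlow <- slowRate(fit)
  # the slow rate carries the signal whatever the (degenerate) split
  expect_lt(abs(kSlow - 0.33), 0.02)
})

test_that("a two-exponential mixture is recovered within 10%", {
  set.seed(35)
  dt <- 0.5
  n <- 20000L
  fast <- runif(n) < 0.7
  dur <- ifelse(fast, rexp(n, 2), rexp(n, 0.2))
  len <- pmax(1L, ceiling(dur / dt))
  d <- data.frame(id = rep(seq_len(n), len),
                  frame = sequence(len) - 1L, x = 0, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = dt, exposure = dt)
  fit <- fitDoubleExponential(survivalProbability(tr))
  expect_lt(abs(fit@kS - 0.2) / 0.2, 0.1)
  expect_lt(abs(fit@kNs - 2) / 2, 0.1)
  expect_lt(abs(fit@fFast - 0.7), 0.07)
})

test_that("the duration threshold is selected where the slow rate converges", {
  set.seed(36)
  dt <- 0.5
  n <- 20000L
  fast <- runif(n) < 0.6
  dur <- ifelse(fast, rexp(n, 2), rexp(n, 0.3))
  len <- pmax(1L, ceiling(dur / dt))
  d <- data.frame(id = rep(seq_len(n), len),
                  frame = sequence(len) - 1L, x = 0, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = dt, exposure = dt)
  sp <- survivalProbability(tr)
  thr <- selectMinDurationThreshold(sp, 1:6)
  expect_lte(thr, 2L)
  ks <- attr(thr, "kS")
  expect_true(all(is.finite(ks[1:3])))
})

test_that("a non-converging scan returns the range maximum with a warning", {
  # a curve whose apparent slow rate keeps drifting: power-law durations
  set.seed(37)
  dt <- 0.5
  n <- 8000L
  dur <- 0.3 * (runif(n)^(-1 / 1.2) - 1) + 0.1  # heavy tail
  len <- pmax(1L, ceiling(dur / dt))
  d <- data.frame(id = rep(seq_len(n), len),
                  frame = sequence(len) - 1L, x = 0, y = 0)
  tr <- new("TrackSet", data = d, frameInterval = dt, exposure = dt)
  sp <- survivalProbability(tr)
  expect_warning(thr <- selectMinDurationThreshold(sp, 1:4),
                 "never converged")
  expect_identical(as.integer(thr), 4L)
})

test_that("bias correction follows k_true = k_s - k_bias", {
  his <- new("DoubleExpFit", fFast = 0.5, kNs = 2, kS = 0.15,
             minDurationFrames = 1L, minProbCut = 1e-3,
             degenerate = FALSE, loss = 0)
  est <- biasCorrectResidenceTime(0.33, his)
  expect_equal(tauRes(est), 1 / 0.18, tolerance = 1e-12)
  expect_equal(est@kSTrue, 0.18, tolerance = 1e-12)
  # zero bias reduces to 1/kS
  his0 <- new("DoubleExpFit", fFast = 0.5, kNs = 2, kS = 1e-9,
              minDurationFrames = 1L, minProbCut = 1e-3,
              degenerate = FALSE, loss = 0)
  expect_equal(tauRes(biasCorrectResidenceTime(0.33, his0)), 1 / 0.33,
               tolerance = 1e-4)
  # bias exceeding the signal is an error
  expect_error(biasCorrectResidenceTime(0.15, his), "bias exceeds signal")
  expect_error(biasCorrectResidenceTime(0.1, his), "bias exceeds signal")
})
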