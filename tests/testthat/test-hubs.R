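test_that("a blank image segments to zero nuclei", {
  set.seed(61)
  img <- matrix(rnorm(256 * 256, 20, 1), 256, 256)
  seg <- segmentNuclei(img, areaRange = c(1000, 20000))
  expect_identical(length(seg@area), 0L)
})

test_that("five discs are found as five near-disc labels", {
  sim <- simulateNucleusMovie(nucleusSimParams(nHubs = 0L, seed = 62L))
  seg <- segmentNuclei(frames(sim$movie)[[1]])
  big <- seg@area > 1500 & seg@eccentricity < 0.5
  expect_identical(sum(big), 5L)
  # areas within a 3-px band of the generator discs
  trueA <- pi * 30^2
  expect_true(all(abs(seg@area[big] - trueA) < pi * (33^2 - 30^2)))
})

test_that("an elongated bar is removed by the eccentricity cutoff", {
  set.seed(63)
  img <- matrix(rnorm(256 * 256, 20, 1), 256, 256)
  rr <- matrix(rep(1:256, 256), 256, 256); cc <- t(rr)
  img[(rr - 60)^2 + (cc - 60)^2 <= 28^2] <- 100          # disc
  img[rr > 150 & rr < 166 & cc > 30 & cc < 226] <- 100   # bar
  img <- img + rnorm(256 * 256)
  seg <- segmentNuclei(img, areaRange = c(1000, 20000), eccMax = 0.9)
  lab <- nucleusLabels(seg)
  # the disc survives; the bar region carries no label
  disc <- lab[55:65, 55:65]
  expect_true(all(disc > 0) && length(unique(c(disc))) == 1L)
  expect_true(all(lab[152:164, 60:200] == 0L))
  expect_true(all(seg@eccentricity <= 0.9))
})

test_that("percentile maps agree with the order-statistics oracle", {
  set.seed(64)
  lab <- matrix(0L, 64, 64)
  lab[10:49, 10:49] <- 1L  # 1600-px square nucleus
  img <- matrix(runif(64 * 64), 64, 64)
  lm <- new("NucleusLabelMap", labels = lab, area = 1600,
            eccentricity = 0)
  map <- relativeDensityMap(img, lm)
  p <- percentileMap(map)
  idx <- which(lab == 1L)
  # oracle: percentile of each pixel from a full sort
  v <- img[idx]
  oracle <- as.integer(ceiling(100 * rank(v, ties.method = "max") /
                                 length(v)))
  expect_identical(p[idx], oracle)
  expect_true(all(p[lab == 0L] == 0L))
  # a linear ramp puts exactly 15% of pixels above 85
  img2 <- matrix(0, 64, 64)
  img2[idx] <- seq_along(idx)
  map2 <- relativeDensityMap(img2, lm)
  expect_identical(sum(percentileMap(map2) > 85), as.integer(0.15 * 1600))
})

test_that("flat nuclei take the top tied percentile", {
  lab <- matrix(0L, 32, 32)
  lab[5:28, 5:28] <- 1L
  img <- matrix(7, 32, 32)
  map <- relativeDensityMap(img, new("NucleusLabelMap", labels = lab,
                                     area = 576, eccentricity = 0))
  p <- percentileMap(map)
  expect_true(all(p[lab == 1L] == 100L))
})

test_that("percentile maps are invariant to per-nucleus rescaling", {
  set.seed(65)
  lab <- matrix(0L, 64, 64)
  lab[5:28, 5:28] <- 1L
  lab[35:58, 35:58] <- 2L
  base <- matrix(runif(64 * 64), 64, 64)
  img1 <- base
  img2 <- base
  img2[lab == 2L] <- 40 + 7 * img2[lab == 2L]  # affine rescale nucleus 2
  lm <- new("NucleusLabelMap", labels = lab, area = c(576, 576),
            eccentricity = c(0, 0))
  expect_identical(percentileMap(relativeDensityMap(img1, lm)),
                   percentileMap(relativeDensityMap(img2, lm)))
})

test_that("trajectory density assignment averages visited percentiles", {
  perc <- matrix(0L, 20, 20)
  perc[5:15, 5:15] <- 50L
  perc[10, 10] <- 90L
  perc[10, 11] <- 80L
  lab <- (perc > 0L) * 1L
  map <- new("RelativeDensityMap", percentiles = perc,
             labels = matrix(as.integer(lab), 20, 20), pixelSizeXY = 0.1)
  # immobile on the 90-percentile pixel (row 10, col 10)
  d <- data.frame(id = 1L, frame = 0:2, x = 0.95, y = 0.95)
  tr <- new("TrackSet", data = d, frameInterval = 0.1, exposure = 0.1)
  expect_equal(unname(assignTrajectoryDensity(tr, map)), 90)
  # two localizations on 80 and 90 average to 85
  d2 <- data.frame(id = 1L, frame = 0:1, x = c(0.95, 1.05), y = 0.95)
  tr2 <- new("TrackSet", data = d2, frameInterval = 0.1, exposure = 0.1)
  expect_equal(unname(assignTrajectoryDensity(tr2, map)), 85)
  # a straddling trajectory ignores out-of-nucleus localizations
  d3 <- data.frame(id = 1L, frame = 0:2, x = c(0.95, 0.05, 0.05),
                   y = c(0.95, 0.05, 0.15))
  tr3 <- new("TrackSet", data = d3, frameInterval = 0.1, exposure = 0.1)
  expect_equal(unname(assignTrajectoryDensity(tr3, map)), 90)
})

test_that("enrichment counting matches exhaustive pixel enumeration", {
  set.seed(66)
  perc <- matrix(0L, 64, 64)
  idx <- as.matrix(expand.grid(10:50, 10:50))
  perc[idx] <- sample(1:100, nrow(idx), replace = TRUE)
  lab <- matrix(as.integer(perc > 0L), 64, 64)
  map <- new("RelativeDensityMap", percentiles = perc, labels = lab,
             pixelSizeXY = 0.1)
  n <- 400L
  px <- idx[sample.int(nrow(idx), n, replace = TRUE), ]
  d <- data.frame(id = seq_len(n), frame = 0L,
                  x = (px[, 2] - 0.5) * 0.1, y = (px[, 1] - 0.5) * 0.1)
  tr <- new("TrackSet", data = d, frameInterval = 0.1, exposure = 0.1)
  er <- foldEnrichment(tr, map, threshold = 85)
  pv <- perc[px]
  cin <- sum(pv > 85); cout <- sum(pv <= 85)
  ain <- sum(perc > 85); aout <- sum(perc > 0 & perc <= 85)
  expect_equal(c(er@countIn, er@countOut), c(cin, cout),
               ignore_attr = TRUE)
  expect_equal(c(er@areaIn, er@areaOut), c(ain, aout), ignore_attr = TRUE)
  expect_equal(enrichmentFold(er), (cin / ain) / (cout / aout),
               tolerance = 1e-12)
})

test_that("uniform placement yields unit fold enrichment end-to-end", {
  tracks <- list(); maps <- list()
  for (i in 1:4) {
    sim <- simulateNucleusMovie(nucleusSimParams(seed = 70L + i))
    img <- frames(sim$movie)[[1]]
    maps[[i]] <- relativeDensityMap(img, segmentNuclei(img))
    tracks[[i]] <- simulateBoundMoleculesInHubs(sim$hubMask,
                     sim$nucleusLabels, fold = 1, n = 2000L,
                     seed = 80L + i)
  }
  er <- foldEnrichment(tracks, maps)
  expect_lt(abs(enrichmentFold(er) - 1), 0.1)
})
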