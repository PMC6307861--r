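test_that("a locus-free volume yields no detections", {
  set.seed(71)
  sim <- simulateMs2Volumes(locusSimParams(locusAmplitude = 0,
                                           nTimepoints = 1L, seed = 71L))
  dets <- detectLoci(frames(sim$mcp)[[1]])
  expect_identical(nrow(dets), 0L)
})

test_that("a simulated locus is detected within one voxel of truth", {
  sim <- simulateMs2Volumes(locusSimParams(nTimepoints = 3L, seed = 72L))
  for (t in 1:3) {
    dets <- detectLoci(frames(sim$mcp)[[t]])
    expect_identical(nrow(dets), 1L)
    expect_lt(abs(dets$x - sim$path$x[t]), 0.1)
    expect_lt(abs(dets$y - sim$path$y[t]), 0.1)
    expect_lt(abs(dets$z - sim$path$z[t]), 0.25)
  }
})

test_that("component size filtering removes specks and blobs", {
  set.seed(73)
  vol <- array(rnorm(48 * 48 * 15, 10, 1), c(48, 48, 15))
  vol[24, 24, 8] <- 500                     # single hot voxel
  vol[5:40, 5:40, 3:12] <- 200              # enormous block
  dets <- detectLoci(vol, sizeRange = c(4, 1000))
  expect_identical(nrow(dets), 0L)
})

test_that("the contrast filter keeps nuclear loci and drops cytoplasmic ones", {
  sim <- simulateMs2Volumes(locusSimParams(nTimepoints = 1L, seed = 74L))
  vol <- frames(sim$mcp)[[1]]
  dets <- detectLoci(vol)
  kept <- contrastFilter(dets[1, ], vol)
  expect_true(kept$keep)
  expect_gt(kept$contrast, 2)
  # a fake detection planted in the bright cytoplasm corner
  fake <- dets[1, ]
  fake$row <- 6; fake$col <- 6; fake$slice <- 12
  fake$x <- 0.55; fake$y <- 0.55
  out <- contrastFilter(fake, vol)
  expect_false(out$keep)
  # a flat volume has ratio ~1 and is discarded
  set.seed(74)
  flat <- array(rnorm(48 * 48 * 15, 100, 0.5), c(48, 48, 15))
  f2 <- fake; f2$row <- 24; f2$col <- 24; f2$slice <- 8
  expect_false(contrastFilter(f2, flat)$keep)
})

test_that("locus tracking links drifting detections and splits on gaps", {
  det <- data.frame(timepoint = c(1, 2, 3, 5, 6),
                    x = c(1, 1.1, 1.2, 1.4, 1.5),
                    y = 1, z = 1)
  tr <- trackLoci(det, maxDisp = 0.5)
  expect_identical(length(unique(tr$track[tr$timepoint <= 3])), 1L)
  # the gap at timepoint 4 starts a new track
  expect_false(tr$track[4] == tr$track[3])
  # two loci in separate nuclei stay separate
  det2 <- data.frame(timepoint = rep(1:3, each = 2),
                     x = rep(c(1, 5), 3), y = 1, z = 1)
  tr2 <- trackLoci(det2, maxDisp = 0.5)
  expect_identical(length(unique(tr2$track)), 2L)
  expect_true(all(tapply(tr2$x, tr2$track, function(v)
    length(unique(v))) == 1L))
})

test_that("window retention matches the exhaustive geometric oracle", {
  n <- 128L
  ps <- 0.1
  mask <- discMask(n, c(64, 64), 38)
  tfFrames <- replicate(9, array(100, c(n, n, 3)), simplify = FALSE)
  tf <- new("Movie", frames = tfFrames, pixelSizeXY = ps, voxelSizeZ = 0.25,
            frameInterval = 5, channelLabel = "TF")
  # loci from the nucleus centre outwards, past the retention boundary
  pos <- data.frame(timepoint = 1:9,
                    x = 6.4 + seq(0, 2.4, by = 0.3), y = 6.4,
                    z = 0.375)
  w <- cropWindows(pos, tf, mask)
  oracle <- windowOracle(pos, mask, ps)
  expect_identical(w$kept$timepoint, which(oracle))
  expect_identical(dim(w$ts)[3], sum(oracle))
})

test_that("a uniform TF field gives a flat unit radial profile", {
  stack <- array(100, c(23, 23, 10))
  out <- averageAndRadialProfile(stack, 0.1)
  expect_true(all(abs(out$profile@meanIntensity - 1) < 1e-12))
})

test_that("locus-centred enrichment matches the analytic profile", {
  # average many noiseless windows with a centred Gaussian enrichment
  amp <- 0.5; sig <- 0.3; ps <- 0.1
  side <- 23L
  ctr <- (side + 1) / 2
  rr <- matrix(rep(seq_len(side), side), side, side)
  cc <- t(rr)
  r2 <- ((rr - ctr)^2 + (cc - ctr)^2) * ps^2
  img <- 100 * (1 + amp * exp(-r2 / (2 * sig^2)))
  stack <- array(rep(img, 40), c(side, side, 40))
  out <- averageAndRadialProfile(stack, ps)
  prof <- out$profile@meanIntensity
  # analytic expectation per annulus
  binIdx <- floor(sqrt(r2) / ps) + 1L
  ana <- tapply((1 + amp * exp(-r2 / (2 * sig^2))), binIdx, mean)
  ana <- as.numeric(ana[seq_along(prof)] / ana[length(prof)])
  expect_lt(max(abs(prof - ana)), 0.05)
  expect_gt(prof[1], 1.3)
})

test_that("TS and RS profiles are indistinguishable without enrichment", {
  sim <- simulateMs2Volumes(locusSimParams(tfEnrichmentAmplitude = 0,
                                           nTimepoints = 8L, seed = 75L))
  dets <- list()
  for (t in 1:8) {
    vol <- frames(sim$mcp)[[t]]
    dd <- detectLoci(vol)
    dd <- dd[contrastFilter(dd[1, ], vol)$keep, , drop = FALSE]
    if (nrow(dd)) { dd$timepoint <- t; dets[[length(dets) + 1L]] <- dd }
  }
  tr <- trackLoci(do.call(rbind, dets))
  w <- cropWindows(tr, sim$tf, sim$nucleusMask)
  nW <- dim(w$ts)[3]
  expect_gte(nW, 4L)
  ts <- averageAndRadialProfile(w$ts)$profile
  rs <- averageAndRadialProfile(w$rs)$profile
  # per-annulus Welch tests with Bonferroni at alpha 0.01
  nBins <- length(ts@radius)
  pvals <- vapply(seq_len(nBins - 1L), function(b) {
    se <- sqrt(ts@se[b]^2 + rs@se[b]^2)
    if (se == 0) return(1)
    2 * stats::pnorm(-abs(ts@meanIntensity[b] - rs@meanIntensity[b]) / se)
  }, 0)
  expect_true(all(pvals > 0.01 / nBins))
})
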