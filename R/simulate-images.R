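#' Parameters for the synthetic nucleus-image generator
#'
#' Nuclei are bright discs on a dim extranuclear field; each nucleus
#' contains amorphous high-density hubs modelled as interior Gaussian
#' bumps on the nucleoplasmic background, plus Gaussian read noise. The
#' nucleus radius denotes the full chromatin domain (where bound
#' molecules can sit); the bright nucleoplasmic core appears smaller by
#' \code{rimWidth} because point-spread blur and envelope-proximal
#' depletion dim the outermost shell, so the apparent half-intensity
#' radius is \code{radii - rimWidth / pixelSizeXY} with a smooth falloff
#' of s.d. \code{edgeSigma}.
#'
#' @param imageShape image size in pixels (rows, cols).
#' @param nNuclei number of nuclei (ignored when \code{centers} given).
#' @param centers optional matrix of nucleus centres (row, col), pixels.
#' @param radii nucleus (chromatin domain) radii in pixels (recycled).
#' @param rimWidth dim envelope-proximal rim, um.
#' @param edgeSigma intensity falloff s.d. at the core edge, um.
#' @param nHubs hubs per nucleus.
#' @param hubSigma hub Gaussian s.d., um.
#' @param hubAmplitude hub peak intensity relative to the nucleoplasmic
#'   background level.
#' @param backgroundLevel nucleoplasmic intensity, arbitrary units.
#' @param noiseSd Gaussian noise s.d., intensity units.
#' @param extranuclearLevel intensity outside nuclei.
#' @param pixelSizeXY micrometres per pixel.
#' @param hubPercentileCut ground-truth hubs are the pixels whose
#'   noiseless in-nucleus intensity percentile exceeds this cut.
#' @param seed integer seed.
#' @return validated parameter list (class \code{NucleusSimParams}).
#' @export
nucleusSimParams <- function(imageShape = c(512L, 512L), nNuclei = 5L,
                             centers = NULL, radii = 30, nHubs = 4L,
                             hubSigma = 0.3, hubAmplitude = 1.2,
                             backgroundLevel = 100, noiseSd = 3,
                             extranuclearLevel = 20, pixelSizeXY = 0.1,
                             rimWidth = 0.5, edgeSigma = 0.15,
                             hubPercentileCut = 85, seed = 1L) {
  p <- list(imageShape = as.integer(imageShape), nNuclei = as.integer(nNuclei),
            centers = centers, radii = radii, nHubs = as.integer(nHubs),
            hubSigma = hubSigma, hubAmplitude = hubAmplitude,
            backgroundLevel = backgroundLevel, noiseSd = noiseSd,
            extranuclearLevel = extranuclearLevel, pixelSizeXY = pixelSizeXY,
            rimWidth = rimWidth, edgeSigma = edgeSigma,
            hubPercentileCut = hubPercentileCut, seed = as.integer(seed))
  stopIfNot(p$hubAmplitude >= 0 && p$backgroundLevel >= 0,
            "amplitudes must be >= 0")
  stopIfNot(all(p$imageShape >= 32L), "image too small")
  class(p) <- "NucleusSimParams"
  p
}

# Place non-overlapping nucleus centres by rejection sampling.
placeNuclei <- function(shape, n, radius) {
  centers <- matrix(NA_real_, 0, 2)
  margin <- radius + 5
  tries <- 0L
  while (nrow(centers) < n && tries < 20000L) {
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    if (!nrow(centers) ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > 2 * radius + 8)
      centers <- rbind(centers, cand)
    tries <- tries + 1L
  }
  if (nrow(centers) < n)
    stop("could not place the requested nuclei; reduce nNuclei or radii")
  centers
}

#' Simulate a nucleus image with high-density hubs
#'
#' @param params a \code{\link{nucleusSimParams}} list.
#' @return list with \code{movie} (a single-frame
#'   \code{\linkS4class{Movie}}), \code{hubMask} (logical ground-truth
#'   matrix: noiseless in-nucleus percentile above the declared cut),
#'   \code{nucleusLabels} (integer matrix of true nucleus discs) and
#'   \code{noiseless} (the clean intensity field).
#' @export
simulateNucleusMovie <- function(params) {
  p <- params
  stopIfNot(inherits(p, "NucleusSimParams"),
            "params must come from nucleusSimParams()")
  withSeed(p$seed, {
    nr <- p$imageShape[1]; nc <- p$imageShape[2]
    radii <- rep(p$radii, length.out = p$nNuclei)
    centers <- if (is.null(p$centers))
      placeNuclei(p$imageShape, p$nNuclei, max(radii)) else p$centers
    stopIfNot(nrow(centers) == p$nNuclei || !is.null(p$centers),
              "centers/nNuclei mismatch")
    nNuc <- nrow(centers)
    radii <- rep(p$radii, length.out = nNuc)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    img <- matrix(p$extranuclearLevel, nr, nc)
    labels <- matrix(0L, nr, nc)
    hubSigmaPx <- p$hubSigma / p$pixelSizeXY
    rimPx <- p$rimWidth / p$pixelSizeXY
    edgePx <- max(p$edgeSigma / p$pixelSizeXY, 1e-6)
    for (k in seq_len(nNuc)) {
      d <- sqrt((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2)
      inside <- d <= radii[k]
      if (any(labels[inside] > 0)) stop("nuclei overlap")
      labels[inside] <- k
      # bright core: half-intensity radius radii - rim, smooth falloff
      w <- stats::pnorm((radii[k] - rimPx - d) / edgePx)
      img <- img + (p$backgroundLevel - p$extranuclearLevel) * w
      if (p$nHubs > 0 && p$hubAmplitude > 0) {
        ang <- stats::runif(p$nHubs, 0, 2 * pi)
        rad <- sqrt(stats::runif(p$nHubs)) * 0.7 * (radii[k] - rimPx)
        hr <- centers[k, 1] + rad * sin(ang)
        hc <- centers[k, 2] + rad * cos(ang)
        bump <- matrix(0, nr, nc)
        for (h in seq_len(p$nHubs))
          bump <- bump + exp(-((rr - hr[h])^2 + (cc - hc[h])^2) /
                               (2 * hubSigmaPx^2))
        img <- img + p$hubAmplitude * p$backgroundLevel * bump * w
      }
    }
    hubMask <- matrix(FALSE, nr, nc)
    for (k in seq_len(nNuc)) {
      idx <- which(labels == k)
      r <- rank(img[idx], ties.method = "max")
      perc <- ceiling(100 * r / length(idx))
      hubMask[idx[perc > p$hubPercentileCut]] <- TRUE
    }
    noisy <- img
    if (p$noiseSd > 0)
      noisy <- noisy + matrix(stats::rnorm(nr * nc, sd = p$noiseSd), nr, nc)
    movie <- methods::new("Movie", frames = list(noisy),
                          pixelSizeXY = p$pixelSizeXY,
                          frameInterval = 0.1, channelLabel = "bulk-TF")
    list(movie = movie, hubMask = hubMask, nucleusLabels = labels,
         noiseless = img)
  })
}

#' Place immobile bound-molecule trajectories with hub enrichment
#'
#' Short immobile trajectories are placed uniformly over the in-nucleus
#' pixels, with the per-pixel placement probability \code{fold} times
#' higher in hub pixels than elsewhere, so the expected number density
#' ratio equals \code{fold} exactly.
#'
#' @param hubMask logical matrix of hub pixels.
#' @param nucleusLabels integer matrix of nucleus labels (placement
#'   domain: labels > 0).
#' @param fold hub-to-nucleoplasm density ratio (>= 0).
#' @param n number of trajectories.
#' @param trackLength localizations per trajectory.
#' @param pixelSizeXY micrometres per pixel.
#' @param jitterSd s.d. of localization jitter within the trajectory, um.
#' @param seed integer seed.
#' @return a \code{\linkS4class{TrackSet}} (frame interval 0.1 s).
#' @export
simulateBoundMoleculesInHubs <- function(hubMask, nucleusLabels, fold = 2,
                                         n = 1000L, trackLength = 3L,
                                         pixelSizeXY = 0.1, jitterSd = 0.02,
                                         seed = 1L) {
  stopIfNot(fold >= 0, "fold must be >= 0")
  stopIfNot(all(dim(hubMask) == dim(nucleusLabels)), "shape mismatch")
  withSeed(seed, {
    inNuc <- which(nucleusLabels > 0)
    stopIfNot(length(inNuc) > 0, "no nucleus pixels")
    wts <- ifelse(hubMask[inNuc], fold, 1)
    pick <- inNuc[sample.int(length(inNuc), n, replace = TRUE,
                             prob = wts / sum(wts))]
    row <- (pick - 1L) %% nrow(hubMask) + 1L
    col <- (pick - 1L) %/% nrow(hubMask) + 1L
    # uniform position within the chosen pixel
    y0 <- (row - 1L + stats::runif(n)) * pixelSizeXY
    x0 <- (col - 1L + stats::runif(n)) * pixelSizeXY
    m <- as.integer(trackLength)
    d <- data.frame(
      id = rep(seq_len(n), each = m),
      frame = rep(seq_len(m) - 1L, times = n),
      x = rep(x0, each = m) + stats::rnorm(n * m, sd = jitterSd),
      y = rep(y0, each = m) + stats::rnorm(n * m, sd = jitterSd))
    methods::new("TrackSet", data = d, frameInterval = 0.1, exposure = 0.1)
  })
}

#' Parameters for the two-channel MS2 volume generator
#'
#' Emulates two-channel 4D imaging of an active transcription locus: the
#' coat-protein (MCP) channel shows dark nucleoplasm inside the nucleus,
#' bright cytoplasm outside, and one diffraction-limited locus following a
#' confined random walk; the TF channel shows a nucleoplasmic field with
#' an optional Gaussian enrichment co-centred on the locus.
#'
#' @param volumeShape voxels (rows, cols, slices).
#' @param nTimepoints number of volumes.
#' @param nucleusRadius nucleus radius, um (circular in xy, all z).
#' @param locusAmplitude peak locus intensity above nucleoplasm (MCP).
#' @param locusSigma locus Gaussian s.d. in lateral voxels (z scaled by
#'   anisotropy).
#' @param cytoplasmLevel,nucleoplasmLevel MCP-channel levels
#'   (cytoplasm must exceed nucleoplasm: that contrast is what the
#'   detector's line-profile filter exploits).
#' @param tfLevel TF-channel nucleoplasmic level.
#' @param tfExtranuclearLevel TF-channel level outside the nucleus.
#' @param tfEnrichmentAmplitude TF enrichment peak as a fraction of
#'   \code{tfLevel} (0 disables).
#' @param tfEnrichmentSigma TF enrichment s.d., um.
#' @param stepSd locus random-walk step s.d. per timepoint, um.
#' @param confinementRadius locus confinement about the nucleus centre,
#'   um.
#' @param noiseSd Gaussian noise s.d. in both channels.
#' @param pixelSizeXY,voxelSizeZ voxel pitch, um.
#' @param seed integer seed.
#' @return validated parameter list (class \code{LocusSimParams}).
#' @export
locusSimParams <- function(volumeShape = c(96L, 96L, 25L), nTimepoints = 5L,
                           nucleusRadius = 3.9, locusAmplitude = 300,
                           locusSigma = 1.3, cytoplasmLevel = 150,
                           nucleoplasmLevel = 30, tfLevel = 100,
                           tfExtranuclearLevel = 40,
                           tfEnrichmentAmplitude = 0.5,
                           tfEnrichmentSigma = 0.3, stepSd = 0.1,
                           confinementRadius = 1, noiseSd = 2,
                           pixelSizeXY = 0.1, voxelSizeZ = 0.25,
                           seed = 1L) {
  p <- list(volumeShape = as.integer(volumeShape),
            nTimepoints = as.integer(nTimepoints),
            nucleusRadius = nucleusRadius, locusAmplitude = locusAmplitude,
            locusSigma = locusSigma, cytoplasmLevel = cytoplasmLevel,
            nucleoplasmLevel = nucleoplasmLevel, tfLevel = tfLevel,
            tfExtranuclearLevel = tfExtranuclearLevel,
            tfEnrichmentAmplitude = tfEnrichmentAmplitude,
            tfEnrichmentSigma = tfEnrichmentSigma, stepSd = stepSd,
            confinementRadius = confinementRadius, noiseSd = noiseSd,
            pixelSizeXY = pixelSizeXY, voxelSizeZ = voxelSizeZ,
            seed = as.integer(seed))
  stopIfNot(p$cytoplasmLevel > p$nucleoplasmLevel,
            "cytoplasmLevel must exceed nucleoplasmLevel")
  stopIfNot(p$nucleusRadius * 2 < min(p$volumeShape[1:2]) * p$pixelSizeXY,
            "nucleus does not fit in the volume")
  class(p) <- "LocusSimParams"
  p
}

#' Simulate two-channel MS2 volumes with ground truth
#'
#' @param params a \code{\link{locusSimParams}} list.
#' @return list with \code{mcp} and \code{tf}
#'   (\code{\linkS4class{Movie}} objects whose frames are 3D volumes),
#'   \code{nucleusMask} (logical xy matrix) and \code{path} (data.frame of
#'   true locus positions per timepoint, um).
#' @export
simulateMs2Volumes <- function(params) {
  p <- params
  stopIfNot(inherits(p, "LocusSimParams"),
            "params must come from locusSimParams()")
  withSeed(p$seed, {
    d <- p$volumeShape
    ps <- p$pixelSizeXY; vz <- p$voxelSizeZ
    ctrY <- d[1] / 2 * ps; ctrX <- d[2] / 2 * ps; ctrZ <- d[3] / 2 * vz
    rr <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
    cc <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    yUm <- pixelCentre(rr, ps); xUm <- pixelCentre(cc, ps)
    nucleusMask <- (yUm - ctrY)^2 + (xUm - ctrX)^2 <= p$nucleusRadius^2
    zUm <- pixelCentre(seq_len(d[3]), vz)
    sigZ <- p$locusSigma * ps  # isotropic in um
    # confined random walk of the locus about the nucleus centre
    path <- matrix(0, p$nTimepoints, 3)
    pos <- c(0, 0, 0)
    for (t in seq_len(p$nTimepoints)) {
      repeat {
        cand <- pos + stats::rnorm(3, sd = p$stepSd)
        if (sqrt(sum(cand[1:2]^2)) <= p$confinementRadius &&
            abs(cand[3]) <= min(p$confinementRadius, (d[3] * vz) / 4)) break
      }
      pos <- cand
      path[t, ] <- pos
    }
    pathUm <- data.frame(timepoint = seq_len(p$nTimepoints),
                         x = ctrX + path[, 1], y = ctrY + path[, 2],
                         z = ctrZ + path[, 3])
    mkVol <- function(base2d, t, amp, sigUm) {
      vol <- array(rep(base2d, d[3]), d)
      if (amp > 0) {
        g2 <- exp(-((yUm - pathUm$y[t])^2 + (xUm - pathUm$x[t])^2) /
                    (2 * sigUm^2))
        gz <- exp(-(zUm - pathUm$z[t])^2 / (2 * sigUm^2))
        for (z in seq_len(d[3]))
          vol[, , z] <- vol[, , z] + amp * g2 * gz[z] * nucleusMask
      }
      if (p$noiseSd > 0)
        vol <- vol + array(stats::rnorm(prod(d), sd = p$noiseSd), d)
      vol
    }
    mcpBase <- ifelse(nucleusMask, p$nucleoplasmLevel, p$cytoplasmLevel)
    tfBase <- ifelse(nucleusMask, p$tfLevel, p$tfExtranuclearLevel)
    mcpFrames <- lapply(seq_len(p$nTimepoints), function(t)
      mkVol(mcpBase, t, p$locusAmplitude, sigZ))
    tfFrames <- lapply(seq_len(p$nTimepoints), function(t)
      mkVol(tfBase, t, p$tfEnrichmentAmplitude * p$tfLevel,
            p$tfEnrichmentSigma))
    mcp <- methods::new("Movie", frames = mcpFrames, pixelSizeXY = ps,
                        voxelSizeZ = vz, frameInterval = 5,
                        channelLabel = "MCP")
    tf <- methods::new("Movie", frames = tfFrames, pixelSizeXY = ps,
                       voxelSizeZ = vz, frameInterval = 5,
                       channelLabel = "TF")
    list(mcp = mcp, tf = tf, nucleusMask = nucleusMask, path = pathUm)
  })
}
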