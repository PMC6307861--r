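#' Segment nuclei from a bulk fluorescence image
#'
#' Fixed pipeline: Gaussian blur (sigma 5 px) -> adaptive local-mean
#' threshold -> binary dilation (disc radius 3) -> optional ROI mask
#' multiply -> hole filling -> connected-component labelling -> removal of
#' components failing the area or eccentricity cutoffs. The adaptive
#' threshold marks a pixel foreground when its blurred intensity exceeds
#' the local mean (computed over a window of about 1/8 of the image side)
#' times (1.6 - sensitivity).
#'
#' @param image numeric matrix (grayscale).
#' @param sigma Gaussian blur s.d., pixels.
#' @param sensitivity adaptive-threshold sensitivity in [0, 1]; higher
#'   marks more foreground.
#' @param dilationRadius disc radius for the morphological dilation, px.
#' @param roiMask optional logical/0-1 matrix multiplied into the binary
#'   mask (stand-in for the hand-drawn embryo-edge mask).
#' @param areaRange keep components with area in this range, px.
#' @param eccMax drop components with ellipse eccentricity above this.
#' @param windowFraction adaptive-threshold window size as a fraction of
#'   the image side.
#' @param noiseFloorMads additive guard on the adaptive threshold, in MADs
#'   of the high-frequency residual: prevents a structure-free (blank)
#'   field, where half the pixels sit above their local mean by chance,
#'   from segmenting into noise blobs. Negligible against genuine
#'   nucleus/background contrast.
#' @return a \code{\linkS4class{NucleusLabelMap}} (possibly with zero
#'   labels).
#' @export
segmentNuclei <- function(image, sigma = 5, sensitivity = 0.6,
                          dilationRadius = 3, roiMask = NULL,
                          areaRange = c(1000, 20000), eccMax = 0.9,
                          windowFraction = 1 / 8, noiseFloorMads = 3) {
  stopIfNot(is.matrix(image), "image must be a matrix")
  g <- EBImage::gblur(image, sigma = sigma)
  w <- 2L * floor(min(dim(image)) * windowFraction / 2) + 1L
  box <- matrix(1 / (w * w), w, w)
  localMean <- EBImage::filter2(g, box, boundary = "replicate")
  floorAbs <- noiseFloorMads * stats::mad(g - localMean)
  fg <- g > localMean * (1.6 - sensitivity) + floorAbs
  if (dilationRadius > 0)
    fg <- EBImage::dilate(fg, EBImage::makeBrush(2L * dilationRadius + 1L,
                                                 shape = "disc"))
  if (!is.null(roiMask)) fg <- fg & (roiMask > 0)
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow = nrow(image))
  nLab <- max(lab)
  if (nLab == 0L)
    return(methods::new("NucleusLabelMap", labels = lab, area = numeric(0),
                        eccentricity = numeric(0)))
  area <- tabulate(lab[lab > 0], nbins = nLab)
  ecc <- labelEccentricity(lab, nLab)
  keep <- which(area >= areaRange[1] & area <= areaRange[2] & ecc <= eccMax)
  relabel <- integer(nLab + 1L)
  relabel[keep + 1L] <- seq_along(keep)
  lab <- matrix(relabel[lab + 1L], nrow = nrow(lab))
  methods::new("NucleusLabelMap", labels = lab, area = area[keep],
               eccentricity = ecc[keep])
}

# Ellipse eccentricity of each label from central second moments.
labelEccentricity <- function(lab, nLab) {
  px <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  n <- tabulate(l, nbins = nLab)
  mr <- rowsum(px[, 1], l)[, 1] / n
  mc <- rowsum(px[, 2], l)[, 1] / n
  dr <- px[, 1] - mr[l]
  dc <- px[, 2] - mc[l]
  mu20 <- rowsum(dr * dr, l)[, 1] / n
  mu02 <- rowsum(dc * dc, l)[, 1] / n
  mu11 <- rowsum(dr * dc, l)[, 1] / n
  tr <- mu20 + mu02
  det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  lMax <- (tr + det) / 2
  lMin <- (tr - det) / 2
  ifelse(lMax <= 0, 0, sqrt(pmax(1 - lMin / lMax, 0)))
}

#' Per-nucleus relative density (percentile) map
#'
#' Each in-nucleus pixel is assigned the integer percentile (resolution 1,
#' values 1..100) of its intensity within its own nucleus's intensity
#' distribution, making the map invariant to per-nucleus brightness
#' scaling. Tied intensity blocks take the maximum rank of the block
#' (which decides hub membership in degenerate flat nuclei). Background
#' pixels are 0.
#'
#' @param image numeric matrix, same shape as the label map.
#' @param labelMap a \code{\linkS4class{NucleusLabelMap}}.
#' @param pixelSizeXY micrometres per pixel, carried for trajectory
#'   assignment.
#' @return a \code{\linkS4class{RelativeDensityMap}}.
#' @export
relativeDensityMap <- function(image, labelMap, pixelSizeXY = 0.1) {
  lab <- nucleusLabels(labelMap)
  stopIfNot(all(dim(image) == dim(lab)), "image/label shape mismatch")
  perc <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_len(max(lab, 0L))) {
    idx <- which(lab == k)
    n <- length(idx)
    if (n == 0L) next
    if (n < 100L)
      warning(sprintf("nucleus %d has %d px; percentile resolution degraded",
                      k, n))
    r <- rank(image[idx], ties.method = "max")
    perc[idx] <- as.integer(ceiling(100 * r / n))
  }
  methods::new("RelativeDensityMap", percentiles = perc, labels = lab,
               pixelSizeXY = pixelSizeXY)
}

#' Mean relative density visited by each trajectory
#'
#' Looks up the percentile value under each localization's pixel and
#' averages over the trajectory; localizations outside any nucleus are
#' excluded, and a trajectory entirely outside gets \code{NA}.
#'
#' @param tracks a \code{\linkS4class{TrackSet}} with coordinates in um.
#' @param map a \code{\linkS4class{RelativeDensityMap}}.
#' @return named numeric vector of mean percentiles, one per trajectory.
#' @export
assignTrajectoryDensity <- function(tracks, map) {
  d <- trackData(tracks)
  ps <- pixelSizeXY(map)
  perc <- percentileMap(map)
  row <- umToPixel(d$y, ps)
  col <- umToPixel(d$x, ps)
  ok <- row >= 1 & row <= nrow(perc) & col >= 1 & col <= ncol(perc)
  v <- rep(NA_real_, nrow(d))
  v[ok] <- perc[cbind(row[ok], col[ok])]
  v[!is.na(v) & v == 0] <- NA  # outside any nucleus
  out <- tapply(v, factor(d$id, levels = unique(d$id)),
                function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  stats::setNames(as.numeric(out), names(out))
}

#' Fold enrichment of trajectories in high-density hubs
#'
#' A trajectory counts as in-hub when its mean visited relative density
#' exceeds the threshold percentile. Trajectory counts and pixel areas are
#' accumulated across all supplied nucleus images before the density ratio
#' (count per unit area in hubs over count per unit area in the remaining
#' nucleoplasm) is formed.
#'
#' @param tracks a \code{\linkS4class{TrackSet}} or list of them (one per
#'   image).
#' @param maps a \code{\linkS4class{RelativeDensityMap}} or list parallel
#'   to \code{tracks}.
#' @param threshold hub percentile cut, in (0, 100); default 85.
#' @return an \code{\linkS4class{EnrichmentResult}}. A zero out-of-hub
#'   count leaves the ratio \code{NA} with a warning.
#' @export
foldEnrichment <- function(tracks, maps, threshold = 85) {
  stopIfNot(threshold > 0 && threshold < 100, "threshold must be in (0, 100)")
  if (!is.list(tracks)) tracks <- list(tracks)
  if (!is.list(maps)) maps <- list(maps)
  stopIfNot(length(tracks) == length(maps),
            "tracks and maps must have the same length")
  cin <- cout <- ain <- aout <- 0
  for (i in seq_along(tracks)) {
    dens <- assignTrajectoryDensity(tracks[[i]], maps[[i]])
    dens <- dens[!is.na(dens)]
    cin <- cin + sum(dens > threshold)
    cout <- cout + sum(dens <= threshold)
    p <- percentileMap(maps[[i]])
    ain <- ain + sum(p > threshold)
    aout <- aout + sum(p > 0L & p <= threshold)
  }
  if (cout == 0 || ain == 0 || aout == 0) {
    warning("undefined enrichment ratio (empty compartment)")
    fold <- NA_real_
  } else {
    fold <- (cin / ain) / (cout / aout)
  }
  methods::new("EnrichmentResult", thresholdPercentile = threshold,
               countIn = cin, countOut = cout, areaIn = ain, areaOut = aout,
               foldEnrichment = fold, nNucleusImages = length(tracks))
}
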