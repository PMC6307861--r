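# Separable 3D Gaussian blur: 2D blur per z-slice plus a 1D pass along z
# with the sigma scaled by the voxel anisotropy.
gaussianBlur3d <- function(vol, sigmaXY, sigmaZ) {
  d <- dim(vol)
  out <- vol
  for (z in seq_len(d[3]))
    out[, , z] <- EBImage::gblur(out[, , z], sigma = sigmaXY)
  if (sigmaZ > 0 && d[3] > 1) {
    half <- max(1L, ceiling(3 * sigmaZ))
    kz <- stats::dnorm(-half:half, sd = sigmaZ)
    kz <- kz / sum(kz)
    res <- array(0, d)
    for (j in seq_along(kz)) {
      off <- j - half - 1L
      zs <- pmin(pmax(seq_len(d[3]) + off, 1L), d[3])  # replicate edges
      res <- res + out[, , zs, drop = FALSE] * kz[j]
    }
    out <- res
  }
  out
}

# 26-connectivity labelling of a sparse voxel set (linear indices into an
# array of dimension `dims`) by union-find.
labelVoxels <- function(idx, dims) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  ord <- order(idx)
  idx <- idx[ord]
  arr <- arrayInd(idx, dims)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin <- function(a) (a[, 3] - 1) * dims[1] * dims[2] + (a[, 2] - 1) * dims[1] + a[, 1]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(arr, 2L, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    m <- match(lin(nb[ok, , drop = FALSE]), idx)
    hit <- which(ok)[!is.na(m)]
    m <- m[!is.na(m)]
    for (q in seq_along(hit)) {
      a <- findRoot(hit[q]); b <- findRoot(m[q])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), findRoot, 0L)
  out <- integer(n)
  out[ord] <- match(roots, unique(roots))
  out
}

#' Detect diffraction-limited loci in a 3D volume
#'
#' Difference-of-Gaussians filtering (small minus large sigma, z sigmas
#' scaled by voxel anisotropy), global thresholding at median plus
#' \code{threshold} MADs of the DoG response, 26-connected component
#' labelling, a component-size filter, and an intensity-weighted centroid
#' per surviving component.
#'
#' @param volume 3D array (rows = y, cols = x, slices = z).
#' @param dogSigmas small and large Gaussian s.d. in lateral voxels.
#' @param threshold MAD multiplier for the global threshold.
#' @param sizeRange keep components whose voxel count lies inside.
#' @param pixelSizeXY,voxelSizeZ voxel pitch, um.
#' @return data.frame with one row per locus: weighted centroid
#'   \code{x,y,z} (um), \code{row,col,slice} (voxels), \code{nVoxels},
#'   \code{peak} intensity.
#' @export
detectLoci <- function(volume, dogSigmas = c(1.3, 3.9), threshold = 8,
                       sizeRange = c(4, 1000), pixelSizeXY = 0.1,
                       voxelSizeZ = 0.25) {
  stopIfNot(length(dim(volume)) == 3, "volume must be a 3D array")
  aniso <- pixelSizeXY / voxelSizeZ
  dog <- gaussianBlur3d(volume, dogSigmas[1], dogSigmas[1] * aniso) -
    gaussianBlur3d(volume, dogSigmas[2], dogSigmas[2] * aniso)
  med <- stats::median(dog)
  madv <- stats::mad(dog)
  cut <- med + threshold * madv
  idx <- which(dog > cut)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      row = numeric(0), col = numeric(0), slice = numeric(0),
                      nVoxels = integer(0), peak = numeric(0))
  if (!length(idx)) return(empty)
  lab <- labelVoxels(idx, dim(volume))
  arr <- arrayInd(idx, dim(volume))
  w <- volume[idx]
  out <- lapply(split(seq_along(idx), lab), function(ii) {
    if (length(ii) < sizeRange[1] || length(ii) > sizeRange[2]) return(NULL)
    ww <- w[ii] / sum(w[ii])
    r <- sum(arr[ii, 1] * ww); c <- sum(arr[ii, 2] * ww)
    s <- sum(arr[ii, 3] * ww)
    data.frame(x = pixelCentre(c, pixelSizeXY), y = pixelCentre(r, pixelSizeXY),
               z = pixelCentre(s, voxelSizeZ), row = r, col = c, slice = s,
               nVoxels = length(ii), peak = max(w[ii]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Contrast-filter a locus detection
#'
#' Line profiles are extracted one micron in each direction from the
#' detection centre along the x and y axes at the centroid z-slice; the
#' max/min ratio of each profile is formed, and the detection is kept when
#' the mean ratio reaches \code{minRatio}. In-nucleus loci sit in dark
#' nucleoplasm (high ratio); detections in the bright extranuclear
#' background have ratios near 1 and are discarded. The centroid is
#' refined to the profile maximum.
#'
#' @param detection one row of \code{\link{detectLoci}} output.
#' @param volume the 3D volume the detection came from.
#' @param halfLength profile half-length, um.
#' @param minRatio minimum mean max/min ratio.
#' @param pixelSizeXY,voxelSizeZ voxel pitch, um.
#' @return the detection row with refined \code{x,y}, added
#'   \code{contrast}, and attribute-free logical column \code{keep}.
#' @export
contrastFilter <- function(detection, volume, halfLength = 1, minRatio = 2,
                           pixelSizeXY = 0.1, voxelSizeZ = 0.25) {
  d <- dim(volume)
  r0 <- round(detection$row); c0 <- round(detection$col)
  s0 <- min(max(round(detection$slice), 1L), d[3])
  hl <- round(halfLength / pixelSizeXY)
  rows <- pmin(pmax(r0 + (-hl:hl), 1L), d[1])
  cols <- pmin(pmax(c0 + (-hl:hl), 1L), d[2])
  profY <- volume[cbind(rows, rep(c0, length(rows)), rep(s0, length(rows)))]
  profX <- volume[cbind(rep(r0, length(cols)), cols, rep(s0, length(cols)))]
  eps <- 1e-12
  ratio <- mean(c(max(profX) / max(min(profX), eps),
                  max(profY) / max(min(profY), eps)))
  detection$contrast <- ratio
  detection$keep <- ratio >= minRatio
  if (detection$keep) {
    detection$col <- cols[which.max(profX)]
    detection$row <- rows[which.max(profY)]
    detection$x <- pixelCentre(detection$col, pixelSizeXY)
    detection$y <- pixelCentre(detection$row, pixelSizeXY)
  }
  detection
}

#' Link locus detections over time by nearest neighbours
#'
#' Greedy nearest-neighbour linking between consecutive timepoints with a
#' distance gate; ties go to the smaller displacement. No gap closing: a
#' missed detection splits the track.
#'
#' @param detections data.frame of detections with a \code{timepoint}
#'   column (as from \code{\link{detectLoci}} rows over time).
#' @param maxDisp linking gate, um.
#' @return the input with a \code{track} column added.
#' @export
trackLoci <- function(detections, maxDisp = 1) {
  stopIfNot(nrow(detections) > 0, "no detections")
  detections <- detections[order(detections$timepoint), ]
  detections$track <- NA_integer_
  nextId <- 1L
  tps <- sort(unique(detections$timepoint))
  prevIdx <- which(detections$timepoint == tps[1])
  detections$track[prevIdx] <- seq_len(length(prevIdx))
  nextId <- length(prevIdx) + 1L
  for (ti in seq_along(tps)[-1]) {
    curIdx <- which(detections$timepoint == tps[ti])
    gap <- tps[ti] - tps[ti - 1L] > 1L
    used <- rep(FALSE, length(prevIdx))
    for (ci in curIdx) detections$track[ci] <- NA_integer_
    if (!gap && length(prevIdx)) {
      dmat <- outer(detections$x[curIdx], detections$x[prevIdx], "-")^2 +
        outer(detections$y[curIdx], detections$y[prevIdx], "-")^2 +
        outer(detections$z[curIdx], detections$z[prevIdx], "-")^2
      dmat <- sqrt(dmat)
      repeat {
        if (!length(dmat) || all(!is.finite(dmat)) || min(dmat) > maxDisp)
          break
        pick <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        ci <- curIdx[pick[1]]; pi <- prevIdx[pick[2]]
        detections$track[ci] <- detections$track[pi]
        dmat[pick[1], ] <- Inf
        dmat[, pick[2]] <- Inf
      }
    }
    for (ci in curIdx) {
      if (is.na(detections$track[ci])) {
        detections$track[ci] <- nextId
        nextId <- nextId + 1L
      }
    }
    prevIdx <- curIdx
  }
  detections
}

#' Crop locus and control windows from the TF channel
#'
#' For each tracked locus timepoint, the TF volume is max-projected over a
#' z range of one nuclear diameter about the locus and a square window of
#' side \code{windowUm} is cropped at the locus position; the window is
#' kept only when it lies fully inside the nucleus mask. A control window
#' is cropped at \code{controlOffsetUm} from the locus, scanning angles in
#' \code{angleStepDeg} increments until the control window also lies fully
#' in-nucleus; if no angle works the locus timepoint is discarded.
#'
#' @param track data.frame rows of one locus track (needs \code{timepoint},
#'   \code{x}, \code{y}, \code{z}).
#' @param tfMovie \code{\linkS4class{Movie}} whose frames are TF-channel 3D
#'   volumes (one per timepoint).
#' @param nucleusMask logical matrix (xy) marking in-nucleus pixels.
#' @param windowUm window side, um (2.18 default).
#' @param controlOffsetUm locus-to-control distance, um (2.6 default).
#' @param zHalfUm half-extent of the z max projection, um (2.5: one
#'   nuclear diameter overall).
#' @param angleStepDeg control-angle scan step, degrees.
#' @return list with \code{ts} and \code{rs} (window stacks, px x px x n),
#'   and \code{kept} (data.frame of timepoint and control angle; discarded
#'   timepoints are absent).
#' @export
cropWindows <- function(track, tfMovie, nucleusMask, windowUm = 2.18,
                        controlOffsetUm = 2.6, zHalfUm = 2.5,
                        angleStepDeg = 10) {
  stopIfNot(windowUm > 0 && controlOffsetUm > 0,
            "window and offset must be > 0")
  ps <- pixelSizeXY(tfMovie)
  vz <- tfMovie@voxelSizeZ
  hw <- round(windowUm / 2 / ps)
  side <- 2L * hw + 1L
  angles <- seq(0, 350, by = angleStepDeg) * pi / 180
  ts <- list(); rs <- list(); kept <- list()
  fullyIn <- function(r0, c0) {
    if (r0 - hw < 1 || c0 - hw < 1 || r0 + hw > nrow(nucleusMask) ||
        c0 + hw > ncol(nucleusMask)) return(FALSE)
    all(nucleusMask[(r0 - hw):(r0 + hw), (c0 - hw):(c0 + hw)])
  }
  for (i in seq_len(nrow(track))) {
    tp <- track$timepoint[i]
    vol <- frames(tfMovie)[[tp]]
    r0 <- umToPixel(track$y[i], ps); c0 <- umToPixel(track$x[i], ps)
    if (!fullyIn(r0, c0)) next
    zc <- if (is.na(vz)) 1L else umToPixel(track$z[i], vz)
    zr <- if (is.na(vz)) 1L else
      max(1L, zc - round(zHalfUm / vz)):min(dim(vol)[3], zc + round(zHalfUm / vz))
    proj <- apply(vol[, , zr, drop = FALSE], c(1, 2), max)
    ctrl <- NULL
    for (a in angles) {
      rc <- r0 + round(controlOffsetUm * sin(a) / ps)
      cc <- c0 + round(controlOffsetUm * cos(a) / ps)
      if (fullyIn(rc, cc)) { ctrl <- c(rc, cc, a); break }
    }
    if (is.null(ctrl)) next
    ts[[length(ts) + 1L]] <- proj[(r0 - hw):(r0 + hw), (c0 - hw):(c0 + hw)]
    rs[[length(rs) + 1L]] <-
      proj[(ctrl[1] - hw):(ctrl[1] + hw), (ctrl[2] - hw):(ctrl[2] + hw)]
    kept[[length(kept) + 1L]] <-
      data.frame(timepoint = tp, angle = ctrl[3] * 180 / pi)
  }
  toStack <- function(l) {
    if (!length(l)) return(array(0, c(side, side, 0)))
    array(unlist(l), c(side, side, length(l)))
  }
  list(ts = toStack(ts), rs = toStack(rs),
       kept = if (length(kept)) do.call(rbind, kept) else
         data.frame(timepoint = integer(0), angle = numeric(0)))
}

#' Average a window stack and compute its radial profile
#'
#' Pixelwise mean across windows, then a radial profile over one-pixel
#' annuli about the window centre, normalized to 1 at the outermost
#' annulus; the per-annulus standard error across windows is carried with
#' the same normalization.
#'
#' @param stack window stack (px x px x n).
#' @param pixelSizeXY micrometres per pixel.
#' @return list with \code{meanImage} and \code{profile} (a
#'   \code{\linkS4class{RadialProfile}}).
#' @export
averageAndRadialProfile <- function(stack, pixelSizeXY = 0.1) {
  stopIfNot(length(dim(stack)) == 3 && dim(stack)[3] >= 1,
            "stack must contain at least one window")
  side <- dim(stack)[1]
  n <- dim(stack)[3]
  ctr <- (side + 1) / 2
  rr <- matrix(rep(seq_len(side), side), side, side)
  cc <- t(rr)
  distPx <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  binIdx <- floor(distPx) + 1L
  nBins <- (side - 1L) %/% 2L + 1L
  use <- binIdx <= nBins
  perWin <- matrix(0, nBins, n)
  for (i in seq_len(n)) {
    w <- stack[, , i]
    perWin[, i] <- rowsum(w[use], binIdx[use])[, 1] /
      tabulate(binIdx[use], nBins)
  }
  meanProf <- rowMeans(perWin)
  norm <- meanProf[nBins]
  stopIfNot(is.finite(norm) && norm != 0, "outermost annulus mean is zero")
  se <- if (n > 1) apply(perWin, 1L, stats::sd) / sqrt(n) else rep(0, nBins)
  prof <- methods::new("RadialProfile",
    radius = ((seq_len(nBins) - 1L) + 0.5) * pixelSizeXY,
    meanIntensity = meanProf / norm, se = se / abs(norm),
    nWindows = as.integer(n))
  list(meanImage = apply(stack, c(1, 2), mean), profile = prof)
}
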