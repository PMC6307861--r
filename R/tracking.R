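#' Detect single-molecule spots in one frame
#'
#' Laplacian-of-Gaussian filtering at the PSF scale, thresholding of the
#' response at median + \code{thresholdMads} * MAD, local-maximum
#' selection, and sub-pixel refinement by intensity-weighted centroid in a
#' 5x5 window.
#'
#' @param frame numeric matrix.
#' @param sigmaPsf PSF s.d., pixels.
#' @param thresholdMads MAD multiplier above the median response.
#' @param pixelSizeXY micrometres per pixel for the output coordinates.
#' @return data.frame with columns \code{x}, \code{y} (um),
#'   \code{row}, \code{col} (px), \code{intensity} and \code{snr}; empty
#'   when nothing is found.
#' @export
detectSpots <- function(frame, sigmaPsf = 1.3, thresholdMads = 6,
                        pixelSizeXY = 0.1) {
  stopIfNot(sigmaPsf > 0, "sigmaPsf must be > 0")
  empty <- data.frame(x = numeric(0), y = numeric(0), row = numeric(0),
                      col = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  # LoG via difference of Gaussians at sigma and 1.6 sigma (standard
  # blob-detector approximation)
  g1 <- EBImage::gblur(frame, sigma = sigmaPsf)
  g2 <- EBImage::gblur(frame, sigma = 1.6 * sigmaPsf)
  resp <- g1 - g2
  med <- stats::median(resp)
  madv <- stats::mad(resp)
  if (madv == 0) return(empty)
  cut <- med + thresholdMads * madv
  nr <- nrow(frame); nc <- ncol(frame)
  cand <- which(resp > cut, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 2 & cand[, 1] < nr - 1 &
                 cand[, 2] > 2 & cand[, 2] < nc - 1, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  isMax <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    resp[r, c] >= max(resp[(r - 1):(r + 1), (c - 1):(c + 1)])
  }, TRUE)
  cand <- cand[isMax, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  bg <- stats::median(frame)
  noiseSd <- stats::mad(frame)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    win <- frame[(r - 2):(r + 2), (c - 2):(c + 2)] - bg
    win[win < 0] <- 0
    if (sum(win) == 0) return(NULL)
    dr <- sum((-2:2) * rowSums(win)) / sum(win)
    dc <- sum((-2:2) * colSums(win)) / sum(win)
    data.frame(x = pixelCentre(c + dc, pixelSizeXY),
               y = pixelCentre(r + dr, pixelSizeXY),
               row = r + dr, col = c + dc,
               intensity = sum(win),
               snr = if (noiseSd > 0) (frame[r, c] - bg) / noiseSd else Inf)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Link per-frame localizations into trajectories
#'
#' Greedy mutual-nearest-neighbour assignment between consecutive frames
#' with a displacement gate; unmatched trajectory ends may bridge up to
#' \code{maxGap} missing frames. Ties are broken by the smaller
#' displacement, then by the lower spot index.
#'
#' @param locs list of data.frames (one per frame, as from
#'   \code{\link{detectSpots}}); empty frames allowed.
#' @param maxDisp maximum displacement per frame step, um.
#' @param maxGap maximum number of bridged missing frames.
#' @param frameInterval,exposure seconds, recorded in the output.
#' @return a \code{\linkS4class{TrackSet}}.
#' @export
linkTrajectories <- function(locs, maxDisp = 0.5, maxGap = 1L,
                             frameInterval = 0.01,
                             exposure = frameInterval) {
  stopIfNot(maxDisp > 0, "maxDisp must be > 0")
  stopIfNot(maxGap >= 0, "maxGap must be >= 0")
  active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       lastFrame = integer(0))
  rows <- list()
  nextId <- 1L
  for (f in seq_along(locs)) {
    cur <- locs[[f]]
    n <- if (is.null(cur)) 0L else nrow(cur)
    assigned <- rep(NA_integer_, n)
    if (n && nrow(active)) {
      # candidate pairs within the gate, gap-aware
      gapOk <- f - active$lastFrame <= maxGap + 1L
      cand <- which(gapOk)
      if (length(cand)) {
        dmat <- sqrt(outer(cur$x, active$x[cand], "-")^2 +
                       outer(cur$y, active$y[cand], "-")^2)
        steps <- (f - active$lastFrame[cand])
        gate <- sweep(dmat, 2L, maxDisp * steps, "<=")
        dmat[!gate] <- Inf
        repeat {
          if (!any(is.finite(dmat))) break
          m <- which(dmat == min(dmat), arr.ind = TRUE)
          m <- m[order(m[, 1], m[, 2]), , drop = FALSE][1, ]
          i <- m[1]; j <- m[2]
          # mutual nearest neighbour check
          if (which.min(dmat[i, ]) == j && which.min(dmat[, j]) == i) {
            assigned[i] <- active$id[cand[j]]
            dmat[i, ] <- Inf
            dmat[, j] <- Inf
          } else {
            dmat[i, j] <- Inf
          }
        }
      }
    }
    if (n) {
      newSpot <- is.na(assigned)
      assigned[newSpot] <- seq_len(sum(newSpot)) + nextId - 1L
      nextId <- nextId + sum(newSpot)
      rows[[f]] <- data.frame(id = assigned, frame = f - 1L,
                              x = cur$x, y = cur$y,
                              intensity = if ("intensity" %in% names(cur))
                                cur$intensity else NA_real_)
      # update or append active entries
      for (i in seq_len(n)) {
        k <- match(assigned[i], active$id)
        if (is.na(k)) {
          active <- rbind(active,
                          data.frame(id = assigned[i], x = cur$x[i],
                                     y = cur$y[i], lastFrame = f))
        } else {
          active$x[k] <- cur$x[i]; active$y[k] <- cur$y[i]
          active$lastFrame[k] <- f
        }
      }
    }
    active <- active[f - active$lastFrame <= maxGap, , drop = FALSE]
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), intensity = numeric(0))
  d <- d[order(d$id, d$frame), ]
  rownames(d) <- NULL
  methods::new("TrackSet", data = d, frameInterval = frameInterval,
               exposure = exposure)
}
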