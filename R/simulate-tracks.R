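#' Parameters for the two-state trajectory simulator
#'
#' Builds the parameter block consumed by \code{\link{simulateTrajectories}}.
#' Molecules are assigned bound (specific or non-specific) or free at steady
#' state; each state carries its own apparent diffusion coefficient. Tracks
#' end at the first of unbinding, photobleaching, axial exit from the
#' detection slice, or movie end.
#'
#' @param nMolecules number of molecules to simulate.
#' @param fBound fraction of molecules in the bound (immobile) state.
#' @param dBound,dFree apparent diffusion coefficients, um^2/s.
#' @param sigmaLoc localization error s.d. per axis, um.
#' @param frameInterval time between frames, s.
#' @param exposure camera exposure, s. At exposures of 100 ms and longer
#'   fast-moving molecules blur into the background; the simulator renders a
#'   molecule in a frame only if it is bound for at least
#'   \code{blurBoundFractionThreshold} of the exposure.
#' @param nFrames movie length, frames.
#' @param sliceDepth axial detection range (slab full width), um. Free
#'   molecules start uniform in the slab and are lost on first exit.
#' @param kOffSpecific,kOffNonspecific off-rates of the two bound classes,
#'   1/s (0 means the class never unbinds).
#' @param fSpecific fraction of bound molecules in the specific class.
#' @param kBleach photobleaching rate, 1/s.
#' @param blurBoundFractionThreshold motion-blur detectability gate.
#' @param dAxialBound axial diffusion coefficient of bound molecules,
#'   um^2/s. Default 0: a bound molecule rides its chromatin locus, whose
#'   axial excursions are negligible relative to the slab on the
#'   measurement timescale, so bound-track loss is dominated by bleaching
#'   (the premise of the histone-based bias correction).
#' @param fov side of the square field of view in which molecules appear,
#'   um.
#' @param seed integer seed; every simulation is deterministic given it.
#' @return a named list of validated parameters (class
#'   \code{TwoStateSimParams}).
#' @export
twoStateSimParams <- function(nMolecules = 10000L, fBound = 0.5,
                              dBound = 0.25, dFree = 3.5, sigmaLoc = 0.03,
                              frameInterval = 0.01, exposure = frameInterval,
                              nFrames = 30L, sliceDepth = 0.8,
                              kOffSpecific = 0.18, kOffNonspecific = 2,
                              fSpecific = 0.5, kBleach = 0.15,
                              blurBoundFractionThreshold = 0.6,
                              dAxialBound = 0, fov = 20, seed = 1L) {
  p <- list(nMolecules = as.integer(nMolecules), fBound = fBound,
            dBound = dBound, dFree = dFree, sigmaLoc = sigmaLoc,
            frameInterval = frameInterval, exposure = exposure,
            nFrames = as.integer(nFrames), sliceDepth = sliceDepth,
            kOffSpecific = kOffSpecific, kOffNonspecific = kOffNonspecific,
            fSpecific = fSpecific, kBleach = kBleach,
            blurBoundFractionThreshold = blurBoundFractionThreshold,
            dAxialBound = dAxialBound, fov = fov, seed = as.integer(seed))
  stopIfNot(p$fBound >= 0 && p$fBound <= 1, "fBound must lie in [0, 1]")
  stopIfNot(p$fSpecific >= 0 && p$fSpecific <= 1,
            "fSpecific must lie in [0, 1]")
  stopIfNot(all(c(p$kOffSpecific, p$kOffNonspecific, p$kBleach) >= 0),
            "rates must be >= 0")
  stopIfNot(p$sliceDepth > 0, "sliceDepth must be > 0")
  stopIfNot(p$frameInterval > 0 && p$nFrames >= 1,
            "need frameInterval > 0 and nFrames >= 1")
  stopIfNot(all(c(p$dBound, p$dFree, p$sigmaLoc, p$dAxialBound) >= 0),
            "diffusion coefficients and sigmaLoc must be >= 0")
  class(p) <- "TwoStateSimParams"
  p
}

#' Kinetic parameter presets
#'
#' Named presets encoding the bound fractions and specific residence times
#' the analysis modules are validated against: \code{"zld_like"} (bound
#' fraction 0.5, specific residence time 5.56 s), \code{"bcd_like"} (0.5,
#' 2.33 s) and \code{"his2b_like"} (0.88, stably bound: the specific class
#' never unbinds, so track duration is limited by bleaching and
#' defocalization only). Diffusion coefficients are implementation
#' defaults chosen in the range typical for nuclear factors, ordered so the
#' bound-state mobility is lowest for the histone.
#'
#' @param name one of \code{"zld_like"}, \code{"bcd_like"},
#'   \code{"his2b_like"}.
#' @param ... overrides passed on to \code{\link{twoStateSimParams}}.
#' @return a \code{TwoStateSimParams} list.
#' @export
kineticPreset <- function(name = c("zld_like", "bcd_like", "his2b_like"),
                          ...) {
  name <- match.arg(name)
  base <- switch(name,
    zld_like  = list(fBound = 0.5, dBound = 0.25, dFree = 3.5,
                     kOffSpecific = 1 / 5.56),
    bcd_like  = list(fBound = 0.5, dBound = 0.3, dFree = 4.5,
                     kOffSpecific = 1 / 2.33),
    his2b_like = list(fBound = 0.88, dBound = 0.15, dFree = 4.5,
                      kOffSpecific = 0))
  over <- list(...)
  do.call(twoStateSimParams, utils::modifyList(base, over))
}

# Cumulative sum restarting at each TRUE in `starts`.
groupCumsum <- function(x, starts) {
  cs <- cumsum(x)
  offset <- cs[starts] - x[starts]
  grp <- cumsum(starts)
  cs - offset[grp]
}

# First-exit times of free Brownian motion from the slab [-L/2, L/2] with
# absorbing boundaries, starting uniform. Steps of dt/nsub with a Brownian
# bridge test for boundary crossings inside each step, so absorption is
# continuous-time accurate (a plain discrete check would behave like a
# wider slab).
axialExitTimes <- function(n, d, dt, nFrames, sliceDepth, nsub = 4L) {
  if (n == 0L) return(numeric(0))
  if (d <= 0) return(rep(Inf, n))
  half <- sliceDepth / 2
  nStep <- nFrames * nsub
  h <- dt / nsub
  sdStep <- sqrt(2 * d * h)
  var2 <- sdStep^2
  tExit <- rep(Inf, n)
  alive <- seq_len(n)
  z <- stats::runif(n, -half, half)
  for (s in seq_len(nStep)) {
    zOld <- z[alive]
    zNew <- zOld + stats::rnorm(length(alive), sd = sdStep)
    out <- abs(zNew) > half
    inn <- !out
    if (any(inn)) {
      # bridge crossing probabilities for the upper and lower barriers
      pUp <- exp(-2 * (half - zOld[inn]) * (half - zNew[inn]) / var2)
      pLo <- exp(-2 * (half + zOld[inn]) * (half + zNew[inn]) / var2)
      cross <- stats::runif(sum(inn)) < pmin(pUp + pLo, 1)
      out[inn][cross] <- TRUE
    }
    if (any(out)) {
      tExit[alive[out]] <- (s - 0.5) * h
      z[alive[!out]] <- zNew[!out]
      alive <- alive[!out]
      if (!length(alive)) break
    } else {
      z[alive] <- zNew
    }
  }
  tExit
}

#' Simulate mixed bound/free single-molecule trajectories
#'
#' Forward model of single-molecule imaging through a finite axial
#' detection slice: molecules are bound (specific or non-specific) or free
#' at steady state, move by 2D Brownian steps with their state's diffusion
#' coefficient, and are observed with i.i.d. Gaussian localization error.
#' Free molecules additionally diffuse axially and are lost on first exit
#' from the slab. A track ends at the first of unbinding, photobleaching,
#' axial exit, or movie end. At exposures of 100 ms or longer, molecules
#' bound for less than \code{blurBoundFractionThreshold} of the exposure
#' are motion-blurred into the background and never rendered.
#'
#' @param params a \code{\link{twoStateSimParams}} list.
#' @return list with \code{tracks} (a \code{\linkS4class{TrackSet}}) and
#'   \code{truth}, a data.frame recording each rendered molecule's state
#'   and true event times (seconds): \code{tUnbind}, \code{tBleach},
#'   \code{tExitZ}, \code{tEnd} and the rendered track length \code{nLoc}.
#' @export
simulateTrajectories <- function(params) {
  p <- params
  stopIfNot(inherits(p, "TwoStateSimParams"),
            "params must come from twoStateSimParams()")
  withSeed(p$seed, {
    n <- p$nMolecules
    dt <- p$frameInterval
    bound <- stats::runif(n) < p$fBound
    specific <- bound & (stats::runif(n) < p$fSpecific)
    state <- ifelse(!bound, "free", ifelse(specific, "specific", "nonspecific"))
    kOff <- ifelse(!bound, 0,
                   ifelse(specific, p$kOffSpecific, p$kOffNonspecific))
    tUnbind <- rep(Inf, n)
    pos <- kOff > 0
    tUnbind[pos] <- stats::rexp(sum(pos), kOff[pos])
    tBleach <- rexpSafe(n, p$kBleach)
    tExit <- rep(Inf, n)
    free <- !bound
    tExit[free] <- axialExitTimes(sum(free), p$dFree, dt, p$nFrames,
                                  p$sliceDepth)
    if (p$dAxialBound > 0)
      tExit[bound] <- axialExitTimes(sum(bound), p$dAxialBound, dt,
                                     p$nFrames, p$sliceDepth)
    movieEnd <- p$nFrames * dt
    tEnd <- pmin(tUnbind, tBleach, tExit, movieEnd)

    blurGate <- p$exposure >= 0.1
    if (blurGate) {
      # rendered frames require the molecule bound for >= threshold of the
      # exposure; free molecules never qualify
      nLocUnbind <- floor((tUnbind - p$blurBoundFractionThreshold *
                             p$exposure) / dt) + 1
      nLocUnbind[!bound] <- 0
    } else {
      nLocUnbind <- ceiling(pmin(tUnbind, movieEnd) / dt)
    }
    nLocOther <- ceiling(pmin(tBleach, tExit, movieEnd) / dt)
    nLoc <- pmin(nLocUnbind, nLocOther, p$nFrames)
    nLoc <- pmax(nLoc, 0)
    keep <- nLoc >= 1
    if (!any(keep)) stop("no molecules rendered; check parameters")

    id <- seq_len(n)[keep]
    nk <- as.integer(nLoc[keep])
    total <- sum(nk)
    rowId <- rep(seq_along(id), nk)
    starts <- c(TRUE, diff(rowId) != 0)
    frame <- sequence(nk) - 1L
    dCoef <- ifelse(bound, p$dBound, p$dFree)[keep]
    sdStep <- sqrt(2 * dCoef * dt)[rowId]
    dx <- stats::rnorm(total, sd = sdStep)
    dy <- stats::rnorm(total, sd = sdStep)
    x0 <- stats::runif(length(id), 0, p$fov)
    y0 <- stats::runif(length(id), 0, p$fov)
    dx[starts] <- x0
    dy[starts] <- y0
    x <- groupCumsum(dx, starts)
    y <- groupCumsum(dy, starts)
    if (p$sigmaLoc > 0) {
      x <- x + stats::rnorm(total, sd = p$sigmaLoc)
      y <- y + stats::rnorm(total, sd = p$sigmaLoc)
    }
    tracks <- methods::new("TrackSet",
      data = data.frame(id = rep(id, nk), frame = frame, x = x, y = y),
      frameInterval = dt, exposure = p$exposure)
    truth <- data.frame(id = seq_len(n), state = state, tUnbind = tUnbind,
                        tBleach = tBleach, tExitZ = tExit, tEnd = tEnd,
                        nLoc = as.integer(nLoc))
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a stably bound histone (His2B-like) control
#'
#' As \code{\link{simulateTrajectories}} but the specific class never
#' unbinds: its tracks end only by bleaching, defocalization or movie end,
#' so the slow rate of a survival fit to these tracks measures the
#' track-loss bias shared by all chromatin-bound molecules.
#'
#' @param params a \code{\link{twoStateSimParams}} list; the specific
#'   off-rate is forced to 0.
#' @return a \code{\linkS4class{TrackSet}}.
#' @export
simulateHis2bControl <- function(params = kineticPreset("his2b_like")) {
  params$kOffSpecific <- 0
  simulateTrajectories(params)$tracks
}
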