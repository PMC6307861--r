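#' @import methods
NULL

#' Movie: a multi-frame fluorescence image stack
#'
#' Container for 2D time series (each frame a matrix) or 4D xyz-t stacks
#' (each frame a 3D array). Intensities are kept in acquisition units.
#'
#' @slot frames list of 2D matrices or 3D arrays, acquisition order.
#' @slot pixelSizeXY lateral sampling, micrometres per pixel.
#' @slot voxelSizeZ axial plane spacing in micrometres (\code{NA} for 2D data).
#' @slot frameInterval time between frames, seconds.
#' @slot channelLabel free-text channel name.
#' @slot embryoPositionEL anteroposterior position as a fraction of embryo
#'   length in [0, 1] (\code{NA} when unknown).
#' @exportClass Movie
setClass("Movie",
  slots = c(
    frames = "list",
    pixelSizeXY = "numeric",
    voxelSizeZ = "numeric",
    frameInterval = "numeric",
    channelLabel = "character",
    embryoPositionEL = "numeric"
  ),
  prototype = list(
    frames = list(),
    pixelSizeXY = 0.1,
    voxelSizeZ = NA_real_,
    frameInterval = 1,
    channelLabel = "",
    embryoPositionEL = NA_real_
  )
)

setValidity("Movie", function(object) {
  msg <- NULL
  if (length(object@frames)) {
    d <- lapply(object@frames, dim)
    if (length(unique(vapply(d, paste, "", collapse = "x"))) != 1L)
      msg <- c(msg, "all frames must share one shape")
  }
  if (!isTRUE(object@pixelSizeXY > 0))
    msg <- c(msg, "pixelSizeXY must be > 0")
  if (!isTRUE(object@frameInterval > 0))
    msg <- c(msg, "frameInterval must be > 0")
  if (!is.na(object@embryoPositionEL) &&
      (object@embryoPositionEL < 0 || object@embryoPositionEL > 1))
    msg <- c(msg, "embryoPositionEL must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' TrackSet: a set of single-molecule trajectories
#'
#' Long-format table of sub-pixel localizations grouped by trajectory id.
#' Coordinates are in micrometres; \code{frame} is a 0-based acquisition
#' index. Within each trajectory frames are strictly increasing; gaps (from
#' gap-closing linkers) are permitted.
#'
#' @slot data data.frame with columns \code{id}, \code{frame}, \code{x},
#'   \code{y} and optionally \code{intensity}.
#' @slot frameInterval seconds between consecutive frames.
#' @slot exposure camera exposure per frame, seconds.
#' @exportClass TrackSet
setClass("TrackSet",
  slots = c(data = "data.frame", frameInterval = "numeric",
            exposure = "numeric"),
  prototype = list(
    data = data.frame(id = integer(), frame = integer(),
                      x = numeric(), y = numeric()),
    frameInterval = 0.01, exposure = 0.01
  )
)

setValidity("TrackSet", function(object) {
  d <- object@data
  msg <- NULL
  need <- c("id", "frame", "x", "y")
  if (!all(need %in% names(d)))
    return(sprintf("data must contain columns %s", paste(need, collapse = ", ")))
  if (!isTRUE(object@frameInterval > 0))
    msg <- c(msg, "frameInterval must be > 0")
  if (nrow(d)) {
    o <- order(d$id, d$frame)
    ds <- d[o, ]
    same <- ds$id[-1] == ds$id[-nrow(ds)]
    if (any(same & diff(ds$frame) <= 0))
      msg <- c(msg, "frames must be strictly increasing within each trajectory")
  }
  if (is.null(msg)) TRUE else msg
})

#' DisplacementSet: displacement magnitudes grouped by frameshift
#'
#' Displacements r (micrometres) at lag k * frameInterval for
#' k = 1 .. timepoints - 1, with a per-trajectory cap on the number of jumps
#' contributed to each lag group.
#'
#' @slot displacements list of numeric vectors, one per frameshift.
#' @slot frameInterval seconds.
#' @slot nTracks number of trajectories compiled.
#' @exportClass DisplacementSet
setClass("DisplacementSet",
  slots = c(displacements = "list", frameInterval = "numeric",
            nTracks = "integer"))

#' TwoStateFit: bound fraction and diffusion coefficients
#'
#' Result of fitting displacement distributions at multiple frameshifts to a
#' two-state (bound / free) Brownian mixture with localization error and a
#' defocalization weight on the free component.
#'
#' @slot fBound bound (immobile) fraction in [0, 1].
#' @slot dBound,dFree apparent diffusion coefficients, um^2/s.
#' @slot sigmaLoc fitted localization error s.d. per axis, um.
#' @slot sliceDepth axial detection range used for the correction, um.
#' @slot loss summed squared residuals of the best fit.
#' @slot nInit number of random initializations tried.
#' @exportClass TwoStateFit
setClass("TwoStateFit",
  slots = c(fBound = "numeric", dBound = "numeric", dFree = "numeric",
            sigmaLoc = "numeric", sliceDepth = "numeric", loss = "numeric",
            nInit = "integer"))

setValidity("TwoStateFit", function(object) {
  msg <- NULL
  if (object@fBound < 0 || object@fBound > 1)
    msg <- c(msg, "fBound must lie in [0, 1]")
  if (!(object@dBound >= 0 && object@dBound < object@dFree))
    msg <- c(msg, "need 0 <= dBound < dFree")
  if (is.null(msg)) TRUE else msg
})

#' SurvivalCurve: survival probability of trajectory durations
#'
#' @slot time duration grid, seconds (integer multiples of the frame
#'   interval).
#' @slot prob fraction of trajectories lasting at least each duration.
#' @slot nTracks number of trajectories.
#' @slot frameInterval seconds.
#' @exportClass SurvivalCurve
setClass("SurvivalCurve",
  slots = c(time = "numeric", prob = "numeric", nTracks = "integer",
            frameInterval = "numeric"))

setValidity("SurvivalCurve", function(object) {
  msg <- NULL
  if (length(object@time) != length(object@prob))
    msg <- c(msg, "time and prob must have equal length")
  if (length(object@prob)) {
    if (any(diff(object@prob) > 1e-12))
      msg <- c(msg, "survival probability must be non-increasing")
    if (abs(object@prob[1] - 1) > 1e-12)
      msg <- c(msg, "survival probability must start at 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' DoubleExpFit: two-exponential survival-probability fit
#'
#' SP(t) = F exp(-kNs t) + (1 - F) exp(-kS t), fitted after discarding
#' durations below a minimum number of frames and probabilities below a cut.
#'
#' @slot fFast amplitude of the fast (non-specific) component.
#' @slot kNs,kS fast and slow off-rates, 1/s, with kNs > kS.
#' @slot minDurationFrames duration threshold used, frames.
#' @slot minProbCut survival probabilities below this were excluded.
#' @slot degenerate TRUE when the two rates are within 5 percent.
#' @slot loss summed squared residuals.
#' @exportClass DoubleExpFit
setClass("DoubleExpFit",
  slots = c(fFast = "numeric", kNs = "numeric", kS = "numeric",
            minDurationFrames = "integer", minProbCut = "numeric",
            degenerate = "logical", loss = "numeric"))

setValidity("DoubleExpFit", function(object) {
  msg <- NULL
  if (!(object@kNs > 0 && object@kS > 0 && object@kNs >= object@kS))
    msg <- c(msg, "need kNs >= kS > 0")
  if (object@fFast < 0 || object@fFast > 1)
    msg <- c(msg, "fFast must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' ResidenceTimeEstimate: bias-corrected specific residence time
#'
#' @slot kS slow off-rate from the target protein's survival fit, 1/s.
#' @slot kBias slow rate of the histone (His2B) control fit, 1/s; measures
#'   photobleaching plus residual track-loss processes.
#' @slot kSTrue kS - kBias, 1/s.
#' @slot tauRes 1 / kSTrue, seconds.
#' @exportClass ResidenceTimeEstimate
setClass("ResidenceTimeEstimate",
  slots = c(kS = "numeric", kBias = "numeric", kSTrue = "numeric",
            tauRes = "numeric"))

setValidity("ResidenceTimeEstimate", function(object) {
  msg <- NULL
  if (!isTRUE(object@kSTrue > 0))
    msg <- c(msg, "kSTrue must be > 0")
  if (abs(object@kSTrue - (object@kS - object@kBias)) > 1e-9)
    msg <- c(msg, "kSTrue must equal kS - kBias")
  if (abs(object@tauRes - 1 / object@kSTrue) > 1e-9)
    msg <- c(msg, "tauRes must equal 1 / kSTrue")
  if (is.null(msg)) TRUE else msg
})

#' TamsdCurve: time- and ensemble-averaged mean square displacement
#'
#' @slot lag lag times, seconds, strictly increasing.
#' @slot msd mean square displacement per lag, um^2.
#' @slot nPairs number of displacement pairs contributing to each lag.
#' @exportClass TamsdCurve
setClass("TamsdCurve",
  slots = c(lag = "numeric", msd = "numeric", nPairs = "integer"))

setValidity("TamsdCurve", function(object) {
  msg <- NULL
  if (any(object@msd < 0)) msg <- c(msg, "msd must be >= 0")
  if (any(diff(object@lag) <= 0)) msg <- c(msg, "lags must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' AnomalousFit: power-law fit MSD(tau) = Gamma tau^alpha
#'
#' @slot gamma generalized diffusion coefficient, um^2/s^alpha.
#' @slot alpha anomalous exponent; 1 for free diffusion, < 1 sub-diffusive.
#' @slot lagRange lag range used for the fit, seconds.
#' @exportClass AnomalousFit
setClass("AnomalousFit",
  slots = c(gamma = "numeric", alpha = "numeric", lagRange = "numeric"))

setValidity("AnomalousFit", function(object) {
  if (object@alpha <= 0 || object@alpha > 2)
    "alpha must lie in (0, 2]" else TRUE
})

#' NucleusLabelMap: segmented nuclei
#'
#' @slot labels integer matrix, 0 = background, nuclei labelled 1..K.
#' @slot area per-label pixel counts.
#' @slot eccentricity per-label ellipse eccentricity in [0, 1).
#' @exportClass NucleusLabelMap
setClass("NucleusLabelMap",
  slots = c(labels = "matrix", area = "numeric", eccentricity = "numeric"))

#' RelativeDensityMap: per-nucleus percentile-ranked intensity map
#'
#' Each in-nucleus pixel carries the integer percentile (1..100) of its
#' intensity within its own nucleus; background pixels are 0. Tied blocks
#' take the maximum rank of the block.
#'
#' @slot percentiles integer matrix of percentile values.
#' @slot labels the nucleus label matrix the map was computed on.
#' @slot pixelSizeXY micrometres per pixel.
#' @exportClass RelativeDensityMap
setClass("RelativeDensityMap",
  slots = c(percentiles = "matrix", labels = "matrix",
            pixelSizeXY = "numeric"))

#' EnrichmentResult: binding enrichment in high-density hubs
#'
#' @slot thresholdPercentile relative-density cut defining hubs (default 85).
#' @slot countIn,countOut trajectories inside / outside hubs.
#' @slot areaIn,areaOut hub and non-hub nucleoplasm areas, pixels.
#' @slot foldEnrichment (countIn/areaIn) / (countOut/areaOut).
#' @slot nNucleusImages number of nucleus images accumulated.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  slots = c(thresholdPercentile = "numeric", countIn = "numeric",
            countOut = "numeric", areaIn = "numeric", areaOut = "numeric",
            foldEnrichment = "numeric", nNucleusImages = "integer"))

setValidity("EnrichmentResult", function(object) {
  msg <- NULL
  if (any(c(object@countIn, object@countOut) < 0))
    msg <- c(msg, "counts must be >= 0")
  if (!is.na(object@foldEnrichment) &&
      object@countOut > 0 && object@areaIn > 0 && object@areaOut > 0) {
    f <- (object@countIn / object@areaIn) / (object@countOut / object@areaOut)
    if (abs(f - object@foldEnrichment) > 1e-9)
      msg <- c(msg, "foldEnrichment inconsistent with counts and areas")
  }
  if (is.null(msg)) TRUE else msg
})

#' RadialProfile: locus-centred average intensity versus radius
#'
#' @slot radius annulus centre radii, micrometres.
#' @slot meanIntensity mean intensity per annulus, normalized to 1 at the
#'   outermost annulus.
#' @slot se standard error per annulus across windows (same normalization).
#' @slot nWindows number of windows averaged.
#' @exportClass RadialProfile
setClass("RadialProfile",
  slots = c(radius = "numeric", meanIntensity = "numeric", se = "numeric",
            nWindows = "integer"))

setValidity("RadialProfile", function(object) {
  n <- length(object@radius)
  if (n && abs(object@meanIntensity[n] - 1) > 1e-9)
    "profile must be 1 at the outermost radius" else TRUE
})

#' FrapExperiment: bleach, control and dark spot traces
#'
#' @slot bleach,control,dark matrices, frames x spots.
#' @slot frameInterval seconds (default 0.024).
#' @slot nPre pre-bleach frames (default 10).
#' @slot measurementRadius radius of the measurement circle, um (0.3, i.e. a
#'   600 nm diameter circle).
#' @exportClass FrapExperiment
setClass("FrapExperiment",
  slots = c(bleach = "matrix", control = "matrix", dark = "matrix",
            frameInterval = "numeric", nPre = "integer",
            measurementRadius = "numeric"),
  prototype = list(frameInterval = 0.024, nPre = 10L,
                   measurementRadius = 0.3))

setValidity("FrapExperiment", function(object) {
  msg <- NULL
  if (object@nPre < 1) msg <- c(msg, "nPre must be >= 1")
  nf <- nrow(object@bleach)
  if (nrow(object@control) != nf || nrow(object@dark) != nf)
    msg <- c(msg, "all trace matrices must have the same number of frames")
  if (is.null(msg)) TRUE else msg
})

#' ReactionDominantFit: FRAP(t) = 1 - A exp(-kA t) - B exp(-kB t)
#'
#' @slot aAmp,bAmp amplitudes A and B.
#' @slot kA,kB exchange rates, 1/s.
#' @slot tHalfSlow ln(2) / min(kA, kB), seconds: half-recovery time of the
#'   bound (slow) population.
#' @slot degenerate TRUE when the two rates are within 5 percent.
#' @exportClass ReactionDominantFit
setClass("ReactionDominantFit",
  slots = c(aAmp = "numeric", bAmp = "numeric", kA = "numeric",
            kB = "numeric", tHalfSlow = "numeric", degenerate = "logical"))

setValidity("ReactionDominantFit", function(object) {
  msg <- NULL
  if (!(object@kA > 0 && object@kB > 0))
    msg <- c(msg, "rates must be > 0")
  if (abs(object@tHalfSlow - log(2) / min(object@kA, object@kB)) > 1e-9)
    msg <- c(msg, "tHalfSlow must equal ln(2)/min(kA, kB)")
  if (is.null(msg)) TRUE else msg
})
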