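# Accessor generics. Slot access from user code goes through these.

#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))
#' @export
setGeneric("trackLengths", function(x) standardGeneric("trackLengths"))
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("pixelSizeXY", function(x) standardGeneric("pixelSizeXY"))
#' @export
setGeneric("fBound", function(x) standardGeneric("fBound"))
#' @export
setGeneric("dBound", function(x) standardGeneric("dBound"))
#' @export
setGeneric("dFree", function(x) standardGeneric("dFree"))
#' @export
setGeneric("slowRate", function(x) standardGeneric("slowRate"))
#' @export
setGeneric("fastRate", function(x) standardGeneric("fastRate"))
#' @export
setGeneric("tauRes", function(x) standardGeneric("tauRes"))
#' @export
setGeneric("enrichmentFold", function(x) standardGeneric("enrichmentFold"))
#' @export
setGeneric("nucleusLabels", function(x) standardGeneric("nucleusLabels"))
#' @export
setGeneric("percentileMap", function(x) standardGeneric("percentileMap"))
#' @export
setGeneric("tHalfSlow", function(x) standardGeneric("tHalfSlow"))
#' @export
setGeneric("alphaExponent", function(x) standardGeneric("alphaExponent"))

#' Accessors for smtf classes
#'
#' Small read-only accessors returning the documented quantity for each
#' result class.
#'
#' @param x an smtf S4 object.
#' @name accessors
#' @aliases trackData frameInterval nTracks trackLengths frames pixelSizeXY
#'   fBound dBound dFree slowRate fastRate tauRes enrichmentFold
#'   nucleusLabels percentileMap tHalfSlow alphaExponent
NULL

setMethod("trackData", "TrackSet", function(x) x@data)
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)
setMethod("frameInterval", "Movie", function(x) x@frameInterval)
setMethod("frameInterval", "SurvivalCurve", function(x) x@frameInterval)
setMethod("nTracks", "TrackSet", function(x) length(unique(x@data$id)))
setMethod("trackLengths", "TrackSet", function(x) {
  if (!nrow(x@data)) return(integer())
  as.integer(table(factor(x@data$id, levels = unique(x@data$id))))
})
setMethod("frames", "Movie", function(x) x@frames)
setMethod("pixelSizeXY", "Movie", function(x) x@pixelSizeXY)
setMethod("pixelSizeXY", "RelativeDensityMap", function(x) x@pixelSizeXY)
setMethod("fBound", "TwoStateFit", function(x) x@fBound)
setMethod("dBound", "TwoStateFit", function(x) x@dBound)
setMethod("dFree", "TwoStateFit", function(x) x@dFree)
setMethod("slowRate", "DoubleExpFit", function(x) x@kS)
setMethod("fastRate", "DoubleExpFit", function(x) x@kNs)
setMethod("tauRes", "ResidenceTimeEstimate", function(x) x@tauRes)
setMethod("enrichmentFold", "EnrichmentResult", function(x) x@foldEnrichment)
setMethod("nucleusLabels", "NucleusLabelMap", function(x) x@labels)
setMethod("nucleusLabels", "RelativeDensityMap", function(x) x@labels)
setMethod("percentileMap", "RelativeDensityMap", function(x) x@percentiles)
setMethod("tHalfSlow", "ReactionDominantFit", function(x) x@tHalfSlow)
setMethod("alphaExponent", "AnomalousFit", function(x) x@alpha)

setMethod("show", "Movie", function(object) {
  d <- if (length(object@frames)) paste(dim(object@frames[[1]]), collapse = " x ") else "empty"
  cat("Movie:", length(object@frames), "frame(s) of", d, "\n")
  cat("  pixel", object@pixelSizeXY, "um,",
      if (!is.na(object@voxelSizeZ)) paste("z-step", object@voxelSizeZ, "um,") else "",
      "frame interval", object@frameInterval, "s\n")
  if (nzchar(object@channelLabel)) cat("  channel:", object@channelLabel, "\n")
})

setMethod("show", "TrackSet", function(object) {
  cat("TrackSet:", nTracks(object), "trajectories,",
      nrow(object@data), "localizations\n")
  cat("  frame interval", object@frameInterval, "s, exposure",
      object@exposure, "s\n")
})

setMethod("show", "DisplacementSet", function(object) {
  cat("DisplacementSet:", length(object@displacements), "frameshift group(s),",
      object@nTracks, "trajectories\n")
  n <- vapply(object@displacements, length, 0L)
  cat("  jumps per group:", paste(n, collapse = ", "), "\n")
})

setMethod("show", "TwoStateFit", function(object) {
  cat(sprintf("Two-state fit: F_bound = %.1f%%, D_bound = %.3f, D_free = %.2f um^2/s\n",
              100 * object@fBound, object@dBound, object@dFree))
  cat(sprintf("  sigma_loc = %.0f nm, slice depth %.2f um, loss %.3g (%d inits)\n",
              1e3 * object@sigmaLoc, object@sliceDepth, object@loss, object@nInit))
})

setMethod("show", "SurvivalCurve", function(object) {
  cat("SurvivalCurve over", length(object@time), "durations,",
      object@nTracks, "trajectories\n")
})

setMethod("show", "DoubleExpFit", function(object) {
  cat(sprintf("Double-exponential SP fit: F = %.2f, k_ns = %.3f /s, k_s = %.3f /s\n",
              object@fFast, object@kNs, object@kS))
  cat(sprintf("  min duration %d frames, SP cut %.0e%s\n",
              object@minDurationFrames, object@minProbCut,
              if (object@degenerate) " [degenerate rates]" else ""))
})

setMethod("show", "ResidenceTimeEstimate", function(object) {
  cat(sprintf("Residence time: tau_res = %.2f s (k_s = %.3f, k_bias = %.3f, k_s,true = %.3f /s)\n",
              object@tauRes, object@kS, object@kBias, object@kSTrue))
})

setMethod("show", "TamsdCurve", function(object) {
  cat("TAMSD curve:", length(object@lag), "lags, max",
      max(object@lag), "s\n")
})

setMethod("show", "AnomalousFit", function(object) {
  cat(sprintf("Anomalous-diffusion fit: alpha = %.3f, Gamma = %.4f um^2/s^alpha\n",
              object@alpha, object@gamma))
})

setMethod("show", "NucleusLabelMap", function(object) {
  cat("NucleusLabelMap:", length(object@area), "nuclei on",
      paste(dim(object@labels), collapse = " x "), "image\n")
})

setMethod("show", "RelativeDensityMap", function(object) {
  cat("RelativeDensityMap over", length(unique(object@labels[object@labels > 0])),
      "nuclei (percentile resolution 1)\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("Hub enrichment (> %g percentile): fold = %.2f\n",
              object@thresholdPercentile, object@foldEnrichment))
  cat(sprintf("  %g trajectories in %g px of hub, %g in %g px outside (%d image(s))\n",
              object@countIn, object@areaIn, object@countOut, object@areaOut,
              object@nNucleusImages))
})

setMethod("show", "RadialProfile", function(object) {
  cat("RadialProfile:", length(object@radius), "annuli,",
      object@nWindows, "windows\n")
})

setMethod("show", "FrapExperiment", function(object) {
  cat("FrapExperiment:", ncol(object@bleach), "bleach spots,",
      ncol(object@control), "control,", ncol(object@dark), "dark;",
      nrow(object@bleach), "frames (", object@nPre, "pre-bleach )\n")
})

setMethod("show", "ReactionDominantFit", function(object) {
  cat(sprintf("Reaction-dominant FRAP fit: A = %.2f (k = %.2f /s), B = %.2f (k = %.3f /s)\n",
              object@aAmp, object@kA, object@bAmp, object@kB))
  cat(sprintf("  slow half-recovery %.2f s%s\n", object@tHalfSlow,
              if (object@degenerate) " [degenerate rates]" else ""))
})
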