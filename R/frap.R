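#' Parameters for the FRAP trace simulator
#'
#' The bleach-spot signal follows the reaction-dominant recovery
#' FRAP(t) = 1 - A exp(-kA t) - B exp(-kB t) (t = 0 at the first
#' post-bleach frame), corrupted by a multiplicative acquisition drift
#' shared with the control spots, an additive dark level and Gaussian
#' noise. Pre-bleach frames sit at unity before corruption.
#'
#' @param aAmp,bAmp amplitudes of the two exchange components (A + B <= 1).
#' @param kA,kB exchange rates, 1/s.
#' @param frameInterval seconds per frame (default 0.024).
#' @param nPre pre-bleach frames (default 10).
#' @param nPost post-bleach frames (default 1000).
#' @param noiseSd Gaussian noise s.d. as a fraction of the pre-bleach
#'   level.
#' @param controlDrift multiplicative intensity decay per frame applied to
#'   bleach and control spots alike (acquisition bleaching).
#' @param darkLevel additive camera offset, intensity units.
#' @param nSpots,nControl,nDark numbers of bleach, control and dark spots.
#' @param seed integer seed.
#' @return validated parameter list (class \code{FrapSimParams}).
#' @export
frapSimParams <- function(aAmp = 0.3, bAmp = 0.4, kA = 2, kB = log(2) / 5,
                          frameInterval = 0.024, nPre = 10L, nPost = 1000L,
                          noiseSd = 0.01, controlDrift = 1, darkLevel = 0,
                          nSpots = 50L, nControl = 5L, nDark = 5L,
                          seed = 1L) {
  p <- list(aAmp = aAmp, bAmp = bAmp, kA = kA, kB = kB,
            frameInterval = frameInterval, nPre = as.integer(nPre),
            nPost = as.integer(nPost), noiseSd = noiseSd,
            controlDrift = controlDrift, darkLevel = darkLevel,
            nSpots = as.integer(nSpots), nControl = as.integer(nControl),
            nDark = as.integer(nDark), seed = as.integer(seed))
  stopIfNot(p$aAmp >= 0 && p$bAmp >= 0 && p$aAmp + p$bAmp <= 1,
            "need aAmp, bAmp >= 0 and aAmp + bAmp <= 1")
  stopIfNot(p$kA > 0 && p$kB > 0, "rates must be > 0")
  stopIfNot(p$nPre >= 1 && p$nPost >= 2, "need nPre >= 1 and nPost >= 2")
  class(p) <- "FrapSimParams"
  p
}

#' Simulate a FRAP experiment
#'
#' @param params a \code{\link{frapSimParams}} list.
#' @return a \code{\linkS4class{FrapExperiment}}.
#' @export
simulateFrap <- function(params) {
  p <- params
  stopIfNot(inherits(p, "FrapSimParams"), "params must come from frapSimParams()")
  withSeed(p$seed, {
    nF <- p$nPre + p$nPost
    tPost <- (seq_len(p$nPost) - 1L) * p$frameInterval
    model <- 1 - p$aAmp * exp(-p$kA * tPost) - p$bAmp * exp(-p$kB * tPost)
    base <- c(rep(1, p$nPre), model)
    drift <- p$controlDrift^(seq_len(nF) - 1L)
    mk <- function(signal, nSpot) {
      m <- matrix(signal * drift, nrow = nF, ncol = nSpot) + p$darkLevel
      m + matrix(stats::rnorm(nF * nSpot, sd = p$noiseSd), nrow = nF)
    }
    methods::new("FrapExperiment",
      bleach = mk(base, p$nSpots),
      control = mk(rep(1, nF), p$nControl),
      dark = mk(rep(0, nF), p$nDark),
      frameInterval = p$frameInterval, nPre = p$nPre,
      measurementRadius = 0.3)
  })
}

#' Background- and bleach-correct FRAP traces
#'
#' Per frame, the mean of the dark spots is subtracted from each bleach
#' trace and from the mean control trace; each bleach trace is divided by
#' the corrected mean control (removing shared acquisition drift) and then
#' by its own pre-bleach mean. Spots whose residual standard deviation
#' about the mean curve exceeds 3x the median are discarded (a stand-in
#' for the manual culling of drifting spots), and the surviving curves are
#' averaged.
#'
#' @param exp a \code{\linkS4class{FrapExperiment}}.
#' @param subtractDarkFromControl subtract the dark mean from the control
#'   traces before ratioing (both readings of the correction order are
#'   available; this is the default).
#' @param outlierFactor spots with residual s.d. above this multiple of
#'   the median are dropped (Inf disables).
#' @return list with \code{time} (s, 0 at the first post-bleach frame),
#'   \code{curve} (mean corrected recovery over the post-bleach frames),
#'   \code{spotCurves} (post-bleach frames x kept spots),
#'   \code{preCurve} (mean corrected pre-bleach values), \code{nSpotsUsed},
#'   \code{frameInterval}.
#' @export
bleachCorrect <- function(exp, subtractDarkFromControl = TRUE,
                          outlierFactor = 3) {
  meanDark <- rowMeans(exp@dark)
  meanCtrl <- rowMeans(exp@control)
  denom <- if (subtractDarkFromControl) meanCtrl - meanDark else meanCtrl
  if (any(denom <= 0))
    stop("control mean does not exceed dark mean; traces unusable")
  corr <- sweep(exp@bleach, 1L, meanDark, "-") / denom
  pre <- colMeans(corr[seq_len(exp@nPre), , drop = FALSE])
  if (any(pre <= 0)) stop("non-positive pre-bleach mean in a bleach trace")
  corr <- sweep(corr, 2L, pre, "/")
  post <- corr[-seq_len(exp@nPre), , drop = FALSE]
  keep <- rep(TRUE, ncol(post))
  if (is.finite(outlierFactor) && ncol(post) >= 3) {
    meanCurve <- rowMeans(post)
    resSd <- apply(post - meanCurve, 2L, stats::sd)
    keep <- resSd <= outlierFactor * stats::median(resSd)
  }
  postKept <- post[, keep, drop = FALSE]
  list(time = (seq_len(nrow(post)) - 1L) * exp@frameInterval,
       curve = rowMeans(postKept),
       spotCurves = postKept,
       preCurve = rowMeans(corr[seq_len(exp@nPre), , drop = FALSE]),
       nSpotsUsed = sum(keep),
       frameInterval = exp@frameInterval)
}

#' Fit the reaction-dominant recovery model to a corrected FRAP curve
#'
#' Least-squares fit of FRAP(t) = 1 - A exp(-kA t) - B exp(-kB t) from the
#' first post-bleach frame (t = 0). The slower rate estimates the
#' half-recovery time of the bound population as ln(2) / k_slow.
#'
#' @param curve a corrected recovery curve: either the list returned by
#'   \code{\link{bleachCorrect}} or a numeric vector of post-bleach values.
#' @param frameInterval seconds per frame (taken from the list if given).
#' @return a \code{\linkS4class{ReactionDominantFit}}; rates within 5
#'   percent of each other are flagged degenerate.
#' @export
fitReactionDominant <- function(curve, frameInterval = NULL) {
  if (is.list(curve)) {
    frameInterval <- curve$frameInterval
    y <- curve$curve
    t <- curve$time
  } else {
    stopIfNot(!is.null(frameInterval), "frameInterval required")
    y <- curve
    t <- (seq_along(y) - 1L) * frameInterval
  }
  stopIfNot(y[1] < 1, "curve must start below 1 after the bleach")
  sse <- function(q) {
    a <- q[1]; b <- q[2]; ka <- exp(q[3]); kb <- exp(q[4])
    sum((y - (1 - a * exp(-ka * t) - b * exp(-kb * t)))^2)
  }
  depth <- max(1 - y[1], 0.1)
  tc <- max(t[length(t)], 1)
  starts <- list(c(depth / 2, depth / 2, log(2), log(0.2)),
                 c(depth / 3, 2 * depth / 3, log(5), log(1 / tc)),
                 c(2 * depth / 3, depth / 3, log(1), log(0.05)),
                 c(depth / 2, depth / 2, log(10), log(1)))
  best <- NULL
  for (q0 in starts) {
    fit <- try(stats::optim(q0, sse, method = "L-BFGS-B",
                            lower = c(0, 0, log(1e-4), log(1e-4)),
                            upper = c(1, 1, log(1e3), log(1e3)),
                            control = list(maxit = 2000)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("reaction-dominant fit failed to converge")
  a <- best$par[1]; b <- best$par[2]
  ka <- exp(best$par[3]); kb <- exp(best$par[4])
  if (ka < kb) {  # order so kA is the faster rate
    tmp <- a; a <- b; b <- tmp
    tmp <- ka; ka <- kb; kb <- tmp
  }
  degenerate <- (ka - kb) / kb < 0.05
  if (degenerate)
    warning("exchange rates within 5%; two-component fit degenerate")
  methods::new("ReactionDominantFit", aAmp = a, bAmp = b, kA = ka, kB = kb,
               tHalfSlow = log(2) / min(ka, kb), degenerate = degenerate)
}
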