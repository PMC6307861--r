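#' Time- and ensemble-averaged mean square displacement
#'
#' For each trajectory the time-averaged MSD at lag k uses all overlapping
#' localization pairs k frames apart; the ensemble average weights each
#' trajectory by its pair count (equivalent to pooling pairs). Lags are
#' limited to \code{maxLagFraction} of the longest trajectory.
#'
#' @param tracks a \code{\linkS4class{TrackSet}} (trajectories of length
#'   >= 3).
#' @param maxLagFraction largest lag as a fraction of the longest
#'   trajectory.
#' @return a \code{\linkS4class{TamsdCurve}}.
#' @export
computeTamsd <- function(tracks, maxLagFraction = 0.25) {
  d <- trackData(tracks)
  stopIfNot(nrow(d) > 0, "no localizations")
  d <- d[order(d$id, d$frame), ]
  len <- trackLengths(tracks)
  stopIfNot(max(len) >= 3, "need trajectories of length >= 3")
  dt <- tracks@frameInterval
  maxLag <- max(1L, floor(maxLagFraction * max(len)))
  key <- as.numeric(d$id) * 1e7 + d$frame
  lag <- integer(0); msd <- numeric(0); np <- integer(0)
  for (k in seq_len(maxLag)) {
    j <- match(key + k, key)
    ok <- which(!is.na(j))
    if (!length(ok)) next
    jj <- j[ok]
    sq <- (d$x[jj] - d$x[ok])^2 + (d$y[jj] - d$y[ok])^2
    lag <- c(lag, k)
    msd <- c(msd, mean(sq))
    np <- c(np, length(ok))
  }
  methods::new("TamsdCurve", lag = lag * dt, msd = msd, nPairs = np)
}

#' Fit an anomalous-diffusion power law to a TAMSD curve
#'
#' Ordinary least squares of log(MSD / tau) on log(tau): for
#' MSD(tau) = Gamma tau^alpha the regression slope is alpha - 1, so free
#' diffusion (alpha = 1) has slope 0 and sub-diffusion a negative slope.
#' The default lag range drops the first lag (localization-error
#' dominated); the curve itself already excludes long, high-variance lags.
#'
#' @param curve a \code{\linkS4class{TamsdCurve}}.
#' @param lagRange numeric length-2 window of lags (seconds) to fit;
#'   default from the second lag to the last.
#' @return an \code{\linkS4class{AnomalousFit}}.
#' @export
fitAnomalous <- function(curve, lagRange = NULL) {
  lag <- curve@lag
  msd <- curve@msd
  if (is.null(lagRange)) {
    lagRange <- c(if (length(lag) > 4) lag[2] else lag[1], lag[length(lag)])
  }
  keep <- lag >= lagRange[1] & lag <= lagRange[2]
  stopIfNot(sum(keep) >= 4, "need at least 4 lags in the fit range")
  stopIfNot(all(msd[keep] > 0), "non-positive MSD values in the fit range")
  x <- log(lag[keep])
  y <- log(msd[keep] / lag[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  alpha <- 1 + fit$coefficients[2]
  methods::new("AnomalousFit", gamma = exp(unname(fit$coefficients[1])),
               alpha = unname(alpha), lagRange = lagRange)
}
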