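#' Survival probability of trajectory durations
#'
#' SP(t) = 1 - CDF of trajectory durations, evaluated on the grid of
#' integer frame counts times the frame interval: SP(j dt) is the fraction
#' of trajectories observed for at least j frames.
#'
#' @param tracks a \code{\linkS4class{TrackSet}}.
#' @return a \code{\linkS4class{SurvivalCurve}}.
#' @export
survivalProbability <- function(tracks) {
  len <- trackLengths(tracks)
  stopIfNot(length(len) > 0, "no trajectories")
  dt <- tracks@frameInterval
  grid <- seq_len(max(len))
  prob <- vapply(grid, function(j) mean(len >= j), 0)
  methods::new("SurvivalCurve", time = grid * dt, prob = prob,
               nTracks = length(len), frameInterval = dt)
}

# Least-squares double-exponential fit on (t, p); returns list(par, sse)
# with par = c(F, kNs, kS). Rates parameterized as kS and kNs = kS + dk to
# keep the ordering during optimization.
fitDoubleExpCore <- function(t, p) {
  model <- function(q, tt) {
    fF <- q[1]; kS <- exp(q[2]); dk <- exp(q[3])
    fF * exp(-(kS + dk) * tt) + (1 - fF) * exp(-kS * tt)
  }
  sse <- function(q) sum((p - model(q, t))^2)
  kGuess <- 1 / max(t[1], mean(t))
  starts <- list(c(0.5, log(kGuess / 2), log(kGuess * 4)),
                 c(0.7, log(kGuess / 4), log(kGuess * 8)),
                 c(0.3, log(kGuess), log(kGuess * 2)),
                 c(0.9, log(kGuess / 8), log(kGuess * 16)),
                 c(0.1, log(kGuess / 2), log(kGuess)))
  best <- NULL
  for (q0 in starts) {
    fit <- try(stats::optim(q0, sse, method = "L-BFGS-B",
                            lower = c(0, log(1e-4), log(1e-4)),
                            upper = c(1, log(1e3), log(1e3)),
                            control = list(maxit = 1000)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("double-exponential fit failed to converge")
  kS <- exp(best$par[2]); dk <- exp(best$par[3])
  fF <- best$par[1]
  if (fF > 0.99) {
    # all amplitude on one exponential: report its rate as the slow rate
    # (single-component boundary of the model)
    kS <- kS + dk
    dk <- 0
    fF <- 0
  }
  list(fFast = fF, kNs = kS + dk, kS = kS, sse = best$value)
}

#' Fit a double-exponential to a survival-probability curve
#'
#' Fits SP(t) = F exp(-kNs t) + (1 - F) exp(-kS t) by unweighted least
#' squares after restricting the curve to durations of at least
#' \code{minDurationFrames} frames (filtering tracking errors and slow
#' diffusers) and survival probabilities of at least \code{minProbCut}
#' (excluding the data-poor tail). The retained curve is renormalized to 1
#' at its first point (disable with \code{renormalize = FALSE}); time is
#' measured from that point, which rescales the amplitudes but leaves the
#' rates untouched.
#'
#' @param sp a \code{\linkS4class{SurvivalCurve}}.
#' @param minDurationFrames minimum trajectory duration kept, frames.
#' @param minProbCut survival probabilities below this are not used
#'   (default 1e-3).
#' @param renormalize divide the retained curve by its first value.
#' @return a \code{\linkS4class{DoubleExpFit}}; rates within 5 percent of
#'   each other are flagged degenerate.
#' @export
fitDoubleExponential <- function(sp, minDurationFrames = 1L,
                                 minProbCut = 1e-3, renormalize = TRUE) {
  dt <- sp@frameInterval
  keep <- sp@time >= minDurationFrames * dt & sp@prob >= minProbCut &
    sp@prob > 0
  t <- sp@time[keep]
  p <- sp@prob[keep]
  if (length(t) < 5)
    stop("fewer than 5 usable survival points after cuts")
  if (renormalize) p <- p / p[1]
  fit <- fitDoubleExpCore(t - t[1], p)
  degenerate <- (fit$kNs - fit$kS) / fit$kS < 0.05
  if (degenerate)
    warning("fast and slow rates within 5%; two-exponential fit degenerate")
  methods::new("DoubleExpFit", fFast = fit$fFast, kNs = fit$kNs,
               kS = fit$kS, minDurationFrames = as.integer(minDurationFrames),
               minProbCut = minProbCut, degenerate = degenerate,
               loss = fit$sse)
}

#' Select the minimum-duration threshold by slow-rate convergence
#'
#' Refits the double-exponential over a range of minimum-duration
#' thresholds and returns the smallest threshold n at which the inferred
#' slow rate has converged, i.e. |kS(n) - kS(n+1)| / kS(n) < 0.05. If the
#' scan never converges the maximum of the range is returned with a
#' warning.
#'
#' @param sp a \code{\linkS4class{SurvivalCurve}}.
#' @param candidates thresholds to scan, frames.
#' @param minProbCut passed to \code{\link{fitDoubleExponential}}.
#' @return the selected threshold (integer frames), with the scanned slow
#'   rates attached as attribute \code{"kS"}.
#' @export
selectMinDurationThreshold <- function(sp, candidates = 1:8,
                                       minProbCut = 1e-3) {
  candidates <- sort(unique(as.integer(candidates)))
  kS <- vapply(candidates, function(n) {
    f <- try(suppressWarnings(
      fitDoubleExponential(sp, minDurationFrames = n,
                           minProbCut = minProbCut)), silent = TRUE)
    if (inherits(f, "try-error")) NA_real_ else f@kS
  }, 0)
  sel <- NA_integer_
  for (i in seq_len(length(candidates) - 1L)) {
    if (!is.na(kS[i]) && !is.na(kS[i + 1]) &&
        abs(kS[i] - kS[i + 1]) / kS[i] < 0.05) {
      sel <- candidates[i]
      break
    }
  }
  if (is.na(sel)) {
    warning("slow rate never converged over the candidate range; ",
            "returning the maximum threshold")
    sel <- candidates[length(candidates)]
  }
  attr(sel, "kS") <- stats::setNames(kS, candidates)
  sel
}

#' Correct a slow off-rate for photobleaching and track-loss bias
#'
#' Track-end processes (photobleaching, defocalization, chromatin motion)
#' add to the apparent slow off-rate. Assuming they are independent Poisson
#' processes shared with a stably bound histone control, the true specific
#' off-rate is kS - kBias, where kBias is the slow rate of the double-
#' exponential fit to the control's survival curve. The specific residence
#' time is 1 / (kS - kBias).
#'
#' @param kS apparent slow off-rate of the target protein, 1/s (or a
#'   \code{\linkS4class{DoubleExpFit}}).
#' @param his2bFit \code{\linkS4class{DoubleExpFit}} of the histone
#'   control.
#' @return a \code{\linkS4class{ResidenceTimeEstimate}}.
#' @export
biasCorrectResidenceTime <- function(kS, his2bFit) {
  if (methods::is(kS, "DoubleExpFit")) kS <- kS@kS
  kBias <- his2bFit@kS
  if (kS <= kBias) stop("bias exceeds signal: kS <= kBias")
  kTrue <- kS - kBias
  methods::new("ResidenceTimeEstimate", kS = kS, kBias = kBias,
               kSTrue = kTrue, tauRes = 1 / kTrue)
}
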