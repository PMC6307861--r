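# Shared fixture builders. Everything is generated in code at test time.

# Render one frame containing Gaussian spots at the given (row, col)
# sub-pixel positions.
renderSpotFrame <- function(px = 64, spots, amp = 100, sigma = 1.3,
                            bg = 10, noiseSd = 1) {
  img <- matrix(stats::rnorm(px * px, bg, noiseSd), px, px)
  rr <- matrix(rep(seq_len(px), px), px, px)
  cc <- t(rr)
  for (s in seq_len(nrow(spots)))
    img <- img + amp * exp(-((rr - spots[s, 1])^2 + (cc - spots[s, 2])^2) /
                             (2 * sigma^2))
  img
}

# Monte-Carlo survival oracle for a Brownian walker in an absorbing slab,
# written independently of the package internals: fine time steps plus an
# exact Brownian-bridge absorption test per step.
mcSlabSurvival <- function(nWalkers, d, t, sliceDepth, nStep = 32L) {
  half <- sliceDepth / 2
  h <- t / nStep
  sdStep <- sqrt(2 * d * h)
  z <- stats::runif(nWalkers, -half, half)
  alive <- rep(TRUE, nWalkers)
  for (s in seq_len(nStep)) {
    zn <- z + stats::rnorm(nWalkers, sd = sdStep)
    crossed <- abs(zn) > half
    inside <- alive & !crossed
    pu <- exp(-2 * (half - z[inside]) * (half - zn[inside]) / sdStep^2)
    pl <- exp(-2 * (half + z[inside]) * (half + zn[inside]) / sdStep^2)
    bridge <- stats::runif(sum(inside)) < pmin(pu + pl, 1)
    alive[alive & crossed] <- FALSE
    idx <- which(inside)
    alive[idx[bridge]] <- FALSE
    z <- zn
  }
  mean(alive)
}

# Disc nucleus mask for locus-window geometry tests.
discMask <- function(n, centre, radiusPx) {
  rr <- matrix(rep(seq_len(n), n), n, n)
  cc <- t(rr)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radiusPx^2
}

# Independent window-retention oracle: brute-force pixel checks of the
# 2.18 um window / 2.6 um control rule.
windowOracle <- function(positionsUm, mask, ps, windowUm = 2.18,
                         controlOffsetUm = 2.6, angleStepDeg = 10) {
  hw <- round(windowUm / 2 / ps)
  ok <- logical(nrow(positionsUm))
  inWin <- function(r0, c0) {
    if (r0 - hw < 1 || c0 - hw < 1 || r0 + hw > nrow(mask) ||
        c0 + hw > ncol(mask)) return(FALSE)
    all(mask[(r0 - hw):(r0 + hw), (c0 - hw):(c0 + hw)])
  }
  for (i in seq_len(nrow(positionsUm))) {
    r0 <- floor(positionsUm$y[i] / ps) + 1L
    c0 <- floor(positionsUm$x[i] / ps) + 1L
    if (!inWin(r0, c0)) next
    for (aDeg in seq(0, 350, by = angleStepDeg)) {
      a <- aDeg * pi / 180
      rc <- r0 + round(controlOffsetUm * sin(a) / ps)
      cc <- c0 + round(controlOffsetUm * cos(a) / ps)
      if (inWin(rc, cc)) { ok[i] <- TRUE; break }
    }
  }
  ok
}
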