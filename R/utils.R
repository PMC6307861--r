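# Internal helpers.

# Run an expression with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG afterwards so package functions never disturb the
# session stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Exponential waiting time that degrades gracefully to Inf at rate 0.
rexpSafe <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Pixel index (1-based, R matrix column/row) of a micrometre coordinate
# under the convention that pixel i (0-based) spans [i*ps, (i+1)*ps) with
# its centre at (i + 0.5) * ps.
umToPixel <- function(u, pixelSize) floor(u / pixelSize) + 1L

pixelCentre <- function(i, pixelSize) (i - 0.5) * pixelSize
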