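## Internal numerical helpers shared across modules.

## Trapezoidal quadrature of y over x; returns the cumulative integral,
## anchored at 0 for the first sample.
.cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(x) * (y[-n] + y[-1L]) / 2))
}

## Linear interpolation that errors instead of extrapolating silently.
.interp <- function(x, y, xout, what = "grid") {
  if (min(xout) < min(x) - 1e-9 || max(xout) > max(x) + 1e-9)
    stop(sprintf("%s extends beyond the sampled range [%g, %g]",
                 what, min(x), max(x)), call. = FALSE)
  stats::approx(x, y, xout = xout, rule = 2)$y
}

## Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Derive per-trajectory seeds from one master seed; the splitting rule is
## fixed so ensembles are reproducible trajectory-by-trajectory.
.splitSeed <- function(seed, n) {
  (as.numeric(seed) * 10007 + seq_len(n)) %% 2147483647
}

.stopInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pepdesign_input_error", "error")))
}
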