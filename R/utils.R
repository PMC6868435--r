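# Thermal energy at room temperature (298 K), pN nm.
KBT_DEFAULT <- 4.11

`%||%` <- rlang::`%||%`

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Running median with odd window k; endpoints use shrunken windows so the
# output has the same length as the input.
running_median <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    median(x[lo:hi])
  }, numeric(1))
}

# Trapezoid cumulative integral of y over x, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Cumulative integral of a positive integrand using the logarithmic mean on
# each interval: exact when y varies exponentially, which is the natural
# behaviour of force-dependent rupture hazards. Falls back to the arithmetic
# mean when an endpoint is ~0 or the endpoints are nearly equal.
cumlogtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  y1 <- y[-n]
  y2 <- y[-1]
  ratio <- ifelse(y1 > 0, y2 / y1, NA_real_)
  logmean <- ifelse(
    !is.na(ratio) & is.finite(ratio) & ratio > 0 & abs(ratio - 1) > 1e-8,
    (y2 - y1) / log(ratio),
    (y1 + y2) / 2
  )
  c(0, cumsum(logmean * diff(x)))
}

# Quadratic refinement of a grid argmax: fit a parabola through the maximum
# and its neighbours. Falls back to the grid point at the boundary.
refine_mode <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])
  h <- x[i] - x[i - 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || denom >= 0) return(x[i])
  x[i] + 0.5 * h * (y0 - y2) / denom
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
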