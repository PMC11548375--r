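#' @keywords internal
"_PACKAGE"

## Shared numerical helpers. Everything stochastic in the package funnels
## through with_seed() so a single integer pins the full output bit pattern
## without clobbering the caller's RNG stream.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, and restores the state on
#' exit, so seeded internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Start indices (1-based) of sliding windows of `win_n` samples with stride
## `stride_n`; trailing partial window dropped. count = floor((n-win)/stride)+1.
window_starts <- function(n, win_n, stride_n) {
  if (win_n > n) stopf("series (%d samples) shorter than one window (%d)", n, win_n)
  k <- floor((n - win_n) / stride_n)
  as.integer(round(seq(0L, k) * stride_n)) + 1L
}

## Matrix whose columns are the sliding windows of x.
window_matrix <- function(x, win_n, starts) {
  idx <- outer(seq_len(win_n) - 1L, starts, `+`)
  matrix(x[idx], nrow = win_n)
}

#' Zero-phase FFT band-pass filter
#'
#' Frequency-domain band-pass with raised-cosine transition edges. Being
#' applied symmetrically in the frequency domain it is exactly zero-phase.
#' The signal mean is removed before filtering.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param low,high pass-band edges in Hz; `low = 0` gives a low-pass.
#' @param transition transition width in Hz for the raised-cosine edges.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_fft <- function(x, fs, low, high, transition = 0.1) {
  n <- length(x)
  if (n < 4L) stopf("series too short to filter")
  if (high <= low) stopf("high edge must exceed low edge")
  xm <- mean(x)
  X <- stats::fft(x - xm)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)               # two-sided frequency magnitude
  gain <- rep(1, n)
  if (low > 0) {
    lo0 <- max(low - transition, 0)
    ramp <- (f - lo0) / max(low - lo0, 1e-12)
    gain <- gain * ifelse(f <= lo0, 0, ifelse(f >= low, 1, 0.5 - 0.5 * cos(pi * ramp)))
  }
  hi1 <- high + transition
  ramp <- (hi1 - f) / transition
  gain <- gain * ifelse(f >= hi1, 0, ifelse(f <= high, 1, 0.5 - 0.5 * cos(pi * ramp)))
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

## Natural cubic spline interpolation (reproduces constants and straight
## lines; evaluates to knot values at knots). No extrapolation: xout is
## clipped to [min(x), max(x)] by the callers.
spline_interp <- function(x, y, xout) {
  if (length(x) < 4L) stopf("spline interpolation needs at least 4 knots, got %d", length(x))
  f <- stats::splinefun(x, y, method = "natural")
  f(xout)
}

## Smooth slow drift: sum of k random low-frequency sinusoids, rescaled to a
## target standard deviation.
gen_drift <- function(n, fs, sd_target, k = 4L, f_lo = 0.002, f_hi = 0.04) {
  if (sd_target <= 0) return(numeric(n))
  t <- seq_len(n) / fs
  fr <- stats::runif(k, f_lo, f_hi)
  ph <- stats::runif(k, 0, 2 * pi)
  am <- stats::runif(k, 0.5, 1)
  d <- drop(sin(outer(t, 2 * pi * fr) + rep(ph, each = n)) %*% am)
  d * sd_target / max(stats::sd(d), 1e-12)
}

fmt_mean_sd <- function(x, digits = 1) {
  sprintf("%.*f ± %.*f", digits, mean(x, na.rm = TRUE), digits, stats::sd(x, na.rm = TRUE))
}
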