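## Heart-rate and respiratory-rate extraction from total hemoglobin by
## windowed spectral peak picking (30 s windows, 7.5 s stride) inside
## adaptive frequency bands, followed by natural-spline interpolation to
## 1 Hz. HR is read off the tHb spectrum directly; RR off the spectrum of a
## normalized-IQR amplitude envelope of the cardiac band.

HR_HARD_BAND <- c(1.3, 4.2)   # Hz, 78-252 BPM
RR_HARD_BAND <- c(0.25, 1.7)  # Hz, 15-102 EPM

#' Vitals-extraction configuration
#'
#' @param window,stride analysis window and stride in seconds (30 / 7.5).
#' @param hr_band,rr_band initial adaptive bands in Hz. Defaults cover
#'   neonatal physiology: HR 90-240 BPM, RR 18-90 EPM.
#' @param adapt_halfwidth half-width (Hz) of the re-centered band around the
#'   median of the last `adapt_history` estimates.
#' @param adapt_history number of past estimates the adaptation remembers.
#' @param grid_hz maximum spectral grid spacing after zero padding.
#' @param min_peak_ratio "no estimate" rule: peak power divided by median
#'   in-band power must exceed this, otherwise the window is flagged.
#' @param env_sub_s,env_stride_s sub-window length and stride (s) of the IQR
#'   envelope used for RR.
#' @param eps floor protecting the envelope normalization.
#' @return list of parameters.
#' @export
vitals_config <- function(window = 30, stride = 7.5,
                          hr_band = c(1.5, 4.0), rr_band = c(0.3, 1.5),
                          adapt_halfwidth = 0.5, adapt_history = 5L,
                          grid_hz = 0.005, min_peak_ratio = 30,
                          env_sub_s = 0.4, env_stride_s = 0.1, eps = 1e-6) {
  list(window = window, stride = stride, hr_band = hr_band, rr_band = rr_band,
       adapt_halfwidth = adapt_halfwidth, adapt_history = adapt_history,
       grid_hz = grid_hz, min_peak_ratio = min_peak_ratio,
       env_sub_s = env_sub_s, env_stride_s = env_stride_s, eps = eps)
}

#' Sliding-window segmentation
#'
#' Segments start at 0, stride, 2*stride, ...; a trailing partial window is
#' dropped, so the count is `floor((T - window)/stride) + 1`.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window,stride seconds.
#' @return list with `starts` (1-based sample indices), `centers_s`
#'   (window-center times) and `n` (samples per window).
#' @export
sliding_windows <- function(x, fs, window = 30, stride = 7.5) {
  win_n <- round(window * fs)
  starts <- window_starts(length(x), win_n, stride * fs)
  list(starts = starts, centers_s = (starts - 1) / fs + window / 2, n = win_n)
}

#' Dominant spectral frequency within a band
#'
#' Detrends (removes a linear fit), applies a Hann taper, zero-pads to a
#' spectral grid of at most `grid_hz`, and returns the in-band magnitude
#' argmax refined by parabolic interpolation around the peak. Ties break
#' toward the lower frequency. Returns `NA` ("no estimate") for degenerate
#' segments or when the peak does not dominate the in-band noise floor
#' (peak power / median in-band power below `min_peak_ratio`).
#'
#' @param segment numeric segment.
#' @param fs sampling rate in Hz.
#' @param band numeric(2) frequency band in Hz within `[0, fs/2]`.
#' @param grid_hz maximum spectral grid spacing.
#' @param min_peak_ratio peak-dominance threshold; 0 disables the check.
#' @return frequency in Hz, or `NA_real_` when no estimate can be made.
#' @export
dominant_frequency <- function(segment, fs, band, grid_hz = 0.005,
                               min_peak_ratio = 0) {
  if (band[1] >= band[2] || band[1] < 0 || band[2] > fs / 2) {
    stopf("band [%g, %g] must be increasing and within [0, %g] Hz",
          band[1], band[2], fs / 2)
  }
  n <- length(segment)
  if (n < 8L || stats::sd(segment) == 0) return(NA_real_)
  t <- seq_len(n)
  seg <- stats::lm.fit(cbind(1, t), segment)$residuals
  hann <- 0.5 - 0.5 * cos(2 * pi * (t - 1) / (n - 1))
  seg <- seg * hann
  nfft <- 2^ceiling(log2(max(n, fs / grid_hz)))
  spec <- abs(stats::fft(c(seg, numeric(nfft - n))))[seq_len(nfft %/% 2 + 1L)]
  f <- (seq_along(spec) - 1) * fs / nfft
  in_band <- which(f >= band[1] & f <= band[2])
  if (!length(in_band)) stopf("empty band after discretization")
  mag <- spec[in_band]
  if (all(mag == 0)) return(NA_real_)
  k <- in_band[which.max(mag)]          # which.max returns first max: lower-f tie-break
  if (min_peak_ratio > 0) {
    med <- stats::median(mag^2)
    if (med <= 0 || spec[k]^2 / med < min_peak_ratio) return(NA_real_)
  }
  ## parabolic refinement on the log-magnitude of the three bins around k
  fk <- f[k]
  if (k > 1L && k < length(spec)) {
    a <- log(spec[k - 1L] + 1e-300); b <- log(spec[k] + 1e-300); cc <- log(spec[k + 1L] + 1e-300)
    den <- a - 2 * b + cc
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (a - cc) / den
      fk <- fk + max(min(delta, 0.5), -0.5) * fs / nfft
    }
  }
  min(max(fk, band[1]), band[2])
}

## Adaptive band bookkeeping: recenter on the median of the recent history,
## +/- halfwidth, clipped to the hard physiological limits; the band is never
## allowed to collapse below 2*halfwidth.
adapt_band <- function(history, halfwidth, hard) {
  if (!length(history)) return(NULL)
  c0 <- stats::median(history)
  lo <- max(hard[1], c0 - halfwidth)
  hi <- min(hard[2], c0 + halfwidth)
  if (hi - lo < 2 * halfwidth) {
    if (lo <= hard[1]) hi <- min(hard[2], lo + 2 * halfwidth)
    if (hi >= hard[2]) lo <- max(hard[1], hi - 2 * halfwidth)
  }
  c(lo, hi)
}

## Shared windowed tracker: spectral peak per window inside an adaptive band.
track_frequency <- function(x, fs, cfg, band0, hard) {
  sw <- sliding_windows(x, fs, cfg$window, cfg$stride)
  est <- numeric(length(sw$starts))
  flagged <- logical(length(sw$starts))
  band <- band0
  history <- numeric(0)
  last <- NA_real_
  for (k in seq_along(sw$starts)) {
    seg <- x[sw$starts[k]:(sw$starts[k] + sw$n - 1L)]
    fk <- dominant_frequency(seg, fs, band, cfg$grid_hz, cfg$min_peak_ratio)
    if (is.na(fk)) {
      flagged[k] <- TRUE
      est[k] <- last                    # flag-and-hold (NA until first estimate)
    } else {
      est[k] <- fk
      last <- fk
      history <- utils::tail(c(history, fk), cfg$adapt_history)
      nb <- adapt_band(history, cfg$adapt_halfwidth, hard)
      if (!is.null(nb)) band <- nb
    }
  }
  list(times = sw$centers_s, freq_hz = est, flagged = flagged)
}

## Normalized-IQR amplitude envelope of the cardiac band of tHb. IQR over
## short sub-windows captures the beat-to-beat pulsation amplitude; dividing
## by a slowly varying running median of |x| keeps the envelope unit-free
## without cancelling the respiratory amplitude modulation (dividing by the
## same sub-window's median would cancel it exactly for narrowband signals).
iqr_envelope <- function(thb, fs, cfg, hard_band = HR_HARD_BAND) {
  xc <- bandpass_fft(thb, fs, hard_band[1], hard_band[2])
  sub_n <- round(cfg$env_sub_s * fs)
  stride_n <- max(1L, round(cfg$env_stride_s * fs))
  starts <- window_starts(length(xc), sub_n, stride_n)
  wm <- window_matrix(xc, sub_n, starts)
  q <- matrixStats::colQuantiles(wm, probs = c(0.25, 0.75))
  env <- q[, 2L] - q[, 1L]
  scale_n <- max(3L, round(cfg$window / cfg$env_stride_s))
  if (scale_n %% 2L == 0L) scale_n <- scale_n + 1L
  scale_n <- min(scale_n, length(env) - (1 - length(env) %% 2L))
  med_abs <- matrixStats::colMedians(abs(wm))
  slow <- stats::runmed(med_abs, scale_n, endrule = "median")
  env <- env / pmax(slow, cfg$eps)
  env_fs <- fs / stride_n
  list(env = env, fs = env_fs,
       time_s = (starts - 1) / fs + cfg$env_sub_s / 2)
}

#' Extract heart rate from total hemoglobin
#'
#' @param thb tHb series (uM) at `fs` Hz from the quality-selected channel.
#' @param fs sampling rate in Hz.
#' @param config a [vitals_config()].
#' @return data.frame `time_s`, `hr_bpm`, `flagged`; one row per window.
#' @export
extract_hr <- function(thb, fs = 100, config = vitals_config()) {
  tr <- track_frequency(thb, fs, config, config$hr_band, HR_HARD_BAND)
  data.frame(time_s = tr$times, hr_bpm = 60 * tr$freq_hz, flagged = tr$flagged)
}

#' Extract respiratory rate from total hemoglobin
#'
#' Builds the normalized-IQR amplitude envelope of the cardiac band of tHb
#' (respiration modulates the cardiac pulsation amplitude) and applies the
#' same windowed dominant-frequency tracker inside the adaptive RR band.
#'
#' @inheritParams extract_hr
#' @return data.frame `time_s`, `rr_epm`, `flagged`.
#' @export
extract_rr <- function(thb, fs = 100, config = vitals_config()) {
  e <- iqr_envelope(thb, fs, config)
  tr <- track_frequency(e$env, e$fs, config, config$rr_band, RR_HARD_BAND)
  data.frame(time_s = tr$times + e$time_s[1L] - config$env_sub_s / 2,
             rr_epm = 60 * tr$freq_hz, flagged = tr$flagged)
}

#' Interpolate windowed vitals estimates to 1 Hz
#'
#' Natural cubic spline through the (window-center, estimate) knots,
#' evaluated at integer seconds spanning the knot range; no extrapolation.
#'
#' @param times_s window-center times (>= 4 unflagged estimates required).
#' @param values estimates (BPM or EPM); `NA` rows are dropped first.
#' @return data.frame `time_s`, `value` at 1 Hz.
#' @export
interpolate_1hz <- function(times_s, values) {
  ok <- is.finite(values)
  times_s <- times_s[ok]; values <- values[ok]
  if (length(values) < 4L) stopf("need at least 4 estimates for spline interpolation")
  grid <- seq(ceiling(times_s[1L]), floor(times_s[length(times_s)]))
  data.frame(time_s = grid, value = spline_interp(times_s, values, grid))
}

#' Extract HR and RR with 1 Hz interpolations
#'
#' @param h a `hemodynamics` object (quality-selected channel).
#' @param config a [vitals_config()].
#' @return object of class `vitals_series`: window-level `hr`, `rr`
#'   data.frames, 1 Hz `hr_1hz`, `rr_1hz`, plus window/stride metadata and
#'   flagged fractions.
#' @export
extract_vitals <- function(h, config = vitals_config()) {
  stopifnot(inherits(h, "hemodynamics"))
  hr <- extract_hr(h$thb, h$sample_rate, config)
  rr <- extract_rr(h$thb, h$sample_rate, config)
  hz1 <- function(df, col) {
    if (sum(is.finite(df[[col]])) >= 4L) {
      out <- interpolate_1hz(df$time_s, df[[col]])
      names(out)[2L] <- col
      out
    } else NULL
  }
  structure(list(hr = hr, rr = rr,
                 hr_1hz = hz1(hr, "hr_bpm"), rr_1hz = hz1(rr, "rr_epm"),
                 window = config$window, stride = config$stride,
                 flagged_frac = c(hr = mean(hr$flagged), rr = mean(rr$flagged))),
            class = "vitals_series")
}

#' @export
print.vitals_series <- function(x, ...) {
  cat(sprintf("<vitals_series> %d windows (%g s / %g s stride)\n",
              nrow(x$hr), x$window, x$stride))
  cat(sprintf("  HR %s BPM (%.0f%% flagged) | RR %s EPM (%.0f%% flagged)\n",
              fmt_mean_sd(x$hr$hr_bpm), 100 * x$flagged_frac[["hr"]],
              fmt_mean_sd(x$rr$rr_epm), 100 * x$flagged_frac[["rr"]]))
  invisible(x)
}

## Window-averaged ground truth aligned to the estimator's window centers;
## used by the agreement benchmarks.
window_truth <- function(trace_1hz, centers_s, window) {
  half <- window / 2
  vapply(centers_s, function(ct) {
    idx <- which(seq_along(trace_1hz) - 1 >= ct - half &
                 seq_along(trace_1hz) - 1 < ct + half)
    mean(trace_1hz[idx])
  }, numeric(1))
}
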