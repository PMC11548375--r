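## Signal quality rating (1-5) per window and channel selection. Simplified
## three-stage scheme: (1) catch very low-quality windows (flat, railed, or
## gross spikes), (5) certify very high-quality windows by cardiac-band
## spectral power, and grade the rest 2-4 monotonically in the same ratio.

#' Quality-rating thresholds
#'
#' @param cardiac_band band (Hz) whose relative power defines quality.
#' @param total_band denominator band (Hz) of the spectral concentration
#'   ratio. The lower edge doubles as the zero-phase high-pass that removes
#'   drift before rating; the upper edge discards irrelevant high-frequency
#'   noise.
#' @param high_ratio cardiac power ratio at or above which a window scores 5.
#' @param mid_ratios increasing cut points mapping the ratio to scores 2/3/4.
#' @param spike_iqr_mult spike rule: score 1 when
#'   `max|x - median| > spike_iqr_mult * IQR`.
#' @param rail_frac score 1 when more than this fraction of samples sit
#'   exactly at the window extremes (railed/clipped signal).
#' @param flat_tol absolute SD below which a window counts as flat-line.
#' @return list of thresholds.
#' @export
quality_config <- function(cardiac_band = c(1.5, 4),
                           total_band = c(0.25, 10),
                           high_ratio = 0.65,
                           mid_ratios = c(0.30, 0.40, 0.50),
                           spike_iqr_mult = 12,
                           rail_frac = 0.2,
                           flat_tol = 1e-10) {
  list(cardiac_band = cardiac_band, total_band = total_band,
       high_ratio = high_ratio, mid_ratios = mid_ratios,
       spike_iqr_mult = spike_iqr_mult, rail_frac = rail_frac,
       flat_tol = flat_tol)
}

## Spectral concentration of the detrended window in the cardiac band,
## relative to the total band. Restricting the denominator in the frequency
## domain is an exactly zero-phase band-pass; a linear detrend removes the
## within-window drift leakage. Affine-invariant by construction.
cardiac_power_ratio <- function(x, fs, cardiac_band, total_band) {
  n <- length(x)
  t <- seq_len(n)
  xd <- stats::lm.fit(cbind(1, t), x)$residuals
  X <- abs(stats::fft(xd))^2
  f <- (t - 1) / n * fs
  half <- f <= fs / 2
  f <- f[half]; X <- X[half]
  num <- sum(X[f >= cardiac_band[1] & f <= cardiac_band[2]])
  den <- sum(X[f >= total_band[1] & f <= total_band[2]])
  if (den <= 0) return(0)
  num / den
}

#' Rate NIRS signal quality per window
#'
#' @param h a `hemodynamics` object (the tHb series is rated).
#' @param window window length in seconds (>= 5).
#' @param stride stride in seconds.
#' @param config thresholds from [quality_config()].
#' @param channel_id identifier recorded in the output.
#' @return data.frame with `window_start_s`, `window_s`, `score` (1-5),
#'   `channel_id`.
#' @export
rate_windows <- function(h, window = 10, stride = 10,
                         config = quality_config(), channel_id = 1L) {
  stopifnot(inherits(h, "hemodynamics"))
  if (window < 5) stopf("quality window must be at least 5 s")
  fs <- h$sample_rate
  x <- h$thb
  win_n <- round(window * fs)
  starts <- window_starts(length(x), win_n, round(stride * fs))
  score <- integer(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + win_n - 1L)
    raw <- x[idx]
    ## stage 1: very low quality on the unfiltered window
    s1 <- FALSE
    if (stats::sd(raw) < config$flat_tol) s1 <- TRUE
    if (!s1) {
      railed <- mean(raw == max(raw) | raw == min(raw))
      if (railed > config$rail_frac) s1 <- TRUE
    }
    if (!s1) {
      iqr <- stats::IQR(raw)
      if (iqr > 0 && max(abs(raw - stats::median(raw))) > config$spike_iqr_mult * iqr) s1 <- TRUE
    }
    if (s1) { score[k] <- 1L; next }
    r <- cardiac_power_ratio(raw, fs, config$cardiac_band, config$total_band)
    score[k] <- if (r >= config$high_ratio) 5L else 2L + sum(r >= config$mid_ratios)
  }
  data.frame(window_start_s = (starts - 1) / fs, window_s = window,
             score = score, channel_id = channel_id)
}

#' Select the best channel by mean quality score
#'
#' Deterministic tie-break toward the lowest channel index.
#'
#' @param ratings list of [rate_windows()] data.frames, one per channel, or
#'   a single data.frame with a `channel_id` column.
#' @return the selected `channel_id`.
#' @export
select_channel <- function(ratings) {
  if (is.data.frame(ratings)) ratings <- split(ratings, ratings$channel_id)
  if (!length(ratings)) stopf("no channel ratings supplied")
  ids <- vapply(ratings, function(r) r$channel_id[1L], numeric(1))
  means <- vapply(ratings, function(r) mean(r$score), numeric(1))
  ord <- order(-means, ids)
  ids[ord[1L]]
}

#' Rate all channels of a recording and pick the best
#'
#' Runs the Beer-Lambert conversion per channel, rates each, and selects.
#'
#' @param rec a `nirs_recording`.
#' @param ... passed to [rate_windows()].
#' @return list with `channel_id`, `ratings` (all channels), `hemodynamics`
#'   (of the selected channel).
#' @export
assess_recording <- function(rec, ...) {
  stopifnot(inherits(rec, "nirs_recording"))
  params <- beer_lambert_params(rec$wavelengths, distance_cm = rec$distance_cm)
  hs <- lapply(seq_along(rec$channels), function(ch) {
    od <- optical_density(rec$channels[[ch]], i0 = rec$i0,
                          sample_rate = rec$sample_rate)
    concentration_changes(od, params, sample_rate = rec$sample_rate,
                          tsi = if (is.null(rec$tsi)) NULL else rec$tsi[, ch])
  })
  ratings <- lapply(seq_along(hs), function(ch)
    rate_windows(hs[[ch]], channel_id = ch, ...))
  best <- select_channel(ratings)
  list(channel_id = best, ratings = do.call(rbind, ratings),
       hemodynamics = hs[[best]])
}
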