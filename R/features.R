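## Eight 1 Hz feature modalities per recording and 8 x 60 feature epochs
## aligned to one-minute sleep labels. Modalities: moving-average-filtered
## O2Hb/HHb/TSI, 1 Hz HR and RR, and three motion/activity statistics on
## 1 s windows with 50% overlap (normalized SD, normalized IQR, O2Hb-HHb
## Pearson correlation).

MODALITY_NAMES <- c("o2hb_f", "hhb_f", "tsi_f", "hr_1hz", "rr_1hz",
                    "mov_std", "mov_iqr", "mov_corr")

#' 1 s moving average followed by 1 Hz down-sampling
#'
#' Boxcar of one second centered on each integer second; edge windows use
#' the available samples (truncated boxcar), so a T-second input yields
#' floor(T) output samples at t = 0, 1, ..., floor(T)-1.
#'
#' @param x series at `fs` Hz.
#' @param fs input sampling rate in Hz.
#' @return data.frame `time_s`, `value` at 1 Hz.
#' @export
moving_average_downsample <- function(x, fs = 100) {
  n <- length(x)
  if (n < fs) stopf("need at least 1 s of data")
  half <- round(fs / 2)
  secs <- 0:(floor(n / fs) - 1L)
  centers <- secs * fs + 1L
  cs <- cumsum(c(0, x))
  lo <- pmax(centers - half, 1L)
  hi <- pmin(centers + half, n)
  data.frame(time_s = secs, value = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

## 1 s windows, 50% overlap -> 2 Hz statistic series, then natural spline to
## 1 Hz. Window k covers [k*0.5, k*0.5 + 1) s, timestamped at its center.
half_overlap_windows <- function(n, fs) {
  win_n <- round(fs)
  starts <- window_starts(n, win_n, fs / 2)
  list(starts = starts, centers = (starts - 1) / fs + 0.5, n = win_n)
}

stat_to_1hz <- function(centers, values) {
  if (length(values) < 4L) stopf("series too short for interpolation")
  grid <- seq(ceiling(centers[1L]), floor(centers[length(centers)]))
  data.frame(time_s = grid, value = spline_interp(centers, values, grid))
}

#' Normalized moving standard deviation
#'
#' Per 1 s window (50% overlap), the sample SD divided by
#' `max(|window mean|, eps)`; spline-interpolated from 2 Hz to 1 Hz. The
#' epsilon floor matters because concentration-change signals have near-zero
#' means and the plain SD/mean ratio would explode.
#'
#' @param x O2Hb series at `fs` Hz.
#' @param fs sampling rate in Hz.
#' @param eps normalization floor.
#' @param interpolate `TRUE` (default) interpolates the 2 Hz window series
#'   to 1 Hz; `FALSE` returns the raw per-window values at window centers.
#' @return data.frame `time_s`, `value`.
#' @export
moving_std_norm <- function(x, fs = 100, eps = 1e-6, interpolate = TRUE) {
  w <- half_overlap_windows(length(x), fs)
  wm <- window_matrix(x, w$n, w$starts)
  v <- matrixStats::colSds(wm) / pmax(abs(colMeans(wm)), eps)
  if (!interpolate) return(data.frame(time_s = w$centers, value = v))
  stat_to_1hz(w$centers, v)
}

#' Normalized moving interquartile range
#'
#' As [moving_std_norm()] with IQR / max(|median|, eps); quantiles use the
#' linear-interpolation (type 7) definition. Sign-flipping the signal leaves
#' the output unchanged.
#'
#' @inheritParams moving_std_norm
#' @return data.frame `time_s`, `value`.
#' @export
moving_iqr_norm <- function(x, fs = 100, eps = 1e-6, interpolate = TRUE) {
  w <- half_overlap_windows(length(x), fs)
  wm <- window_matrix(x, w$n, w$starts)
  q <- matrixStats::colQuantiles(wm, probs = c(0.25, 0.5, 0.75))
  v <- (q[, 3L] - q[, 1L]) / pmax(abs(q[, 2L]), eps)
  if (!interpolate) return(data.frame(time_s = w$centers, value = v))
  stat_to_1hz(w$centers, v)
}

#' Moving O2Hb-HHb Pearson correlation
#'
#' Per 1 s window (50% overlap), Pearson's r between the two series;
#' windows where either signal is constant are undefined and set to 0 (and
#' counted); interpolated to 1 Hz and clipped to [-1, 1]. Strongly negative
#' values are a neurovascular-coupling signature, strongly positive values a
#' motion-artifact signature.
#'
#' @param o2hb,hhb series at `fs` Hz, equal length.
#' @param fs sampling rate in Hz.
#' @param interpolate as in [moving_std_norm()].
#' @return data.frame `time_s`, `value`; attribute `n_undefined` counts
#'   degenerate windows.
#' @export
moving_correlation <- function(o2hb, hhb, fs = 100, interpolate = TRUE) {
  if (length(o2hb) != length(hhb)) {
    stopf("length mismatch: %d vs %d", length(o2hb), length(hhb))
  }
  w <- half_overlap_windows(length(o2hb), fs)
  a <- window_matrix(o2hb, w$n, w$starts)
  b <- window_matrix(hhb, w$n, w$starts)
  ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  undef <- den == 0
  r <- ifelse(undef, 0, num / pmax(den, 1e-300))
  r <- pmin(pmax(r, -1), 1)
  if (!interpolate) {
    out <- data.frame(time_s = w$centers, value = r)
    attr(out, "n_undefined") <- sum(undef)
    return(out)
  }
  out <- stat_to_1hz(w$centers, r)
  out$value <- pmin(pmax(out$value, -1), 1)
  attr(out, "n_undefined") <- sum(undef)
  out
}

#' Modality set container
#'
#' @param mods 8 x T numeric matrix with rownames exactly the eight
#'   modality names (`o2hb_f`, `hhb_f`, `tsi_f`, `hr_1hz`, `rr_1hz`,
#'   `mov_std`, `mov_iqr`, `mov_corr`) on a common 1 Hz grid.
#' @param time_s integer-second time base of the columns.
#' @param flags optional logical T-vector marking invalid samples.
#' @return object of class `modality_set`.
#' @export
modality_set <- function(mods, time_s, flags = NULL) {
  if (!is.matrix(mods) || nrow(mods) != 8L) stopf("mods must be an 8 x T matrix")
  missing <- setdiff(MODALITY_NAMES, rownames(mods))
  if (length(missing)) stopf("missing modality '%s'", missing[1L])
  mods <- mods[MODALITY_NAMES, , drop = FALSE]
  if (ncol(mods) != length(time_s)) stopf("time base does not match columns")
  if (is.null(flags)) flags <- rep(FALSE, length(time_s))
  structure(list(mods = mods, time_s = time_s, flags = flags),
            class = "modality_set")
}

#' @export
print.modality_set <- function(x, ...) {
  cat(sprintf("<modality_set> 8 x %d @ 1 Hz, t = [%g, %g] s, %.1f%% flagged\n",
              ncol(x$mods), min(x$time_s), max(x$time_s), 100 * mean(x$flags)))
  invisible(x)
}

#' Assemble the eight 1 Hz modalities
#'
#' Computes the three filtered/down-sampled hemoglobin modalities and the
#' three moving statistics from the hemodynamics, takes the 1 Hz HR/RR from
#' the vitals series, and aligns everything on the intersection of valid
#' time ranges (nearest-second alignment).
#'
#' @param h `hemodynamics` of the selected channel (must carry TSI).
#' @param v a `vitals_series` with 1 Hz interpolations available.
#' @return a [modality_set()].
#' @export
build_modalities <- function(h, v) {
  stopifnot(inherits(h, "hemodynamics"), inherits(v, "vitals_series"))
  if (is.null(h$tsi)) stopf("missing modality 'tsi_f': hemodynamics has no TSI channel")
  if (is.null(v$hr_1hz) || is.null(v$rr_1hz)) {
    stopf("vitals series has no 1 Hz interpolation (too few unflagged windows)")
  }
  fs <- h$sample_rate
  parts <- list(
    o2hb_f  = moving_average_downsample(h$o2hb, fs),
    hhb_f   = moving_average_downsample(h$hhb, fs),
    tsi_f   = moving_average_downsample(h$tsi, fs),
    hr_1hz  = data.frame(time_s = v$hr_1hz$time_s, value = v$hr_1hz$hr_bpm),
    rr_1hz  = data.frame(time_s = v$rr_1hz$time_s, value = v$rr_1hz$rr_epm),
    mov_std = moving_std_norm(h$o2hb, fs),
    mov_iqr = moving_iqr_norm(h$o2hb, fs),
    mov_corr = moving_correlation(h$o2hb, h$hhb, fs)
  )
  t0 <- max(vapply(parts, function(p) min(p$time_s), numeric(1)))
  t1 <- min(vapply(parts, function(p) max(p$time_s), numeric(1)))
  if (t1 < t0) stopf("modalities have no common time range")
  grid <- seq(ceiling(t0), floor(t1))
  mods <- do.call(rbind, lapply(parts, function(p) {
    p$value[match(round(grid), round(p$time_s))]
  }))
  rownames(mods) <- names(parts)
  modality_set(mods, grid)
}

#' Feature-epoch set container
#'
#' @param x 8 x 60 x N array of per-epoch feature matrices.
#' @param label factor with levels `AS`, `QS` (Wake excluded upstream).
#' @param epoch_start_s epoch start times on the recording clock.
#' @param recording_id,subject_id identifiers recycled to N.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(x, label, epoch_start_s,
                      recording_id = "r1", subject_id = recording_id) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1L] == 8L, dim(x)[2L] == 60L)
  n <- dim(x)[3L]
  label <- factor(as.character(label), levels = c("AS", "QS"))
  if (anyNA(label)) stopf("labels must be AS or QS")
  if (length(label) != n || length(epoch_start_s) != n) stopf("metadata length mismatch")
  structure(list(x = x, label = label, epoch_start_s = epoch_start_s,
                 recording_id = rep_len(as.character(recording_id), n),
                 subject_id = rep_len(as.character(subject_id), n)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (8 x 60): %s QS / %s AS, %d recording(s)\n",
              length(x$label), sum(x$label == "QS"), sum(x$label == "AS"),
              length(unique(x$recording_id))))
  invisible(x)
}

#' Combine epoch sets from several recordings
#'
#' @param ... `epoch_set` objects (or one list of them).
#' @return a pooled `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "epoch_set")) sets <- sets[[1L]]
  x <- array(unlist(lapply(sets, `[[`, "x")), dim = c(8L, 60L, sum(vapply(sets, function(s) length(s$label), integer(1)))))
  epoch_set(x,
            label = unlist(lapply(sets, function(s) as.character(s$label))),
            epoch_start_s = unlist(lapply(sets, `[[`, "epoch_start_s")),
            recording_id = unlist(lapply(sets, `[[`, "recording_id")),
            subject_id = unlist(lapply(sets, `[[`, "subject_id")))
}

#' Cut a modality set into labeled one-minute feature epochs
#'
#' One 8 x 60 epoch per fully covered labeled minute. Wake epochs are
#' excluded (binary AS-vs-QS task); epochs whose flagged/missing fraction
#' exceeds `max_invalid_frac` are dropped with a recorded reason.
#'
#' @param m a [modality_set()].
#' @param timeline a `sleep_timeline` on the same recording clock.
#' @param max_invalid_frac tolerated fraction of flagged samples per epoch.
#' @param recording_id,subject_id identifiers for the produced epochs.
#' @return an [epoch_set()]; dropped epochs are listed in
#'   `attr(, "dropped")`.
#' @export
epochize <- function(m, timeline, max_invalid_frac = 0.1,
                     recording_id = "r1", subject_id = recording_id) {
  stopifnot(inherits(m, "modality_set"), inherits(timeline, "sleep_timeline"))
  keep <- list(); labs <- character(0); starts <- numeric(0)
  dropped <- list()
  for (e in seq_along(timeline$labels)) {
    st <- timeline$start_s + (e - 1L) * timeline$epoch_s
    lab <- timeline$labels[e]
    idx <- match(st:(st + 59L), m$time_s)
    if (anyNA(idx)) {
      dropped[[length(dropped) + 1L]] <- data.frame(epoch_start_s = st, reason = "incomplete coverage")
      next
    }
    if (lab == "Wake") {
      dropped[[length(dropped) + 1L]] <- data.frame(epoch_start_s = st, reason = "wake excluded")
      next
    }
    sub <- m$mods[, idx, drop = FALSE]
    invalid <- mean(m$flags[idx] | colSums(!is.finite(sub)) > 0)
    if (invalid > max_invalid_frac) {
      dropped[[length(dropped) + 1L]] <- data.frame(epoch_start_s = st, reason = "flagged samples")
      next
    }
    keep[[length(keep) + 1L]] <- sub
    labs <- c(labs, lab); starts <- c(starts, st)
  }
  if (!length(keep)) stopf("no usable epochs")
  x <- array(unlist(keep), dim = c(8L, 60L, length(keep)),
             dimnames = list(MODALITY_NAMES, NULL, NULL))
  es <- epoch_set(x, labs, starts, recording_id, subject_id)
  attr(es, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  es
}
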