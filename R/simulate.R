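## Synthetic neonatal NIRS simulator. A stated world: defaults encode
## neonatal physiology (HR ~120-170 BPM, RR ~30-70 EPM, active sleep with
## 2-3x the short-term HR/RR variability and more motion than quiet sleep)
## and the acquisition geometry of a two-channel 100 Hz forehead sensor with
## a 0.4 Hz reference monitor and 1-minute behavioral sleep labels.

SLEEP_STATES <- c("AS", "QS", "Wake")

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator. Amplitudes are uM-equivalent
#' concentration changes; rates are per minute; every random draw descends
#' from `seed`, so a fixed seed fixes the full output bit pattern.
#'
#' @param seed integer master seed.
#' @param duration_min recording duration in minutes (>= 3).
#' @param hr_range,rr_range named lists of per-state (AS/QS/Wake) ranges,
#'   BPM within [80, 250] and EPM within [15, 100].
#' @param hr_wander_sd,rr_wander_sd named per-state random-walk step SD
#'   (BPM or EPM per second); active sleep defaults to ~2.5x quiet sleep.
#' @param mean_reversion pull (per second) of the vitals random walk toward
#'   the state's range midpoint; keeps traces inside physiology.
#' @param cardiac_amplitude amplitude of the cardiac tHb oscillation (uM).
#' @param resp_amplitude amplitude of the additive respiratory component (uM).
#' @param resp_mod_depth fractional amplitude modulation of the cardiac
#'   pulsation by respiration (the carrier the RR extractor relies on).
#' @param drift_amplitude SD of slow hemodynamic drift (uM).
#' @param noise_sd white measurement noise SD per 100 Hz sample (uM).
#' @param channel2_noise_factor multiplier on `noise_sd` for the second
#'   channel (makes channel selection testable).
#' @param motion_amplitude motion artifact spike amplitude (uM).
#' @param motion_rate named per-state artifact rate (events per minute).
#' @param dwell_mean named per-state mean dwell time in minutes (geometric).
#' @param qs_fraction target fraction of QS epochs; `wake_fraction` likewise.
#' @param balance_gain self-correction gain of the sleep-state scheduler;
#'   0 recovers a plain semi-Markov process.
#' @param ref_rate reference monitor rate in Hz (0.4).
#' @param ref_jitter_hr,ref_jitter_rr SD of reference-monitor error.
#' @param sample_rate optical sampling rate in Hz (100).
#' @param wavelengths,dpf,distance_cm forward optics (see
#'   [beer_lambert_params()]).
#' @param tsi_base,tsi_sd tissue saturation index level (%) and slow wander.
#' @param i0 reference intensity (arbitrary units).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_min = 30,
                       hr_range = list(AS = c(130, 170), QS = c(115, 145), Wake = c(130, 175)),
                       rr_range = list(AS = c(35, 70),  QS = c(28, 55),  Wake = c(35, 75)),
                       hr_wander_sd = c(AS = 2.0, QS = 0.8, Wake = 2.5),
                       rr_wander_sd = c(AS = 1.2, QS = 0.5, Wake = 1.5),
                       mean_reversion = 0.05,
                       cardiac_amplitude = 0.30,
                       resp_amplitude = 0.15,
                       resp_mod_depth = 0.5,
                       drift_amplitude = 0.5,
                       noise_sd = 0.05,
                       channel2_noise_factor = 3,
                       motion_amplitude = 6,
                       motion_rate = c(AS = 0.4, QS = 0.05, Wake = 1.0),
                       dwell_mean = c(AS = 6, QS = 4, Wake = 1.5),
                       qs_fraction = 0.26,
                       wake_fraction = 0.05,
                       balance_gain = 25,
                       ref_rate = 0.4,
                       ref_jitter_hr = 0.5,
                       ref_jitter_rr = 1.0,
                       sample_rate = 100,
                       wavelengths = c(760, 850),
                       dpf = NULL,
                       distance_cm = 3.0,
                       tsi_base = 65,
                       tsi_sd = 2,
                       i0 = 1.0) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  ## accept YAML-style nested lists for the per-state parameters
  for (f in c("hr_range", "rr_range")) {
    cfg[[f]] <- lapply(cfg[[f]], function(v) as.numeric(unlist(v)))
  }
  for (f in c("hr_wander_sd", "rr_wander_sd", "motion_rate", "dwell_mean")) {
    v <- unlist(cfg[[f]])
    cfg[[f]] <- stats::setNames(as.numeric(v), names(v))
  }
  cfg$optics <- beer_lambert_params(wavelengths, dpf, distance_cm)
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$duration_min < 3) stopf("duration must be at least 3 minutes")
  for (s in SLEEP_STATES) {
    hr <- cfg$hr_range[[s]]; rr <- cfg$rr_range[[s]]
    if (is.null(hr) || is.null(rr)) stopf("missing hr/rr range for state %s", s)
    if (hr[1] > hr[2] || hr[1] < 80 || hr[2] > 250) {
      stopf("HR range for %s must lie within [80, 250] BPM", s)
    }
    if (rr[1] > rr[2] || rr[1] < 15 || rr[2] > 100) {
      stopf("RR range for %s must lie within [15, 100] EPM", s)
    }
  }
  amps <- c(cfg$cardiac_amplitude, cfg$resp_amplitude, cfg$resp_mod_depth,
            cfg$drift_amplitude, cfg$noise_sd, cfg$motion_amplitude,
            unlist(cfg$motion_rate), cfg$hr_wander_sd, cfg$rr_wander_sd)
  if (any(amps < 0)) stopf("amplitudes, noise levels and rates must be non-negative")
  if (any(cfg$dwell_mean <= 0)) stopf("dwell means must be positive")
  if (cfg$qs_fraction < 0 || cfg$qs_fraction > 1 ||
      cfg$wake_fraction < 0 || cfg$qs_fraction + cfg$wake_fraction > 1) {
    stopf("qs_fraction/wake_fraction must define a valid state mixture")
  }
  invisible(cfg)
}

#' Construct a sleep-state timeline
#'
#' @param labels character vector of per-minute states from `AS`, `QS`, `Wake`.
#' @param epoch_s epoch duration in seconds (fixed at 60).
#' @param start_s recording-clock start of the first epoch.
#' @return object of class `sleep_timeline`.
#' @export
sleep_timeline <- function(labels, epoch_s = 60, start_s = 0) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), SLEEP_STATES)
  if (length(bad)) {
    stopf("unknown sleep state '%s'; allowed: %s", bad[1L],
          paste(SLEEP_STATES, collapse = ", "))
  }
  structure(list(labels = labels, epoch_s = epoch_s, start_s = start_s),
            class = "sleep_timeline")
}

#' @export
print.sleep_timeline <- function(x, ...) {
  tab <- table(factor(x$labels, SLEEP_STATES))
  cat(sprintf("<sleep_timeline> %d min: %s\n", length(x$labels),
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Simulate a per-minute sleep-state timeline
#'
#' Semi-Markov schedule with geometric dwell times (in minutes). The
#' next-state draw is self-correcting: state weights are proportional to
#' `occupancy/dwell` tilted by `exp(balance_gain * deficit)`, so the realized
#' QS fraction converges to `qs_fraction` as the recording grows while dwell
#' structure stays random (`balance_gain = 0` gives the plain process).
#'
#' @param config a [sim_config()].
#' @return `sleep_timeline` of `duration_min` labels.
#' @export
## Base next-state weights of the embedded chain. Dwell blocks are drawn
## geometric with mean d_s, and the next state is sampled from w *including*
## the current state (a self-draw merely extends the dwell, and a geometric
## sum of geometrics stays geometric). Occupancy is then
## o_j ~ w_j d_j / (1 - w_j); inverting o = pi gives w_j = c u_j/(1 + c u_j)
## with u = pi/d and c solving sum(w) = 1 - always feasible, no bias.
solve_state_weights <- function(u) {
  active <- u > 0
  if (sum(active) == 1L) return(ifelse(active, 1, 0))
  f <- function(cc) sum(cc * u / (1 + cc * u)) - 1
  cc <- stats::uniroot(f, c(1e-9, 1e12))$root
  cc * u / (1 + cc * u)
}

simulate_timeline <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$duration_min))
  pi_t <- c(AS = 1 - config$qs_fraction - config$wake_fraction,
            QS = config$qs_fraction, Wake = config$wake_fraction)
  d <- config$dwell_mean[SLEEP_STATES]
  u <- pi_t / d                       # target visit rates
  w_base <- solve_state_weights(u)
  names(w_base) <- SLEEP_STATES
  with_seed(config$seed + 1L, {
    labels <- character(0)
    counts <- c(AS = 0, QS = 0, Wake = 0)
    state <- sample(SLEEP_STATES, 1L, prob = pmax(pi_t, 1e-12))
    while (length(labels) < n) {
      dwell <- 1L + stats::rgeom(1L, 1 / d[[state]])
      take <- min(dwell, n - length(labels))
      ## quota cap: a single dwell may not push the state's realized share
      ## beyond target + margin (margin loosens early, tightens to 7 pp)
      len <- length(labels)
      margin <- max(0.07, 4 / max(len, 1))
      if (pi_t[[state]] + margin < 1) {
        cap <- floor(((pi_t[[state]] + margin) * len - counts[[state]]) /
                       (1 - pi_t[[state]] - margin))
        take <- max(1L, min(take, cap))
      }
      labels <- c(labels, rep(state, take))
      counts[state] <- counts[state] + take
      realized <- counts / max(sum(counts), 1)
      w <- w_base * exp(config$balance_gain * (pi_t - realized))
      w[pi_t <= 0] <- 0
      state <- if (all(w <= 0)) state else sample(SLEEP_STATES, 1L, prob = w)
    }
    sleep_timeline(labels[seq_len(n)])
  })
}

## Mean-reverting (OU-style) random walk at 1 Hz inside per-state ranges.
## Degenerate limit: step SD identically zero for every visited state gives
## the exact piecewise-constant range-midpoint trace.
state_walk <- function(states_1s, range_by_state, sd_by_state, lambda) {
  n <- length(states_1s)
  mid <- vapply(range_by_state, mean, numeric(1))[states_1s]
  lo <- vapply(range_by_state, `[`, numeric(1), 1L)[states_1s]
  hi <- vapply(range_by_state, `[`, numeric(1), 2L)[states_1s]
  sds <- sd_by_state[states_1s]
  if (all(sds == 0)) return(unname(mid))
  x <- numeric(n)
  x[1L] <- min(max(mid[1L] + stats::rnorm(1L, 0, sds[1L]), lo[1L]), hi[1L])
  eps <- stats::rnorm(n)
  for (i in 2:n) {
    xi <- x[i - 1L] + lambda * (mid[i] - x[i - 1L]) + sds[i] * eps[i]
    x[i] <- min(max(xi, lo[i]), hi[i])
  }
  x
}

#' Simulate ground-truth vitals and motion-artifact schedule
#'
#' Per-state mean-reverting random walks for HR and RR at 1 Hz, clipped to
#' the state's configured range and continuous across state boundaries, plus
#' a Poisson motion-artifact schedule with state-dependent rates.
#'
#' @param timeline a `sleep_timeline`.
#' @param config a [sim_config()].
#' @return object of class `ground_truth`: `time_s`, `hr`, `rr` (1 Hz),
#'   `artifacts` (data.frame start_s/end_s), `timeline`.
#' @export
simulate_vitals <- function(timeline, config) {
  stopifnot(inherits(timeline, "sleep_timeline"), inherits(config, "sim_config"))
  n_min <- length(timeline$labels)
  if (n_min == 0L) stopf("timeline is empty")
  states_1s <- rep(timeline$labels, each = 60L)
  with_seed(config$seed + 2L, {
    hr <- state_walk(states_1s, config$hr_range, config$hr_wander_sd, config$mean_reversion)
    rr <- state_walk(states_1s, config$rr_range, config$rr_wander_sd, config$mean_reversion)
    arts <- list()
    for (m in seq_len(n_min)) {
      k <- stats::rpois(1L, config$motion_rate[[timeline$labels[m]]])
      if (k > 0) {
        start <- sort(stats::runif(k, (m - 1) * 60, m * 60))
        dur <- stats::runif(k, 0.5, 3)
        arts[[length(arts) + 1L]] <- data.frame(start_s = start,
                                                end_s = pmin(start + dur, n_min * 60))
      }
    }
    artifacts <- if (length(arts)) do.call(rbind, arts) else
      data.frame(start_s = numeric(0), end_s = numeric(0))
    structure(list(time_s = seq_len(length(hr)) - 1, hr = hr, rr = rr,
                   artifacts = artifacts, timeline = timeline),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d s | HR %s BPM | RR %s EPM | %d artifacts\n",
              length(x$hr), fmt_mean_sd(x$hr), fmt_mean_sd(x$rr),
              nrow(x$artifacts)))
  invisible(x)
}

## Target concentration-change traces (uM) at 100 Hz for one channel.
synth_concentrations <- function(truth, config, noise_scale = 1) {
  fs <- config$sample_rate
  n <- length(truth$hr) * fs
  t1 <- truth$time_s
  hr100 <- stats::approx(t1, truth$hr, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  rr100 <- stats::approx(t1, truth$rr, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  phase_c <- cumsum(2 * pi * hr100 / 60 / fs)
  phase_r <- cumsum(2 * pi * rr100 / 60 / fs)
  cardiac <- config$cardiac_amplitude *
    (1 + config$resp_mod_depth * sin(phase_r)) * sin(phase_c)
  resp <- config$resp_amplitude * sin(phase_r)
  motion <- numeric(n)
  if (nrow(truth$artifacts) && config$motion_amplitude > 0) {
    for (i in seq_len(nrow(truth$artifacts))) {
      a <- truth$artifacts[i, ]
      i0 <- max(1L, floor(a$start_s * fs) + 1L)
      i1 <- min(n, ceiling(a$end_s * fs))
      if (i1 <= i0) next
      tt <- seq(0, 1, length.out = i1 - i0 + 1L)
      motion[i0:i1] <- motion[i0:i1] +
        config$motion_amplitude * exp(-4 * tt) * sin(pi * tt)
    }
  }
  ## cardiac and respiratory pulsation anti-correlated across O2Hb/HHb
  ## (neurovascular-style signature), motion positively correlated; both
  ## components appear in tHb at exactly the configured amplitudes
  o2hb <- 1.2 * cardiac + 1.2 * resp + gen_drift(n, fs, config$drift_amplitude) +
    motion + stats::rnorm(n, 0, config$noise_sd * noise_scale)
  hhb <- -0.2 * cardiac - 0.2 * resp + gen_drift(n, fs, config$drift_amplitude * 0.5) +
    0.8 * motion + stats::rnorm(n, 0, config$noise_sd * noise_scale)
  tsi <- config$tsi_base + gen_drift(n, fs, config$tsi_sd, f_lo = 0.001, f_hi = 0.01)
  tsi <- pmin(pmax(tsi, 40), 90)
  list(o2hb = o2hb, hhb = hhb, tsi = tsi)
}

#' Simulate the optical recording and reference vitals
#'
#' Builds per-channel O2Hb/HHb concentration-change traces whose total
#' hemoglobin carries a cardiac sinusoid at HR/60, a respiratory component
#' at RR/60 (additive plus amplitude modulation of the cardiac pulsation),
#' slow drift, white noise and motion spikes (positively correlated across
#' O2Hb and HHb), then inverts the modified Beer-Lambert law (G = 0 - it
#' cancels in changes) into two-wavelength light intensities. The second
#' channel carries `channel2_noise_factor` times the measurement noise.
#' Reference vitals are the truth traces at the 0.4 Hz monitor grid with
#' configurable jitter.
#'
#' @param truth a [simulate_vitals()] result covering the full duration.
#' @param config a [sim_config()].
#' @return list with `recording` (class `nirs_recording`) and `reference`
#'   (class `reference_vitals`). The injected concentration traces are kept
#'   in `attr(recording, "concentrations")` for round-trip testing.
#' @export
simulate_recording <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (length(truth$hr) < config$duration_min * 60) {
    stopf("ground truth (%d s) does not cover the configured duration (%d min)",
          length(truth$hr), config$duration_min)
  }
  fs <- config$sample_rate
  with_seed(config$seed + 3L, {
    noise_scales <- c(1, config$channel2_noise_factor)
    channels <- vector("list", 2L)
    conc <- vector("list", 2L)
    for (ch in 1:2) {
      conc[[ch]] <- synth_concentrations(truth, config, noise_scales[ch])
      od <- forward_od(conc[[ch]]$o2hb, conc[[ch]]$hhb, config$optics)
      channels[[ch]] <- config$i0 * 10^(-od)
      colnames(channels[[ch]]) <- as.character(config$wavelengths)
    }
    rec <- nirs_recording(channels = channels, sample_rate = fs,
                          wavelengths = config$wavelengths,
                          distance_cm = config$distance_cm, i0 = config$i0,
                          tsi = vapply(conc, `[[`, numeric(nrow(channels[[1L]])), "tsi"))
    attr(rec, "concentrations") <- conc
    tg <- seq(0, length(truth$hr) - 1, by = 1 / config$ref_rate)
    reference <- structure(list(
      time_s = tg,
      hr = stats::approx(truth$time_s, truth$hr, tg, rule = 2)$y +
        stats::rnorm(length(tg), 0, config$ref_jitter_hr),
      rr = stats::approx(truth$time_s, truth$rr, tg, rule = 2)$y +
        stats::rnorm(length(tg), 0, config$ref_jitter_rr),
      rate_hz = config$ref_rate), class = "reference_vitals")
    list(recording = rec, reference = reference)
  })
}

#' Raw NIRS intensity recording container
#'
#' @param channels list of samples-x-wavelengths intensity matrices
#'   (strictly positive, arbitrary units).
#' @param sample_rate Hz.
#' @param wavelengths nm, length >= 2.
#' @param distance_cm source-detector separation.
#' @param i0 per-wavelength reference intensity (or `NULL` to estimate from
#'   the initial baseline window downstream).
#' @param tsi optional samples-x-channels matrix of tissue saturation index
#'   (%) as delivered by spatially-resolved devices; carried as an input
#'   channel, never computed here.
#' @return object of class `nirs_recording`.
#' @export
nirs_recording <- function(channels, sample_rate, wavelengths,
                           distance_cm = 3.0, i0 = NULL, tsi = NULL) {
  if (!length(channels)) stopf("need at least one channel")
  if (length(wavelengths) < 2L) stopf("need at least 2 wavelengths")
  n <- nrow(channels[[1L]])
  for (ch in seq_along(channels)) {
    m <- channels[[ch]]
    if (!is.matrix(m) || ncol(m) != length(wavelengths) || nrow(m) != n) {
      stopf("channel %d must be a %d x %d intensity matrix", ch, n, length(wavelengths))
    }
    if (any(m <= 0)) stopf("channel %d has non-positive intensities", ch)
  }
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  if (!is.null(tsi)) {
    tsi <- as.matrix(tsi)
    if (nrow(tsi) != n || ncol(tsi) != length(channels)) {
      stopf("tsi must be a %d x %d matrix (samples x channels)", n, length(channels))
    }
  }
  structure(list(channels = channels, sample_rate = sample_rate,
                 wavelengths = wavelengths, distance_cm = distance_cm,
                 i0 = i0, tsi = tsi),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %d channel(s), wavelengths %s nm, %d samples @ %g Hz\n",
              length(x$channels), paste(x$wavelengths, collapse = "/"),
              nrow(x$channels[[1L]]), x$sample_rate))
  invisible(x)
}

#' Simulate one complete measurement
#'
#' Convenience wrapper running [simulate_timeline()], [simulate_vitals()]
#' and [simulate_recording()] under one seed.
#'
#' @param config a [sim_config()].
#' @return list with `timeline`, `truth`, `recording`, `reference`, `config`.
#' @export
simulate_measurement <- function(config) {
  timeline <- simulate_timeline(config)
  truth <- simulate_vitals(timeline, config)
  rec <- simulate_recording(truth, config)
  list(timeline = timeline, truth = truth,
       recording = rec$recording, reference = rec$reference, config = config)
}

#' Fast feature-level simulator for classifier experiments
#'
#' Generates one-minute 8 x 60 feature epochs directly at 1 Hz from the same
#' state-conditional model the full simulator uses (HR/RR random walks,
#' state-dependent motion statistics, slow hemodynamic wander), bypassing
#' the 100 Hz optical synthesis. `separation` scales every state-dependent
#' contrast: 0 makes AS and QS statistically identical (no-information
#' control), 1 is the default contrast, larger values separate further.
#'
#' @param config a [sim_config()].
#' @param separation class-contrast multiplier (>= 0).
#' @return An `epoch_set` (see [epoch_set()]), Wake epochs excluded.
#' @export
simulate_epochs <- function(config, separation = 1) {
  stopifnot(inherits(config, "sim_config"), separation >= 0)
  blend <- function(as_val, qs_val) {           # move state params toward common mean
    m <- (as_val + qs_val) / 2
    list(AS = m + (as_val - m) * separation, QS = m + (qs_val - m) * separation,
         Wake = m + (as_val - m) * separation)
  }
  clamp_range <- function(r, lims) {
    r <- pmin(pmax(r, lims[1]), lims[2])
    if (r[1] > r[2]) r <- rev(r)
    r
  }
  hrr <- lapply(blend(config$hr_range$AS, config$hr_range$QS), clamp_range, lims = c(80, 250))
  rrr <- lapply(blend(config$rr_range$AS, config$rr_range$QS), clamp_range, lims = c(15, 100))
  hsd <- lapply(blend(config$hr_wander_sd[["AS"]], config$hr_wander_sd[["QS"]]), max, 0)
  rsd <- lapply(blend(config$rr_wander_sd[["AS"]], config$rr_wander_sd[["QS"]]), max, 0)
  mot <- lapply(blend(config$motion_rate[["AS"]], config$motion_rate[["QS"]]), max, 0)
  timeline <- simulate_timeline(config)
  cfg2 <- config
  cfg2$hr_range <- hrr; cfg2$rr_range <- rrr
  cfg2$hr_wander_sd <- c(AS = hsd$AS, QS = hsd$QS, Wake = hsd$Wake)
  cfg2$rr_wander_sd <- c(AS = rsd$AS, QS = rsd$QS, Wake = rsd$Wake)
  cfg2$motion_rate <- c(AS = mot$AS, QS = mot$QS, Wake = mot$Wake)
  truth <- simulate_vitals(timeline, cfg2)
  n_s <- length(truth$hr)
  with_seed(config$seed + 4L, {
    ## 1 Hz surrogates for the optical modalities
    art <- logical(n_s)
    if (nrow(truth$artifacts)) {
      for (i in seq_len(nrow(truth$artifacts))) {
        idx <- (floor(truth$artifacts$start_s[i]) + 1L):min(n_s, ceiling(truth$artifacts$end_s[i]))
        art[idx] <- TRUE
      }
    }
    o2hb <- gen_drift(n_s, 1, config$drift_amplitude) + stats::rnorm(n_s, 0, 0.05)
    hhb <- gen_drift(n_s, 1, config$drift_amplitude * 0.5) + stats::rnorm(n_s, 0, 0.05)
    tsi <- config$tsi_base + gen_drift(n_s, 1, config$tsi_sd, f_lo = 0.001, f_hi = 0.01)
    mov_std <- 0.1 + 0.05 * stats::rnorm(n_s)^2 + ifelse(art, 1.5, 0)
    mov_iqr <- 0.12 + 0.06 * stats::rnorm(n_s)^2 + ifelse(art, 1.8, 0)
    mov_corr <- pmin(pmax(-0.2 + 0.3 * stats::rnorm(n_s) + ifelse(art, 0.9, 0), -1), 1)
    mods <- rbind(o2hb_f = o2hb, hhb_f = hhb, tsi_f = tsi,
                  hr_1hz = truth$hr, rr_1hz = truth$rr,
                  mov_std = mov_std, mov_iqr = mov_iqr, mov_corr = mov_corr)
    ms <- modality_set(mods, time_s = seq_len(n_s) - 1)
    epochize(ms, timeline)
  })
}
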