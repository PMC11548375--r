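# Shared fixtures, all generated in code at test time.

# Small, fast simulator configuration used where the test content does not
# depend on recording length.
quick_cfg <- function(seed = 1, duration_min = 5, ...) {
  sim_config(seed = seed, duration_min = duration_min, ...)
}

# Fully deterministic single-state configuration: constant HR/RR, no noise,
# no drift, no motion, so the injected oscillation frequencies are exact.
clean_cfg <- function(seed = 1, duration_min = 5, hr = 150, rr = 48, ...) {
  args <- list(
    seed = seed, duration_min = duration_min,
    hr_range = list(AS = c(hr, hr), QS = c(hr, hr), Wake = c(hr, hr)),
    rr_range = list(AS = c(rr, rr), QS = c(rr, rr), Wake = c(rr, rr)),
    hr_wander_sd = c(AS = 0, QS = 0, Wake = 0),
    rr_wander_sd = c(AS = 0, QS = 0, Wake = 0),
    drift_amplitude = 0, noise_sd = 0,
    motion_rate = c(AS = 0, QS = 0, Wake = 0),
    ref_jitter_hr = 0, ref_jitter_rr = 0,
    qs_fraction = 0, wake_fraction = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Injected concentration traces of channel 1 (simulator diagnostic).
sim_thb <- function(sim, channel = 1) {
  conc <- attr(sim$recording, "concentrations")[[channel]]
  conc$o2hb + conc$hhb
}

# Hand-built epoch set with a deterministic class contrast on the HR row:
# QS epochs sit at hr_qs, AS epochs at hr_as, everything else is seeded
# noise. separable enough for any sane classifier when the gap is large.
toy_epochs <- function(n_as = 30, n_qs = 30, hr_as = 160, hr_qs = 120,
                       noise = 1, seed = 42) {
  n <- n_as + n_qs
  withr::with_seed(seed, {
    x <- array(rnorm(8 * 60 * n, sd = noise), dim = c(8, 60, n))
    lab <- c(rep("AS", n_as), rep("QS", n_qs))
    for (i in seq_len(n)) {
      x[4, , i] <- x[4, , i] + if (lab[i] == "AS") hr_as else hr_qs
    }
    dimnames(x) <- list(nirsleep:::MODALITY_NAMES, NULL, NULL)
    epoch_set(x, lab, epoch_start_s = 60 * (seq_len(n) - 1))
  })
}

# Modality set spanning `minutes` whole minutes with smooth deterministic
# content; convenient for epochize tests.
toy_modalities <- function(minutes) {
  t <- seq_len(minutes * 60) - 1
  mods <- rbind(
    o2hb_f = sin(t / 50), hhb_f = cos(t / 70), tsi_f = 65 + sin(t / 200),
    hr_1hz = 140 + 5 * sin(t / 100), rr_1hz = 50 + 3 * cos(t / 90),
    mov_std = abs(sin(t / 30)), mov_iqr = abs(cos(t / 40)),
    mov_corr = 0.5 * sin(t / 60))
  modality_set(mods, time_s = t)
}
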