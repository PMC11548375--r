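test_that("timeline respects degenerate mixtures, length and determinism", {
  all_as <- simulate_timeline(quick_cfg(qs_fraction = 0, wake_fraction = 0))
  expect_true(all(all_as$labels == "AS"))

  expect_length(simulate_timeline(quick_cfg(duration_min = 5))$labels, 5L)

  t1 <- simulate_timeline(quick_cfg(seed = 7, duration_min = 40))
  t2 <- simulate_timeline(quick_cfg(seed = 7, duration_min = 40))
  expect_identical(t1$labels, t2$labels)
})

test_that("invalid timeline configs are rejected", {
  expect_error(quick_cfg(dwell_mean = c(AS = -1, QS = 4, Wake = 1)), "dwell")
  expect_error(quick_cfg(duration_min = 2), "at least 3")
  expect_error(quick_cfg(hr_range = list(AS = c(60, 170), QS = c(115, 145),
                                         Wake = c(130, 175))), "\\[80, 250\\]")
  expect_error(sleep_timeline(c("AS", "REM")), "unknown sleep state")
})

test_that("realized QS fraction converges to the target", {
  cfg <- quick_cfg(seed = 9, duration_min = 300, qs_fraction = 0.26)
  tl <- simulate_timeline(cfg)
  expect_lt(abs(mean(tl$labels == "QS") - 0.26), 0.05)
  # and within 10 percentage points already at 60 min
  tl60 <- simulate_timeline(quick_cfg(seed = 4, duration_min = 60, qs_fraction = 0.26))
  expect_lt(abs(mean(tl60$labels == "QS") - 0.26), 0.10)
})

test_that("zero wander gives piecewise-constant vitals at range midpoints", {
  cfg <- quick_cfg(seed = 1, duration_min = 12, qs_fraction = 0.5,
                   wake_fraction = 0,
                   hr_wander_sd = c(AS = 0, QS = 0, Wake = 0),
                   rr_wander_sd = c(AS = 0, QS = 0, Wake = 0))
  tl <- simulate_timeline(cfg)
  truth <- simulate_vitals(tl, cfg)
  mids <- vapply(cfg$hr_range, mean, numeric(1))[rep(tl$labels, each = 60)]
  expect_identical(truth$hr, unname(mids))
})

test_that("constant configured RR range gives a constant trace", {
  cfg <- quick_cfg(rr_range = list(AS = c(40, 40), QS = c(40, 40), Wake = c(40, 40)))
  truth <- simulate_vitals(simulate_timeline(cfg), cfg)
  expect_true(all(truth$rr == 40))
})

test_that("active sleep carries higher short-term HR variability than quiet sleep", {
  cfg <- quick_cfg(seed = 21, duration_min = 60, qs_fraction = 0.5,
                   wake_fraction = 0, dwell_mean = c(AS = 5, QS = 5, Wake = 1),
                   hr_wander_sd = c(AS = 3, QS = 1, Wake = 3))
  tl <- simulate_timeline(cfg)
  truth <- simulate_vitals(tl, cfg)
  st <- rep(tl$labels, each = 60)
  inc <- diff(truth$hr)
  same_state <- st[-1] == st[-length(st)]
  v_as <- var(inc[same_state & st[-1] == "AS"])
  v_qs <- var(inc[same_state & st[-1] == "QS"])
  expect_gt(v_as, v_qs)
})

test_that("vitals traces stay inside configured ranges and cover the duration", {
  cfg <- quick_cfg(seed = 5, duration_min = 30)
  tl <- simulate_timeline(cfg)
  truth <- simulate_vitals(tl, cfg)
  expect_length(truth$hr, 30 * 60)
  st <- rep(tl$labels, each = 60)
  for (s in unique(st)) {
    expect_true(all(truth$hr[st == s] >= cfg$hr_range[[s]][1] - 1e-9))
    expect_true(all(truth$hr[st == s] <= cfg$hr_range[[s]][2] + 1e-9))
  }
  if (nrow(truth$artifacts)) {
    expect_true(all(truth$artifacts$start_s >= 0))
    expect_true(all(truth$artifacts$end_s <= 30 * 60))
  }
})

test_that("noise-free tHb spectrum peaks at the configured HR and RR", {
  cfg <- clean_cfg(seed = 1, duration_min = 5, hr = 150, rr = 48)
  sim <- simulate_measurement(cfg)
  thb <- sim_thb(sim)
  n <- length(thb)
  spec <- Mod(fft(thb - mean(thb)))[1:(n %/% 2)]
  f <- (seq_len(n %/% 2) - 1) * 100 / n
  bin <- 100 / n
  cardiac <- f[f > 1.5 & f < 4][which.max(spec[f > 1.5 & f < 4])]
  resp <- f[f > 0.5 & f < 1.2][which.max(spec[f > 0.5 & f < 1.2])]
  expect_lt(abs(cardiac - 150 / 60), bin + 1e-9)
  expect_lt(abs(resp - 48 / 60), bin + 1e-9)
})

test_that("zero cardiac and respiratory amplitude gives flat tHb", {
  cfg <- clean_cfg(seed = 1, duration_min = 3, cardiac_amplitude = 0,
                   resp_amplitude = 0, resp_mod_depth = 0)
  sim <- simulate_measurement(cfg)
  expect_lt(sd(sim_thb(sim)), 1e-12)
})

test_that("reference vitals with zero jitter equal truth at the 0.4 Hz grid", {
  cfg <- clean_cfg(seed = 3, duration_min = 3)
  sim <- simulate_measurement(cfg)
  expect_equal(diff(sim$reference$time_s), rep(2.5, length(sim$reference$time_s) - 1))
  truth_at <- approx(sim$truth$time_s, sim$truth$hr, sim$reference$time_s, rule = 2)$y
  expect_equal(sim$reference$hr, truth_at)
})

test_that("the full simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_measurement(quick_cfg(seed = 13, duration_min = 4))
  s2 <- simulate_measurement(quick_cfg(seed = 13, duration_min = 4))
  expect_identical(s1$recording$channels, s2$recording$channels)
  expect_identical(s1$truth$hr, s2$truth$hr)
  expect_identical(s1$reference$rr, s2$reference$rr)
  s3 <- simulate_measurement(quick_cfg(seed = 14, duration_min = 4))
  expect_false(identical(s1$recording$channels, s3$recording$channels))
})

test_that("recording container validates its invariants", {
  expect_error(nirs_recording(list(matrix(1, 5, 1)), 100, c(760, 850)), "matrix")
  m <- matrix(1, 5, 2)
  expect_error(nirs_recording(list(m * 0), 100, c(760, 850)), "non-positive")
  expect_error(nirs_recording(list(m), 100, 760), "2 wavelengths")
})

test_that("feature-level simulator controls class separation", {
  es0 <- simulate_epochs(quick_cfg(seed = 2, duration_min = 40, qs_fraction = 0.4,
                                   wake_fraction = 0), separation = 0)
  es1 <- simulate_epochs(quick_cfg(seed = 2, duration_min = 40, qs_fraction = 0.4,
                                   wake_fraction = 0), separation = 1)
  expect_s3_class(es0, "epoch_set")
  expect_identical(dim(es0$x)[1:2], c(8L, 60L))
  # zero separation: state-conditional HR distributions coincide
  hr_by_lab <- function(es) tapply(colMeans(es$x[4, , ], dims = 1), es$label, mean)
  d0 <- abs(diff(hr_by_lab(es0))); d1 <- abs(diff(hr_by_lab(es1)))
  expect_lt(d0, d1)
})
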