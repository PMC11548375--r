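test_that("sliding window counts follow the stride formula", {
  expect_length(sliding_windows(numeric(60 * 100), 100)$starts, 5L)   # (60-30)/7.5+1
  expect_length(sliding_windows(numeric(30 * 100), 100)$starts, 1L)
  expect_error(sliding_windows(numeric(29 * 100), 100), "shorter than one window")
  for (T in c(45, 67.5, 120, 300)) {
    n <- sliding_windows(numeric(T * 100), 100)$starts
    expect_length(n, floor((T - 30) / 7.5) + 1)
  }
})

test_that("dominant_frequency finds tones, ignores out-of-band energy, flags degenerates", {
  t <- seq_len(3000) / 100
  expect_lt(abs(dominant_frequency(sin(2 * pi * 2.5 * t), 100, c(1.5, 4)) - 2.5), 0.01)
  two <- sin(2 * pi * 2.5 * t) + 3 * sin(2 * pi * 0.8 * t)
  expect_lt(abs(dominant_frequency(two, 100, c(1.5, 4)) - 2.5), 0.01)
  expect_true(is.na(dominant_frequency(rep(1, 3000), 100, c(1.5, 4))))
  expect_error(dominant_frequency(sin(t), 100, c(4, 1.5)), "band")
})

test_that("dominant_frequency matches an exhaustive fine-grid DFT oracle", {
  # independent oracle: explicit projection onto a dense frequency grid,
  # same detrend/taper definition, no FFT, no parabolic refinement
  oracle <- function(x, fs, band) {
    n <- length(x)
    tt <- seq_len(n)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
    x <- x * (0.5 - 0.5 * cos(2 * pi * (tt - 1) / (n - 1)))
    fgrid <- seq(band[1], band[2], by = 0.002)
    pw <- vapply(fgrid, function(f) {
      Mod(sum(x * exp(-2i * pi * f * (tt - 1) / fs)))
    }, numeric(1))
    fgrid[which.max(pw)]
  }
  set.seed(31)
  for (i in 1:50) {
    f0 <- runif(1, 1.6, 3.9)
    t <- seq_len(1500) / 100
    x <- sin(2 * pi * f0 * t + runif(1, 0, 2 * pi)) + rnorm(1500, 0, 0.3)
    got <- dominant_frequency(x, 100, c(1.5, 4))
    expect_lt(abs(got - oracle(x, 100, c(1.5, 4))), 0.02)
  }
})

test_that("constant simulated HR is recovered within 1 BPM in every window", {
  sim <- simulate_measurement(clean_cfg(seed = 4, duration_min = 5, hr = 150,
                                        noise_sd = 0.05, drift_amplitude = 0.5))
  hr <- extract_hr(sim_thb(sim), 100)
  expect_true(all(abs(hr$hr_bpm - 150) <= 1))
  expect_true(all(!hr$flagged))
})

test_that("HR tracks a linear ramp with at most one window of lag", {
  fs <- 100
  T <- 600
  t <- seq_len(T * fs) / fs
  hr_t <- 120 + (160 - 120) * t / T
  phase <- cumsum(2 * pi * hr_t / 60 / fs)
  thb <- 0.3 * sin(phase) + rnorm(length(t), 0, 0.03)
  hr <- extract_hr(thb, fs)
  truth <- 120 + 40 * hr$time_s / T
  err <- hr$hr_bpm - truth
  # one window of lag on a 40 BPM / 10 min ramp is 2 BPM
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("recordings without cardiac content are fully flagged for HR", {
  set.seed(8)
  thb <- nirsleep:::gen_drift(100 * 120, 100, 0.5) + rnorm(100 * 120, 0, 0.05)
  hr <- extract_hr(thb, 100)
  expect_true(all(hr$flagged))
})

test_that("constant simulated RR is recovered within 2 EPM", {
  sim <- simulate_measurement(clean_cfg(seed = 5, duration_min = 5, rr = 48,
                                        noise_sd = 0.05, drift_amplitude = 0.5))
  rr <- extract_rr(sim_thb(sim), 100)
  expect_true(all(abs(rr$rr_epm[!rr$flagged] - 48) <= 2))
  expect_lt(mean(rr$flagged), 0.2)
})

test_that("absent respiration flags the RR windows", {
  sim <- simulate_measurement(clean_cfg(seed = 6, duration_min = 4,
                                        resp_amplitude = 0, resp_mod_depth = 0,
                                        noise_sd = 0.05))
  rr <- extract_rr(sim_thb(sim), 100)
  expect_gt(mean(rr$flagged), 0.8)
})

test_that("an RR step settles within three windows", {
  fs <- 100
  T <- 480
  t <- seq_len(T * fs) / fs
  rr_t <- ifelse(t < T / 2, 40, 60)
  phase_r <- cumsum(2 * pi * rr_t / 60 / fs)
  phase_c <- cumsum(2 * pi * rep(150 / 60, length(t)) / fs)
  thb <- 0.3 * (1 + 0.5 * sin(phase_r)) * sin(phase_c) + rnorm(length(t), 0, 0.03)
  rr <- extract_rr(thb, fs)
  after <- which(rr$time_s > T / 2 + 3 * 7.5)
  expect_true(all(abs(rr$rr_epm[after] - 60) <= 3))
})

test_that("emitted estimates respect the hard physiological bands", {
  sim <- simulate_measurement(quick_cfg(seed = 10, duration_min = 10))
  v <- extract_vitals(assess_recording(sim$recording)$hemodynamics)
  expect_true(all(v$hr$hr_bpm >= 60 * 1.3 & v$hr$hr_bpm <= 60 * 4.2))
  expect_true(all(v$rr$rr_epm >= 60 * 0.25 & v$rr$rr_epm <= 60 * 1.7, na.rm = TRUE))
  expect_equal(nrow(v$hr), floor((600 - 30) / 7.5) + 1)
})

test_that("1 Hz interpolation is a faithful natural spline", {
  times <- seq(15, 90, by = 7.5)
  const <- interpolate_1hz(times, rep(150, length(times)))
  expect_true(all(const$value == 150))
  # knot reproduction
  lin <- interpolate_1hz(times, 2 * times + 5)
  expect_equal(lin$value, 2 * lin$time_s + 5, tolerance = 1e-9)
  at_knot <- interpolate_1hz(c(10, 20, 30, 40), c(1, 4, 9, 16))
  expect_equal(at_knot$value[at_knot$time_s == 20], 4)
  expect_error(interpolate_1hz(c(1, 2, 3), c(1, 2, 3)), "at least 4")
})
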