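test_that("moving-average down-sampling: constants, length, boxcar response", {
  expect_equal(moving_average_downsample(rep(3.7, 1000))$value, rep(3.7, 10))
  out <- moving_average_downsample(rnorm(100 * 100))
  expect_equal(nrow(out), 100L)
  expect_equal(out$time_s, 0:99)

  # 2.3 Hz cardiac-range tone attenuated by the 101-tap boxcar (Dirichlet
  # gain); 2.3 Hz aliases to 0.3 Hz on the 1 Hz grid with the same amplitude
  t <- seq_len(100 * 100) / 100
  tone <- sin(2 * pi * 2.3 * t)
  filt <- moving_average_downsample(tone)$value
  expected_gain <- abs(sin(pi * 2.3 * 1.01) / (101 * sin(pi * 2.3 / 100)))
  # compare RMS amplitudes away from the edges (101-tap boxcar, aliased Dirichlet gain)
  got_gain <- sqrt(mean(filt[5:95]^2)) / sqrt(mean(tone^2))
  expect_equal(got_gain, expected_gain, tolerance = 0.05)
  expect_lt(got_gain, 0.2)    # strong attenuation either way
})

test_that("normalized moving SD matches a brute-force loop and handles degenerates", {
  expect_true(all(moving_std_norm(rep(5, 1000))$value == 0))
  expect_true(all(moving_std_norm(rep(0, 1000))$value == 0))
  set.seed(12)
  x <- rnorm(100 * 20, mean = 2)
  got <- moving_std_norm(x, interpolate = FALSE)
  for (k in sample(nrow(got), 25)) {
    i0 <- (k - 1) * 50 + 1
    win <- x[i0:(i0 + 99)]
    expect_equal(got$value[k], sd(win) / max(abs(mean(win)), 1e-6), tolerance = 1e-12)
  }
})

test_that("normalized moving IQR matches quantile oracle and is sign-symmetric", {
  expect_true(all(moving_iqr_norm(rep(2, 500))$value == 0))
  set.seed(13)
  x <- rnorm(100 * 20, mean = 1)
  got <- moving_iqr_norm(x, interpolate = FALSE)
  for (k in sample(nrow(got), 25)) {
    i0 <- (k - 1) * 50 + 1
    win <- x[i0:(i0 + 99)]
    oracle <- (quantile(win, 0.75) - quantile(win, 0.25)) /
      max(abs(median(win)), 1e-6)
    expect_equal(got$value[k], unname(oracle), tolerance = 1e-12)
  }
  flipped <- moving_iqr_norm(-x, interpolate = FALSE)
  expect_equal(got$value, flipped$value, tolerance = 1e-12)
})

test_that("moving correlation: perfect, affine and independent cases", {
  set.seed(14)
  x <- rnorm(100 * 20)
  anti <- moving_correlation(x, -x, interpolate = FALSE)
  expect_true(all(abs(anti$value + 1) < 1e-12))
  aff <- moving_correlation(x, 2 * x + 3, interpolate = FALSE)
  expect_true(all(abs(aff$value - 1) < 1e-12))

  y <- rnorm(length(x))
  ind <- moving_correlation(x, y, interpolate = FALSE)
  expect_lt(mean(abs(ind$value)), 0.2)
  for (k in sample(nrow(ind), 25)) {
    i0 <- (k - 1) * 50 + 1
    expect_equal(ind$value[k], cor(x[i0:(i0 + 99)], y[i0:(i0 + 99)]),
                 tolerance = 1e-12)
  }
  expect_error(moving_correlation(x, y[-1]), "mismatch")
  # constant windows are defined as zero
  z <- moving_correlation(rep(1, 500), rnorm(500), interpolate = FALSE)
  expect_true(all(z$value == 0))
  expect_equal(attr(z, "n_undefined"), nrow(z))
})

test_that("build_modalities assembles eight aligned series from the pipeline", {
  sim <- simulate_measurement(quick_cfg(seed = 15, duration_min = 10))
  sel <- assess_recording(sim$recording)
  v <- extract_vitals(sel$hemodynamics)
  ms <- build_modalities(sel$hemodynamics, v)
  expect_s3_class(ms, "modality_set")
  expect_equal(nrow(ms$mods), 8L)
  expect_true(all(is.finite(ms$mods)))
  expect_true(all(ms$mods["mov_corr", ] >= -1 & ms$mods["mov_corr", ] <= 1))
  expect_true(all(ms$mods["mov_std", ] >= 0) && all(ms$mods["mov_iqr", ] >= 0))
  # the common grid is the intersection of the parts (vitals start latest)
  expect_equal(min(ms$time_s), min(v$hr_1hz$time_s, v$rr_1hz$time_s))

  h2 <- sel$hemodynamics
  h2$tsi <- NULL
  expect_error(build_modalities(h2, v), "tsi_f")
})

test_that("epochize keeps complete AS/QS minutes and drops the rest", {
  ms <- toy_modalities(75)
  tl <- sleep_timeline(rep("AS", 75))
  es <- epochize(ms, tl)
  expect_length(es$label, 75L)
  expect_identical(dim(es$x), c(8L, 60L, 75L))

  tl3 <- sleep_timeline(c("AS", "Wake", "QS"))
  es3 <- epochize(toy_modalities(3), tl3)
  expect_length(es3$label, 2L)
  expect_identical(as.character(es3$label), c("AS", "QS"))
  expect_true("wake excluded" %in% attr(es3, "dropped")$reason)

  # last epoch straddles the recording end -> dropped
  ms_short <- toy_modalities(3)
  tl4 <- sleep_timeline(c("AS", "QS", "AS", "QS"))
  es4 <- epochize(ms_short, tl4)
  expect_length(es4$label, 3L)

  # heavily flagged epochs are dropped
  ms_f <- toy_modalities(3)
  ms_f$flags[61:120] <- TRUE
  es5 <- epochize(ms_f, sleep_timeline(c("AS", "QS", "AS")))
  expect_length(es5$label, 2L)
  expect_true("flagged samples" %in% attr(es5, "dropped")$reason)

  expect_error(epochize(toy_modalities(3), sleep_timeline(rep("Wake", 3))),
               "no usable epochs")
})

test_that("motion artifacts shift the O2Hb-HHb correlation positive", {
  cfg <- quick_cfg(seed = 16, duration_min = 10, motion_rate = c(AS = 2, QS = 2, Wake = 2),
                   motion_amplitude = 8)
  sim <- simulate_measurement(cfg)
  conc <- attr(sim$recording, "concentrations")[[1]]
  mc <- moving_correlation(conc$o2hb, conc$hhb, interpolate = FALSE)
  art <- rep(FALSE, nrow(mc))
  for (i in seq_len(nrow(sim$truth$artifacts))) {
    a <- sim$truth$artifacts[i, ]
    art[mc$time_s >= a$start_s & mc$time_s <= a$end_s] <- TRUE
  }
  expect_gt(sum(art), 5)
  expect_gt(mean(mc$value[art]), mean(mc$value[!art]) + 0.2)
})
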