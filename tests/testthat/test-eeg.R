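test_that("band-pass filter preserves passband, removes DC and stopband", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  sine10 <- sin(2 * pi * 10 * t)
  out <- bandpass_filter(sine10, fs)
  mid <- out[500:1500]
  expect_lt(abs(max(mid) - 1), 0.05)       # passband centre within 5%
  sine50 <- sin(2 * pi * 50 * t)
  out50 <- bandpass_filter(sine50, fs)
  expect_lt(max(abs(out50[500:1500])), 0.1) # >= 90% attenuation at 50 Hz
  # analytic magnitude at 50 Hz for the 4th-order edges
  g50 <- sqrt(1 / (1 + (50 / 20)^8)) * sqrt((50 / 1)^8 / (1 + (50 / 1)^8))
  expect_lt(g50, 0.1)
  dc <- rep(100, 2001)
  expect_lt(max(abs(bandpass_filter(dc, fs)[500:1500])), 1)
  expect_error(bandpass_filter(sine10, fs = 30), "too low")
})

test_that("EEG segmentation yields 700-sample epochs and drops edge events", {
  fs <- 1000
  rec <- matrix(rnorm(3 * 5000), nrow = 3)
  ep <- segment_eeg(rec, fs, c("a", "b", "M1"), events_s = c(1, 2, 4.96))
  expect_equal(dim(ep), c(2L, 3L, 700L))
  expect_equal(attr(ep, "dropped_events"), 3L)
  expect_equal(attr(ep, "time_ms")[1], -200)
  # epoch content matches the recording slice
  expect_equal(unclass(ep)[1, 2, ], rec[2, 801:1500])
})

test_that("artifact detection matches the rule's boundary cases", {
  fs <- 1000
  qc <- qc_params()
  expect_false(detect_artifact(rep(0, 700), fs, qc))
  # a 0 -> 120 uV step deviates 60 uV from the centred 80-ms mean
  step <- c(rep(0, 350), rep(120, 350))
  expect_true(detect_artifact(step, fs, qc, rule = "deviation"))
  # a slow 40 uV drift never strays from its local mean nor spans 55 uV
  drift <- 40 * seq(0, 1, length.out = 700)
  expect_false(detect_artifact(drift, fs, qc))
  # a 150 uV half-sine blink is smooth (small local deviation) but its
  # smoothed excursion far exceeds 55 uV
  tt <- seq(0, 0.699, by = 1 / fs)
  blink <- ifelse(tt >= 0.2 & tt <= 0.5, 150 * sin(pi * (tt - 0.2) / 0.3), 0)
  expect_false(detect_artifact(blink, fs, qc, rule = "deviation"))
  expect_true(detect_artifact(blink, fs, qc, rule = "smoothed"))
  expect_true(detect_artifact(blink, fs, qc))
  # a 20 uV deflection stays below threshold under every rule
  small <- ifelse(tt >= 0.2 & tt <= 0.5, 20 * sin(pi * (tt - 0.2) / 0.3), 0)
  expect_false(detect_artifact(small, fs, qc))
})

test_that("artifact detection is monotone under amplitude scaling", {
  fs <- 1000
  set.seed(3)
  tt <- seq(0, 0.699, by = 1 / fs)
  base <- 30 * sin(2 * pi * 3 * tt) + rnorm(700, 0, 5)
  scales <- c(0.5, 1, 2, 4, 8)
  flags <- vapply(scales, function(s) detect_artifact(base * s, fs), TRUE)
  # once flagged, every larger multiple is flagged
  first <- match(TRUE, flags)
  if (!is.na(first)) expect_true(all(flags[first:length(flags)]))
})

test_that("channel/subject rejection uses strict 'more than' thresholds", {
  spec <- tiny_spec(n = c(AA = 1, AG = 1, GG = 1))
  dat <- array(0, dim = c(100, 64, 700))
  ep <- eeg_epochs(dat, 1000, default_montage())
  flags <- matrix(FALSE, 100, 64)
  flags[1:21, 5] <- TRUE  # flagged in 21% of epochs -> bad
  flags[1:20, 6] <- TRUE  # exactly 20% -> retained
  out <- apply_rejection_rules(ep, qc_params(), flags = flags)
  expect_equal(attr(out, "bad_channels"), default_montage()[5])
  expect_false(attr(out, "excluded"))
  # epochs flagged on the retained channel 6 are dropped; channel 5 is bad,
  # so its flags no longer drop epochs
  expect_equal(length(attr(out, "retained_epochs")), 80)
  # 11 bad channels -> excluded; 10 -> retained
  f11 <- matrix(FALSE, 100, 64); f11[1:30, 1:11] <- TRUE
  expect_true(attr(apply_rejection_rules(ep, flags = f11), "excluded"))
  f10 <- matrix(FALSE, 100, 64); f10[1:30, 1:10] <- TRUE
  expect_false(attr(apply_rejection_rules(ep, flags = f10), "excluded"))
})

test_that("mastoid re-referencing zeroes the mastoid mean and shifts once", {
  dat <- array(rnorm(5 * 64 * 700), dim = c(5, 64, 700))
  ep <- eeg_epochs(dat, 1000, default_montage())
  out <- rereference_mastoids(ep)
  m1 <- match("M1", default_montage()); m2 <- match("M2", default_montage())
  expect_lt(max(abs((unclass(out)[, m1, ] + unclass(out)[, m2, ]) / 2)), 1e-12)
  expect_error(rereference_mastoids(out), "already re-referenced")
  # constant 5 uV mastoids shift every channel by -5
  dat2 <- array(0, dim = c(2, 64, 700))
  dat2[, m1, ] <- 5; dat2[, m2, ] <- 5
  out2 <- rereference_mastoids(eeg_epochs(dat2, 1000, default_montage()))
  expect_equal(unique(as.vector(unclass(out2)[, 1, ])), -5)
  expect_error(rereference_mastoids(eeg_epochs(dat2[, 1:10, , drop = FALSE],
                                               1000, default_montage()[1:10])),
               "M1")
})

test_that("ERP averaging baseline-corrects and peak measurement is exact", {
  spec <- tiny_spec(n = c(AA = 1, AG = 1, GG = 1))
  # identical noise-free epochs: average equals the (baseline-corrected) epoch
  one <- simulate_eeg_epoch(-5, 8, spec, noise_rms_uv = 0)
  dat <- array(0, dim = c(4, 64, 700))
  for (i in 1:4) dat[i, , ] <- one
  ep <- eeg_epochs(dat, 1000, spec$eeg_channels)
  erp <- average_erp(ep)
  expect_equal(unname(erp[match("FCz", spec$eeg_channels), ]),
               unname(one[match("FCz", spec$eeg_channels), ]),
               tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(erp[, attr(erp, "time_ms") < 0]))), 1e-9)
  pk <- measure_erp_peaks(erp)
  fcz <- pk[pk$electrode == "FCz", ]
  expect_equal(fcz$n1_amp_uv, -5)
  expect_equal(fcz$n1_lat_ms, 120)
  expect_equal(fcz$p2_amp_uv, 8)
  expect_equal(fcz$p2_lat_ms, 230)
  # fronto-central topography: FCz exceeds Cz
  cz <- pk[pk$electrode == "Cz", ]
  expect_gt(fcz$p2_amp_uv, cz$p2_amp_uv)
  expect_lt(fcz$n1_amp_uv, cz$n1_amp_uv)
  # flat waveform: zero amplitudes, latencies at window starts (tie rule)
  flat <- average_erp(eeg_epochs(array(0, dim = c(1, 64, 700)), 1000,
                                 spec$eeg_channels))
  pk0 <- measure_erp_peaks(flat)
  expect_true(all(pk0$n1_amp_uv == 0) && all(pk0$p2_amp_uv == 0))
  expect_true(all(pk0$n1_lat_ms == 80) && all(pk0$p2_lat_ms == 180))
  expect_error(measure_erp_peaks(flat, component_windows(electrodes = "XX")),
               "XX")
})

test_that("filtering, re-referencing and averaging are jointly linear", {
  spec <- tiny_spec(n = c(AA = 1, AG = 1, GG = 1))
  set.seed(8)
  dat <- array(rnorm(6 * 64 * 700, sd = 10), dim = c(6, 64, 700))
  run <- function(d) {
    ep <- eeg_epochs(d, 1000, spec$eeg_channels)
    ep <- bandpass_filter(ep)
    ep <- rereference_mastoids(ep)
    average_erp(ep)
  }
  e1 <- run(dat)
  e3 <- run(3 * dat)
  expect_equal(as.vector(3 * unclass(e1)), as.vector(unclass(e3)),
               tolerance = 1e-6)
})

test_that("averaged P2 converges to the generator amplitude under noise", {
  spec <- tiny_spec(n = c(AA = 1, AG = 1, GG = 1), trials = 300)
  set.seed(12)
  ep <- fafpipe:::simulate_subject_eeg(-5, 8, 0, spec, n_trials = 300)
  ep <- apply_rejection_rules(ep, qc_params())
  erp <- average_erp(rereference_mastoids(ep))
  pk <- measure_erp_peaks(erp)
  p2 <- pk$p2_amp_uv[pk$electrode == "FCz"]
  # within 3 SEM of truth (pointwise noise RMS 8, n = 300), plus max bias
  expect_lt(abs(p2 - 8), 3 * 8 / sqrt(300) + 0.6)
})
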