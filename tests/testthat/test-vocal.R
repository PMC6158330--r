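make_trace <- function(f0_cents, fs = 100) {
  f0_trace(seq_along(f0_cents) / fs - 1 / fs, f0_cents, fs_hz = fs,
           unit = "cents")
}

test_that("segmentation uses the half-open window with 20+70 frames at 100 Hz", {
  tr <- make_trace(rep(10, 300))
  ev <- data.frame(trial_id = 1, onset_s = 1.6, magnitude_cents = -200,
                   duration_ms = 200)
  eps <- segment_vocal_trials(tr, ev)
  e <- eps[[1]]
  expect_length(e$values, 90)
  expect_equal(sum(e$time_ms < 0), 20)
  expect_equal(range(e$time_ms), c(-200, 690))
  # a 3 s trace with an event at 1.6 s spans [1.4, 2.3) s
  ev2 <- data.frame(trial_id = 1, onset_s = 1.6, magnitude_cents = -50,
                    duration_ms = 200)
  e2 <- segment_vocal_trials(make_trace(seq_len(300)), ev2)[[1]]
  expect_equal(e2$values[1], 141)  # sample at 1.40 s
  expect_equal(e2$values[90], 230) # sample at 2.29 s
})

test_that("events too close to the edge are marked bad with a reason", {
  tr <- make_trace(rep(0, 300))
  ev <- data.frame(trial_id = 1:2, onset_s = c(0.1, 2.95),
                   magnitude_cents = -200, duration_ms = 200)
  eps <- segment_vocal_trials(tr, ev)
  expect_equal(eps[[1]]$label, "bad")
  expect_match(eps[[1]]$reason, "baseline")
  expect_equal(eps[[2]]$label, "bad")
  expect_match(eps[[2]]$reason, "post")
})

test_that("baseline normalization subtracts the pre-onset mean exactly", {
  e <- make_epoch(rep(30, 90))
  en <- baseline_normalize(e)
  expect_equal(en$values, rep(0, 90))
  expect_equal(en$baseline_mean_cents, 30)
  e2 <- make_epoch(c(rep(10, 20), rep(25, 70)))
  en2 <- baseline_normalize(e2)
  expect_equal(unique(en2$values[en2$time_ms >= 0]), 15)
  # algebraic identity: normalized baseline mean is zero
  set.seed(1)
  e3 <- baseline_normalize(make_epoch(rnorm(90, 100, 30)))
  expect_lt(abs(mean(e3$values[e3$time_ms < 0])), 1e-9)
})

test_that("direction classification opposes the perturbation sign", {
  up <- baseline_normalize(make_epoch(c(rep(0, 20), rep(20, 70))))
  expect_equal(classify_trial(up)$label, "compensatory")
  down <- baseline_normalize(make_epoch(c(rep(0, 20), rep(-20, 70))))
  expect_equal(classify_trial(down)$label, "following")
  # missing frames above 20% make the trial bad
  v <- c(rep(0, 20), rep(20, 70)); v[sample(21:90, 36)] <- NA
  bad <- classify_trial(baseline_normalize(make_epoch(v)))
  expect_equal(bad$label, "bad")
  # excursions beyond the outlier bound make the trial bad
  v2 <- c(rep(0, 20), rep(20, 70)); v2[50] <- 900
  expect_equal(classify_trial(baseline_normalize(make_epoch(v2)))$label, "bad")
})

test_that("averaging compensatory epochs is the pointwise mean", {
  e1 <- classify_trial(baseline_normalize(make_epoch(c(rep(0, 20), rep(10, 70)))))
  e2 <- classify_trial(baseline_normalize(make_epoch(c(rep(0, 20), rep(30, 70)))))
  eps <- structure(list(e1, e2), class = "vocal_epochs")
  avg <- average_vocal_response(eps)
  expect_equal(avg$n_trials, 2)
  expect_equal(unique(avg$contour[avg$time_ms >= 0]), 20)
  # averaging identical epochs returns the epoch
  avg2 <- average_vocal_response(structure(list(e1, e1), class = "vocal_epochs"))
  expect_equal(avg2$contour, e1$values)
  # no compensatory epochs -> flagged no-response result
  f1 <- classify_trial(baseline_normalize(make_epoch(c(rep(0, 20), rep(-10, 70)))))
  avg3 <- average_vocal_response(structure(list(f1), class = "vocal_epochs"))
  expect_true(avg3$no_response)
  expect_equal(avg3$n_trials, 0)
})

test_that("peak measurement returns max, earliest tie, and edge flags", {
  tm <- (seq_len(90) - 21) * 10
  mkavg <- function(contour) structure(list(time_ms = tm, contour = contour,
                                            n_trials = 10, no_response = FALSE),
                                       class = "averaged_vocal_response")
  y <- numeric(90); y[tm == 350] <- 30
  pk <- measure_vocal_peak(mkavg(y))
  expect_equal(pk$magnitude_cents, 30)
  expect_equal(pk$latency_ms, 350)
  expect_false(pk$edge_peak)
  # plateau 300-320 ms resolves to the earliest sample
  y2 <- numeric(90); y2[tm >= 300 & tm <= 320] <- 15
  expect_equal(measure_vocal_peak(mkavg(y2))$latency_ms, 300)
  # monotone rising contour peaks at the window edge and is flagged
  y3 <- seq(-1, 1, length.out = 90)
  pk3 <- measure_vocal_peak(mkavg(y3))
  expect_equal(pk3$latency_ms, 690)
  expect_true(pk3$edge_peak)
})

test_that("baseline variability is the n-1 SD of per-trial baseline means", {
  mk <- function(b) classify_trial(baseline_normalize(
    make_epoch(c(rep(b, 20), rep(b + 20, 70)))))
  eps <- structure(lapply(c(-5, 5), mk), class = "vocal_epochs")
  expect_equal(baseline_variability(eps), sqrt(2 * 25 / 1)) # 7.0711
  eps2 <- structure(lapply(c(3, 3, 3), mk), class = "vocal_epochs")
  expect_equal(baseline_variability(eps2), 0)
  expect_warning(v <- baseline_variability(structure(list(mk(1)),
                                                     class = "vocal_epochs")),
                 "fewer than 2")
  expect_true(is.na(v))
})

test_that("averaged-then-normalized equals normalized-then-averaged", {
  set.seed(7)
  mats <- replicate(6, rnorm(90, 50, 10))
  eps <- structure(lapply(seq_len(6), function(i) {
    classify_trial(baseline_normalize(make_epoch(mats[, i])))
  }), class = "vocal_epochs")
  keep <- vapply(eps, function(e) e$label == "compensatory", TRUE)
  avg <- average_vocal_response(eps)
  raw_mean <- rowMeans(mats[, keep, drop = FALSE])
  manual <- raw_mean - mean(raw_mean[1:20])
  expect_equal(avg$contour, manual, tolerance = 1e-10)
})

test_that("matrix fast path equals the per-trial vocal pipeline", {
  spec <- tiny_spec(n = c(AA = 1, AG = 1, GG = 1), trials = 15)
  set.seed(11)
  pr <- draw_subject_params(spec)
  set.seed(99)
  sv <- fafpipe:::simulate_subject_vocal(pr$subjects[1, ], pr$comp_gain[1, ],
                                         spec)
  fast <- analyze_vocal_matrix(sv$f0_hz, sv$time_s, 100, sv$events,
                               unit = "hz")
  trace_all <- lapply(seq_len(nrow(sv$f0_hz)), function(i) {
    f0_trace(sv$time_s, sv$f0_hz[i, ], fs_hz = 100, unit = "hz")
  })
  # per-trial path: segment/normalize/classify/average each trial by hand
  for (cond in unique(sv$events$magnitude_cents)) {
    idx <- which(sv$events$magnitude_cents == cond)
    eps <- lapply(idx, function(i) {
      tr <- trace_to_cents(trace_all[[i]])
      e <- segment_vocal_trials(tr, sv$events[i, , drop = FALSE])[[1]]
      classify_trial(baseline_normalize(e))
    })
    eps <- structure(eps, class = "vocal_epochs")
    avg <- average_vocal_response(eps)
    pk <- measure_vocal_peak(avg)
    row <- fast[fast$condition_cents == cond, ]
    expect_equal(row$peak_magnitude_cents, pk$magnitude_cents,
                 tolerance = 1e-12)
    expect_equal(row$peak_latency_ms, pk$latency_ms)
    expect_equal(row$n_compensatory, avg$n_trials)
    expect_equal(row$baseline_sd_cents,
                 suppressWarnings(baseline_variability(eps)),
                 tolerance = 1e-12)
  }
})

test_that("compensation measures are invariant to absolute baseline F0", {
  spec <- noise_free_spec()
  set.seed(5)
  pr <- draw_subject_params(spec)
  row <- pr$subjects[1, ]
  set.seed(21)
  sv1 <- fafpipe:::simulate_subject_vocal(row, pr$comp_gain[1, ], spec)
  row2 <- row; row2$baseline_f0_hz <- row$baseline_f0_hz * 1.4
  set.seed(21)
  sv2 <- fafpipe:::simulate_subject_vocal(row2, pr$comp_gain[1, ], spec)
  a1 <- analyze_vocal_matrix(sv1$f0_hz, sv1$time_s, 100, sv1$events)
  a2 <- analyze_vocal_matrix(sv2$f0_hz, sv2$time_s, 100, sv2$events)
  expect_equal(a1$peak_magnitude_cents, a2$peak_magnitude_cents,
               tolerance = 1e-6)
  expect_equal(a1$peak_latency_ms, a2$peak_latency_ms)
})
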