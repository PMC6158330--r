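#' QC parameters for EEG artifact and channel rejection
#'
#' The rejection rules: a trial's channel trace is flagged when its voltage
#' behaves like an artifact relative to an 80-ms moving average with a ±55 uV
#' criterion (see [detect_artifact()]); a channel is bad when flagged in more
#' than 20% of epochs; a subject is excluded when more than 10 channels are
#' bad.
#'
#' @param artifact_threshold_uv Voltage criterion (uV).
#' @param moving_window_ms Moving-average window length (ms).
#' @param max_bad_epoch_fraction Channel rejected when flagged in strictly
#'   more than this fraction of epochs.
#' @param max_bad_channels Subject excluded when strictly more than this many
#'   channels are bad.
#' @return List of class `"qc_params"`.
#' @export
qc_params <- function(artifact_threshold_uv = 55, moving_window_ms = 80,
                      max_bad_epoch_fraction = 0.20, max_bad_channels = 10) {
  stopifnot(artifact_threshold_uv > 0, moving_window_ms > 0,
            max_bad_epoch_fraction > 0, max_bad_channels > 0)
  structure(list(artifact_threshold_uv = artifact_threshold_uv,
                 moving_window_ms = moving_window_ms,
                 max_bad_epoch_fraction = max_bad_epoch_fraction,
                 max_bad_channels = max_bad_channels), class = "qc_params")
}

#' N1/P2 component windows and measurement electrodes
#'
#' N1 is the negative peak 80-160 ms and P2 the positive peak 180-280 ms
#' after the perturbation onset, measured at ten fronto-central electrodes
#' where both components are most pronounced.
#'
#' @param n1_ms,p2_ms Length-2 windows in ms (inclusive).
#' @param electrodes Electrode labels at which peaks are measured.
#' @return List of class `"component_windows"`.
#' @export
component_windows <- function(n1_ms = c(80, 160), p2_ms = c(180, 280),
                              electrodes = c("FC1", "FC2", "FC3", "FC4", "FCz",
                                             "C1", "C2", "C3", "C4", "Cz")) {
  structure(list(n1_ms = n1_ms, p2_ms = p2_ms, electrodes = electrodes),
            class = "component_windows")
}

#' Construct an EEG epoch set
#'
#' @param data 3-d array `epoch x channel x time` of voltages in uV.
#' @param fs_hz Sampling rate (Hz).
#' @param channels Channel labels (unique, length = `dim(data)[2]`).
#' @param t0_ms Time of the first sample relative to the event (ms).
#' @param reference Reference state: `"vertex"` (as recorded) or
#'   `"mastoid-average"`.
#' @return Object of class `"eeg_epochs"`: the array plus attributes
#'   (`fs_hz`, `channels`, `time_ms`, `reference`, empty QC state).
#' @export
eeg_epochs <- function(data, fs_hz, channels, t0_ms = -200,
                       reference = "vertex") {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(channels),
            !anyDuplicated(channels))
  time_ms <- t0_ms + (seq_len(dim(data)[3]) - 1L) * 1000 / fs_hz
  structure(data, class = "eeg_epochs", fs_hz = fs_hz,
            channels = channels, time_ms = time_ms, reference = reference,
            flags = NULL, bad_channels = character(0),
            retained_epochs = seq_len(dim(data)[1]),
            excluded = FALSE, exclusion_reason = NA_character_)
}

n_epochs <- function(x) dim(x)[1]

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass (default 1-20 Hz, 4th order) as a
#' zero-phase magnitude response in the frequency domain: each trace is
#' reflect-padded, transformed, multiplied by the analytic Butterworth
#' amplitude response, and transformed back. This realisation has exactly the
#' Butterworth passband/stopband shape with no phase distortion, and
#' vectorises over thousands of epoch-channel traces.
#'
#' @param x Numeric vector, a matrix with time in rows (each column filtered
#'   independently), or an `"eeg_epochs"` object (filtered along time).
#' @param fs Sampling rate (Hz); taken from the object for `"eeg_epochs"`.
#' @param low_hz,high_hz Band edges (Hz). `fs` must exceed `2 * high_hz`.
#' @param order Butterworth order of each band edge.
#' @return Filtered object of the same shape.
#' @export
bandpass_filter <- function(x, fs = NULL, low_hz = 1, high_hz = 20, order = 4) {
  if (inherits(x, "eeg_epochs")) {
    fs <- attr(x, "fs_hz")
    d <- dim(x)
    mat <- matrix(aperm(unclass(x), c(3, 1, 2)), nrow = d[3])
    out <- bandpass_filter(mat, fs, low_hz, high_hz, order)
    res <- aperm(array(out, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    attributes(res) <- attributes(x)
    return(res)
  }
  if (is.null(fs)) stop("`fs` is required for vector/matrix input")
  if (fs <= 2 * high_hz) stop("sampling rate too low for the requested band")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  pad <- min(n - 1L, ceiling(fs / low_hz))
  # 2-3-5-smooth transform length keeps the FFT fast; the tail beyond the
  # reflection padding is zero-filled, far from the retained segment
  np <- stats::nextn(n + 2L * pad, c(2L, 3L, 5L))
  xp <- rbind(x[(pad + 1L):2L, , drop = FALSE], x,
              x[(n - 1L):(n - pad), , drop = FALSE],
              matrix(0, np - n - 2L * pad, ncol(x)))
  f <- (seq_len(np) - 1L) * fs / np
  f <- pmin(f, fs - f) # two-sided spectrum frequencies
  gain <- sqrt(1 / (1 + (f / high_hz)^(2 * order))) *
    sqrt((f / low_hz)^(2 * order) / (1 + (f / low_hz)^(2 * order)))
  y <- Re(mvfft(mvfft(xp) * gain, inverse = TRUE)) / np
  y <- y[(pad + 1L):(pad + n), , drop = FALSE]
  if (vec) y[, 1L] else y
}

#' Segment a continuous EEG recording into event-locked epochs
#'
#' Cuts `[-baseline_ms, post_ms)` epochs around each event, with time 0 at the
#' first sample at or after the event (the same half-open convention as the
#' vocal epochs). Events too close to the recording edges are dropped and
#' reported in the `"dropped_events"` attribute.
#'
#' @param recording Matrix `channel x time` of voltages (uV).
#' @param fs Sampling rate (Hz).
#' @param channels Channel labels.
#' @param events_s Event onset times (s, relative to recording start).
#' @param baseline_ms,post_ms Epoch extent (ms).
#' @return An [eeg_epochs()] object.
#' @export
segment_eeg <- function(recording, fs, channels, events_s,
                        baseline_ms = 200, post_ms = 500) {
  stopifnot(is.matrix(recording), nrow(recording) == length(channels))
  nb <- round(baseline_ms / 1000 * fs)
  np <- round(post_ms / 1000 * fs)
  onset_idx <- floor(events_s * fs + 1e-9) + 1L
  ok <- onset_idx - nb >= 1L & onset_idx + np - 1L <= ncol(recording)
  dropped <- which(!ok)
  dat <- array(NA_real_, dim = c(sum(ok), length(channels), nb + np))
  for (k in seq_along(which(ok))) {
    i <- which(ok)[k]
    dat[k, , ] <- recording[, (onset_idx[i] - nb):(onset_idx[i] + np - 1L)]
  }
  out <- eeg_epochs(dat, fs_hz = fs, channels = channels, t0_ms = -baseline_ms)
  attr(out, "dropped_events") <- dropped
  out
}

# Centred moving average with reflection padding; x is a column-wise matrix
# (time in rows). `w` is the window length in samples (forced odd).
moving_average <- function(x, w, align = c("centered", "trailing")) {
  align <- match.arg(align)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (align == "centered" && w %% 2L == 0L) w <- w + 1L
  pad_l <- if (align == "centered") (w - 1L) %/% 2L else w - 1L
  pad_r <- if (align == "centered") (w - 1L) %/% 2L else 0L
  stopifnot(n > max(pad_l, pad_r))
  left <- if (pad_l > 0L) x[(pad_l + 1L):2L, , drop = FALSE]
  right <- if (pad_r > 0L) x[(n - 1L):(n - pad_r), , drop = FALSE]
  xp <- rbind(left, x, right)
  cs <- apply(xp, 2L, cumsum)
  cs <- rbind(0, cs)
  ma <- (cs[(w + 1L):(nrow(cs)), , drop = FALSE] -
           cs[1L:(nrow(cs) - w), , drop = FALSE]) / w
  ma <- ma[seq_len(n), , drop = FALSE]
  if (vec) ma[, 1L] else ma
}

#' Detect an artifact in a single epoch-channel trace
#'
#' The criterion combines two readings of the ±55 uV / 80-ms moving-average
#' rule: (i) *deviation* — some sample departs from the centred 80-ms moving
#' average by more than the threshold (fast artifacts: muscle bursts, steps);
#' (ii) *smoothed excursion* — the 80-ms-smoothed trace spans more than the
#' threshold peak-to-peak within the epoch (slow artifacts: blinks, eye
#' movements, which a local-deviation test alone cannot see because they are
#' smooth). The default flags when either fires; each sub-rule is available
#' alone via `rule`.
#'
#' @param trace Numeric vector, one channel of one epoch (uV).
#' @param fs Sampling rate (Hz).
#' @param qc A [qc_params()] object.
#' @param rule `"combined"`, `"deviation"` or `"smoothed"`.
#' @param align Moving-average alignment, `"centered"` (default) or
#'   `"trailing"`.
#' @return Logical flag.
#' @export
detect_artifact <- function(trace, fs, qc = qc_params(),
                            rule = c("combined", "deviation", "smoothed"),
                            align = c("centered", "trailing")) {
  rule <- match.arg(rule)
  align <- match.arg(align)
  w <- max(2L, round(qc$moving_window_ms / 1000 * fs))
  if (length(trace) < w) stop("trace shorter than the moving-average window")
  ma <- moving_average(trace, w, align = align)
  thr <- qc$artifact_threshold_uv
  dev_hit <- any(abs(trace - ma) > thr)
  slow_hit <- (max(ma) - min(ma)) > thr
  switch(rule, combined = dev_hit || slow_hit, deviation = dev_hit,
         smoothed = slow_hit)
}

# Vectorised artifact flags for a whole epoch set: logical epoch x channel.
artifact_flags <- function(epochs, qc = qc_params(),
                           rule = "combined", align = "centered") {
  d <- dim(epochs)
  fs <- attr(epochs, "fs_hz")
  w <- max(2L, round(qc$moving_window_ms / 1000 * fs))
  mat <- matrix(aperm(unclass(epochs), c(3, 1, 2)), nrow = d[3])
  ma <- moving_average(mat, w, align = align)
  thr <- qc$artifact_threshold_uv
  dev_hit <- apply(abs(mat - ma), 2L, max) > thr
  slow_hit <- (apply(ma, 2L, max) - apply(ma, 2L, min)) > thr
  hits <- switch(rule, combined = dev_hit | slow_hit,
                 deviation = dev_hit, smoothed = slow_hit)
  matrix(hits, nrow = d[1], ncol = d[2])
}

#' Apply channel and subject rejection rules
#'
#' Computes artifact flags per (epoch, channel) unless supplied, then: marks a
#' channel bad when flagged in strictly more than
#' `max_bad_epoch_fraction` of epochs; excludes the subject when strictly more
#' than `max_bad_channels` channels are bad; and drops from averaging every
#' epoch flagged on any retained channel.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param qc A [qc_params()] object.
#' @param flags Optional precomputed logical `epoch x channel` matrix.
#' @param rule,align Passed to the artifact detector.
#' @return The epoch set with attributes `flags`, `bad_channels`,
#'   `retained_epochs`, `excluded` and `qc_report` (counts and reasons).
#' @export
apply_rejection_rules <- function(epochs, qc = qc_params(), flags = NULL,
                                  rule = "combined", align = "centered") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(flags)) flags <- artifact_flags(epochs, qc, rule, align)
  d <- dim(epochs)
  stopifnot(nrow(flags) == d[1], ncol(flags) == d[2])
  channels <- attr(epochs, "channels")
  frac <- colMeans(flags)
  bad_ch <- channels[frac > qc$max_bad_epoch_fraction]
  excluded <- length(bad_ch) > qc$max_bad_channels
  retained_ch <- setdiff(channels, bad_ch)
  epoch_bad <- rowSums(flags[, match(retained_ch, channels), drop = FALSE]) > 0L
  retained <- which(!epoch_bad)
  attr(epochs, "flags") <- flags
  attr(epochs, "bad_channels") <- bad_ch
  attr(epochs, "retained_epochs") <- retained
  attr(epochs, "excluded") <- excluded
  attr(epochs, "exclusion_reason") <-
    if (excluded) sprintf("bad channels > %d", qc$max_bad_channels) else NA_character_
  attr(epochs, "qc_report") <- list(
    n_epochs = d[1], n_channels = d[2],
    flagged_pairs = sum(flags),
    bad_channels = bad_ch, n_bad_channels = length(bad_ch),
    n_epochs_dropped = d[1] - length(retained),
    n_epochs_retained = length(retained),
    excluded = excluded)
  epochs
}

#' Re-reference epochs to the mastoid average
#'
#' Subtracts the per-sample mean of the two mastoid channels from every
#' channel, converting vertex-referenced recordings to the average-mastoid
#' reference. May be applied exactly once.
#'
#' @param epochs An [eeg_epochs()] object in the `"vertex"` reference state.
#' @param mastoid_labels The two mastoid channel labels.
#' @return The re-referenced epoch set (`reference = "mastoid-average"`).
#' @export
rereference_mastoids <- function(epochs, mastoid_labels = c("M1", "M2")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (attr(epochs, "reference") != "vertex") {
    stop("epochs are already re-referenced (state: ", attr(epochs, "reference"), ")")
  }
  channels <- attr(epochs, "channels")
  miss <- setdiff(mastoid_labels, channels)
  if (length(miss)) stop("mastoid channel(s) missing from montage: ",
                         paste(miss, collapse = ", "))
  idx <- match(mastoid_labels, channels)
  ref <- (unclass(epochs)[, idx[1], , drop = FALSE] +
            unclass(epochs)[, idx[2], , drop = FALSE]) / 2
  out <- unclass(epochs) - ref[, rep(1L, length(channels)), , drop = FALSE]
  attributes(out) <- attributes(epochs)
  attr(out, "reference") <- "mastoid-average"
  out
}

#' Average retained epochs into an ERP
#'
#' Pointwise mean over the retained epochs per channel, followed by baseline
#' correction (subtracting each channel's mean over the pre-stimulus
#' interval).
#'
#' @param epochs An [eeg_epochs()] object (after QC; all epochs are used if
#'   no rejection has been applied).
#' @return Matrix `channel x time` of class `"erp_waveform"` with attributes
#'   `channels`, `time_ms`, `fs_hz`, `n_epochs`.
#' @export
average_erp <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- attr(epochs, "retained_epochs")
  if (!length(keep)) stop("no retained epochs to average; condition is missing")
  erp <- apply(unclass(epochs)[keep, , , drop = FALSE], c(2, 3), mean)
  time_ms <- attr(epochs, "time_ms")
  erp <- erp - rowMeans(erp[, time_ms < 0, drop = FALSE])
  structure(erp, class = "erp_waveform", channels = attr(epochs, "channels"),
            time_ms = time_ms, fs_hz = attr(epochs, "fs_hz"),
            n_epochs = length(keep))
}

#' Measure N1 and P2 peaks from an averaged ERP
#'
#' N1 is the minimum sample within its window and P2 the maximum within its
#' window (inclusive bounds); ties resolve to the earliest sample. Amplitudes
#' keep component polarity.
#'
#' @param erp An `"erp_waveform"` from [average_erp()].
#' @param windows A [component_windows()] object.
#' @return Data frame with one row per electrode: `electrode`, `n1_amp_uv`,
#'   `n1_lat_ms`, `p2_amp_uv`, `p2_lat_ms`.
#' @export
measure_erp_peaks <- function(erp, windows = component_windows()) {
  stopifnot(inherits(erp, "erp_waveform"))
  channels <- attr(erp, "channels")
  time_ms <- attr(erp, "time_ms")
  miss <- setdiff(windows$electrodes, channels)
  if (length(miss)) stop("electrode(s) absent from montage: ",
                         paste(miss, collapse = ", "))
  n1_sel <- which(time_ms >= windows$n1_ms[1] & time_ms <= windows$n1_ms[2])
  p2_sel <- which(time_ms >= windows$p2_ms[1] & time_ms <= windows$p2_ms[2])
  if (!length(n1_sel) || !length(p2_sel)) stop("component window outside epoch")
  rows <- lapply(windows$electrodes, function(el) {
    y <- erp[match(el, channels), ]
    i1 <- which.min(y[n1_sel])
    i2 <- which.max(y[p2_sel])
    data.frame(electrode = el,
               n1_amp_uv = y[n1_sel][i1], n1_lat_ms = time_ms[n1_sel][i1],
               p2_amp_uv = y[p2_sel][i2], p2_lat_ms = time_ms[p2_sel][i2])
  })
  do.call(rbind, rows)
}

#' Full per-subject ERP measurement chain
#'
#' Band-pass filtering (optional), artifact detection and rejection rules,
#' mastoid re-referencing of the retained epochs, averaging with baseline
#' correction, and N1/P2 peak measurement.
#'
#' @param epochs An [eeg_epochs()] object for one subject and condition.
#' @param qc [qc_params()].
#' @param windows [component_windows()].
#' @param filter Apply the 1-20 Hz band-pass first (as in a standard
#'   pipeline); disable for already-filtered or noise-free data.
#' @param mastoid_labels Passed to [rereference_mastoids()].
#' @param ... Passed to [apply_rejection_rules()].
#' @return List with `measurements` (see [measure_erp_peaks()], `NULL` when
#'   the subject is excluded), `qc_report`, `excluded`, `n_retained`.
#' @export
analyze_eeg_subject <- function(epochs, qc = qc_params(),
                                windows = component_windows(), filter = TRUE,
                                mastoid_labels = c("M1", "M2"), ...) {
  if (filter) epochs <- bandpass_filter(epochs)
  epochs <- apply_rejection_rules(epochs, qc, ...)
  rep_ <- attr(epochs, "qc_report")
  if (attr(epochs, "excluded")) {
    return(list(measurements = NULL, qc_report = rep_, excluded = TRUE,
                n_retained = 0L))
  }
  epochs <- rereference_mastoids(epochs, mastoid_labels)
  erp <- average_erp(epochs)
  meas <- measure_erp_peaks(erp, windows)
  meas$n_retained <- attr(erp, "n_epochs")
  list(measurements = meas, qc_report = rep_, excluded = FALSE,
       n_retained = attr(erp, "n_epochs"))
}
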