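#' Construct an F0 trace
#'
#' An F0 trace is a frame-based contour of voice fundamental frequency:
#' sample times (strictly increasing), values (Hz or cents; `NA` marks
#' unvoiced frames), and the frame rate.
#'
#' @param time_s Numeric vector of strictly increasing sample times (s).
#' @param f0 Numeric vector of F0 values, same length as `time_s`.
#' @param fs_hz Frame rate in Hz (frames per second).
#' @param unit `"hz"` or `"cents"`.
#' @return A `data.frame` of class `"f0_trace"` with columns `time_s` and
#'   `f0`, and attributes `fs_hz` and `unit`.
#' @export
f0_trace <- function(time_s, f0, fs_hz, unit = c("hz", "cents")) {
  unit <- match.arg(unit)
  if (length(time_s) != length(f0)) stop("`time_s` and `f0` must have the same length")
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing")
  }
  if (unit == "hz" && any(f0 <= 0, na.rm = TRUE)) {
    stop("voiced `f0` values must be positive when unit is \"hz\"")
  }
  out <- data.frame(time_s = as.numeric(time_s), f0 = as.numeric(f0))
  attr(out, "fs_hz") <- fs_hz
  attr(out, "unit") <- unit
  class(out) <- c("f0_trace", "data.frame")
  out
}

#' Convert the unit of an F0 trace
#'
#' @param trace An [f0_trace()].
#' @param reference_hz Cent-scale reference frequency.
#' @return The trace with `f0` in cents (or Hz) and the unit attribute updated.
#' @export
trace_to_cents <- function(trace, reference_hz = G3_HZ) {
  stopifnot(inherits(trace, "f0_trace"))
  if (attr(trace, "unit") == "cents") return(trace)
  f0_trace(trace$time_s, hz_to_cents(trace$f0, reference_hz),
           fs_hz = attr(trace, "fs_hz"), unit = "cents")
}

#' Estimate voice F0 from a mono waveform
#'
#' Frame-based autocorrelation pitch tracking: the waveform is cut into
#' overlapping frames, each frame is mean-removed, and the normalised
#' autocorrelation is searched for its highest peak within the candidate lag
#' range implied by `f0_range_hz`. The lag is refined by parabolic
#' interpolation; frames whose peak falls below `voicing_threshold` (or whose
#' energy is negligible) are marked unvoiced (`NA`).
#'
#' @param wave Numeric vector, mono audio samples.
#' @param fs Sampling rate in Hz (at least 8 kHz).
#' @param frame_ms Analysis frame length in ms.
#' @param hop_ms Hop between frame centres in ms; the F0 frame rate is
#'   `1000 / hop_ms`.
#' @param f0_range_hz Length-2 numeric, candidate F0 range; must lie within
#'   50-600 Hz.
#' @param voicing_threshold Minimum normalised autocorrelation peak for a
#'   frame to count as voiced.
#' @return An [f0_trace()] in Hz; unvoiced frames are `NA`. If every frame is
#'   unvoiced a warning is issued.
#' @examples
#' fs <- 10000
#' tone <- sin(2 * pi * 200 * seq(0, 1, by = 1 / fs))
#' tr <- estimate_f0(tone, fs)
#' range(tr$f0, na.rm = TRUE) # close to 200 Hz
#' @export
estimate_f0 <- function(wave, fs, frame_ms = 40, hop_ms = 10,
                        f0_range_hz = c(75, 500), voicing_threshold = 0.3) {
  if (fs < 8000) stop("`fs` must be at least 8 kHz for F0 estimation")
  if (length(f0_range_hz) != 2L || f0_range_hz[1] >= f0_range_hz[2] ||
      f0_range_hz[1] < 50 || f0_range_hz[2] > 600) {
    stop("`f0_range_hz` must be an increasing interval within [50, 600] Hz")
  }
  wave <- as.numeric(wave)
  n_frame <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  lag_min <- max(2L, floor(fs / f0_range_hz[2]))
  lag_max <- ceiling(fs / f0_range_hz[1])
  if (n_frame <= 2L * lag_max) {
    # need at least two periods of the lowest candidate in a frame
    n_frame <- 2L * lag_max + 1L
  }
  starts <- seq(1L, length(wave) - n_frame + 1L, by = hop)
  if (length(starts) == 0L) stop("waveform shorter than one analysis frame")
  centre_s <- (starts - 1L + n_frame / 2) / fs
  peak_amp <- max(abs(wave), 1e-12)
  f0 <- rep(NA_real_, length(starts))
  lags <- lag_min:lag_max
  # Hann analysis window; dividing the windowed-signal autocorrelation by
  # the window's own autocorrelation removes the lag taper and edge
  # distortion, leaving an almost unbiased normalised autocorrelation.
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_frame) - 1L) / (n_frame - 1L))
  ac <- function(v, l) sum(v[1:(n_frame - l)] * v[(1 + l):n_frame])
  rw <- vapply(c(0L, lags), ac, 0, v = hann)
  for (k in seq_along(starts)) {
    x <- wave[starts[k]:(starts[k] + n_frame - 1L)]
    x <- (x - mean(x)) * hann
    r0 <- sum(x * x)
    if (r0 < (1e-4 * peak_amp)^2 * sum(hann^2)) next # silent frame
    r <- vapply(lags, ac, 0, v = x)
    rn <- (r / r0) / (rw[-1L] / rw[1L])
    if (max(rn) < voicing_threshold) next
    # shortest lag within a small margin of the best peak, to avoid
    # picking a period multiple (octave-down error)
    is_peak <- rn >= c(rn[-1L], -Inf) & rn >= c(-Inf, rn[-length(rn)])
    i <- which(is_peak & rn >= max(rn) - 0.02)[1L]
    if (is.na(i)) i <- which.max(rn)
    lag <- lags[i]
    if (i > 1L && i < length(rn)) {
      # near the peak the autocorrelation is locally A*cos(w*(l - p)):
      # solve for p exactly from three samples (parabola as fallback)
      tri <- rn[(i - 1L):(i + 1L)]
      cosw <- (tri[1] + tri[3]) / (2 * tri[2])
      if (is.finite(cosw) && cosw > 0 && cosw < 1) {
        w <- acos(cosw)
        lag <- lag - atan2((tri[1] - tri[3]) / 2, tri[2] * sin(w)) / w
      } else {
        denom <- tri[1] - 2 * tri[2] + tri[3]
        if (abs(denom) > 1e-12) lag <- lag + 0.5 * (tri[1] - tri[3]) / denom
      }
    }
    f0[k] <- fs / lag
  }
  if (all(is.na(f0))) warning("no voiced frames detected; returning all-missing trace")
  f0_trace(centre_s, f0, fs_hz = 1000 / hop_ms, unit = "hz")
}

#' Synthesise a vowel-like test tone
#'
#' Renders a sine wave with optional vibrato (sinusoidal F0 modulation on the
#' cent scale), used to exercise [estimate_f0()] with a known ground-truth
#' contour. This is a test signal, not a vocal-tract model.
#'
#' @param duration_s Duration in seconds.
#' @param fs Audio sampling rate in Hz.
#' @param f0_hz Carrier fundamental frequency in Hz.
#' @param vibrato_cents Peak vibrato depth in cents (0 disables).
#' @param vibrato_hz Vibrato rate in Hz.
#' @param amplitude Peak amplitude in [0, 1].
#' @return Numeric vector of audio samples.
#' @export
render_vowel_audio <- function(duration_s, fs = 10000, f0_hz = 200,
                               vibrato_cents = 0, vibrato_hz = 5,
                               amplitude = 0.8) {
  t <- seq(0, duration_s, by = 1 / fs)
  inst <- f0_hz * 2^(vibrato_cents * sin(2 * pi * vibrato_hz * t) / 1200)
  phase <- 2 * pi * cumsum(inst) / fs
  amplitude * sin(phase)
}
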