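#' Default 64-channel montage
#'
#' A 64-label 10-10-style montage including the ten fronto-central
#' measurement electrodes (FC1-4, FCz, C1-4, Cz) and the two mastoids
#' (M1, M2).
#'
#' @return Character vector of 64 unique labels.
#' @export
default_montage <- function() {
  labs <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
            "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
            "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
            "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
            "M1", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
            "TP8", "M2",
            "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
            "O1", "Oz", "O2")
  stopifnot(length(labs) == 64L, !anyDuplicated(labs))
  labs
}

# Fronto-central topographic weights for the N1/P2 generators: maximal and
# exactly 1 at FCz, frontal row above central row, near zero posteriorly and
# exactly zero at the mastoids.
component_topography <- function(channels) {
  w <- c(FCz = 1, FC1 = 0.95, FC2 = 0.95, FC3 = 0.85, FC4 = 0.85,
         FC5 = 0.7, FC6 = 0.7, FT7 = 0.5, FT8 = 0.5,
         Cz = 0.9, C1 = 0.82, C2 = 0.82, C3 = 0.72, C4 = 0.72,
         C5 = 0.55, C6 = 0.55, T7 = 0.35, T8 = 0.35,
         Fz = 0.8, F1 = 0.75, F2 = 0.75, F3 = 0.65, F4 = 0.65,
         F5 = 0.5, F6 = 0.5, F7 = 0.4, F8 = 0.4,
         CPz = 0.6, CP1 = 0.55, CP2 = 0.55, CP3 = 0.45, CP4 = 0.45,
         CP5 = 0.35, CP6 = 0.35, TP7 = 0.25, TP8 = 0.25,
         Fp1 = 0.3, Fpz = 0.3, Fp2 = 0.3,
         AF7 = 0.35, AF3 = 0.35, AF4 = 0.35, AF8 = 0.35,
         Pz = 0.35, P1 = 0.3, P2 = 0.3,
         M1 = 0, M2 = 0)
  out <- w[channels]
  out[is.na(out)] <- ifelse(grepl("^PO|^O", channels[is.na(out)]), 0.12, 0.22)
  names(out) <- channels
  unname(out)
}

#' Effect and noise parameters of the synthetic cohort
#'
#' Defaults encode the generative structure the analyses assume: compensatory
#' gains around 25/27 cents for the -50/-200 cents conditions (the two
#' conditions barely differing) with 10 cents between-subject SD, truncated
#' positive; a GG deficit of 0.8 pooled SD at -200 cents; subject gains
#' correlated 0.7 across conditions (compensation is trait-like);
#' baseline-variability-to-gain correlations of 0.53/0.26/0.10 for AA/AG/GG;
#' AR(1) F0 jitter dominated by frame-level tracking noise; N1 amplitudes
#' independent of genotype; P2 larger for -200 cents and boosted by 0.8 SD
#' for GG at -200; blink-like artifacts on the far-frontal channels at 15%
#' of epochs.
#'
#' @param comp_gain_mean_cents Named mean compensatory gain per condition.
#' @param comp_gain_sd_cents Between-subject SD of the gains.
#' @param comp_gain_min_cents Lower truncation of the gains (compensatory
#'   gains oppose the downward shift, hence are positive).
#' @param gg_deficit_sd GG gain reduction at `gg_conditions`, in units of
#'   `comp_gain_sd_cents`.
#' @param gg_conditions Conditions (magnitudes) at which the GG deficit and
#'   P2 boost apply.
#' @param cross_condition_cor Correlation of a subject's gains across
#'   conditions.
#' @param sd_gain_cor Named per-genotype correlation between a subject's
#'   baseline F0 variability and compensatory gain.
#' @param baseline_sd_mean_cents,baseline_sd_sd_cents,baseline_sd_min_cents
#'   Distribution of the per-subject F0 jitter scale (normal, truncated
#'   below at the minimum).
#' @param jitter_phi AR(1) coefficient of the frame-rate F0 jitter.
#' @param onset_latency_ms Vocal response onset after the perturbation.
#' @param comp_latency_mean_ms,comp_latency_sd_ms Peak-latency distribution
#'   (truncated to 250-550 ms).
#' @param following_fraction Fraction of trials generated with a response
#'   following (same sign as) the perturbation.
#' @param following_scale Relative size of following responses.
#' @param n1_amp_mean_uv,p2_amp_mean_uv Named component amplitude means per
#'   condition (uV; N1 negative).
#' @param n1_amp_sd_uv,p2_amp_sd_uv Between-subject SDs.
#' @param gg_p2_boost_sd GG P2 increase at `gg_conditions` in units of
#'   `p2_amp_sd_uv`.
#' @param eeg_noise_rms_uv RMS of the 1/f EEG background per channel.
#' @param artifact_rate Probability an epoch carries a blink artifact.
#' @param blink_amplitude_uv,blink_duration_ms Blink half-sine shape.
#' @param male_fraction Named per-genotype fraction of male subjects.
#' @return List of class `"effect_params"`.
#' @export
effect_params <- function(comp_gain_mean_cents = c(`-50` = 25, `-200` = 27),
                          comp_gain_sd_cents = 10,
                          comp_gain_min_cents = 2,
                          gg_deficit_sd = 0.8,
                          gg_conditions = -200,
                          cross_condition_cor = 0.7,
                          sd_gain_cor = c(AA = 0.53, AG = 0.26, GG = 0.10),
                          baseline_sd_mean_cents = 8,
                          baseline_sd_sd_cents = 3,
                          baseline_sd_min_cents = 2,
                          jitter_phi = 0.55,
                          onset_latency_ms = 150,
                          comp_latency_mean_ms = 350,
                          comp_latency_sd_ms = 40,
                          following_fraction = 0.15,
                          following_scale = 0.6,
                          n1_amp_mean_uv = c(`-50` = -5, `-200` = -7),
                          n1_amp_sd_uv = 1.5,
                          p2_amp_mean_uv = c(`-50` = 6, `-200` = 8),
                          p2_amp_sd_uv = 2,
                          gg_p2_boost_sd = 0.8,
                          eeg_noise_rms_uv = 8,
                          artifact_rate = 0.15,
                          blink_amplitude_uv = 150,
                          blink_duration_ms = 300,
                          male_fraction = c(AA = 14 / 49, AG = 18 / 63,
                                            GG = 4 / 21)) {
  if (any(sd_gain_cor^2 > cross_condition_cor + 1e-12)) {
    stop("`cross_condition_cor` must be at least the square of every `sd_gain_cor`")
  }
  if (following_fraction < 0 || following_fraction > 1) {
    stop("`following_fraction` must lie in [0, 1]")
  }
  if (artifact_rate < 0 || artifact_rate > 1) stop("`artifact_rate` must lie in [0, 1]")
  structure(as.list(environment()), class = "effect_params")
}

#' Null-effect parameters
#'
#' [effect_params()] with every genotype-linked effect removed: no GG gain
#' deficit, no GG P2 boost, and identical (zero) variability-gain
#' correlations, so genotype labels are exchangeable and any downstream
#' genotype test measures pure false-positive rate.
#'
#' @param ... Overrides passed on to [effect_params()].
#' @export
null_effects <- function(...) {
  effect_params(gg_deficit_sd = 0, gg_p2_boost_sd = 0,
                sd_gain_cor = c(AA = 0, AG = 0, GG = 0), ...)
}

#' Cohort design specification
#'
#' Describes the study design being emulated: 49/63/21 subjects with
#' AA/AG/GG genotypes, 100 trials per perturbation magnitude (-50 and -200
#' cents), 200-ms downward pitch shifts delivered 1500-2000 ms after vocal
#' onset during 3-s vocalizations, frame-rate F0 contours at 100 Hz and
#' 64-channel EEG at 1000 Hz.
#'
#' @param n_per_genotype Named subject counts for AA/AG/GG.
#' @param trials_per_condition Trials per perturbation magnitude.
#' @param magnitudes_cents Perturbation magnitudes (negative: downward).
#' @param perturbation_duration_ms Perturbation duration.
#' @param perturbation_onset_range_ms Onset window after vocal onset.
#' @param vocalization_ms Vocalization length.
#' @param vocal_fs_hz F0 contour frame rate.
#' @param eeg_fs_hz EEG sampling rate.
#' @param eeg_channels Montage labels (must include mastoids M1/M2).
#' @param blink_channels Channels carrying blink artifacts.
#' @param effects An [effect_params()] object.
#' @return List of class `"cohort_spec"` (validated).
#' @export
cohort_spec <- function(n_per_genotype = c(AA = 49, AG = 63, GG = 21),
                        trials_per_condition = 100,
                        magnitudes_cents = c(-50, -200),
                        perturbation_duration_ms = 200,
                        perturbation_onset_range_ms = c(1500, 2000),
                        vocalization_ms = 3000,
                        vocal_fs_hz = 100,
                        eeg_fs_hz = 1000,
                        eeg_channels = default_montage(),
                        blink_channels = c("Fp1", "Fpz", "Fp2", "AF7",
                                           "AF3", "AF4", "AF8"),
                        effects = effect_params()) {
  if (any(n_per_genotype <= 0)) stop("`n_per_genotype`: all counts must be > 0")
  if (!identical(sort(names(n_per_genotype)), c("AA", "AG", "GG"))) {
    stop("`n_per_genotype` must be named AA, AG, GG")
  }
  if (trials_per_condition <= 0) stop("`trials_per_condition` must be > 0")
  if (any(magnitudes_cents >= 0)) {
    stop("`magnitudes_cents`: perturbations must be negative (downward shifts)")
  }
  if (perturbation_onset_range_ms[2] + 700 > vocalization_ms) {
    stop("`perturbation_onset_range_ms`: latest onset leaves < 700 ms of vocalization")
  }
  if (perturbation_onset_range_ms[1] < 200) {
    stop("`perturbation_onset_range_ms`: earliest onset leaves no 200 ms baseline")
  }
  if (anyDuplicated(eeg_channels)) stop("`eeg_channels`: labels must be unique")
  if (!all(blink_channels %in% eeg_channels)) {
    stop("`blink_channels` must be a subset of `eeg_channels`")
  }
  if (!inherits(effects, "effect_params")) stop("`effects` must come from effect_params()")
  miss_cond <- setdiff(as.character(magnitudes_cents),
                       names(effects$comp_gain_mean_cents))
  if (length(miss_cond)) {
    stop("`effects`: no comp_gain_mean_cents entry for condition(s) ",
         paste(miss_cond, collapse = ", "))
  }
  structure(list(n_per_genotype = n_per_genotype,
                 trials_per_condition = trials_per_condition,
                 magnitudes_cents = magnitudes_cents,
                 perturbation_duration_ms = perturbation_duration_ms,
                 perturbation_onset_range_ms = perturbation_onset_range_ms,
                 vocalization_ms = vocalization_ms,
                 vocal_fs_hz = vocal_fs_hz, eeg_fs_hz = eeg_fs_hz,
                 eeg_channels = eeg_channels, blink_channels = blink_channels,
                 effects = effects), class = "cohort_spec")
}

#' Draw per-subject generative parameters
#'
#' Samples, for every subject, the genotype-conditional latent parameters:
#' baseline F0 (sex-dependent), baseline F0 jitter scale, compensatory gain
#' per condition (correlated with the jitter scale at the genotype-specific
#' target, correlated across conditions, GG deficit applied), peak latency,
#' N1/P2 amplitudes per condition (P2 GG boost applied), and artifact rate.
#' Uses the current RNG state; wrap in a seed for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (data frame) and per-condition matrices
#'   `comp_gain`, `n1_amp`, `p2_amp` (subject x condition).
#' @export
draw_subject_params <- function(spec) {
  eff <- spec$effects
  genos <- rep(c("AA", "AG", "GG"), times = spec$n_per_genotype[c("AA", "AG", "GG")])
  n <- length(genos)
  conds <- spec$magnitudes_cents
  nc <- length(conds)
  male <- rbinom(n, 1L, eff$male_fraction[genos]) == 1L
  age <- pmin(29L, pmax(18L, round(rnorm(n, 21, 2))))
  baseline_f0 <- ifelse(male, pmax(80, rnorm(n, 130, 20)),
                        pmax(150, rnorm(n, 220, 25)))
  z_sd <- rnorm(n)
  baseline_sd <- pmax(eff$baseline_sd_min_cents,
                      eff$baseline_sd_mean_cents +
                        eff$baseline_sd_sd_cents * z_sd)
  rho <- eff$sd_gain_cor[genos]
  b <- sqrt(pmax(0, eff$cross_condition_cor - rho^2))
  cc <- sqrt(1 - eff$cross_condition_cor)
  u <- rnorm(n)
  comp_gain <- matrix(NA_real_, n, nc, dimnames = list(NULL, as.character(conds)))
  for (j in seq_len(nc)) {
    mu <- rep(eff$comp_gain_mean_cents[[as.character(conds[j])]], n)
    if (conds[j] %in% eff$gg_conditions) {
      mu[genos == "GG"] <- mu[genos == "GG"] -
        eff$gg_deficit_sd * eff$comp_gain_sd_cents
    }
    comp_gain[, j] <- pmax(eff$comp_gain_min_cents,
                           mu + eff$comp_gain_sd_cents *
                             (rho * z_sd + b * u + cc * rnorm(n)))
  }
  comp_latency <- pmin(550, pmax(250, rnorm(n, eff$comp_latency_mean_ms,
                                            eff$comp_latency_sd_ms)))
  n1_amp <- matrix(NA_real_, n, nc, dimnames = list(NULL, as.character(conds)))
  p2_amp <- matrix(NA_real_, n, nc, dimnames = list(NULL, as.character(conds)))
  for (j in seq_len(nc)) {
    key <- as.character(conds[j])
    n1_amp[, j] <- eff$n1_amp_mean_uv[[key]] + eff$n1_amp_sd_uv * rnorm(n)
    mu2 <- rep(eff$p2_amp_mean_uv[[key]], n)
    if (conds[j] %in% eff$gg_conditions) {
      mu2[genos == "GG"] <- mu2[genos == "GG"] +
        eff$gg_p2_boost_sd * eff$p2_amp_sd_uv
    }
    p2_amp[, j] <- mu2 + eff$p2_amp_sd_uv * rnorm(n)
  }
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), genotype = genos,
    sex = ifelse(male, "M", "F"), age = age,
    baseline_f0_hz = baseline_f0, baseline_sd_cents = baseline_sd,
    comp_latency_ms = comp_latency, artifact_rate = eff$artifact_rate,
    stringsAsFactors = FALSE)
  list(subjects = subjects, comp_gain = comp_gain, n1_amp = n1_amp,
       p2_amp = p2_amp)
}

# Smooth gamma-like response bump: 0 before the onset latency, rising to
# exactly 1 at the peak latency, decaying smoothly afterwards.
response_bump <- function(tau_s, onset_latency_s, peak_latency_s) {
  x <- (tau_s - onset_latency_s) / (peak_latency_s - onset_latency_s)
  out <- numeric(length(x))
  pos <- which(x > 0)
  out[pos] <- (x[pos] * exp(1 - x[pos]))^2
  dim(out) <- dim(tau_s)
  out
}

# Stationary AR(1) jitter: matrix n_time x n_trials in cents. Draws
# n_time * n_trials normals column-by-column (trial-by-trial order identical
# to repeated single-trial calls).
ar1_jitter <- function(n_time, n_trials, sd_cents, phi) {
  z <- matrix(rnorm(n_time * n_trials), n_time, n_trials)
  if (sd_cents == 0) return(matrix(0, n_time, n_trials))
  x <- z
  x[1L, ] <- sd_cents * z[1L, ]
  se <- sd_cents * sqrt(1 - phi^2)
  for (t in 2:n_time) x[t, ] <- phi * x[t - 1L, ] + se * z[t, ]
  x
}

#' Simulate one vocal trial
#'
#' Generates a frame-rate F0 trace for a single vocalization: the subject's
#' baseline F0, slow AR(1) jitter on the cent scale, and a smooth
#' compensatory bump that starts `onset_latency_ms` after the perturbation
#' onset, peaks at exactly the compensatory gain at the peak latency, and
#' decays afterwards. Following trials get the bump with the perturbation's
#' own sign, scaled by `following_scale`.
#'
#' @param baseline_f0_hz,baseline_sd_cents,comp_gain_cents,comp_latency_ms
#'   Subject/trial parameters.
#' @param onset_s Perturbation onset (s after vocal onset).
#' @param spec A [cohort_spec()] (timing, frame rate, effect constants).
#' @param following Logical: generate a following rather than compensatory
#'   response.
#' @return An [f0_trace()] in Hz covering the vocalization.
#' @export
simulate_vocal_trial <- function(baseline_f0_hz, baseline_sd_cents,
                                 comp_gain_cents, comp_latency_ms, onset_s,
                                 spec = cohort_spec(), following = FALSE) {
  eff <- spec$effects
  fs <- spec$vocal_fs_hz
  n_time <- round(spec$vocalization_ms / 1000 * fs)
  if (onset_s <= 0 || onset_s >= n_time / fs) stop("event onset outside trace duration")
  t_s <- (seq_len(n_time) - 1L) / fs
  jit <- ar1_jitter(n_time, 1L, baseline_sd_cents, eff$jitter_phi)[, 1L]
  gain <- if (following) -eff$following_scale * comp_gain_cents else comp_gain_cents
  bump <- gain * response_bump(t_s - onset_s, eff$onset_latency_ms / 1000,
                               comp_latency_ms / 1000)
  f0_trace(t_s, baseline_f0_hz * 2^((jit + bump) / 1200), fs_hz = fs, unit = "hz")
}

# Batch vocal generation for one subject: all trials as a matrix plus the
# event table. Draw order: magnitudes are interleaved deterministically,
# then onsets, then following flags, then the jitter matrix.
simulate_subject_vocal <- function(params_row, comp_gain_row, spec) {
  eff <- spec$effects
  fs <- spec$vocal_fs_hz
  n_time <- round(spec$vocalization_ms / 1000 * fs)
  conds <- spec$magnitudes_cents
  ntr <- spec$trials_per_condition * length(conds)
  magnitude <- rep(conds, each = spec$trials_per_condition)[
    sample.int(ntr)]
  onset <- runif(ntr, spec$perturbation_onset_range_ms[1] / 1000,
                 spec$perturbation_onset_range_ms[2] / 1000)
  following <- runif(ntr) < eff$following_fraction
  jit <- t(ar1_jitter(n_time, ntr, params_row$baseline_sd_cents, eff$jitter_phi))
  t_s <- (seq_len(n_time) - 1L) / fs
  tau <- outer(-onset, t_s, `+`)
  gain <- comp_gain_row[as.character(magnitude)]
  gain <- ifelse(following, -eff$following_scale * gain, gain)
  bump <- gain * response_bump(tau, eff$onset_latency_ms / 1000,
                               params_row$comp_latency_ms / 1000)
  f0_hz <- params_row$baseline_f0_hz * 2^((jit + bump) / 1200)
  events <- data.frame(trial_id = seq_len(ntr), onset_s = onset,
                       magnitude_cents = magnitude,
                       duration_ms = spec$perturbation_duration_ms,
                       following = following)
  list(f0_hz = f0_hz, time_s = t_s, events = events)
}

# 1/f ("pink") noise, one column per trace: white Gaussian noise spectrally
# shaped by 1/sqrt(f) and scaled to the requested RMS (in expectation).
pink_noise <- function(n_time, n_traces, fs, rms) {
  if (rms == 0) return(matrix(0, n_time, n_traces))
  w <- matrix(rnorm(n_time * n_traces), n_time, n_traces)
  k <- seq_len(n_time) - 1L
  f <- k * fs / n_time
  f <- pmin(f, fs - f)
  g <- ifelse(f > 0, 1 / sqrt(f), 0)
  g <- g * rms / sqrt(mean(g^2))
  Re(mvfft(mvfft(w) * g, inverse = TRUE)) / n_time
}

#' Simulate one EEG epoch
#'
#' One `channel x time` epoch spanning -200..500 ms: N1 and P2 raised-cosine
#' components centred at 120 and 230 ms (widths matching the 80-160 and
#' 180-280 ms measurement windows), scaled by the fronto-central topographic
#' weights, plus per-channel 1/f background noise. The baseline interval
#' carries no component energy.
#'
#' @param n1_amp_uv,p2_amp_uv Component amplitudes at the topographic maximum
#'   (FCz); N1 is negative.
#' @param spec A [cohort_spec()].
#' @param noise_rms_uv Override the background noise RMS (default from
#'   `spec$effects`).
#' @return Matrix `channel x time` (uV) with channel labels as rownames.
#' @export
simulate_eeg_epoch <- function(n1_amp_uv, p2_amp_uv, spec = cohort_spec(),
                               noise_rms_uv = spec$effects$eeg_noise_rms_uv) {
  fs <- spec$eeg_fs_hz
  ch <- spec$eeg_channels
  time_ms <- -200 + (seq_len(round(0.7 * fs)) - 1L) * 1000 / fs
  comp <- n1_amp_uv * raised_cosine(time_ms, 120, 40) +
    p2_amp_uv * raised_cosine(time_ms, 230, 50)
  wts <- component_topography(ch)
  epoch <- outer(wts, comp) +
    t(pink_noise(length(time_ms), length(ch), fs, noise_rms_uv))
  rownames(epoch) <- ch
  epoch
}

raised_cosine <- function(t, centre, halfwidth) {
  out <- numeric(length(t))
  sel <- abs(t - centre) <= halfwidth
  out[sel] <- 0.5 * (1 + cos(pi * (t[sel] - centre) / halfwidth))
  out
}

#' Inject blink-like artifacts into an epoch set
#'
#' Adds a slow half-sine deflection (default 150 uV peak over 300 ms) to the
#' far-frontal channels of the selected epochs, recording ground truth as a
#' logical `epoch x channel` matrix in the `"artifact_truth"` attribute.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param rate Per-epoch artifact probability (ignored when `epoch_idx`
#'   given).
#' @param epoch_idx Optional explicit epochs to contaminate.
#' @param channels Channel labels receiving the deflection.
#' @param amplitude_uv,duration_ms Blink shape.
#' @param onset_range_s Blink onset window relative to the epoch start.
#' @return The epoch set with artifacts added and ground truth attached.
#' @export
inject_artifacts <- function(epochs, rate = 0.15, epoch_idx = NULL,
                             channels = c("Fp1", "Fpz", "Fp2", "AF7", "AF3",
                                          "AF4", "AF8"),
                             amplitude_uv = 150, duration_ms = 300,
                             onset_range_s = c(0, 0.35)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  labs <- attr(epochs, "channels")
  time_ms <- attr(epochs, "time_ms")
  chan_idx <- match(channels, labs)
  if (anyNA(chan_idx)) stop("blink channel(s) absent from montage")
  ne <- n_epochs(epochs)
  if (is.null(epoch_idx)) {
    epoch_idx <- which(runif(ne) < rate)
  }
  truth <- matrix(FALSE, ne, length(labs))
  if (length(epoch_idx)) {
    onsets <- runif(length(epoch_idx), onset_range_s[1], onset_range_s[2])
    t0 <- time_ms[1] / 1000
    for (k in seq_along(epoch_idx)) {
      tt <- (time_ms / 1000 - t0) - onsets[k]
      blink <- ifelse(tt >= 0 & tt <= duration_ms / 1000,
                      amplitude_uv * sin(pi * tt / (duration_ms / 1000)), 0)
      for (ci in chan_idx) {
        epochs[epoch_idx[k], ci, ] <- epochs[epoch_idx[k], ci, ] + blink
      }
      truth[epoch_idx[k], chan_idx] <- TRUE
    }
  }
  attr(epochs, "artifact_truth") <- truth
  epochs
}

# Batch EEG generation for one subject and condition.
simulate_subject_eeg <- function(n1_amp, p2_amp, artifact_rate, spec,
                                 n_trials = spec$trials_per_condition) {
  fs <- spec$eeg_fs_hz
  ch <- spec$eeg_channels
  nt <- round(0.7 * fs)
  wts <- component_topography(ch)
  time_ms <- -200 + (seq_len(nt) - 1L) * 1000 / fs
  comp <- n1_amp * raised_cosine(time_ms, 120, 40) +
    p2_amp * raised_cosine(time_ms, 230, 50)
  template <- outer(wts, comp) # channel x time
  noise <- pink_noise(nt, n_trials * length(ch), fs,
                      spec$effects$eeg_noise_rms_uv)
  dat <- aperm(array(noise, dim = c(nt, length(ch), n_trials)), c(3, 2, 1))
  dat <- dat + aperm(array(template, dim = c(length(ch), nt, n_trials)),
                     c(3, 1, 2))
  ep <- eeg_epochs(dat, fs_hz = fs, channels = ch, t0_ms = -200)
  inject_artifacts(ep, rate = artifact_rate,
                   channels = spec$blink_channels,
                   amplitude_uv = spec$effects$blink_amplitude_uv,
                   duration_ms = spec$effects$blink_duration_ms)
}

#' Simulate a full cohort with ground truth
#'
#' Materialises every subject's data: per-trial F0 traces with the event
#' table, and (optionally) EEG epoch sets per condition, alongside the
#' ground-truth parameter table. Deterministic given `spec` and `seed`.
#' Intended for small-to-moderate cohorts; for full-size studies use the
#' streaming driver [run_faf_study()], which processes subjects one at a time.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param components Character subset of `c("vocal", "eeg")`.
#' @return List of class `"faf_cohort"`: `spec`, `truth` (see
#'   [draw_subject_params()]), and `subjects` — per subject a list with
#'   `vocal` (`f0_hz` matrix trials x frames, `time_s`, `events`) and `eeg`
#'   (named list of [eeg_epochs()] per condition).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            components = c("vocal", "eeg")) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  truth <- draw_subject_params(spec)
  n <- nrow(truth$subjects)
  subjects <- vector("list", n)
  names(subjects) <- truth$subjects$subject_id
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    s <- list()
    if ("vocal" %in% components) {
      s$vocal <- simulate_subject_vocal(truth$subjects[i, ],
                                        truth$comp_gain[i, ], spec)
    }
    if ("eeg" %in% components) {
      s$eeg <- lapply(seq_along(spec$magnitudes_cents), function(j) {
        simulate_subject_eeg(truth$n1_amp[i, j], truth$p2_amp[i, j],
                             truth$subjects$artifact_rate[i], spec)
      })
      names(s$eeg) <- as.character(spec$magnitudes_cents)
    }
    subjects[[i]] <- s
  }
  structure(list(spec = spec, truth = truth, subjects = subjects),
            class = "faf_cohort")
}

# Deterministic per-subject substream seed (kept below 2^31).
subject_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 7919 * i) %% 2147483647
}

#' Run the full synthetic study, streaming subject by subject
#'
#' Generates and analyses each subject in turn, retaining only the summary
#' tables: the vocal compensation summary (peak magnitude, latency, baseline
#' variability per condition), the ERP N1/P2 measurements per electrode and
#' condition, the genotype table, and per-subject QC reports. Memory use is
#' one subject at a time, so full-size cohorts are practical.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param components Subset of `c("vocal", "eeg")`.
#' @param qc [qc_params()].
#' @param windows [component_windows()].
#' @param filter Band-pass filter the EEG before QC.
#' @param reference_hz Cent-scale reference for the vocal pipeline.
#' @param collect_contours Also retain the per-subject averaged compensatory
#'   contours (long data frame in `$contours`).
#' @return List of class `"faf_study"` with `vocal`, `erp`, `genotypes`,
#'   `truth`, `qc`, `manifest` (stage counts), `contours` (when collected),
#'   `spec`, `seed`.
#' @export
run_faf_study <- function(spec = cohort_spec(), seed = 1L,
                          components = c("vocal", "eeg"),
                          qc = qc_params(), windows = component_windows(),
                          filter = TRUE, reference_hz = G3_HZ,
                          collect_contours = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  truth <- draw_subject_params(spec)
  n <- nrow(truth$subjects)
  vocal_rows <- list(); erp_rows <- list(); qc_rows <- list()
  contour_rows <- list()
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    sid <- truth$subjects$subject_id[i]
    if ("vocal" %in% components) {
      sv <- simulate_subject_vocal(truth$subjects[i, ], truth$comp_gain[i, ], spec)
      vs <- analyze_vocal_matrix(sv$f0_hz, sv$time_s, spec$vocal_fs_hz,
                                 sv$events, unit = "hz",
                                 reference_hz = reference_hz,
                                 return_contours = collect_contours)
      if (collect_contours && !is.null(attr(vs, "contours"))) {
        contour_rows[[i]] <- cbind(subject_id = sid, attr(vs, "contours"))
      }
      attr(vs, "contours") <- NULL
      vs <- cbind(subject_id = sid, vs)
      vocal_rows[[i]] <- vs
    }
    if ("eeg" %in% components) {
      per_cond <- lapply(seq_along(spec$magnitudes_cents), function(j) {
        ep <- simulate_subject_eeg(truth$n1_amp[i, j], truth$p2_amp[i, j],
                                   truth$subjects$artifact_rate[i], spec)
        res <- analyze_eeg_subject(ep, qc = qc, windows = windows,
                                   filter = filter)
        list(cond = spec$magnitudes_cents[j], res = res)
      })
      qc_rows[[i]] <- data.frame(
        subject_id = sid,
        condition_cents = vapply(per_cond, function(x) x$cond, 0),
        excluded = vapply(per_cond, function(x) x$res$excluded, FALSE),
        n_bad_channels = vapply(per_cond, function(x)
          x$res$qc_report$n_bad_channels, 0L),
        n_retained = vapply(per_cond, function(x) x$res$n_retained, 0L))
      meas <- lapply(per_cond, function(x) {
        if (is.null(x$res$measurements)) return(NULL)
        cbind(subject_id = sid, condition_cents = x$cond, x$res$measurements)
      })
      erp_rows[[i]] <- do.call(rbind, meas)
    }
  }
  vocal <- if (length(vocal_rows)) do.call(rbind, vocal_rows) else NULL
  erp <- if (length(erp_rows)) do.call(rbind, erp_rows) else NULL
  qc_tab <- if (length(qc_rows)) do.call(rbind, qc_rows) else NULL
  genotypes <- truth$subjects[, c("subject_id", "genotype", "sex", "age")]
  excluded_ids <- if (!is.null(qc_tab)) {
    unique(qc_tab$subject_id[qc_tab$excluded])
  } else character(0)
  manifest <- list(
    n_subjects = n,
    n_subjects_erp_excluded = length(excluded_ids),
    n_subjects_entering_stats = n - length(excluded_ids),
    vocal_trials_total = if (!is.null(vocal)) sum(vocal$n_trials) else 0L,
    vocal_trials_compensatory = if (!is.null(vocal)) sum(vocal$n_compensatory) else 0L,
    eeg_epochs_total = if (!is.null(qc_tab))
      sum(!qc_tab$excluded) * spec$trials_per_condition +
      sum(qc_tab$excluded) * spec$trials_per_condition else 0L,
    eeg_epochs_retained = if (!is.null(qc_tab)) sum(qc_tab$n_retained) else 0L)
  contours <- if (length(contour_rows)) do.call(rbind, contour_rows) else NULL
  structure(list(vocal = vocal, erp = erp, genotypes = genotypes,
                 truth = truth, qc = qc_tab, manifest = manifest,
                 contours = contours, spec = spec, seed = seed),
            class = "faf_study")
}
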