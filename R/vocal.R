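#' Segment an F0 trace into perturbation-locked epochs
#'
#' Cuts a cents-scale F0 contour into epochs spanning `[-baseline_ms,
#' post_ms)` ms relative to each perturbation onset. Time 0 is assigned to the
#' first frame at or after the event onset; frames are `1/fs` apart, so at the
#' default 100 Hz frame rate an epoch holds 90 samples of which the first 20
#' form the baseline. Events too close to the trace edges yield epochs marked
#' `"bad"` with an explanatory reason instead of an error.
#'
#' @param trace An [f0_trace()] in cents (convert with [trace_to_cents()]).
#' @param events Data frame with columns `trial_id`, `onset_s`,
#'   `magnitude_cents` and `duration_ms` (one row per perturbation).
#' @param baseline_ms,post_ms Epoch extent before/after the onset (ms).
#' @return A list of class `"vocal_epochs"`; each element is a
#'   `"vocal_epoch"` list with fields `trial_id`, `time_ms`, `values` (cents),
#'   `magnitude_cents`, `baseline_mean_cents` (filled by
#'   [baseline_normalize()]), `normalized`, `label` and `reason`.
#' @export
segment_vocal_trials <- function(trace, events, baseline_ms = 200, post_ms = 700) {
  stopifnot(inherits(trace, "f0_trace"))
  if (attr(trace, "unit") != "cents") {
    stop("`trace` must be in cents; use trace_to_cents() first")
  }
  req <- c("trial_id", "onset_s", "magnitude_cents")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("`events` is missing column(s): ", paste(miss, collapse = ", "))
  fs <- attr(trace, "fs_hz")
  nb <- round(baseline_ms / 1000 * fs)
  np <- round(post_ms / 1000 * fs)
  rel_ms <- (seq_len(nb + np) - nb - 1L) * 1000 / fs
  n <- nrow(trace)
  epochs <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    onset_idx <- match(TRUE, trace$time_s >= events$onset_s[i] - 1e-9)
    ep <- list(trial_id = events$trial_id[i], time_ms = rel_ms, values = NULL,
               magnitude_cents = events$magnitude_cents[i],
               baseline_mean_cents = NA_real_, normalized = FALSE,
               label = NA_character_, reason = NA_character_)
    if (is.na(onset_idx) || onset_idx + np - 1L > n) {
      ep$label <- "bad"; ep$reason <- "insufficient post-perturbation trace"
    } else if (onset_idx - nb < 1L) {
      ep$label <- "bad"; ep$reason <- "insufficient baseline"
    } else {
      ep$values <- trace$f0[(onset_idx - nb):(onset_idx + np - 1L)]
    }
    class(ep) <- "vocal_epoch"
    epochs[[i]] <- ep
  }
  structure(epochs, class = "vocal_epochs", fs_hz = fs, baseline_ms = baseline_ms)
}

#' Baseline-normalize a vocal epoch
#'
#' Subtracts the mean F0 over the pre-perturbation baseline (`time < 0`) from
#' the whole epoch and stores that mean in `baseline_mean_cents`.
#'
#' @param epoch A `"vocal_epoch"` from [segment_vocal_trials()].
#' @return The epoch with `values` centred on its baseline and
#'   `normalized = TRUE`.
#' @export
baseline_normalize <- function(epoch) {
  stopifnot(inherits(epoch, "vocal_epoch"))
  if (is.null(epoch$values)) stop("cannot normalize a bad epoch with no samples")
  base <- epoch$values[epoch$time_ms < 0]
  if (!length(base) || all(is.na(base))) stop("empty baseline interval")
  epoch$baseline_mean_cents <- mean(base, na.rm = TRUE)
  epoch$values <- epoch$values - epoch$baseline_mean_cents
  epoch$normalized <- TRUE
  epoch
}

#' Classify a vocal epoch as compensatory, following, or bad
#'
#' A trial opposes the perturbation ("compensatory") when the mean of its
#' baseline-normalized contour over the response window has the sign opposite
#' to the perturbation; a trial moving with the perturbation is "following".
#' Trials with too many missing frames or implausibly large excursions
#' (vocal interruptions, tracking errors) are "bad".
#'
#' @param epoch A normalized `"vocal_epoch"`.
#' @param window_ms Response window (ms, half-open) over which the mean
#'   direction is taken.
#' @param max_missing Maximum tolerated fraction of missing frames.
#' @param outlier_cents Absolute normalized excursion beyond which the trial
#'   is discarded as contaminated.
#' @return The epoch with `label` set to `"compensatory"`, `"following"` or
#'   `"bad"` (and `reason` for bad trials).
#' @export
classify_trial <- function(epoch, window_ms = c(100, 500), max_missing = 0.2,
                           outlier_cents = 600) {
  stopifnot(inherits(epoch, "vocal_epoch"))
  if (identical(epoch$label, "bad")) return(epoch)
  if (!isTRUE(epoch$normalized)) stop("classify_trial() requires a baseline-normalized epoch")
  vals <- epoch$values
  if (mean(is.na(vals)) > max_missing) {
    epoch$label <- "bad"; epoch$reason <- "missing frames above tolerance"
    return(epoch)
  }
  if (any(abs(vals) > outlier_cents, na.rm = TRUE)) {
    epoch$label <- "bad"; epoch$reason <- "excursion beyond outlier bound"
    return(epoch)
  }
  sel <- epoch$time_ms >= window_ms[1] & epoch$time_ms < window_ms[2]
  m <- mean(vals[sel], na.rm = TRUE)
  # perturbations are downward (negative); opposing means positive drift
  opposing <- m * sign(epoch$magnitude_cents) < 0
  epoch$label <- if (isTRUE(opposing)) "compensatory" else "following"
  epoch
}

#' Average compensatory vocal epochs into an overall response
#'
#' Pointwise mean of the baseline-normalized contours of the compensatory
#' trials, the estimate of a participant's overall compensatory response for
#' one condition.
#'
#' @param epochs A `"vocal_epochs"` list whose elements have been normalized
#'   and classified.
#' @return A list of class `"averaged_vocal_response"`: `time_ms`, `contour`
#'   (cents), `n_trials`, and `no_response` (`TRUE` when no compensatory
#'   trial was available; the contour is then all-`NA`).
#' @export
average_vocal_response <- function(epochs) {
  comp <- Filter(function(e) identical(e$label, "compensatory"), epochs)
  if (!length(comp)) {
    first <- epochs[[1]]
    return(structure(list(time_ms = first$time_ms,
                          contour = rep(NA_real_, length(first$time_ms)),
                          n_trials = 0L, no_response = TRUE),
                     class = "averaged_vocal_response"))
  }
  mat <- do.call(rbind, lapply(comp, `[[`, "values"))
  structure(list(time_ms = comp[[1]]$time_ms,
                 contour = colMeans(mat, na.rm = TRUE),
                 n_trials = length(comp), no_response = FALSE),
            class = "averaged_vocal_response")
}

#' Measure the peak of an averaged vocal response
#'
#' The response magnitude is the greatest F0 value of the averaged contour
#' within the search window, and the latency is the time of that maximum.
#' Ties resolve to the earliest sample; a maximum on the window edge is
#' flagged, since it may indicate a response still rising at the epoch end.
#'
#' @param avg An `"averaged_vocal_response"`.
#' @param search_window_ms Window (ms, half-open on the right) searched for
#'   the maximum; defaults to the full post-perturbation extent.
#' @return List with `magnitude_cents`, `latency_ms` and `edge_peak`.
#' @export
measure_vocal_peak <- function(avg, search_window_ms = c(0, 700)) {
  stopifnot(inherits(avg, "averaged_vocal_response"))
  sel <- which(avg$time_ms >= search_window_ms[1] & avg$time_ms < search_window_ms[2])
  if (!length(sel)) stop("empty peak search window")
  y <- avg$contour[sel]
  if (all(is.na(y))) stop("averaged contour has no data in the search window")
  i <- which.max(y) # first index on ties
  list(magnitude_cents = y[i],
       latency_ms = avg$time_ms[sel][i],
       edge_peak = i == 1L || i == length(sel))
}

#' Baseline F0 variability across trials
#'
#' The standard deviation (n-1 denominator) across trials of the per-trial
#' baseline mean F0, an index of the natural variability of the speaker's
#' voice in the absence of feedback perturbations.
#'
#' @param epochs A `"vocal_epochs"` list (normalized, classified); only
#'   compensatory trials — those entering the averaged response — are used.
#' @param use Which trials enter: `"compensatory"` (default) or `"retained"`
#'   (everything not bad).
#' @return The SD in cents, or `NA` with a warning when fewer than two trials
#'   are available.
#' @export
baseline_variability <- function(epochs, use = c("compensatory", "retained")) {
  use <- match.arg(use)
  keep <- vapply(epochs, function(e) {
    if (use == "compensatory") identical(e$label, "compensatory")
    else !identical(e$label, "bad")
  }, logical(1))
  means <- vapply(epochs[keep], `[[`, 0, "baseline_mean_cents")
  if (length(means) < 2L) {
    warning("fewer than 2 retained trials; baseline variability is NA")
    return(NA_real_)
  }
  sd(means)
}

#' Per-subject vocal response summary
#'
#' Runs the full vocal measurement chain — segmentation, baseline
#' normalization, direction classification, averaging, peak measurement, and
#' baseline variability — separately for each perturbation magnitude present
#' in `events`.
#'
#' @param trace An [f0_trace()] in Hz or cents.
#' @param events Perturbation event table (see [segment_vocal_trials()]).
#' @param reference_hz Cent-scale reference used when `trace` is in Hz.
#' @param window_ms,max_missing,outlier_cents Passed to [classify_trial()].
#' @param search_window_ms Passed to [measure_vocal_peak()].
#' @return Data frame with one row per condition: `condition_cents`,
#'   `n_trials`, `n_compensatory`, `n_bad`, `peak_magnitude_cents`,
#'   `peak_latency_ms`, `baseline_sd_cents`, `edge_peak`, `no_response`.
#' @export
vocal_subject_summary <- function(trace, events, reference_hz = G3_HZ,
                                  window_ms = c(100, 500), max_missing = 0.2,
                                  outlier_cents = 600,
                                  search_window_ms = c(0, 700)) {
  trace <- trace_to_cents(trace, reference_hz)
  conditions <- sort(unique(events$magnitude_cents), decreasing = TRUE)
  rows <- lapply(conditions, function(cond) {
    ev <- events[events$magnitude_cents == cond, , drop = FALSE]
    eps <- segment_vocal_trials(trace, ev)
    eps[] <- lapply(eps, function(e) {
      if (identical(e$label, "bad")) return(e)
      classify_trial(baseline_normalize(e), window_ms = window_ms,
                     max_missing = max_missing, outlier_cents = outlier_cents)
    })
    avg <- average_vocal_response(eps)
    if (avg$no_response) {
      pk <- list(magnitude_cents = NA_real_, latency_ms = NA_real_, edge_peak = NA)
      bsd <- NA_real_
    } else {
      pk <- measure_vocal_peak(avg, search_window_ms)
      bsd <- suppressWarnings(baseline_variability(eps))
    }
    labels <- vapply(eps, `[[`, "", "label")
    data.frame(condition_cents = cond, n_trials = length(eps),
               n_compensatory = sum(labels == "compensatory"),
               n_bad = sum(labels == "bad"),
               peak_magnitude_cents = pk$magnitude_cents,
               peak_latency_ms = pk$latency_ms,
               baseline_sd_cents = bsd,
               edge_peak = isTRUE(pk$edge_peak),
               no_response = avg$no_response)
  })
  do.call(rbind, rows)
}

# Vectorised equivalent of vocal_subject_summary() for a subject whose trials
# are stored as a matrix (one trial per row, one frame per column, values in
# cents or Hz). Used by the cohort drivers; numerically identical to the
# per-trial path (see tests).
analyze_vocal_matrix <- function(f0_mat, time_s, fs, events, unit = "hz",
                                 reference_hz = G3_HZ,
                                 baseline_ms = 200, post_ms = 700,
                                 window_ms = c(100, 500), max_missing = 0.2,
                                 outlier_cents = 600,
                                 search_window_ms = c(0, 700),
                                 return_contours = FALSE) {
  if (unit == "hz") f0_mat <- hz_to_cents(f0_mat, reference_hz)
  nb <- round(baseline_ms / 1000 * fs)
  np <- round(post_ms / 1000 * fs)
  rel_ms <- (seq_len(nb + np) - nb - 1L) * 1000 / fs
  ntr <- nrow(f0_mat)
  onset_idx <- findInterval(events$onset_s - 1e-9, time_s) + 1L
  bad_edge <- onset_idx - nb < 1L | onset_idx + np - 1L > ncol(f0_mat)
  if (any(bad_edge)) stop("event(s) too close to trace edge in matrix path")
  cols <- rep(onset_idx, each = nb + np) + rep(seq_len(nb + np) - nb - 1L, times = ntr)
  epochs <- matrix(f0_mat[cbind(rep(seq_len(ntr), each = nb + np), cols)],
                   nrow = ntr, ncol = nb + np, byrow = TRUE)
  base_mean <- rowMeans(epochs[, seq_len(nb), drop = FALSE], na.rm = TRUE)
  epochs <- epochs - base_mean
  wsel <- rel_ms >= window_ms[1] & rel_ms < window_ms[2]
  wmean <- rowMeans(epochs[, wsel, drop = FALSE], na.rm = TRUE)
  missing_frac <- rowMeans(is.na(epochs))
  outlier <- apply(abs(epochs), 1L, max, na.rm = TRUE) > outlier_cents
  bad <- missing_frac > max_missing | outlier
  comp <- !bad & (wmean * sign(events$magnitude_cents) < 0)
  psel <- which(rel_ms >= search_window_ms[1] & rel_ms < search_window_ms[2])
  conditions <- sort(unique(events$magnitude_cents), decreasing = TRUE)
  contours <- list()
  rows <- lapply(conditions, function(cond) {
    in_cond <- events$magnitude_cents == cond
    idx <- which(in_cond & comp)
    if (!length(idx)) {
      return(data.frame(condition_cents = cond, n_trials = sum(in_cond),
                        n_compensatory = 0L, n_bad = sum(in_cond & bad),
                        peak_magnitude_cents = NA_real_, peak_latency_ms = NA_real_,
                        baseline_sd_cents = NA_real_, edge_peak = NA,
                        no_response = TRUE))
    }
    contour <- colMeans(epochs[idx, , drop = FALSE], na.rm = TRUE)
    if (return_contours) {
      contours[[as.character(cond)]] <<- data.frame(
        condition_cents = cond, time_ms = rel_ms, mean_cents = contour,
        n_trials = length(idx))
    }
    y <- contour[psel]
    i <- which.max(y)
    bsd <- if (length(idx) >= 2L) sd(base_mean[idx]) else NA_real_
    data.frame(condition_cents = cond, n_trials = sum(in_cond),
               n_compensatory = length(idx), n_bad = sum(in_cond & bad),
               peak_magnitude_cents = y[i], peak_latency_ms = rel_ms[psel][i],
               baseline_sd_cents = bsd,
               edge_peak = i == 1L || i == length(psel), no_response = FALSE)
  })
  out <- do.call(rbind, rows)
  if (return_contours) attr(out, "contours") <- do.call(rbind, contours)
  out
}
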