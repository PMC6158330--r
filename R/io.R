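read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  d
}

write_delim <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write F0 traces, event tables and genotype tables
#'
#' Tab-delimited text with a header row. F0 traces need columns `time_s` and
#' `f0_hz` (`NA` for unvoiced frames); event tables need `trial_id`,
#' `onset_s`, `magnitude_cents`, `duration_ms`; genotype tables need
#' `subject_id`, `genotype` (AA/AG/GG), `sex`, `age`. Malformed files raise
#' validation errors naming the missing column.
#'
#' @param path File path.
#' @param trace,events,genotypes Objects to write.
#' @param fs_hz Frame rate stored on the returned [f0_trace()] (inferred from
#'   the median time step when `NULL`).
#' @return Readers return the typed object; writers return the path,
#'   invisibly.
#' @name faf_io
NULL

#' @rdname faf_io
#' @export
read_f0_trace <- function(path, fs_hz = NULL) {
  d <- read_delim_checked(path, c("time_s", "f0_hz"), "F0 trace")
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(d$time_s))
  f0_trace(d$time_s, d$f0_hz, fs_hz = fs_hz, unit = "hz")
}

#' @rdname faf_io
#' @export
write_f0_trace <- function(trace, path) {
  stopifnot(inherits(trace, "f0_trace"))
  stopifnot(attr(trace, "unit") == "hz")
  write_delim(data.frame(time_s = trace$time_s, f0_hz = trace$f0), path)
}

#' @rdname faf_io
#' @export
read_events <- function(path) {
  read_delim_checked(path, c("trial_id", "onset_s", "magnitude_cents",
                             "duration_ms"), "events")
}

#' @rdname faf_io
#' @export
write_events <- function(events, path) write_delim(events, path)

#' @rdname faf_io
#' @export
read_genotypes <- function(path) {
  d <- read_delim_checked(path, c("subject_id", "genotype", "sex", "age"),
                          "genotype")
  bad <- setdiff(unique(d$genotype), c("AA", "AG", "GG"))
  if (length(bad)) stop("invalid genotype value(s): ", paste(bad, collapse = ", "))
  d
}

#' @rdname faf_io
#' @export
write_genotypes <- function(genotypes, path) write_delim(genotypes, path)

#' Write and read EEG epoch sets in the binary fixture format
#'
#' Voltages are stored as little-endian float32 in epoch-major,
#' channel-then-time order in `<stem>.f32`, with a JSON sidecar
#' `<stem>.json` carrying `fs_hz`, `channels`, `t0_ms`, dimensions and the
#' reference state. Values survive the round trip to float32 precision
#' (about 7 significant digits).
#'
#' @param epochs An [eeg_epochs()] object.
#' @param stem Path without extension.
#' @return `write_eeg_epochs()` returns `stem` invisibly;
#'   `read_eeg_epochs()` returns the [eeg_epochs()] object.
#' @export
write_eeg_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs)
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(unclass(epochs), c(3, 2, 1))), con, size = 4L,
           endian = "little")
  meta <- list(fs_hz = attr(epochs, "fs_hz"),
               channels = attr(epochs, "channels"),
               t0_ms = attr(epochs, "time_ms")[1],
               n_epochs = d[1], n_channels = d[2], n_samples = d[3],
               reference = attr(epochs, "reference"),
               byte_order = "little", dtype = "float32")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_eeg_epochs
#' @export
read_eeg_epochs <- function(stem) {
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path)) stop("sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("fs_hz", "channels", "t0_ms", "n_epochs", "n_channels",
            "n_samples")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sidecar missing field(s): ", paste(miss, collapse = ", "))
  n <- meta$n_epochs * meta$n_channels * meta$n_samples
  con <- file(paste0(stem, ".f32"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  if (length(vals) != n) stop("fixture truncated: ", stem, ".f32")
  dat <- aperm(array(vals, dim = c(meta$n_samples, meta$n_channels,
                                   meta$n_epochs)), c(3, 2, 1))
  eeg_epochs(dat, fs_hz = meta$fs_hz, channels = meta$channels,
             t0_ms = meta$t0_ms,
             reference = meta$reference %||% "vertex")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read a simulated cohort as a directory of fixtures
#'
#' Per-subject subdirectories hold the F0 trials (long tab-delimited text),
#' the event table, and EEG epoch fixtures per condition; the cohort root
#' holds the genotype table and the ground-truth parameter table.
#'
#' @param cohort A `"faf_cohort"` from [simulate_cohort()].
#' @param dir Output directory (created).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a list with `subjects` (vocal matrices + events + EEG epoch sets),
#'   `genotypes` and `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "faf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- cohort$truth
  write_genotypes(tr$subjects[, c("subject_id", "genotype", "sex", "age")],
                  file.path(dir, "genotypes.tsv"))
  truth_flat <- cbind(tr$subjects,
                      stats::setNames(as.data.frame(tr$comp_gain),
                                      paste0("comp_gain_", colnames(tr$comp_gain))),
                      stats::setNames(as.data.frame(tr$n1_amp),
                                      paste0("n1_amp_", colnames(tr$n1_amp))),
                      stats::setNames(as.data.frame(tr$p2_amp),
                                      paste0("p2_amp_", colnames(tr$p2_amp))))
  write_delim(truth_flat, file.path(dir, "ground_truth.tsv"))
  for (sid in names(cohort$subjects)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    s <- cohort$subjects[[sid]]
    if (!is.null(s$vocal)) {
      ntr <- nrow(s$vocal$f0_hz)
      long <- data.frame(
        trial_id = rep(seq_len(ntr), each = length(s$vocal$time_s)),
        time_s = rep(s$vocal$time_s, times = ntr),
        f0_hz = as.vector(t(s$vocal$f0_hz)))
      write_delim(long, file.path(sdir, "f0_trials.tsv"))
      write_events(s$vocal$events, file.path(sdir, "events.tsv"))
    }
    if (!is.null(s$eeg)) {
      for (cond in names(s$eeg)) {
        write_eeg_epochs(s$eeg[[cond]],
                         file.path(sdir, paste0("eeg_", cond)))
      }
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  genotypes <- read_genotypes(file.path(dir, "genotypes.tsv"))
  truth <- read.table(file.path(dir, "ground_truth.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  subjects <- list()
  for (sid in genotypes$subject_id) {
    sdir <- file.path(dir, sid)
    s <- list()
    f0p <- file.path(sdir, "f0_trials.tsv")
    if (file.exists(f0p)) {
      long <- read_delim_checked(f0p, c("trial_id", "time_s", "f0_hz"),
                                 "F0 trials")
      ids <- unique(long$trial_id)
      time_s <- long$time_s[long$trial_id == ids[1]]
      s$vocal <- list(
        f0_hz = matrix(long$f0_hz, nrow = length(ids), byrow = TRUE),
        time_s = time_s,
        events = read_events(file.path(sdir, "events.tsv")))
    }
    stems <- sub("\\.json$", "",
                 list.files(sdir, pattern = "^eeg_.*\\.json$", full.names = TRUE))
    if (length(stems)) {
      s$eeg <- lapply(stems, read_eeg_epochs)
      names(s$eeg) <- sub("^eeg_", "", basename(stems))
    }
    subjects[[sid]] <- s
  }
  list(subjects = subjects, genotypes = genotypes, truth = truth)
}

#' Default run configuration
#'
#' A nested configuration mirroring the pipeline stages; every default is the
#' study value (perturbation design, cents reference, QC thresholds,
#' component windows, classification windows, filter band). Round-trips
#' losslessly through YAML.
#'
#' @param seed Integer seed.
#' @param components Pipeline components to run.
#' @return Nested list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, components = c("vocal", "eeg")) {
  structure(list(
    seed = seed,
    components = components,
    cohort = list(n_per_genotype = c(AA = 49, AG = 63, GG = 21),
                  trials_per_condition = 100,
                  magnitudes_cents = c(-50, -200)),
    vocal = list(reference_hz = G3_HZ, classify_window_ms = c(100, 500),
                 peak_window_ms = c(0, 700), max_missing = 0.2,
                 outlier_cents = 600),
    eeg = list(filter = TRUE, low_hz = 1, high_hz = 20,
               artifact_threshold_uv = 55, moving_window_ms = 80,
               max_bad_epoch_fraction = 0.20, max_bad_channels = 10,
               artifact_rule = "combined", moving_average_align = "centered"),
    stats = list(alpha = 0.05)), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(raw)) {
    if (is.list(raw[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- unlist_preserve(raw[[nm]][[k]])
    } else {
      cfg[[nm]] <- unlist_preserve(raw[[nm]])
    }
  }
  cfg
}

#' @rdname run_config
#' @param config A `"run_config"` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

unlist_preserve <- function(x) if (is.list(x)) unlist(x) else x

#' Run the complete pipeline and write all result tables
#'
#' Simulate (streamed) -> vocal measurement -> ERP measurement with QC ->
#' statistics, writing the vocal summary, ERP measurements, genotype table,
#' ANOVA and correlation tables, and a JSON run manifest whose stage counts
#' reconcile (input = retained + excluded at every stage). Deterministic for
#' a given configuration and seed.
#'
#' @param config A `"run_config"` (or path to a YAML file).
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(
    n_per_genotype = config$cohort$n_per_genotype,
    trials_per_condition = config$cohort$trials_per_condition,
    magnitudes_cents = config$cohort$magnitudes_cents)
  qc <- qc_params(config$eeg$artifact_threshold_uv,
                  config$eeg$moving_window_ms,
                  config$eeg$max_bad_epoch_fraction,
                  config$eeg$max_bad_channels)
  study <- run_faf_study(spec, seed = config$seed,
                         components = config$components, qc = qc,
                         filter = config$eeg$filter,
                         reference_hz = config$vocal$reference_hz,
                         collect_contours = TRUE)
  if (!is.null(study$vocal)) write_delim(study$vocal, file.path(out_dir, "vocal_summary.tsv"))
  if (!is.null(study$contours)) {
    write_delim(study$contours, file.path(out_dir, "vocal_contours.tsv"))
  }
  if (!is.null(study$erp)) write_delim(study$erp, file.path(out_dir, "erp_measurements.tsv"))
  write_genotypes(study$genotypes, file.path(out_dir, "genotypes.tsv"))
  if (!is.null(study$qc)) write_delim(study$qc, file.path(out_dir, "eeg_qc.tsv"))
  report <- replicate_paper_analyses(study$vocal, study$erp, study$genotypes,
                                     alpha = config$stats$alpha)
  if (!is.null(report$vocal)) {
    write_delim(report$vocal$magnitude_anova,
                file.path(out_dir, "vocal_magnitude_anova.tsv"))
    write_delim(report$vocal$latency_anova,
                file.path(out_dir, "vocal_latency_anova.tsv"))
    write_delim(report$vocal$correlations,
                file.path(out_dir, "vocal_correlations.tsv"))
  }
  if (!is.null(report$erp)) {
    for (meas in c("n1_amp_uv", "n1_lat_ms", "p2_amp_uv", "p2_lat_ms")) {
      write_delim(report$erp[[paste0(meas, "_anova")]],
                  file.path(out_dir, paste0(meas, "_anova.tsv")))
    }
  }
  manifest <- c(study$manifest,
                list(seed = config$seed,
                     components = config$components,
                     hwe = report$hwe[c("chi2", "p")],
                     package_version = as.character(utils::packageVersion("fafpipe")),
                     outputs = list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
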