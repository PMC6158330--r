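#' Run the full statistical battery on study outputs
#'
#' Reproduces the analysis structure of a FAF genotype-association study:
#'
#' * Hardy-Weinberg equilibrium chi-square on the genotype counts.
#' * Two-way mixed RM-ANOVAs (stimulus magnitude within, genotype between)
#'   on vocal compensation magnitudes and latencies, with follow-up one-way
#'   genotype ANOVAs per condition and Bonferroni post hocs when the
#'   magnitude-by-genotype interaction (or a genotype main effect) reaches
#'   the criterion.
#' * Three-way mixed RM-ANOVAs (magnitude and electrode within, genotype
#'   between) on N1/P2 amplitudes and latencies, with per-condition
#'   follow-ups and Bonferroni post hocs for P2 when warranted.
#' * Per-genotype Pearson correlations between compensation magnitude and
#'   baseline F0 variability, pooling subject-by-condition points.
#'
#' @param vocal Vocal summary table (one row per subject and condition; see
#'   [run_faf_study()]), or `NULL` to skip vocal analyses.
#' @param erp ERP measurement table (one row per subject, condition and
#'   electrode), or `NULL` to skip ERP analyses.
#' @param genotypes Data frame with `subject_id` and `genotype`.
#' @param genotype_counts Optional length-3 counts (AA, AG, GG) for the HWE
#'   test — e.g. the pre-exclusion sample; defaults to counts in
#'   `genotypes`.
#' @param alpha Significance criterion for follow-ups.
#' @return List of class `"faf_report"`: `hwe`, `vocal` (ANOVA tables,
#'   follow-ups, post hocs, correlations), `erp` (per-measure ANOVA tables
#'   and P2 follow-ups), `alpha`.
#' @export
replicate_paper_analyses <- function(vocal = NULL, erp = NULL, genotypes,
                                     genotype_counts = NULL, alpha = 0.05) {
  if (missing(genotypes) || is.null(genotypes)) {
    stop("missing input: `genotypes` (stage: genotype table)")
  }
  need <- c("subject_id", "genotype")
  miss <- setdiff(need, names(genotypes))
  if (length(miss)) stop("`genotypes` missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(genotype_counts)) {
    genotype_counts <- c(sum(genotypes$genotype == "AA"),
                         sum(genotypes$genotype == "AG"),
                         sum(genotypes$genotype == "GG"))
  }
  report <- list(hwe = hwe_chisq(genotype_counts[1], genotype_counts[2],
                                 genotype_counts[3]),
                 alpha = alpha)
  if (!is.null(vocal)) {
    report$vocal <- analyze_vocal_stats(vocal, genotypes, alpha)
  }
  if (!is.null(erp)) {
    report$erp <- analyze_erp_stats(erp, genotypes, alpha)
  }
  class(report) <- "faf_report"
  report
}

analyze_vocal_stats <- function(vocal, genotypes, alpha) {
  need <- c("subject_id", "condition_cents", "peak_magnitude_cents",
            "peak_latency_ms", "baseline_sd_cents")
  miss <- setdiff(need, names(vocal))
  if (length(miss)) stop("vocal summary missing column(s): ", paste(miss, collapse = ", "))
  d <- merge(vocal, genotypes[, c("subject_id", "genotype")], by = "subject_id")
  d <- d[complete.cases(d[, c("peak_magnitude_cents", "peak_latency_ms")]), ]
  d$condition <- factor(d$condition_cents)
  # subjects must contribute every condition to the split-plot design
  keep <- names(which(table(d$subject_id) == nlevels(d$condition)))
  d <- d[d$subject_id %in% keep, ]
  out <- list()
  out$magnitude_anova <- mixed_rm_anova(d, "peak_magnitude_cents",
                                        "subject_id", within = "condition",
                                        between = "genotype")
  out$latency_anova <- mixed_rm_anova(d, "peak_latency_ms", "subject_id",
                                      within = "condition",
                                      between = "genotype")
  inter <- out$magnitude_anova
  inter_p <- inter$p_gg[inter$effect == "condition:genotype"]
  out$magnitude_followup <- list()
  if (length(inter_p) && inter_p < alpha) {
    for (cond in levels(d$condition)) {
      dc <- d[d$condition == cond, ]
      fu <- oneway_anova(dc$peak_magnitude_cents, dc$genotype)
      entry <- list(anova = fu)
      if (fu$p[1] < alpha) {
        entry$posthoc <- bonferroni_pairwise(dc$peak_magnitude_cents,
                                             dc$genotype,
                                             error_ms = fu$ss_error / fu$df2,
                                             error_df = fu$df2, alpha = alpha)
      }
      out$magnitude_followup[[cond]] <- entry
    }
  }
  # correlations pool subject-by-condition points within genotype
  out$correlations <- do.call(rbind, lapply(c("AA", "AG", "GG"), function(g) {
    dg <- d[d$genotype == g & is.finite(d$baseline_sd_cents), ]
    if (nrow(dg) < 3L) {
      return(data.frame(genotype = g, r = NA_real_, n = nrow(dg), p = NA_real_))
    }
    ct <- pearson_correlation(dg$baseline_sd_cents, dg$peak_magnitude_cents)
    data.frame(genotype = g, r = ct$r, n = ct$n, p = ct$p)
  }))
  out
}

analyze_erp_stats <- function(erp, genotypes, alpha) {
  need <- c("subject_id", "condition_cents", "electrode", "n1_amp_uv",
            "n1_lat_ms", "p2_amp_uv", "p2_lat_ms")
  miss <- setdiff(need, names(erp))
  if (length(miss)) stop("ERP table missing column(s): ", paste(miss, collapse = ", "))
  d <- merge(erp, genotypes[, c("subject_id", "genotype")], by = "subject_id")
  d$condition <- factor(d$condition_cents)
  d$electrode <- factor(d$electrode)
  # retain only subjects with the complete crossing (both conditions survive QC)
  full <- nlevels(d$condition) * nlevels(d$electrode)
  keep <- names(which(table(d$subject_id) == full))
  d <- d[d$subject_id %in% keep, ]
  out <- list(n_subjects = length(keep))
  for (meas in c("n1_amp_uv", "n1_lat_ms", "p2_amp_uv", "p2_lat_ms")) {
    out[[paste0(meas, "_anova")]] <-
      mixed_rm_anova(d, meas, "subject_id",
                     within = c("condition", "electrode"),
                     between = "genotype")
  }
  # P2 amplitude follow-ups per condition when magnitude x genotype interacts
  p2 <- out$p2_amp_uv_anova
  ip <- p2$p_gg[p2$effect == "condition:genotype"]
  out$p2_amp_followup <- list()
  if (length(ip) && ip < alpha) {
    for (cond in levels(d$condition)) {
      dc <- d[d$condition == cond, ]
      fu <- mixed_rm_anova(dc, "p2_amp_uv", "subject_id",
                           within = "electrode", between = "genotype")
      entry <- list(anova = fu)
      gp <- fu$p_gg[fu$effect == "genotype"]
      if (length(gp) && gp < alpha) {
        subj_mean <- aggregate(p2_amp_uv ~ subject_id + genotype, dc, mean)
        gg <- fu[fu$effect == "genotype", ]
        entry$posthoc <- bonferroni_pairwise(
          subj_mean$p2_amp_uv, subj_mean$genotype,
          error_ms = gg$ss_error / gg$df2 / nlevels(dc$electrode),
          error_df = gg$df2, alpha = alpha)
      }
      out$p2_amp_followup[[cond]] <- entry
    }
  }
  out
}

#' @export
print.faf_report <- function(x, ...) {
  cat("FAF study statistical report\n")
  cat(sprintf("  HWE: chi2 = %.3f, df = 1, p = %.3f\n", x$hwe$chi2, x$hwe$p))
  if (!is.null(x$vocal)) {
    cat("\nVocal compensation magnitude (condition x genotype):\n")
    print(x$vocal$magnitude_anova)
    cat("\nCompensation-variability correlations (per genotype):\n")
    print(x$vocal$correlations, row.names = FALSE)
  }
  if (!is.null(x$erp)) {
    cat(sprintf("\nERP analyses on %d subjects with complete data\n",
                x$erp$n_subjects))
    cat("\nP2 amplitude (condition x electrode x genotype):\n")
    print(x$erp$p2_amp_uv_anova)
  }
  invisible(x)
}
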