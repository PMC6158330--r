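#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the allele frequency from the genotype counts,
#' `p = (2 n_AA + n_AG) / (2n)`, forms the expected counts
#' `(n p^2, 2 n p (1 - p), n (1 - p)^2)`, and computes the Pearson chi-square
#' with 1 degree of freedom (biallelic locus, one estimated allele
#' frequency).
#'
#' @param n_AA,n_AG,n_GG Non-negative genotype counts. Alternatively pass a
#'   length-3 named or ordered vector as `n_AA`.
#' @return List with `chi2`, `df` (= 1), `p`, `allele_freq`, `expected`.
#' @examples
#' hwe_chisq(55, 71, 24) # chi2 ~ 0.018, p ~ 0.89
#' @export
hwe_chisq <- function(n_AA, n_AG = NULL, n_GG = NULL) {
  if (is.null(n_AG)) {
    stopifnot(length(n_AA) == 3L)
    counts <- as.numeric(n_AA)
  } else {
    counts <- c(n_AA, n_AG, n_GG)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1L, lower.tail = FALSE),
       allele_freq = p, expected = expected)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on an r x c contingency table, without continuity
#' correction, `df = (r - 1)(c - 1)`.
#'
#' @param tab Matrix (or table) of non-negative counts.
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
contingency_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("table total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column marginal")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), expected = res$expected)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors, `n >= 3`, finite values.
#' @return List of class `"correlation_result"` with `r`, `n`, `df`
#'   (`n - 2`), `p` (two-sided), and `degenerate` (`TRUE` with `r = NA` when
#'   either input has zero variance).
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(structure(list(r = NA_real_, n = n, df = n - 2L, p = NA_real_,
                          degenerate = TRUE), class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = n, df = unname(ct$parameter),
                 p = ct$p.value, degenerate = FALSE),
            class = "correlation_result")
}

#' One-way between-subjects ANOVA
#'
#' Classical one-way ANOVA with partial eta-squared, used for follow-up
#' analyses within a single condition.
#'
#' @param values Numeric response, one observation per subject.
#' @param groups Grouping factor.
#' @return Data frame of class `"faf_anova"` (single effect row).
#' @export
oneway_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  grand <- mean(values)
  ss_b <- sum(ng * (gm - grand)^2)
  ss_w <- sum((values - gm[groups])^2)
  df1 <- k - 1L; df2 <- n - k
  f <- (ss_b / df1) / (ss_w / df2)
  out <- data.frame(effect = "group", df1 = df1, df2 = df2,
                    ss = ss_b, ss_error = ss_w, f = f,
                    p = pf(f, df1, df2, lower.tail = FALSE),
                    gg_epsilon = NA_real_, df1_gg = df1, df2_gg = df2,
                    p_gg = pf(f, df1, df2, lower.tail = FALSE),
                    pes = ss_b / (ss_b + ss_w),
                    mauchly_w = NA_real_, mauchly_p = NA_real_)
  class(out) <- c("faf_anova", "data.frame")
  out
}

# Orthonormal contrast basis for a factor with l levels (columns span the
# deviation-from-mean subspace, unit length, mutually orthogonal).
orthonormal_contrasts <- function(l) {
  h <- stats::contr.helmert(l)
  sweep(h, 2L, sqrt(colSums(h^2)), `/`)
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Univariate split-plot ANOVA for designs with one or two within-subject
#' factors (complete, one observation per cell) and an optional
#' between-subjects factor, with unequal group sizes handled by Type III
#' (sum-to-zero) hypotheses — the SPSS GLM conventions. For every
#' within-subject effect the Greenhouse-Geisser epsilon is estimated from
#' the effect-specific error covariance (orthonormal contrast space) and a
#' sphericity-corrected p-value is reported alongside the uncorrected one;
#' two-level factors have epsilon = 1 by construction. Mauchly's sphericity
#' test is computed and reported for effects with more than one numerator
#' contrast. Effect sizes are partial eta-squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param between Optional single between-subjects factor column.
#' @return Data frame of class `"faf_anova"`, one row per effect, with
#'   columns `effect`, `df1`, `df2`, `ss`, `ss_error`, `f`, `p`,
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p_gg`, `pes`, `mauchly_w`,
#'   `mauchly_p`.
#' @export
mixed_rm_anova <- function(data, dv, subject, within, between = NULL) {
  stopifnot(is.data.frame(data), dv %in% names(data), subject %in% names(data))
  if (length(within) < 1L || length(within) > 2L) {
    stop("`within` must name 1 or 2 within-subject factors")
  }
  miss <- setdiff(c(within, between), names(data))
  if (length(miss)) stop("column(s) not in `data`: ", paste(miss, collapse = ", "))
  if (any(!is.finite(data[[dv]]))) stop("`dv` contains non-finite values")
  subj <- as.character(data[[subject]])
  wf <- lapply(within, function(w) factor(data[[w]]))
  names(wf) <- within
  cell <- interaction(wf, lex.order = FALSE) # first within factor fastest
  levels_per <- vapply(wf, nlevels, 0L)
  p <- prod(levels_per)
  # validate complete crossing: each subject exactly once per cell
  tab <- table(subj, cell)
  bad <- rownames(tab)[rowSums(tab != 1L) > 0L]
  if (length(bad)) {
    stop("incomplete or duplicated within-subject cells for subject(s): ",
         paste(bad, collapse = ", "))
  }
  subj_ids <- rownames(tab)
  n <- length(subj_ids)
  # wide response matrix, cells ordered with the first within factor fastest
  cell_levels <- levels(cell)
  Y <- matrix(NA_real_, n, p, dimnames = list(subj_ids, cell_levels))
  Y[cbind(match(subj, subj_ids), match(as.character(cell), cell_levels))] <-
    data[[dv]]
  # between design
  if (!is.null(between)) {
    g_by_subj <- tapply(as.character(data[[between]]), subj, function(v) {
      u <- unique(v)
      if (length(u) > 1L) NA_character_ else u
    })
    if (anyNA(g_by_subj)) {
      stop("subject(s) with multiple between-factor levels: ",
           paste(names(g_by_subj)[is.na(g_by_subj)], collapse = ", "))
    }
    grp <- factor(g_by_subj[subj_ids])
    if (any(table(grp) < 2L)) stop("each between-subjects group needs >= 2 subjects")
    X <- stats::model.matrix(~grp, contrasts.arg = list(grp = "contr.sum"))
  } else {
    X <- matrix(1, n, 1L)
  }
  k <- ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y - X %*% B)
  df_res <- n - k
  if (df_res < 1L) stop("no residual degrees of freedom")
  # within-effect contrast matrices (orthonormal columns)
  ones <- function(l) matrix(1 / sqrt(l), l, 1L)
  Cs <- lapply(levels_per, orthonormal_contrasts)
  M_list <- list()
  if (length(within) == 1L) {
    M_list[[within[1]]] <- Cs[[1]]
  } else {
    M_list[[within[1]]] <- kronecker(ones(levels_per[2]), Cs[[1]])
    M_list[[within[2]]] <- kronecker(Cs[[2]], ones(levels_per[1]))
    M_list[[paste(within[1], within[2], sep = ":")]] <-
      kronecker(Cs[[2]], Cs[[1]])
  }
  L_int <- matrix(0, 1L, k); L_int[1, 1] <- 1
  L_btw <- if (k > 1L) cbind(matrix(0, k - 1L, 1L), diag(k - 1L)) else NULL
  test_effect <- function(L, M) {
    q <- ncol(M)
    LB <- L %*% B %*% M
    H <- crossprod(LB, solve(L %*% XtXi %*% t(L), LB))
    S <- crossprod(M, E %*% M)
    ss_h <- sum(diag(H)); ss_e <- sum(diag(S))
    df1 <- nrow(L) * q; df2 <- df_res * q
    f <- (ss_h / df1) / (ss_e / df2)
    eps <- sum(diag(S))^2 / (q * sum(S * S))
    if (q == 1L) eps <- 1
    mw <- mp <- NA_real_
    if (q > 1L) {
      w <- det(S) / (sum(diag(S)) / q)^q
      dcoef <- 1 - (2 * q^2 + q + 2) / (6 * q * df_res)
      chi <- -df_res * dcoef * log(max(w, .Machine$double.xmin))
      mw <- w
      mp <- pchisq(chi, q * (q + 1) / 2 - 1, lower.tail = FALSE)
    }
    data.frame(df1 = df1, df2 = df2, ss = ss_h, ss_error = ss_e, f = f,
               p = pf(f, df1, df2, lower.tail = FALSE),
               gg_epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
               p_gg = pf(f, eps * df1, eps * df2, lower.tail = FALSE),
               pes = ss_h / (ss_h + ss_e), mauchly_w = mw, mauchly_p = mp)
  }
  rows <- list()
  if (!is.null(L_btw)) {
    rows[[between]] <- test_effect(L_btw, ones(p))
  }
  for (nm in names(M_list)) {
    rows[[nm]] <- test_effect(L_int, M_list[[nm]])
    if (!is.null(L_btw)) {
      rows[[paste(nm, between, sep = ":")]] <- test_effect(L_btw, M_list[[nm]])
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(effect = names(rows), out)
  rownames(out) <- NULL
  class(out) <- c("faf_anova", "data.frame")
  out
}

#' Bonferroni-adjusted pairwise group comparisons
#'
#' All pairwise two-sample t comparisons between groups, using a pooled
#' error term: by default the one-way pooled within-group variance; pass the
#' ANOVA error mean square and degrees of freedom (`error_ms`, `error_df`) to
#' use the split-plot error stratum instead (the convention for post hoc
#' tests on estimated marginal means). Adjusted p-values are
#' `min(1, m * p)` with `m` the number of pairs.
#'
#' @param values Numeric response (one value per subject).
#' @param groups Grouping factor (each group needs >= 2 values).
#' @param error_ms,error_df Optional pooled error mean square and df.
#' @param alpha Significance level used for the `significant` column.
#' @return Data frame: `group1`, `group2`, `difference`, `t`, `df`, `p`,
#'   `p_adj`, `m`, `significant`.
#' @export
bonferroni_pairwise <- function(values, groups, error_ms = NULL,
                                error_df = NULL, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ng <- tapply(values, groups, length)
  if (any(ng < 2L)) {
    stop("group(s) with fewer than 2 values: ",
         paste(names(ng)[ng < 2L], collapse = ", "))
  }
  gm <- tapply(values, groups, mean)
  if (is.null(error_ms)) {
    error_df <- sum(ng) - nlevels(groups)
    error_ms <- sum((values - gm[groups])^2) / error_df
  }
  pairs <- combn(levels(groups), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- gm[[a]] - gm[[b]]
    se <- sqrt(error_ms * (1 / ng[[a]] + 1 / ng[[b]]))
    tval <- diff / se
    p <- 2 * pt(abs(tval), error_df, lower.tail = FALSE)
    data.frame(group1 = a, group2 = b, difference = diff, t = tval,
               df = error_df, p = p, p_adj = min(1, m * p), m = m)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' @export
print.faf_anova <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
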