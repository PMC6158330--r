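# Independent split-plot ANOVA oracle: textbook mean-based sums of squares
# for BALANCED designs (equal subjects per group, complete within crossing).
# Written directly from the classical decomposition, no shared code with
# mixed_rm_anova().

# One within factor: data frame with columns y, subject, group, w.
splitplot_oracle_1w <- function(d) {
  G <- sort(unique(d$group)); P <- sort(unique(d$w))
  g_n <- length(G); p <- length(P)
  n <- length(unique(d$subject)) / g_n
  m <- mean(d$y)
  m_g <- tapply(d$y, d$group, mean)
  m_gi <- tapply(d$y, d$subject, mean)
  subj_group <- tapply(d$group, d$subject, function(v) v[1])
  m_j <- tapply(d$y, d$w, mean)
  m_gj <- tapply(d$y, list(d$group, d$w), mean)
  ss_G <- p * n * sum((m_g - m)^2)
  ss_SG <- p * sum((m_gi - m_g[subj_group])^2)
  ss_W <- g_n * n * sum((m_j - m)^2)
  ss_GW <- n * sum((m_gj - outer(m_g, rep(1, p)) -
                      outer(rep(1, g_n), m_j) + m)^2)
  fit <- m_gi[as.character(d$subject)] + m_gj[cbind(as.character(d$group),
                                                    as.character(d$w))] -
    m_g[as.character(d$group)]
  ss_err <- sum((d$y - fit)^2)
  df_sg <- g_n * (n - 1)
  list(
    group = list(ss = ss_G, ss_error = ss_SG, df1 = g_n - 1, df2 = df_sg,
                 f = (ss_G / (g_n - 1)) / (ss_SG / df_sg)),
    w = list(ss = ss_W, ss_error = ss_err, df1 = p - 1,
             df2 = (p - 1) * df_sg,
             f = (ss_W / (p - 1)) / (ss_err / ((p - 1) * df_sg))),
    gw = list(ss = ss_GW, ss_error = ss_err, df1 = (g_n - 1) * (p - 1),
              df2 = (p - 1) * df_sg,
              f = (ss_GW / ((g_n - 1) * (p - 1))) /
                (ss_err / ((p - 1) * df_sg))))
}

# Greenhouse-Geisser epsilon by the double-centering formula on the pooled
# within-group covariance of the within-factor profiles.
gg_epsilon_oracle <- function(d) {
  P <- sort(unique(d$w)); p <- length(P)
  subj <- sort(unique(d$subject))
  Y <- matrix(NA_real_, length(subj), p)
  for (j in seq_len(p)) {
    dj <- d[d$w == P[j], ]
    Y[match(dj$subject, subj), j] <- dj$y
  }
  grp <- tapply(d$group, d$subject, function(v) v[1])[as.character(subj)]
  resid <- Y
  for (g in unique(grp)) {
    rows <- which(grp == g)
    resid[rows, ] <- sweep(Y[rows, , drop = FALSE], 2L,
                           colMeans(Y[rows, , drop = FALSE]))
  }
  S <- crossprod(resid)
  J <- diag(p) - matrix(1 / p, p, p)
  T_ <- J %*% S %*% J
  sum(diag(T_))^2 / ((p - 1) * sum(T_ * T_))
}

# Random balanced split-plot dataset (one within factor).
random_splitplot_1w <- function(n_groups, n_per_group, p, effects = TRUE) {
  subj <- sprintf("s%02d", seq_len(n_groups * n_per_group))
  group <- rep(LETTERS[seq_len(n_groups)], each = n_per_group)
  d <- expand.grid(subject = subj, w = paste0("w", seq_len(p)),
                   stringsAsFactors = FALSE)
  d$group <- group[match(d$subject, subj)]
  d$y <- rnorm(nrow(d))
  if (effects) {
    d$y <- d$y + as.numeric(factor(d$group)) * 0.5 +
      as.numeric(factor(d$w)) * 0.3 + rnorm(length(subj))[match(d$subject, subj)]
  }
  d
}

# Wide-format helper for car::Anova cross-checks (two within factors).
car_rm_oracle <- function(d, dv, subject, within, between) {
  wfl <- lapply(within, function(w) factor(d[[w]]))
  names(wfl) <- within
  cells <- do.call(expand.grid, lapply(wfl, levels))
  names(cells) <- within
  subj <- sort(unique(d[[subject]]))
  Y <- matrix(NA_real_, length(subj), nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(d))
    for (w in within) sel <- sel & d[[w]] == as.character(cells[i, w])
    di <- d[sel, ]
    Y[match(di[[subject]], subj), i] <- di[[dv]]
  }
  g <- factor(tapply(as.character(d[[between]]), d[[subject]],
                     function(v) v[1])[as.character(subj)])
  mod <- stats::lm(Y ~ g, contrasts = list(g = "contr.sum"))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = cells, idesign = idesign, type = 3)
  suppressWarnings(summary(av, multivariate = FALSE))
}

# Analytic variance of the mean of n consecutive samples of a stationary
# AR(1) process with marginal sd sigma and coefficient phi.
ar1_mean_var <- function(sigma, phi, n) {
  k <- seq_len(n - 1)
  sigma^2 / n^2 * (n + 2 * sum((n - k) * phi^k))
}
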