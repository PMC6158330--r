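test_that("HWE chi-square matches hand-computed cases", {
  # exact HWE proportions give chi2 = 0
  expect_equal(hwe_chisq(25, 50, 25)$chi2, 0, tolerance = 1e-12)
  # hand computation with p_hat = 0.5: expected (7.5, 15, 7.5)
  h <- hwe_chisq(10, 10, 10)
  expect_equal(h$allele_freq, 0.5)
  expect_equal(h$chi2, (2.5^2 / 7.5) + (5^2 / 15) + (2.5^2 / 7.5),
               tolerance = 1e-9)
  expect_equal(h$chi2, 10 / 3, tolerance = 1e-3)
  expect_error(hwe_chisq(0, 0, 0), "positive")
  expect_error(hwe_chisq(1.5, 2, 3), "integers")
  # chi2 is zero iff observed equals HWE expectation
  set.seed(1)
  for (i in 1:20) {
    cnt <- as.vector(stats::rmultinom(1, 200, c(0.3, 0.5, 0.2)))
    h <- hwe_chisq(cnt[1], cnt[2], cnt[3])
    expect_gte(h$chi2, 0)
    if (h$chi2 < 1e-12) expect_equal(cnt, h$expected, tolerance = 1e-6)
  }
})

test_that("contingency chi-square is Pearson without correction", {
  expect_equal(contingency_chisq(matrix(c(10, 20, 20, 40), 2))$chi2, 0,
               tolerance = 1e-12)
  tab <- matrix(c(10, 10, 10, 20), 2)
  res <- contingency_chisq(tab)
  # hand expansion: expected from marginals
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_error(contingency_chisq(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("pearson correlation matches hand computation and flags degeneracy", {
  r1 <- pearson_correlation(1:10, 2 * (1:10) + 1)
  expect_equal(r1$r, 1)
  r2 <- pearson_correlation(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$r, 0.5, tolerance = 1e-12)
  expect_equal(r2$df, 1)
  expect_warning(rd <- pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(rd$degenerate && is.na(rd$r))
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("null correlation p-values are uniform", {
  set.seed(42)
  n <- 20
  p <- replicate(2000, pearson_correlation(rnorm(n), rnorm(n))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("split-plot ANOVA equals the textbook oracle on balanced designs", {
  set.seed(100)
  for (i in 1:100) {
    g_n <- sample(2:3, 1); n <- sample(3:5, 1); p <- sample(2:4, 1)
    d <- random_splitplot_1w(g_n, n, p)
    fit <- mixed_rm_anova(d, "y", "subject", within = "w", between = "group")
    orc <- splitplot_oracle_1w(d)
    for (eff in list(c("group", "group"), c("w", "w"),
                     c("w:group", "gw"))) {
      row <- fit[fit$effect == eff[1], ]
      o <- orc[[eff[2]]]
      expect_equal(row$f, o$f, tolerance = 1e-8)
      expect_equal(row$ss, o$ss, tolerance = 1e-8)
      expect_equal(row$ss_error, o$ss_error, tolerance = 1e-8)
      expect_equal(row$df1, o$df1)
      expect_equal(row$df2, o$df2)
    }
    if (p > 2) {
      expect_equal(fit$gg_epsilon[fit$effect == "w"], gg_epsilon_oracle(d),
                   tolerance = 1e-8)
    } else {
      expect_equal(fit$gg_epsilon[fit$effect == "w"], 1)
    }
  }
})

test_that("ANOVA matches car::Anova on unbalanced two-within designs", {
  skip_if_not_installed("car")
  set.seed(200)
  for (i in 1:15) {
    ns <- sample(3:5, 3, replace = TRUE)
    subj <- sprintf("s%02d", seq_len(sum(ns)))
    grp <- rep(c("AA", "AG", "GG"), ns)
    d <- expand.grid(subject_id = subj, cond = c("c1", "c2"),
                     el = paste0("e", 1:3), stringsAsFactors = FALSE)
    d$genotype <- grp[match(d$subject_id, subj)]
    d$y <- rnorm(nrow(d)) + rnorm(length(subj))[match(d$subject_id, subj)]
    fit <- mixed_rm_anova(d, "y", "subject_id", within = c("cond", "el"),
                          between = "genotype")
    s <- car_rm_oracle(d, "y", "subject_id", c("cond", "el"), "genotype")
    ut <- s$univariate.tests
    map <- c(genotype = "g", cond = "cond", `cond:genotype` = "g:cond",
             el = "el", `el:genotype` = "g:el", `cond:el` = "cond:el",
             `cond:el:genotype` = "g:cond:el")
    for (eff in names(map)) {
      row <- fit[fit$effect == eff, ]
      o <- ut[map[[eff]], ]
      expect_equal(row$f, unname(o["F value"]), tolerance = 1e-8)
      expect_equal(row$ss, unname(o["Sum Sq"]), tolerance = 1e-8)
      expect_equal(row$p, unname(o["Pr(>F)"]), tolerance = 1e-8)
    }
    pa <- s$pval.adjustments
    expect_equal(fit$gg_epsilon[fit$effect == "el"],
                 unname(pa["g:el", "GG eps"]), tolerance = 1e-8)
    expect_equal(fit$p_gg[fit$effect == "el:genotype"],
                 unname(pa["g:el", "Pr(>F[GG])"]), tolerance = 1e-8)
    sph <- s$sphericity.tests
    expect_equal(fit$mauchly_w[fit$effect == "el"],
                 unname(sph["g:el", "Test statistic"]), tolerance = 1e-6)
    expect_equal(fit$mauchly_p[fit$effect == "el"],
                 unname(sph["g:el", "p-value"]), tolerance = 1e-6)
  }
})

test_that("ANOVA F is invariant to affine transforms of the response", {
  set.seed(5)
  d <- random_splitplot_1w(3, 4, 3)
  f1 <- mixed_rm_anova(d, "y", "subject", "w", "group")
  d$y <- 3.7 * d$y - 11
  f2 <- mixed_rm_anova(d, "y", "subject", "w", "group")
  expect_equal(f1$f, f2$f, tolerance = 1e-8)
  expect_equal(f1$gg_epsilon, f2$gg_epsilon, tolerance = 1e-8)
  expect_equal(f1$pes, f2$pes, tolerance = 1e-8)
})

test_that("degenerate and malformed ANOVA inputs raise informative errors", {
  d <- random_splitplot_1w(2, 3, 2)
  # identical values across the within levels: zero within-effect SS
  d0 <- d; d0$y <- rnorm(length(unique(d$subject)))[
    match(d0$subject, unique(d0$subject))]
  fit <- mixed_rm_anova(d0, "y", "subject", "w", "group")
  expect_equal(fit$ss[fit$effect == "w"], 0, tolerance = 1e-12)
  # a subject missing one cell is named in the error
  dm <- d[!(d$subject == "s01" & d$w == "w2"), ]
  expect_error(mixed_rm_anova(dm, "y", "subject", "w", "group"), "s01")
  # two-level within factor forces epsilon 1
  expect_equal(fit$gg_epsilon[fit$effect == "w"], 1)
})

test_that("Bonferroni pairwise comparisons cap and count correctly", {
  set.seed(30)
  v <- c(rnorm(10), rnorm(10, 2), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  out <- bonferroni_pairwise(v, g)
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$m), 3)
  expect_equal(out$p_adj, pmin(1, 3 * out$p))
  expect_true(all(out$p_adj <= 1))
  expect_error(bonferroni_pairwise(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  # against base pairwise.t.test with common pooled SD
  pt <- stats::pairwise.t.test(v, g, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  expect_equal(out$p_adj[out$group1 == "a" & out$group2 == "b"],
               pt$p.value["b", "a"], tolerance = 1e-9)
})

test_that("one-way ANOVA agrees with stats::aov", {
  set.seed(31)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  mine <- oneway_anova(v, g)
  ref <- summary(stats::aov(v ~ g))[[1]]
  expect_equal(mine$f, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})
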