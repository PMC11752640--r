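test_that("ANCOVA F agrees with the nested linear-model oracle", {
  # identical group means, balanced, no covariates: F = 0
  y <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  st <- ancova_f(y, g, n_perm = 99, seed = 1)
  expect_equal(st$statistic, 0, tolerance = 1e-12)

  # fixed toy table: compare against anova(lm()) computed independently
  set.seed(42)
  y2 <- rnorm(12) + rep(c(0, 0.5, 1), each = 4)
  cov <- data.frame(age = rnorm(12, 60, 5))
  st2 <- ancova_f(y2, g, cov, n_perm = 199, seed = 2)
  ref <- anova(lm(y2 ~ age + factor(g), data = cbind(cov, g = g)))
  expect_equal(st2$statistic, ref["factor(g)", "F value"], tolerance = 1e-10)
  expect_equal(st2$p_param, ref["factor(g)", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(st2$df, c(2, 8))
  expect_gte(st2$p_perm, 1 / 200)
  expect_error(ancova_f(y2, rep("a", 12)), "2 groups")
  expect_error(ancova_f(y2, g, data.frame(x = rep(1, 12), y = rep(2, 12))),
               "singular")
})

test_that("pairwise t matches the textbook statistic and lm", {
  set.seed(7)
  a <- rnorm(20); b <- rnorm(20) + 1
  y <- c(a, b); g <- rep(c("A", "B"), each = 20)
  st <- pairwise_t(y, g, n_perm = 999, seed = 3)
  # pooled-variance two-sample t, direct formula
  sp <- sqrt((19 * var(a) + 19 * var(b)) / 38)
  t_direct <- (mean(b) - mean(a)) / (sp * sqrt(2 / 20))
  expect_equal(st$statistic, t_direct, tolerance = 1e-10)
  expect_equal(st$p_param, t.test(b, a, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  # identical samples give t = 0
  st0 <- pairwise_t(c(a, a), g, n_perm = 99, seed = 1)
  expect_equal(st0$statistic, 0, tolerance = 1e-12)
  # with a covariate, match summary(lm()) for the group coefficient
  cov <- data.frame(age = rnorm(40, 65, 7))
  st2 <- pairwise_t(y, g, cov, n_perm = 199, seed = 4)
  fit <- summary(lm(y ~ age + gg, data = data.frame(age = cov$age,
                                                    gg = factor(g))))
  expect_equal(st2$statistic, fit$coefficients["ggB", "t value"],
               tolerance = 1e-10)
})

test_that("permutation and parametric p-values agree on Gaussian data", {
  set.seed(15)
  diffs <- replicate(6, {
    y <- rnorm(40) + rep(c(0, 0.4), each = 20)
    g <- rep(c("A", "B"), each = 20)
    st <- pairwise_t(y, g, n_perm = 9999)
    st$p_perm - st$p_param
  })
  expect_lt(max(abs(diffs)), 0.02)
})

test_that("signature models apply Bonferroni over the metric family", {
  spec <- cohort_spec(effects = list(fqfwf = c("SCD+" = 1.5)))
  coh <- generate_cohort(spec, seed = 5)
  res <- signature_models(coh, n_perm = 499, seed = 6)
  expect_equal(nrow(res), 5)
  expect_equal(res$n_tests, rep(5, 5))
  expect_equal(res$p_bonferroni, pmin(1, res$p_perm * 5))
  expect_lt(res$p_bonferroni[res$metric == "fqfwf"], 0.05)
  # listwise exclusion is reported
  coh$mwf[c(3, 9)] <- NA
  res2 <- signature_models(coh, n_perm = 99, seed = 1)
  expect_equal(res2$n_excluded[res2$metric == "mwf"], 2)
  expect_equal(res2$n_used[res2$metric == "mwf"], 137)
})

test_that("group effects carried purely by hippocampal volume are absorbed by the Z covariate", {
  # fqfwf depends on the hippocampal Z-score only (volume-driven effect);
  # group differences arise solely from the groups' Z distributions
  spec <- cohort_spec(z_slope = c(fqfwf = -1.0))
  hits_plain <- 0; hits_adj <- 0
  for (s in 1:30) {
    coh <- generate_cohort(spec, seed = 100 + s)
    plain <- signature_models(coh, metric_cols = "fqfwf_hip_left",
                              covariate_cols = c("age", "gds"),
                              n_perm = 199, seed = s)
    adj <- signature_models(coh, metric_cols = "fqfwf_hip_left",
                            covariate_cols = c("age", "gds", "z_hip_left"),
                            n_perm = 199, seed = s)
    hits_plain <- hits_plain + (plain$p_perm < 0.05)
    hits_adj <- hits_adj + (adj$p_perm < 0.05)
  }
  expect_gt(hits_plain, 20)   # unadjusted: the volume effect shows as group
  expect_lt(hits_adj, 7)      # adjusted: attenuates toward the nominal rate
})

test_that("power at the study's group sizes detects a 0.8 SD shift", {
  spec <- cohort_spec(effects = list(fqfwf = c("SCD+" = 0.8)))
  hits <- 0
  for (s in 1:200) {
    coh <- generate_cohort(spec, seed = 200 + s)
    keep <- coh$group %in% c("SCD-", "SCD+")
    st <- pairwise_t(coh$fqfwf[keep], coh$group[keep],
                     data.frame(age = coh$age[keep], gds = coh$gds[keep]),
                     n_perm = 999, seed = s)
    hits <- hits + (st$p_perm * 5 <= 0.05)   # Bonferroni over 5 metrics
  }
  expect_gt(hits / 200, 0.5)
})
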