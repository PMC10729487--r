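test_that("group comparison handles identical samples and matches the BH step-up oracle", {
  vals <- rep(c(1, 2, 3, 4), 3)
  groups <- rep(c("NC", "asym_MC", "sym_MC"), each = 4)
  gc0 <- group_comparison(vals, groups)
  expect_equal(gc0$statistic, 0)
  expect_true(all(gc0$pairwise$p_fdr == 1))

  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("pairwise Wilcoxon uses exact enumeration for small samples", {
  gc <- group_comparison(c(1, 2, 3, 4, 5, 6),
                         rep(c("NC", "sym_MC"), each = 3))
  # fully separated 3 vs 3: exact two-sided p = 2 * 1/C(6,3) = 0.1
  expect_equal(gc$pairwise$p, 0.1, tolerance = 1e-12)
  expect_error(group_comparison(1:3, rep("NC", 3)), "2 non-empty")
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum rejection set", {
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(12, 0.8)
    kw <- group_comparison(c(a, b), rep(c("A", "B"), c(15, 12)))
    w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(kw$p.value < 0.05, w$p.value < 0.05)
  }
})

test_that("Levene's test is mean-centered, calibrated, and powered", {
  expect_equal(levene_test(rep(c(3, 7), each = 4),
                           rep(c("A", "B"), each = 4))$statistic, 0)
  set.seed(3)
  rejections <- vapply(1:50, function(i) {
    v <- rnorm(90); g <- rep(c("A", "B", "C"), each = 30)
    levene_test(v, g)$p.value < 0.05
  }, logical(1))
  expect_lte(sum(rejections), 8)   # ~5% nominal over 50 null draws
  v <- c(rnorm(100, 0, 1), rnorm(100, 0, 10))
  expect_lt(levene_test(v, rep(c("A", "B"), each = 100))$p.value, 0.001)
  expect_error(levene_test(1:3, c("A", "A", "B")), "fewer than 2")
})

test_that("with zero family variance the mixed model reduces to OLS", {
  tab <- slope_cohort(n_per_group = 80, family_sd = 0, seed = 4)
  fit <- fit_lme_biomarker(tab, "bm")
  ols <- lm(bag ~ bm * group + sex + education + apoe4, data = tab)
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)),
               tolerance = 1e-6)
  expect_lt(fit$family_var, 1e-8)
})

test_that("group-specific slopes produce a detectable interaction with sensible effect sizes", {
  tab <- slope_cohort(n_per_group = 134, seed = 5)
  fit <- fit_lme_biomarker(tab, "bm")
  int_row <- fit$terms[fit$terms$term == "bm:group", ]
  expect_lt(int_row$p, 0.05)
  expect_true(all(fit$terms$eta_p2 >= 0 & fit$terms$eta_p2 <= 1))
  # partial eta^2 is invariant to affine rescaling of the response
  tab2 <- tab; tab2$bag <- 3 * tab2$bag + 10
  fit2 <- fit_lme_biomarker(tab2, "bm")
  expect_equal(fit$terms$eta_p2, fit2$terms$eta_p2, tolerance = 1e-6)
  expect_error(fit_lme_biomarker(transform(tab, bm = 1), "bm"), "constant")
})

test_that("within-group correlations match hand computations", {
  tab <- data.frame(group = factor(rep("sym_MC", 3), levels = c("NC", "asym_MC", "sym_MC")),
                    bm = c(1, 2, 3), bag = c(2, 1, 3))
  r <- group_correlations(tab, "bm", "sym_MC")
  expect_equal(r$r, 0.5, tolerance = 1e-12)
  tab2 <- data.frame(group = "sym_MC", bm = 1:10, bag = 1:10)
  expect_equal(group_correlations(tab2, "bm", "sym_MC")$r, 1)
  expect_error(group_correlations(transform(tab2, bm = 1), "bm", "sym_MC"),
               "constant")
})

test_that("generated plasma pTau correlation in symptomatic carriers is near its target", {
  spec <- cohort_spec(n_nc = 60L, n_asym_mc = 60L, n_sym_mc = 300L)
  co <- make_bag_cohort(spec, seed = 6, harmonize = FALSE)
  co$log_ptau <- log(co$plasma_ptau)
  r <- group_correlations(co, "log_ptau", "sym_MC", response = "true_bag")
  expect_lt(abs(r$r - 0.53), 0.1)
})

test_that("log sensitivity rejects non-positive values and preserves the effect direction", {
  tab <- slope_cohort(n_per_group = 60, seed = 7)
  both <- log_sensitivity(tab, "bm")
  b_raw <- both$bm$original$coefficients
  b_log <- both$bm$log$coefficients
  est_raw <- b_raw$estimate[b_raw$coef == "bm"]
  est_log <- b_log$estimate[b_log$coef == "bm"]
  expect_equal(sign(est_raw), sign(est_log))
  tab$bm[3] <- -1
  expect_error(log_sensitivity(tab, "bm"), "non-positive.*3")
})

test_that("mediation decomposition is exact and recovers a full-mediation truth", {
  set.seed(8)
  n <- 400
  dat <- data.frame(
    x = rnorm(n), family_id = factor(sample.int(100, n, replace = TRUE)),
    sex = factor(sample(c("F", "M"), n, TRUE)), education = rnorm(n, 15, 2),
    apoe4 = rbinom(n, 1, 0.3))
  dat$m_var <- 0.5 * dat$x + rnorm(n, 0, 0.5)
  dat$y_var <- -0.8 * dat$m_var + rnorm(n, 0, 0.5)
  med <- mediate(dat, x = "x", m = "m_var", y = "y_var", n_boot = 500, seed = 9)
  expect_lt(abs(med$total - (med$direct + med$indirect)), 1e-8)
  expect_gte(med$indirect, -0.5)
  expect_lte(med$indirect, -0.3)
  expect_true(med$ci_high < 0)

  # null mediation: m unrelated to x
  dat$m_null <- rnorm(n)
  dat$y_null <- -0.8 * dat$m_null + rnorm(n, 0, 0.5)
  med0 <- mediate(dat, x = "x", m = "m_null", y = "y_null", n_boot = 500,
                  seed = 10)
  expect_true(med0$ci_low < 0 && med0$ci_high > 0)
  expect_equal(med0$label, "no mediation")
  expect_error(mediate(dat, x = "x", m = "m_var", y = "y_var", n_boot = 50),
               "n_boot")
})

test_that("Cohen's d matches the pooled-SD hand formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  g1 <- c(12.1, 9.8, 11.4, 10.6, 12.9, 10.2)
  g2 <- c(8.4, 9.1, 7.6, 10.0, 8.8, 9.5)
  sp <- sqrt((5 * var(g1) + 5 * var(g2)) / 10)
  d_hand <- (mean(g1) - mean(g2)) / sp
  out <- cohens_d(g1, g2)
  expect_equal(out$d, d_hand, tolerance = 1e-12)
  expect_lt(out$ci_low, out$d); expect_gt(out$ci_high, out$d)
  set.seed(11)
  big <- cohens_d(rnorm(20000, 1), rnorm(20000, 0))
  expect_equal(big$d, 1, tolerance = 0.05)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
})
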