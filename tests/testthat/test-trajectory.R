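test_that("cr basis has the right dimension and a linear null space", {
  x <- seq(-30, 10, length.out = 80)
  b <- build_cr_basis(x, k = 4)
  expect_equal(ncol(b$X), 4)
  expect_equal(qr(b$X)$rank, 4)
  # cr coefficients are function values at the knots: a linear function is
  # penalty-free, a curved one is not
  lin <- 2 + 3 * b$knots
  expect_lt(drop(t(lin) %*% b$S %*% lin), 1e-8)
  quad <- b$knots^2
  expect_gt(drop(t(quad) %*% b$S %*% quad), 1e-3)
  expect_error(build_cr_basis(rep(1:3, 5), k = 4), "distinct")
})

test_that("an unpenalized smooth equals least squares on the basis columns", {
  set.seed(10)
  x <- runif(150, -20, 10)
  y <- 5 + 0.3 * x - 0.05 * x^2 + rnorm(150, 0, 1)
  g <- mgcv::gam(y ~ s(x, k = 4, bs = "cr"), sp = 0, method = "REML")
  B <- build_cr_basis(x, k = 4)
  ols_fit <- lm.fit(cbind(1, B$X), y)$fitted.values
  expect_equal(unname(fitted(g)), unname(ols_fit), tolerance = 1e-8)
})

test_that("forcing lambda to infinity reproduces the linear mixed model", {
  # interior variance optimum so neither REML lands on the boundary
  spec <- cohort_spec(n_nc = 120L, n_asym_mc = 120L, n_sym_mc = 60L,
                      n_sites = 6L, family_sd = 3, noise_sd = 2)
  co <- make_bag_cohort(spec, seed = 21)
  co$mutation_status <- factor(ifelse(co$group == "NC", "NC", "MC"),
                               levels = c("NC", "MC"))
  lmm <- lme4::lmer(bag ~ mutation_status * eyo + sex + education + apoe4 +
                      (1 | family_id), data = co, REML = TRUE)
  # same variance ratio on both sides: the penalized fits must coincide
  ratio <- 1 / unname(lme4::getME(lmm, "theta"))^2
  fit_inf <- fit_gamm(co, sp = c(1e10, 1e10, ratio))
  expect_equal(unname(fitted(fit_inf$gam)), unname(fitted(lmm)),
               tolerance = 1e-6)
  # with both REMLs free, estimates and fits still agree closely
  fit_free <- fit_gamm(co, sp = c(1e10, 1e10, -1))
  expect_equal(fit_free$family_sd,
               sqrt(unname(lme4::VarCorr(lmm)$family_id[1])),
               tolerance = 1e-3)
  expect_lt(max(abs(fitted(fit_free$gam) - fitted(lmm))), 1e-3)
})

test_that("smooth EDFs stay inside [1, k] and the smooth test finds the generative signal", {
  co <- make_bag_cohort(small_spec(), seed = 22)
  fit <- fit_gamm(co)
  for (term in c("NC", "MC")) {
    tt <- smooth_term_test(fit, term)
    expect_gte(tt[["edf"]], 1 - 1e-6)
    expect_lte(tt[["edf"]], 4)
  }
  # carriers carry a strong nonlinear signal; non-carriers are flat
  big <- make_bag_cohort(cohort_spec(n_nc = 160L, n_asym_mc = 160L,
                                     n_sym_mc = 80L), seed = 23)
  fit_big <- fit_gamm(big)
  expect_lt(smooth_term_test(fit_big, "MC")[["p"]], 0.001)
  expect_error(smooth_term_test(fit_big, "nope"))
})

test_that("pure linear truth drives the smooth EDF toward its null space", {
  set.seed(24)
  n <- 400
  tab <- data.frame(
    eyo = runif(n, -25, 8),
    family_id = factor(sprintf("F%02d", sample.int(60, n, replace = TRUE))),
    group = factor(rep(c("NC", "asym_MC"), each = n / 2),
                   levels = c("NC", "asym_MC", "sym_MC")),
    sex = factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M")),
    education = round(rnorm(n, 15, 2)), apoe4 = rbinom(n, 1, 0.3))
  tab$bag <- 1 + 0.2 * tab$eyo + rnorm(n, 0, 2)
  fit <- fit_gamm(tab)
  expect_lt(smooth_term_test(fit, "NC")[["edf"]], 1.5)
  expect_lt(smooth_term_test(fit, "MC")[["edf"]], 1.5)
})

test_that("family random-intercept SD is recovered across seeds", {
  ests <- vapply(1:10, function(s) {
    # site shifts are shared by co-sited families and would inflate the
    # apparent family variance, so they are off in this recovery condition
    co <- make_bag_cohort(cohort_spec(n_nc = 250L, n_asym_mc = 250L,
                                      n_sym_mc = 100L, family_sd = 2,
                                      site_shift_sd = 0,
                                      scanner_scale_sd = 0),
                          seed = s, harmonize = FALSE)
    fit_gamm(co, engine = "bam")$family_sd
  }, numeric(1))
  expect_gte(mean(ests), 1.6)
  expect_lte(mean(ests), 2.4)
})

test_that("the simultaneous multiplier dominates the pointwise quantile", {
  co <- make_bag_cohort(small_spec(), seed = 25)
  fit <- fit_gamm(co)
  set.seed(1)
  b <- simultaneous_band(fit, "MC", grid_step = 0.5, n_draws = 4000)
  expect_gte(b$m, qnorm(1 - (1 - 0.834) / 2))
  expect_true(all(b$band$lower <= b$band$fit & b$band$fit <= b$band$upper))
  # single-point grid: m collapses to the pointwise quantile
  b1 <- simultaneous_band(fit, "MC", grid = 0, n_draws = 40000)
  expect_equal(b1$m, qnorm(0.917), tolerance = 0.03)
  expect_error(simultaneous_band(fit, "MC", grid = c(-100, 0)), "outside")
})

test_that("a wider nominal level yields an everywhere-containing band", {
  co <- make_bag_cohort(small_spec(), seed = 26)
  fit <- fit_gamm(co)
  set.seed(2)
  b83 <- simultaneous_band(fit, "MC", grid_step = 0.5, level = 0.834,
                           n_draws = 4000)
  b95 <- simultaneous_band(fit, "MC", grid_step = 0.5, level = 0.95,
                           n_draws = 4000)
  expect_true(all(b95$band$lower <= b83$band$lower))
  expect_true(all(b95$band$upper >= b83$band$upper))
})

test_that("divergence detection follows the sustained-separation rule", {
  mk_band <- function(grid, fit, half, group) {
    structure(list(band = data.frame(eyo = grid, fit = fit,
                                     lower = fit - half, upper = fit + half,
                                     se = half),
                   m = 2, level = 0.834, group = group, n_draws = 0),
              class = "bag_band")
  }
  grid <- seq(-10, 5, by = 0.5)
  flat <- mk_band(grid, rep(0, length(grid)), 1, "NC")
  expect_true(is.na(find_divergence(mk_band(grid, rep(0, length(grid)), 1, "MC"),
                                    flat)))
  # disjoint constant bands everywhere -> grid minimum
  high <- mk_band(grid, rep(10, length(grid)), 1, "MC")
  expect_equal(find_divergence(high, flat), min(grid))
  # an isolated early crossing is ignored; sustained separation from -2 on
  fitv <- ifelse(grid < -8, 10, ifelse(grid < -2, 0, 10))
  wob <- mk_band(grid, fitv, 1, "MC")
  expect_equal(find_divergence(wob, flat), -2)
  expect_error(find_divergence(mk_band(grid + 1, fitv, 1, "MC"), flat),
               "different grids")
})

test_that("bootstrap divergence is deterministic given the seed and censors non-divergent replicates", {
  spec <- cohort_spec(n_nc = 80L, n_asym_mc = 60L, n_sym_mc = 40L,
                      n_sites = 5L, noise_sd = 3)
  co <- make_bag_cohort(spec, seed = 30)
  co <- add_synthetic_measure(co, "flat_measure", divergence_eyo = -1,
                              elevation = 0.01, noise_sd = 3, spec = spec,
                              seed = 31)
  b1 <- bootstrap_divergence(co, c("bag", "flat_measure"), n_boot = 100,
                             seed = 99, grid_step = 0.5, n_draws = 300,
                             family_re = FALSE)
  b2 <- bootstrap_divergence(co, c("bag", "flat_measure"), n_boot = 100,
                             seed = 99, grid_step = 0.5, n_draws = 300,
                             family_re = FALSE)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$summary, b2$summary)
  # the near-flat measure rarely diverges: censored + one-sided flag
  row_flat <- b1$summary[b1$summary$measure == "flat_measure", ]
  expect_true(row_flat$one_sided)
  expect_true(is.na(row_flat$ci_high))
  # CI brackets the median for the real measure
  row_bag <- b1$summary[b1$summary$measure == "bag", ]
  expect_lte(row_bag$ci_low, row_bag$median)
  expect_error(bootstrap_divergence(co, "bag", n_boot = 10), "n_boot")
})
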