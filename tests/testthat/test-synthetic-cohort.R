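test_that("zero-count spec yields an empty table with the full column schema", {
  spec <- cohort_spec(n_nc = 0L, n_asym_mc = 0L, n_sym_mc = 0L)
  co <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(co), 0L)
  expect_true(all(c("participant_id", "family_id", "site_id", "scanner_id",
                    "group", "variant", "age", "eyo", "sex", "education",
                    "apoe4", "cdr", "raw_predicted_age", "plasma_ptau",
                    "cognitive_composite", "cdr_sb", "true_bag") %in% names(co)))
  full <- generate_cohort(small_spec(), seed = 1)
  expect_setequal(names(co), names(full))
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(cohort_spec(n_nc = -1), "n_nc")
  expect_error(cohort_spec(noise_sd = -2), "noise_sd")
  expect_error(cohort_spec(icc_target = 1.5), "icc_target")
  expect_error(cohort_spec(divergence_eyo = 2), "divergence_eyo")
  expect_error(cohort_spec(site_shift_sd = NA), "site_shift_sd")
})

test_that("with all variance and offset sources off, NC predictions equal age exactly", {
  co <- generate_cohort(noiseless_spec(), seed = 7)
  nc <- co[co$group == "NC", ]
  expect_equal(nc$raw_predicted_age, nc$age, tolerance = 1e-12)
  # carriers deviate from age exactly by the generative trajectory
  mc <- co[co$group != "NC", ]
  expect_equal(mc$raw_predicted_age - mc$age, mc$true_curve, tolerance = 1e-12)
})

test_that("identical spec and seed give byte-identical tables", {
  spec <- small_spec()
  expect_identical(generate_cohort(spec, seed = 42),
                   generate_cohort(spec, seed = 42))
  expect_false(identical(generate_cohort(spec, seed = 42),
                         generate_cohort(spec, seed = 43)))
})

test_that("trajectory is zero for non-carriers and before divergence", {
  spec <- cohort_spec()
  expect_equal(true_bag_curve(c(-20, -7.0001, -40), "sym_MC", spec), rep(0, 3))
  expect_equal(true_bag_curve(seq(-30, 10, by = 5), "NC", spec), rep(0, 9))
  # smooth monotone ramp after onset
  ramp <- true_bag_curve(seq(-7, 10, by = 0.5), "asym_MC", spec)
  expect_true(all(diff(ramp) >= 0))
})

test_that("ramp height is calibrated to the symptomatic-stage elevation (numeric integration oracle)", {
  spec <- cohort_spec()
  mu <- spec$eyo_params$sym_MC[["mean"]]; s <- spec$eyo_params$sym_MC[["sd"]]
  oracle <- integrate(function(e) true_bag_curve(e, "sym_MC", spec) * dnorm(e, mu, s),
                      lower = spec$divergence_eyo, upper = Inf,
                      rel.tol = 1e-10)$value
  expect_equal(oracle, spec$sym_elevation, tolerance = 1e-6)
})

test_that("sex and education effects are recovered exactly by OLS on noise-free data", {
  spec <- cohort_spec(noise_sd = 0, site_shift_sd = 0, scanner_scale_sd = 0,
                      family_sd = 0)
  co <- generate_cohort(spec, seed = 11)
  nc <- co[co$group == "NC", ]
  fit <- lm(I(raw_predicted_age - age) ~ I(sex == "M") + I(education - 14.8),
            data = nc)
  expect_equal(unname(coef(fit)), c(0, spec$sex_effect, spec$education_slope),
               tolerance = 1e-10)
})

test_that("turning a variance source off removes exactly its contribution", {
  # only the family intercept left on: residual from the known mean structure
  # is constant within family and varies between families
  spec <- cohort_spec(noise_sd = 0, site_shift_sd = 0, scanner_scale_sd = 0,
                      family_sd = 2, sex_effect = 0, education_slope = 0)
  co <- generate_cohort(spec, seed = 5)
  resid <- co$raw_predicted_age - co$age - co$true_curve
  within_var <- tapply(resid, co$family_id, function(x) diff(range(x)))
  expect_lt(max(within_var, na.rm = TRUE), 1e-10)
  expect_gt(sd(tapply(resid, co$family_id, mean), na.rm = TRUE), 0.5)
})

test_that("biomarker latent construction hits the target BAG correlation", {
  spec <- cohort_spec(n_nc = 50L, n_asym_mc = 50L, n_sym_mc = 400L)
  co <- generate_cohort(spec, seed = 3)
  sym <- co[co$group == "sym_MC", ]
  r <- cor(log(sym$plasma_ptau), sym$true_bag)
  expect_lt(abs(r - 0.53), 0.1)
  r_nfl <- cor(log(sym$plasma_nfl), sym$true_bag)
  expect_lt(abs(r_nfl - 0.55), 0.1)
})

test_that("retest construction spans the ICC range", {
  co <- generate_cohort(cohort_spec(n_nc = 500L, n_asym_mc = 0L, n_sym_mc = 0L),
                        seed = 2)
  rt1 <- generate_retest(co, icc_target = 1, seed = 9)
  expect_equal(rt1$visit2, rt1$visit1, tolerance = 1e-12)
  rt0 <- generate_retest(co, icc_target = 0, seed = 9)
  expect_lt(abs(cor(rt0$visit1, rt0$visit2)), 0.15)
  rt9 <- generate_retest(co, icc_target = 0.9, seed = 9)
  icc <- icc_a1(rt9$visit1, rt9$visit2)$icc
  expect_gte(icc, 0.87)
  expect_lte(icc, 0.93)
  expect_error(generate_retest(co, icc_target = 1.2), "icc_target")
})

test_that("group labels, CDR and EYO bookkeeping respect the generative rules", {
  co <- generate_cohort(small_spec(), seed = 13)
  expect_true(all(co$cdr[co$group == "sym_MC"] > 0))
  expect_true(all(co$cdr[co$group != "sym_MC"] == 0))
  # single onset age per family: age - eyo identical for all family members
  onset <- co$age - co$eyo
  spread <- tapply(onset, co$family_id, function(x) diff(range(x)))
  expect_lt(max(spread, na.rm = TRUE), 1e-9)
  expect_true(all(co$true_curve[co$group == "NC"] == 0))
})

test_that("added synthetic measures carry their own divergence truth", {
  spec <- small_spec()
  co <- generate_cohort(spec, seed = 1)
  co <- add_synthetic_measure(co, "thickness", divergence_eyo = -3,
                              elevation = 10, noise_sd = 1, spec = spec,
                              seed = 2)
  expect_true(all(co$true_thickness[co$eyo <= -3] == 0))
  expect_true(all(co$true_thickness[co$group == "NC"] == 0))
  mc_late <- co$group != "NC" & co$eyo > -3
  if (any(mc_late)) expect_true(all(co$true_thickness[mc_late] > 0))
})
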