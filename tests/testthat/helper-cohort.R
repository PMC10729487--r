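# Shared fixture builders. Everything is generated in code at test time.

# Desk-scale spec for tests that only need structure, not power.
small_spec <- function(...) {
  cohort_spec(n_nc = 60L, n_asym_mc = 60L, n_sym_mc = 30L,
              n_sites = 6L, n_scanners = 4L, ...)
}

# Deterministic generator with every stochastic/offset source switched off:
# raw_predicted_age == age + carrier trajectory exactly.
noiseless_spec <- function(...) {
  cohort_spec(noise_sd = 0, site_shift_sd = 0, scanner_scale_sd = 0,
              family_sd = 0, sex_effect = 0, education_slope = 0, ...)
}

# Generate, calibrate and harmonize in one step; adds corrected_age and bag.
make_bag_cohort <- function(spec, seed = 1L, harmonize = TRUE) {
  co <- generate_cohort(spec, seed = seed)
  cal <- fit_calibration(co[co$group == "NC", , drop = FALSE])
  co$corrected_age <- apply_calibration(cal, co$raw_predicted_age)
  if (harmonize) {
    co$bag <- compute_bag(harmonize_predicted_age(co)$values, co$age)
  } else {
    co$bag <- compute_bag(co$corrected_age, co$age)
  }
  attr(co, "calibration") <- cal
  co
}

# Biomarker panel with zero BAG correlation in every group (null slopes).
null_biomarker_params <- function() {
  bp <- default_biomarker_params()
  lapply(bp, function(p) { p$r[] <- 0; p })
}

# Independent normal-equations OLS oracle (2-column design with intercept).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Independent ICC(A,1) oracle from a two-way ANOVA (aov mean squares).
icc_oracle_aov <- function(v1, v2) {
  n <- length(v1)
  d <- data.frame(y = c(v1, v2),
                  subj = factor(rep(seq_len(n), 2)),
                  visit = factor(rep(1:2, each = n)))
  ms <- anova(aov(y ~ subj + visit, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Data with group-specific biomarker -> response slopes for interaction tests.
slope_cohort <- function(n_per_group = 134L, slopes = c(NC = 0, asym_MC = 0.2,
                                                        sym_MC = 0.5),
                         noise_sd = 1, family_sd = 0.5, seed = 1L) {
  set.seed(seed)
  n <- 3L * n_per_group
  group <- factor(rep(names(slopes), each = n_per_group),
                  levels = names(slopes))
  family_id <- factor(sprintf("F%03d", sample.int(ceiling(n / 3), n, replace = TRUE)))
  fam_u <- rnorm(nlevels(family_id), 0, family_sd)
  bm <- exp(rnorm(n, 1, 0.4))
  sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
  education <- round(rnorm(n, 15, 2.5))
  apoe4 <- rbinom(n, 1, 0.3)
  y <- slopes[as.character(group)] * bm + fam_u[as.integer(family_id)] +
    rnorm(n, 0, noise_sd)
  data.frame(group = group, family_id = family_id, bm = bm, bag = unname(y),
             sex = sex, education = education, apoe4 = apoe4)
}
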