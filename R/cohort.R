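#' Specification of a synthetic ADAD-like cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. Defaults
#' reproduce the structure of a multi-site, family-based autosomal dominant
#' Alzheimer disease (ADAD) observational cohort: three mutation groups
#' (non-carriers `NC`, asymptomatic carriers `asym_MC`, symptomatic carriers
#' `sym_MC`), family clustering with a single expected symptom-onset age per
#' family, additive site and multiplicative scanner batch effects on the raw
#' brain-predicted age, and a fluid/PET biomarker panel whose within-group
#' correlations with the true brain-age gap (BAG) are imposed through a shared
#' latent disease-severity variable.
#'
#' The default group sizes (179/183/74), group age and EYO distributions,
#' symptomatic-stage BAG elevation (13.4 y), sex offset (+3.15 y, male minus
#' female), education slope (-0.38 y per education year) and biomarker
#' correlation targets mirror the values typically reported for ADAD
#' brain-age cohorts; the true BAG trajectory of carriers is zero until
#' `divergence_eyo` and then rises as a smooth quadratic ramp (see
#' [true_bag_curve()]).
#'
#' @param n_nc,n_asym_mc,n_sym_mc group sizes (non-negative integers).
#' @param age_params named list of `c(mean, sd)` in years per group. The `NC`
#'   entry is sampled directly; carrier ages are induced as
#'   `family onset age + EYO` so that the EYO distributions below hold
#'   exactly (the carrier entries are retained as descriptive targets).
#' @param eyo_params named list of `c(mean, sd)` in years for the two carrier
#'   groups; non-carrier EYO is induced as `age - family onset age`.
#' @param n_sites,n_scanners number of acquisition sites and scanner models.
#' @param site_shift_sd SD (years) of the additive per-site shift on
#'   predicted age.
#' @param scanner_scale_sd SD (log scale, dimensionless) of the multiplicative
#'   per-scanner factor on predicted age.
#' @param family_size_mean mean family size; sizes are `1 + Poisson(mean - 1)`.
#' @param family_sd SD (years) of the family random intercept on true BAG.
#' @param divergence_eyo EYO (years, negative = pre-onset) at which the carrier
#'   BAG trajectory leaves zero.
#' @param sym_elevation mean true BAG (years) over the symptomatic-stage EYO
#'   distribution; calibrates the ramp height.
#' @param noise_sd SD (years) of the per-scan prediction noise.
#' @param sex_effect male minus female offset on true BAG (years).
#' @param education_slope change in true BAG per year of education
#'   (years/year); education is centered at 14.8 y.
#' @param biomarker_params named list describing the biomarker panel; see
#'   [default_biomarker_params()].
#' @param cognition_params list with per-group `mean`, `sd` (z-units) and
#'   target correlation `r` with true BAG for the global cognitive composite.
#' @param onset_params list with per-variant mean onset ages (`means`, years)
#'   and the between-family onset SD (`sd`).
#' @param variant_probs sampling probabilities of the four mutation variants.
#' @param icc_target population ICC(A,1) used by [generate_retest()] when a
#'   retest table is requested from the pipeline; in `[0, 1]`.
#' @param seed default RNG seed used when [generate_cohort()] is called
#'   without one.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()], [true_bag_curve()], [generate_retest()]
#' @export
#' @examples
#' spec <- cohort_spec(n_nc = 40, n_asym_mc = 40, n_sym_mc = 20)
#' cohort <- generate_cohort(spec, seed = 1)
#' table(cohort$group)
cohort_spec <- function(n_nc = 179L, n_asym_mc = 183L, n_sym_mc = 74L,
                        age_params = list(
                          NC      = c(mean = 37.5, sd = 10.6),
                          asym_MC = c(mean = 34.3, sd = 9.1),
                          sym_MC  = c(mean = 46.3, sd = 8.7)),
                        eyo_params = list(
                          asym_MC = c(mean = -14.3, sd = 9.0),
                          sym_MC  = c(mean = 1.4,  sd = 5.7)),
                        n_sites = 15L, n_scanners = 9L,
                        site_shift_sd = 1.5, scanner_scale_sd = 0.02,
                        family_size_mean = 3, family_sd = 2,
                        divergence_eyo = -7, sym_elevation = 13.4,
                        noise_sd = 5,
                        sex_effect = 3.15, education_slope = -0.38,
                        biomarker_params = default_biomarker_params(),
                        cognition_params = list(
                          mean = c(NC = 0, asym_MC = -0.2, sym_MC = -1.5),
                          sd   = c(NC = 0.8, asym_MC = 0.9, sym_MC = 1.1),
                          r    = c(NC = -0.21, asym_MC = -0.25, sym_MC = -0.61)),
                        onset_params = list(
                          means = c("APP" = 49.5, "PSEN1<200" = 42.5,
                                    "PSEN1 200+" = 46.5, "PSEN2" = 55),
                          sd = 5),
                        variant_probs = c("APP" = 0.21, "PSEN1<200" = 0.29,
                                          "PSEN1 200+" = 0.39, "PSEN2" = 0.11),
                        icc_target = 0.94, seed = 1L) {
  spec <- list(
    n_nc = n_nc, n_asym_mc = n_asym_mc, n_sym_mc = n_sym_mc,
    age_params = age_params, eyo_params = eyo_params,
    n_sites = n_sites, n_scanners = n_scanners,
    site_shift_sd = site_shift_sd, scanner_scale_sd = scanner_scale_sd,
    family_size_mean = family_size_mean, family_sd = family_sd,
    divergence_eyo = divergence_eyo, sym_elevation = sym_elevation,
    noise_sd = noise_sd, sex_effect = sex_effect,
    education_slope = education_slope,
    biomarker_params = biomarker_params,
    cognition_params = cognition_params,
    onset_params = onset_params, variant_probs = variant_probs,
    icc_target = icc_target, seed = seed)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default biomarker panel parameters
#'
#' One entry per biomarker with per-group log-normal location (`meanlog`) and
#' scale (`sdlog`) parameters, and the target within-group correlation with
#' true BAG (`r`, on the log scale; group order `NC`, `asym_MC`, `sym_MC`).
#' Biomarkers are generated strictly positive so that log-transform
#' sensitivity analyses are always defined.
#'
#' @return Named list of per-biomarker parameter lists.
#' @export
default_biomarker_params <- function() {
  bm <- function(means, sdlog, r_asym, r_sym, r_nc = 0) {
    list(meanlog = log(means), sdlog = sdlog,
         r = c(NC = r_nc, asym_MC = r_asym, sym_MC = r_sym))
  }
  list(
    pib_suvr      = bm(c(1.05, 1.60, 2.60), c(0.08, 0.35, 0.30),  0.24,  0.34),
    csf_ab42_40   = bm(c(0.090, 0.055, 0.040), c(0.15, 0.35, 0.30), -0.10, -0.14),
    csf_ptau_ab40 = bm(c(0.005, 0.012, 0.020), c(0.30, 0.50, 0.40),  0.30,  0.45),
    plasma_ptau   = bm(c(1.5, 3.0, 6.0), c(0.30, 0.50, 0.45),  0.32,  0.53),
    csf_nfl       = bm(c(600, 900, 2000), c(0.30, 0.40, 0.50),  0.14,  0.46),
    plasma_nfl    = bm(c(8, 12, 25), c(0.30, 0.40, 0.50),  0.17,  0.55))
}

cohort_groups <- c("NC", "asym_MC", "sym_MC")

validate_cohort_spec <- function(spec) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
      stop(sprintf("invalid cohort_spec field '%s': must be a single non-negative integer", nm),
           call. = FALSE)
  }
  chk_sd <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0)
      stop(sprintf("invalid cohort_spec field '%s': must be a single finite value >= 0", nm),
           call. = FALSE)
  }
  for (nm in c("n_nc", "n_asym_mc", "n_sym_mc", "n_sites", "n_scanners"))
    chk_count(spec[[nm]], nm)
  for (nm in c("site_shift_sd", "scanner_scale_sd", "family_sd", "noise_sd"))
    chk_sd(spec[[nm]], nm)
  if (spec$family_size_mean < 1)
    stop("invalid cohort_spec field 'family_size_mean': must be >= 1", call. = FALSE)
  if (!is.finite(spec$icc_target) || spec$icc_target < 0 || spec$icc_target > 1)
    stop("invalid cohort_spec field 'icc_target': must be in [0, 1]", call. = FALSE)
  if (!is.finite(spec$divergence_eyo) || spec$divergence_eyo >= 0)
    stop("invalid cohort_spec field 'divergence_eyo': must be negative (pre-onset)",
         call. = FALSE)
  if (!all(c("asym_MC", "sym_MC") %in% names(spec$eyo_params)))
    stop("invalid cohort_spec field 'eyo_params': needs 'asym_MC' and 'sym_MC' entries",
         call. = FALSE)
  if (!("NC" %in% names(spec$age_params)))
    stop("invalid cohort_spec field 'age_params': needs an 'NC' entry", call. = FALSE)
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic ADAD cohort specification\n")
  cat(sprintf("  groups: NC = %d, asym_MC = %d, sym_MC = %d\n",
              x$n_nc, x$n_asym_mc, x$n_sym_mc))
  cat(sprintf("  sites/scanners: %d / %d (site shift SD %.2f y, scanner scale SD %.3f)\n",
              x$n_sites, x$n_scanners, x$site_shift_sd, x$scanner_scale_sd))
  cat(sprintf("  BAG trajectory: divergence at EYO %.1f, symptomatic elevation %.1f y\n",
              x$divergence_eyo, x$sym_elevation))
  cat(sprintf("  noise SD %.1f y, family SD %.1f y, sex effect %+.2f y, education slope %+.2f y/y\n",
              x$noise_sd, x$family_sd, x$sex_effect, x$education_slope))
  cat(sprintf("  biomarkers: %s\n", paste(names(x$biomarker_params), collapse = ", ")))
  invisible(x)
}

# Scale of the quadratic ramp: solves
#   E[ scale * (Y)+^2 ] = sym_elevation,  Y = EYO - divergence_eyo,
# with EYO ~ N(mean, sd) of the symptomatic group. Closed form via the
# truncated-normal second moment.
ramp_scale <- function(spec) {
  m <- spec$eyo_params$sym_MC[["mean"]] - spec$divergence_eyo
  s <- spec$eyo_params$sym_MC[["sd"]]
  if (s <= 0) {
    e2 <- max(m, 0)^2
  } else {
    z <- m / s
    e2 <- (m^2 + s^2) * stats::pnorm(z) + m * s * stats::dnorm(z)
  }
  if (e2 <= 0)
    stop("ramp calibration failed: symptomatic EYO distribution lies entirely before divergence_eyo")
  spec$sym_elevation / e2
}

#' Ground-truth BAG trajectory of the generator
#'
#' The generative mean BAG as a function of estimated years to symptom onset
#' (EYO). Non-carriers have zero trajectory everywhere. Carriers are zero up
#' to `spec$divergence_eyo` and then follow a quadratic ramp
#' `scale * (eyo - divergence_eyo)^2`, which is continuously differentiable at
#' onset; `scale` is calibrated so that the expected value of the ramp over
#' the symptomatic-stage EYO distribution equals `spec$sym_elevation`.
#'
#' @param eyo numeric vector of EYO values (years).
#' @param group one of `"NC"`, `"asym_MC"`, `"sym_MC"` (any carrier group
#'   follows the same ramp; the group label determines only carrier status).
#' @param spec a [cohort_spec()].
#' @return Numeric vector of mean BAG values (years).
#' @export
#' @examples
#' spec <- cohort_spec()
#' true_bag_curve(c(-20, -7, 0, 5), "sym_MC", spec)
true_bag_curve <- function(eyo, group, spec) {
  group <- match.arg(group, cohort_groups)
  if (group == "NC") return(rep(0, length(eyo)))
  sc <- ramp_scale(spec)
  sc * pmax(eyo - spec$divergence_eyo, 0)^2
}

#' Generate a synthetic ADAD-like cohort
#'
#' Draws a complete per-participant table with known ground truth. Families
#' are sampled with `1 + Poisson(family_size_mean - 1)` sizes and contain both
#' carrier and non-carrier members; each family carries a single mutation
#' variant, a single expected symptom-onset age, and a shared random
#' intercept on true BAG. Carrier EYO values are drawn from the group EYO
#' distributions and chronological age is `onset + EYO`; non-carrier ages are
#' drawn directly and their (bookkeeping) EYO is `age - family onset age`.
#'
#' The raw predicted age is assembled as
#' `(age + true_bag + site_shift) * scanner_factor + noise`, where
#' `true_bag = trajectory(eyo, group) + sex/education offsets + family
#' intercept`. Ground-truth columns are prefixed `true_` and can be dropped
#' when writing with [write_cohort()]'s `blind` option.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed; defaults to `spec$seed`. Identical
#'   `spec` + `seed` yield byte-identical tables.
#' @param n_slices if positive, also generate this many per-slice predictions
#'   per participant (columns `slice_1 ... slice_k`), constructed so their
#'   median equals `raw_predicted_age` exactly.
#' @return A `data.frame` with one row per participant (see Details for the
#'   column dictionary in `vignette("bag-trajectories")`).
#' @export
generate_cohort <- function(spec, seed = spec$seed, n_slices = 0L) {
  validate_cohort_spec(spec)
  set.seed(seed)
  n <- spec$n_nc + spec$n_asym_mc + spec$n_sym_mc
  if (n == 0L) return(empty_cohort(spec, n_slices))

  group <- factor(rep(cohort_groups, c(spec$n_nc, spec$n_asym_mc, spec$n_sym_mc)),
                  levels = cohort_groups)
  carrier <- group != "NC"

  ## -- families ------------------------------------------------------------
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, 1L + stats::rpois(max(16L, ceiling(n / spec$family_size_mean)),
                                        spec$family_size_mean - 1))
  sizes <- sizes[cumsum(sizes) - sizes < n]          # families actually used
  n_fam <- length(sizes)
  fam_of <- rep(seq_len(n_fam), sizes)[seq_len(n)]
  fam_of <- fam_of[sample.int(n)]                    # mix groups across families

  fam_site <- sample.int(spec$n_sites, n_fam, replace = TRUE)
  # multi-site eligibility rule: only sites with at least 5 participants are
  # used; families at undersized sites are folded into the largest other site
  repeat {
    sizes <- tabulate(fam_site[fam_of], nbins = spec$n_sites)
    nonempty <- which(sizes > 0)
    small <- nonempty[sizes[nonempty] < 5]
    if (length(small) == 0 || length(nonempty) < 2) break
    s <- small[1]
    others <- setdiff(nonempty, s)
    target <- others[which.max(sizes[others])]
    fam_site[fam_site == s] <- target
  }

  fam_variant <- sample(names(spec$variant_probs), n_fam, replace = TRUE,
                        prob = spec$variant_probs)
  fam_onset <- stats::rnorm(n_fam,
                            spec$onset_params$means[fam_variant],
                            spec$onset_params$sd)
  site_scanner <- sample.int(spec$n_scanners, spec$n_sites, replace = TRUE)
  site_shift <- stats::rnorm(spec$n_sites, 0, spec$site_shift_sd)
  scanner_logscale <- stats::rnorm(spec$n_scanners, 0, spec$scanner_scale_sd)
  fam_u <- stats::rnorm(n_fam, 0, spec$family_sd)

  ## -- demographics ---------------------------------------------------------
  sex <- factor(ifelse(stats::runif(n) < 0.55, "F", "M"), levels = c("F", "M"))
  education <- pmin(pmax(round(stats::rnorm(n, 14.8, 2.8)), 8), 20)
  apoe4 <- stats::rbinom(n, 1L, 0.31)

  ## -- age / EYO ------------------------------------------------------------
  age <- numeric(n)
  eyo <- numeric(n)
  onset <- fam_onset[fam_of]
  nc <- which(!carrier)
  age[nc] <- pmin(pmax(stats::rnorm(length(nc),
                                    spec$age_params$NC[["mean"]],
                                    spec$age_params$NC[["sd"]]), 18), 75)
  eyo[nc] <- age[nc] - onset[nc]
  for (g in c("asym_MC", "sym_MC")) {
    idx <- which(group == g)
    eyo[idx] <- stats::rnorm(length(idx),
                             spec$eyo_params[[g]][["mean"]],
                             spec$eyo_params[[g]][["sd"]])
    age[idx] <- onset[idx] + eyo[idx]
  }

  cdr <- numeric(n)
  sym <- which(group == "sym_MC")
  cdr[sym] <- sample(c(0.5, 1, 2), length(sym), replace = TRUE,
                     prob = c(0.59, 0.35, 0.06))

  ## -- true BAG and raw prediction ------------------------------------------
  curve <- ifelse(carrier,
                  true_bag_curve(eyo, "asym_MC", spec),
                  0)
  demo <- spec$sex_effect * (sex == "M") +
    spec$education_slope * (education - 14.8)
  true_bag <- curve + demo + fam_u[fam_of]
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  scanner_id <- site_scanner[fam_site[fam_of]]
  raw <- (age + true_bag + site_shift[fam_site[fam_of]]) *
    exp(scanner_logscale[scanner_id]) + noise

  ## -- biomarkers through a shared latent severity --------------------------
  zbag <- numeric(n)
  for (g in cohort_groups) {
    idx <- which(group == g)
    if (length(idx) > 1 && stats::sd(true_bag[idx]) > 0)
      zbag[idx] <- (true_bag[idx] - mean(true_bag[idx])) / stats::sd(true_bag[idx])
  }
  gi <- as.integer(group)
  biomarkers <- lapply(spec$biomarker_params, function(p) {
    r <- p$r[as.character(group)]
    eps <- stats::rnorm(n)
    exp(p$meanlog[gi] + p$sdlog[gi] * (r * zbag + sqrt(1 - r^2) * eps))
  })

  cp <- spec$cognition_params
  rg <- cp$r[as.character(group)]
  cognitive_composite <- cp$mean[as.character(group)] +
    cp$sd[as.character(group)] * (rg * zbag + sqrt(1 - rg^2) * stats::rnorm(n))

  cdr_sb <- numeric(n)
  if (length(sym)) {
    zs <- zbag[sym]
    cdr_sb[sym] <- pmax(0.5, 5 + 3 * (0.61 * zs + sqrt(1 - 0.61^2) * stats::rnorm(length(sym))))
  }

  out <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    family_id = factor(sprintf("F%03d", fam_of)),
    site_id = factor(sprintf("S%02d", fam_site[fam_of])),
    scanner_id = factor(sprintf("SC%02d", scanner_id)),
    group = group,
    variant = factor(fam_variant[fam_of], levels = names(spec$variant_probs)),
    age = age, eyo = eyo, sex = sex, education = education,
    apoe4 = apoe4, cdr = cdr,
    raw_predicted_age = raw,
    stringsAsFactors = FALSE)
  for (nm in names(biomarkers)) out[[nm]] <- unname(biomarkers[[nm]])
  out$cognitive_composite <- unname(cognitive_composite)
  out$cdr_sb <- cdr_sb
  out$true_bag <- true_bag
  out$true_curve <- curve
  out$true_site_shift <- site_shift[fam_site[fam_of]]

  if (n_slices > 0L) {
    dev <- matrix(stats::rnorm(n * n_slices, 0, 8), n, n_slices)
    dev <- dev - apply(dev, 1, stats::median)   # per-row median exactly 0
    slices <- raw + dev
    colnames(slices) <- sprintf("slice_%d", seq_len(n_slices))
    out <- cbind(out, as.data.frame(slices))
  }
  rownames(out) <- NULL
  out
}

empty_cohort <- function(spec, n_slices = 0L) {
  out <- data.frame(
    participant_id = character(0),
    family_id = factor(character(0)),
    site_id = factor(character(0)),
    scanner_id = factor(character(0)),
    group = factor(character(0), levels = cohort_groups),
    variant = factor(character(0), levels = names(spec$variant_probs)),
    age = numeric(0), eyo = numeric(0),
    sex = factor(character(0), levels = c("F", "M")),
    education = numeric(0), apoe4 = integer(0), cdr = numeric(0),
    raw_predicted_age = numeric(0), stringsAsFactors = FALSE)
  for (nm in names(spec$biomarker_params)) out[[nm]] <- numeric(0)
  out$cognitive_composite <- numeric(0)
  out$cdr_sb <- numeric(0)
  out$true_bag <- numeric(0)
  out$true_curve <- numeric(0)
  out$true_site_shift <- numeric(0)
  if (n_slices > 0L)
    for (j in seq_len(n_slices)) out[[sprintf("slice_%d", j)]] <- numeric(0)
  out
}

#' Generate a retest (second-visit) prediction table
#'
#' Constructs second-visit predicted ages whose population ICC(A,1) with the
#' first visit equals `icc_target`, by the variance-partition construction
#' `y2 = m + rho * (y1 - m) + sd(y1) * sqrt(1 - rho^2) * z` with
#' `m = mean(y1)` and independent standard-normal `z`: means and variances of
#' the two visits agree, so absolute-agreement and consistency ICC coincide
#' and both equal `rho` in the population. `icc_target = 1` reproduces visit 1
#' exactly; `icc_target = 0` yields an independent retest.
#'
#' @param table a cohort table from [generate_cohort()] (uses
#'   `raw_predicted_age` as the first visit).
#' @param icc_target target population ICC(A,1), in `[0, 1]`.
#' @param interval_years nominal scan interval recorded in the output.
#' @param seed integer RNG seed.
#' @return `data.frame` with `participant_id`, `visit1`, `visit2`,
#'   `interval_years`.
#' @export
generate_retest <- function(table, icc_target, interval_years = 2.11, seed = 1L) {
  if (!is.finite(icc_target) || icc_target < 0 || icc_target > 1)
    stop("icc_target must be in [0, 1]", call. = FALSE)
  y1 <- table$raw_predicted_age
  set.seed(seed)
  m <- mean(y1)
  s <- stats::sd(y1)
  if (!is.finite(s)) s <- 0
  y2 <- m + icc_target * (y1 - m) +
    s * sqrt(1 - icc_target^2) * stats::rnorm(length(y1))
  data.frame(participant_id = table$participant_id,
             visit1 = y1, visit2 = y2,
             interval_years = interval_years)
}

#' Add a second synthetic MRI-like measure to a cohort
#'
#' Creates an additional noisy measure column sharing the cohort's EYO and
#' group structure but with its own divergence point and elevation, for
#' between-measure divergence comparisons (e.g., a stand-in for a cortical
#' thickness signature expressed in BAG-like units). The measure is
#' `trajectory(eyo) + family intercept share + noise` for carriers and pure
#' noise around zero for non-carriers.
#'
#' @param table cohort table from [generate_cohort()].
#' @param name column name for the new measure.
#' @param divergence_eyo,elevation ramp onset (years, negative) and mean
#'   symptomatic-stage elevation (years) for the new measure.
#' @param noise_sd per-observation noise SD (years).
#' @param spec the [cohort_spec()] used to generate `table` (supplies the
#'   symptomatic EYO distribution for ramp calibration).
#' @param seed integer RNG seed.
#' @return `table` with the new column appended, plus a `true_<name>` column.
#' @export
add_synthetic_measure <- function(table, name, divergence_eyo, elevation,
                                  noise_sd, spec, seed = 1L) {
  spec2 <- spec
  spec2$divergence_eyo <- divergence_eyo
  spec2$sym_elevation <- elevation
  validate_cohort_spec(spec2)
  set.seed(seed)
  carrier <- table$group != "NC"
  curve <- ifelse(carrier, true_bag_curve(table$eyo, "asym_MC", spec2), 0)
  vals <- curve + stats::rnorm(nrow(table), 0, noise_sd)
  table[[paste0("true_", name)]] <- curve
  table[[name]] <- vals
  table
}
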