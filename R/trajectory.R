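#' Cubic regression spline basis with curvature penalty
#'
#' Builds a natural cubic regression spline ("cr") basis with `k` basis
#' functions and knots at evenly spaced quantiles of `x` (or user-supplied
#' knots), together with the integrated squared-second-derivative penalty
#' matrix. The penalty's null space is the space of linear functions of `x`.
#'
#' @param x numeric covariate values with at least `k` distinct values.
#' @param k number of basis functions (>= 3; default 4).
#' @param knots optional numeric vector of `k` knot locations.
#' @return Object of class `bag_spline_basis` with elements `X` (design
#'   columns, un-constrained), `S` (penalty matrix), `knots`, `k`, and the
#'   underlying smooth construction for evaluation at new points.
#' @export
build_cr_basis <- function(x, k = 4L, knots = NULL) {
  if (k < 3) stop("k must be >= 3", call. = FALSE)
  if (length(unique(x)) < k)
    stop(sprintf("need at least k = %d distinct x values (got %d)",
                 k, length(unique(x))), call. = FALSE)
  kn <- if (is.null(knots)) NULL else list(x = knots)
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"),
                        data = data.frame(x = x), knots = kn,
                        absorb.cons = FALSE)[[1]]
  structure(list(X = sm$X, S = sm$S[[1]], knots = sm$xp, k = k, smooth = sm),
            class = "bag_spline_basis")
}

#' Evaluate a spline basis at new covariate values
#' @param basis a [build_cr_basis()] result.
#' @param x numeric vector of new covariate values.
#' @return Design matrix with `k` columns.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "bag_spline_basis"))
  mgcv::PredictMat(basis$smooth, data.frame(x = x))
}

#' Fit the BAG-trajectory GAMM
#'
#' Penalized-spline generalized additive mixed model of a measure against
#' estimated years to symptom onset (EYO), with separate cubic regression
#' spline smooths (`k` basis functions each) for non-carriers and mutation
#' carriers, a carrier-status main effect, linear/categorical covariate terms,
#' and a family random intercept expressed as a penalized ("re") smooth.
#' Smoothing parameters and the random-intercept variance are selected by
#' REML; the returned coefficient covariance is the Bayesian posterior form
#' used for simultaneous bands.
#'
#' @param table cohort table; needs `eyo`, `family_id`, the response column,
#'   the covariates, and either a `mutation_status` factor (`NC`/`MC`) or a
#'   `group` column from which carrier status is derived.
#' @param response name of the response column (e.g. `"bag"`).
#' @param k basis dimension per smooth (default 4).
#' @param covariates covariate column names entering linearly (factors
#'   allowed).
#' @param family_re include the family random intercept (default `TRUE`).
#' @param sp optional fixed smoothing parameters passed to [mgcv::gam()]
#'   (ordered: NC smooth, MC smooth, then the family term if present; use
#'   `-1` to leave an entry estimated).
#' @param engine `"gam"` (exact REML, default) or `"bam"`
#'   (`method = "fREML"`, `discrete = TRUE`; much faster, used for
#'   bootstrap-scale refitting).
#' @return Object of class `bag_gamm`: the `mgcv` fit plus metadata
#'   (`edf` per smooth, `family_sd`, `residual_sd`, `reml`, covariate
#'   reference values used for prediction).
#' @export
fit_gamm <- function(table, response = "bag", k = 4L,
                     covariates = c("sex", "education", "apoe4"),
                     family_re = TRUE, sp = NULL,
                     engine = c("gam", "bam")) {
  engine <- match.arg(engine)
  needed <- c("eyo", response, covariates, if (family_re) "family_id")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  dat <- table
  if (is.null(dat$mutation_status)) {
    if (is.null(dat$group))
      stop("need a 'mutation_status' or 'group' column", call. = FALSE)
    dat$mutation_status <- factor(ifelse(dat$group == "NC", "NC", "MC"),
                                  levels = c("NC", "MC"))
  }
  dat$mutation_status <- droplevels(as.factor(dat$mutation_status))
  if (nlevels(dat$mutation_status) < 2)
    stop("both carrier and non-carrier rows are required", call. = FALSE)
  if (family_re) {
    dat$family_id <- droplevels(as.factor(dat$family_id))
    if (nlevels(dat$family_id) < 2)
      stop("need at least 2 families for the random intercept", call. = FALSE)
  }
  dat <- dat[stats::complete.cases(dat[needed]), , drop = FALSE]

  rhs <- c("mutation_status",
           sprintf("s(eyo, by = mutation_status, k = %d, bs = \"cr\")", k),
           covariates,
           if (family_re) "s(family_id, bs = \"re\")")
  fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  gfit <- if (engine == "bam")
    mgcv::bam(fml, data = dat, method = "fREML", discrete = TRUE, sp = sp)
  else mgcv::gam(fml, data = dat, method = "REML", sp = sp)

  sm_names <- vapply(gfit$smooth, function(s) s$label, character(1))
  edf_all <- smooth_edfs(gfit)
  family_sd <- NA_real_
  if (family_re) {
    i_re <- grep("family_id", sm_names)
    sp_re <- gfit$sp[grep("family_id", names(gfit$sp))]
    if (length(sp_re) == 1 && is.finite(sp_re) && sp_re > 0)
      family_sd <- unname(sqrt(gfit$sig2 / sp_re))
  }
  ref <- covariate_reference(dat, covariates)
  structure(list(gam = gfit, response = response, k = k,
                 covariates = covariates, family_re = family_re,
                 edf = edf_all, family_sd = family_sd,
                 residual_sd = sqrt(gfit$sig2),
                 reml = as.numeric(gfit$gcv.ubre),
                 eyo_range = range(dat$eyo),
                 cov_ref = ref, n = nrow(dat),
                 smooth_labels = sm_names),
            class = "bag_gamm")
}

smooth_edfs <- function(gfit) {
  vapply(seq_along(gfit$smooth), function(i) {
    s <- gfit$smooth[[i]]
    sum(gfit$edf[s$first.para:s$last.para])
  }, numeric(1))
}

covariate_reference <- function(dat, covariates) {
  ref <- lapply(covariates, function(v) {
    x <- dat[[v]]
    if (is.numeric(x)) mean(x) else factor(levels(as.factor(x))[1],
                                           levels = levels(as.factor(x)))
  })
  names(ref) <- covariates
  ref
}

#' @export
print.bag_gamm <- function(x, ...) {
  cat(sprintf("BAG trajectory GAMM: %s ~ s(eyo) by carrier status (k = %d), n = %d\n",
              x$response, x$k, x$n))
  st <- summary(x$gam)$s.table
  print(round(st, 4))
  if (x$family_re)
    cat(sprintf("family random-intercept SD = %.3f, residual SD = %.3f, REML = %.2f\n",
                x$family_sd, x$residual_sd, x$reml))
  invisible(x)
}

#' EDF and approximate p-value of a smooth term
#'
#' Effective degrees of freedom (trace of the smoother sub-block) and the
#' Wald-type test on the smooth coefficients with an EDF-adjusted reference
#' distribution, as reported by [mgcv::summary.gam()].
#'
#' @param fit a [fit_gamm()] result.
#' @param term `"NC"`, `"MC"` (the per-group EYO smooths) or `"family"`.
#' @return Named numeric vector `c(edf, p)`.
#' @export
smooth_term_test <- function(fit, term = c("MC", "NC", "family")) {
  stopifnot(inherits(fit, "bag_gamm"))
  term <- match.arg(term)
  st <- summary(fit$gam)$s.table
  pattern <- switch(term,
                    MC = "mutation_statusMC",
                    NC = "mutation_statusNC",
                    family = "family_id")
  row <- grep(pattern, rownames(st), fixed = TRUE)
  if (length(row) != 1) stop(sprintf("unknown term '%s' in fit", term), call. = FALSE)
  c(edf = unname(st[row, "edf"]), p = unname(st[row, "p-value"]))
}

#' Simultaneous confidence band for a group trajectory
#'
#' Critical-value-corrected band for the fitted EYO trajectory of one group,
#' valid jointly over the whole evaluation grid. `n_draws` coefficient
#' vectors are drawn from the Bayesian posterior `N(beta_hat, Vp)`; the
#' multiplier `m` is the `level` quantile of the maximal standardized absolute
#' deviation over the grid, and the band is `fit +/- m * SE`. Covariates are
#' held at reference values (numeric means / first factor level) and the
#' family random intercept is excluded, so the band describes the population
#' trajectory.
#'
#' @param fit a [fit_gamm()] result.
#' @param group `"NC"` or `"MC"`.
#' @param grid numeric EYO grid (must lie within the observed EYO range);
#'   default: observed range at `grid_step` spacing.
#' @param grid_step grid spacing when `grid` is `NULL` (default 0.01).
#' @param level simultaneous coverage level (default 0.834, the
#'   pairwise-comparison convention whose non-overlap approximates a
#'   two-group test at alpha ~ 0.05).
#' @param n_draws number of posterior draws (default 10000).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return Object of class `bag_band`: data.frame `band` (`eyo`, `fit`,
#'   `lower`, `upper`), multiplier `m`, `level`, `group`, `n_draws`.
#' @export
simultaneous_band <- function(fit, group, grid = NULL, grid_step = 0.01,
                              level = 0.834, n_draws = 10000L, seed = NULL) {
  stopifnot(inherits(fit, "bag_gamm"))
  group <- match.arg(group, c("NC", "MC"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid))
    grid <- seq(fit$eyo_range[1], fit$eyo_range[2], by = grid_step)
  if (min(grid) < fit$eyo_range[1] - 1e-8 || max(grid) > fit$eyo_range[2] + 1e-8)
    stop("grid extends outside the observed EYO range", call. = FALSE)

  Xp <- band_lpmatrix(fit, group, grid)
  core <- band_from_lpmatrix(Xp, stats::coef(fit$gam), fit$gam$Vp,
                             level = level, n_draws = n_draws)
  structure(list(band = data.frame(eyo = grid, fit = core$fit,
                                   lower = core$lower, upper = core$upper,
                                   se = core$se),
                 m = core$m, level = level, group = group, n_draws = n_draws),
            class = "bag_band")
}

band_from_lpmatrix <- function(Xp, beta, Vp, level, n_draws) {
  fit_vals <- drop(Xp %*% beta)
  se <- sqrt(pmax(rowSums((Xp %*% Vp) * Xp), 1e-300))
  draws <- mgcv::rmvn(n_draws, beta, Vp)
  maxstat <- max_abs_std_dev(draws, beta, Xp, se)
  m <- unname(stats::quantile(maxstat, level))
  list(fit = fit_vals, lower = fit_vals - m * se, upper = fit_vals + m * se,
       se = se, m = m)
}

#' Simultaneous band for an arbitrary mgcv fit
#'
#' Lower-level interface behind [simultaneous_band()]: computes the
#' simulation-based simultaneous confidence band for the linear predictor of
#' any [mgcv::gam()]/[mgcv::bam()] fit over the rows of `newdata`.
#'
#' @param gfit an mgcv fit.
#' @param newdata prediction data.frame.
#' @param level simultaneous coverage level.
#' @param n_draws number of posterior draws.
#' @param seed optional RNG seed (`NULL`: continue current stream).
#' @param exclude optional fixed substring; lpmatrix columns whose names
#'   contain it are zeroed (e.g. `"s(family_id)"` to drop random effects).
#' @return List with `fit`, `lower`, `upper`, `se`, `m`.
#' @export
gam_simultaneous_band <- function(gfit, newdata, level = 0.834,
                                  n_draws = 10000L, seed = NULL,
                                  exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Xp <- stats::predict(gfit, newdata = newdata, type = "lpmatrix")
  if (!is.null(exclude)) {
    cols <- grep(exclude, colnames(Xp), fixed = TRUE)
    if (length(cols)) Xp[, cols] <- 0
  }
  band_from_lpmatrix(Xp, stats::coef(gfit), gfit$Vp,
                     level = level, n_draws = n_draws)
}

band_lpmatrix <- function(fit, group, grid) {
  nd <- data.frame(eyo = grid,
                   mutation_status = factor(group, levels = c("NC", "MC")))
  for (v in names(fit$cov_ref)) nd[[v]] <- fit$cov_ref[[v]]
  if (fit$family_re) {
    fam_lev <- fit$gam$model$family_id
    nd$family_id <- factor(levels(fam_lev)[1], levels = levels(fam_lev))
  }
  Xp <- stats::predict(fit$gam, newdata = nd, type = "lpmatrix")
  re_cols <- grep("s(family_id)", colnames(Xp), fixed = TRUE)
  if (length(re_cols)) Xp[, re_cols] <- 0
  Xp
}

## max over grid of |Xp (b - beta)| / se per posterior draw, in column blocks
max_abs_std_dev <- function(draws, beta, Xp, se, block = 512L) {
  nd <- nrow(draws)
  centered <- sweep(draws, 2, beta)
  maxstat <- rep(0, nd)
  G <- nrow(Xp)
  for (start in seq(1, G, by = block)) {
    idx <- start:min(start + block - 1, G)
    Xb <- Xp[idx, , drop = FALSE] / se[idx]
    M <- abs(centered %*% t(Xb))
    maxstat <- do.call(pmax, c(list(maxstat),
                               lapply(seq_len(ncol(M)), function(j) M[, j])))
  }
  maxstat
}

#' @export
print.bag_band <- function(x, ...) {
  cat(sprintf("Simultaneous %.1f%% band for %s trajectory: %d grid points, m = %.3f\n",
              100 * x$level, x$group, nrow(x$band), x$m))
  invisible(x)
}

#' Earliest EYO of sustained band separation
#'
#' Scans a shared EYO grid for the earliest point from which the two groups'
#' simultaneous bands do not overlap at every subsequent grid point up to the
#' grid maximum (sustained-separation rule, which suppresses isolated
#' crossings). Returns `NA` when no such point exists.
#'
#' @param band_mc,band_nc [simultaneous_band()] results on identical grids.
#' @return Earliest divergence EYO (years) or `NA_real_`.
#' @export
find_divergence <- function(band_mc, band_nc) {
  stopifnot(inherits(band_mc, "bag_band"), inherits(band_nc, "bag_band"))
  if (!isTRUE(all.equal(band_mc$band$eyo, band_nc$band$eyo)))
    stop("bands are on different grids", call. = FALSE)
  sep <- band_mc$band$lower > band_nc$band$upper |
    band_mc$band$upper < band_nc$band$lower
  sustained <- rev(cumprod(rev(sep))) > 0
  if (!any(sustained)) return(NA_real_)
  band_mc$band$eyo[which(sustained)[1]]
}

#' Fit, band, and locate divergence for one measure
#'
#' Convenience wrapper: fits the GAMM for `response`, computes both groups'
#' simultaneous bands on a common grid, and returns the earliest sustained
#' divergence EYO.
#'
#' @inheritParams fit_gamm
#' @inheritParams simultaneous_band
#' @return List with `fit`, `band_nc`, `band_mc`, `eyo_star`.
#' @export
divergence_point <- function(table, response = "bag", k = 4L,
                             covariates = c("sex", "education", "apoe4"),
                             grid = NULL, grid_step = 0.01, level = 0.834,
                             n_draws = 10000L, seed = NULL, family_re = TRUE,
                             engine = c("gam", "bam")) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_gamm(table, response = response, k = k, covariates = covariates,
                  family_re = family_re, engine = engine)
  if (is.null(grid))
    grid <- seq(fit$eyo_range[1], fit$eyo_range[2], by = grid_step)
  b_nc <- simultaneous_band(fit, "NC", grid = grid, level = level,
                            n_draws = n_draws)
  b_mc <- simultaneous_band(fit, "MC", grid = grid, level = level,
                            n_draws = n_draws)
  list(fit = fit, band_nc = b_nc, band_mc = b_mc,
       eyo_star = find_divergence(b_mc, b_nc))
}

#' Bootstrap distribution and comparison of divergence EYOs
#'
#' Resamples participants with replacement (stratified by mutation group, or
#' whole families with `resample = "family"`), refits the GAMM for every
#' measure per replicate, and records each measure's earliest divergence EYO;
#' replicates without divergence are censored at the grid maximum and
#' counted. Reports per-measure median and 95% percentile interval, and
#' pairwise between-measure p-values
#' `2 * min(Pr(diff < 0), Pr(diff > 0))` (ties split evenly) over the paired
#' replicate differences.
#'
#' @param table cohort table containing every measure column.
#' @param measures character vector of response columns to compare.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed controlling the whole procedure (resampling and
#'   posterior draws); identical seed + `n_boot` give identical results.
#' @param grid_step,level,n_draws,k,covariates,family_re model/band settings
#'   per replicate (coarser defaults than the primary analysis for speed).
#' @param resample `"participant"` (default) or `"family"`.
#' @param engine GAMM engine for the refits; default `"bam"` for speed.
#' @param fix_sp hold smoothing parameters (and the random-intercept
#'   variance ratio) at their full-sample REML estimates inside the
#'   bootstrap, refitting only coefficients and random intercepts per
#'   replicate (default `TRUE`; set `FALSE` to re-estimate them in every
#'   replicate).
#' @return Object of class `bag_divergence_boot`: per-measure summary table,
#'   the replicate-by-measure matrix of divergence EYOs, censoring counts,
#'   and the pairwise p-value matrix.
#' @export
bootstrap_divergence <- function(table, measures, n_boot = 500L, seed = 1L,
                                 grid_step = 0.1, level = 0.834,
                                 n_draws = 1000L, k = 4L,
                                 covariates = c("sex", "education", "apoe4"),
                                 family_re = TRUE,
                                 resample = c("participant", "family"),
                                 engine = c("bam", "gam"), fix_sp = TRUE) {
  resample <- match.arg(resample)
  engine <- match.arg(engine)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  missing_cols <- setdiff(measures, names(table))
  if (length(missing_cols))
    stop(sprintf("missing measure column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  sp_full <- NULL
  if (fix_sp) {
    sp_full <- lapply(measures, function(m) {
      full <- fit_gamm(table, response = m, k = k, covariates = covariates,
                       family_re = family_re, engine = engine)
      unname(full$gam$sp)
    })
    names(sp_full) <- measures
  }
  set.seed(seed)
  grid <- seq(min(table$eyo), max(table$eyo), by = grid_step)
  grid_max <- max(grid)
  res <- matrix(NA_real_, n_boot, length(measures),
                dimnames = list(NULL, measures))
  cens <- matrix(FALSE, n_boot, length(measures),
                 dimnames = list(NULL, measures))
  groups <- split(seq_len(nrow(table)), table$group, drop = TRUE)
  fams <- split(seq_len(nrow(table)), table$family_id, drop = TRUE)

  for (b in seq_len(n_boot)) {
    idx <- if (resample == "participant") {
      unlist(lapply(groups, function(ix) sample(ix, length(ix), replace = TRUE)),
             use.names = FALSE)
    } else {
      unlist(fams[sample(seq_along(fams), length(fams), replace = TRUE)],
             use.names = FALSE)
    }
    boot_tab <- table[idx, , drop = FALSE]
    g_lo <- max(min(boot_tab$eyo), min(grid))
    g_hi <- min(max(boot_tab$eyo), max(grid))
    g <- grid[grid >= g_lo & grid <= g_hi]
    for (m in measures) {
      e_star <- tryCatch({
        fit <- if (fix_sp)
          fit_gamm(boot_tab, response = m, k = k, covariates = covariates,
                   family_re = family_re, engine = "gam", sp = sp_full[[m]])
        else fit_gamm(boot_tab, response = m, k = k, covariates = covariates,
                      family_re = family_re, engine = engine)
        b_nc <- simultaneous_band(fit, "NC", grid = g, level = level,
                                  n_draws = n_draws)
        b_mc <- simultaneous_band(fit, "MC", grid = g, level = level,
                                  n_draws = n_draws)
        find_divergence(b_mc, b_nc)
      }, error = function(e) NA_real_)
      if (is.na(e_star)) {
        res[b, m] <- grid_max
        cens[b, m] <- TRUE
      } else res[b, m] <- e_star
    }
  }

  summary_tab <- do.call(rbind, lapply(measures, function(m) {
    x <- res[, m]
    n_cen <- sum(cens[, m])
    one_sided <- n_cen > n_boot / 2
    ci <- if (one_sided)
      c(unname(stats::quantile(x, 0.05)), NA_real_)
    else unname(stats::quantile(x, c(0.025, 0.975)))
    data.frame(measure = m, median = stats::median(x),
               ci_low = ci[1], ci_high = ci[2],
               n_censored = n_cen, one_sided = one_sided)
  }))
  pmat <- matrix(NA_real_, length(measures), length(measures),
                 dimnames = list(measures, measures))
  if (length(measures) > 1) {
    for (i in seq_along(measures)) for (j in seq_along(measures)) {
      if (i >= j) next
      d <- res[, i] - res[, j]
      p <- 2 * min(mean(d < 0) + 0.5 * mean(d == 0),
                   mean(d > 0) + 0.5 * mean(d == 0))
      pmat[i, j] <- pmat[j, i] <- min(p, 1)
    }
  }
  structure(list(summary = summary_tab, draws = res, censored = cens,
                 pairwise_p = pmat, n_boot = n_boot, seed = seed,
                 level = level, grid_range = range(grid)),
            class = "bag_divergence_boot")
}

#' @export
print.bag_divergence_boot <- function(x, ...) {
  cat(sprintf("Bootstrap divergence comparison (%d replicates, %.1f%% bands)\n",
              x$n_boot, 100 * x$level))
  print(x$summary, row.names = FALSE)
  if (nrow(x$summary) > 1) {
    cat("pairwise p-values:\n")
    print(round(x$pairwise_p, 4))
  }
  invisible(x)
}
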