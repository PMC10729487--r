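#' Omnibus and pairwise nonparametric group comparison
#'
#' Tie-corrected Kruskal-Wallis test across mutation groups followed by all
#' pairwise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg FDR
#' adjustment. Pairwise tests use exact enumeration when the combined group
#' size is at most 20 and there are no ties, and the normal approximation
#' with tie and continuity corrections otherwise.
#'
#' @param values numeric vector.
#' @param groups group labels (at least 2 non-empty groups).
#' @return Object of class `bag_group_comparison`: omnibus `statistic`, `df`,
#'   `p.value`, and a `pairwise` data.frame (`group1`, `group2`, `W`, `p`,
#'   `p_fdr`).
#' @export
group_comparison <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  omnibus <- if (length(unique(values)) == 1)
    list(statistic = 0, parameter = nlevels(groups) - 1, p.value = 1)
  else stats::kruskal.test(values, groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- values[groups == pairs[1, j]]
    g2 <- values[groups == pairs[2, j]]
    exact <- (length(g1) + length(g2)) <= 20 &&
      !any(duplicated(c(g1, g2)))
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = exact,
                                              correct = TRUE))
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               W = unname(wt$statistic), p = wt$p.value)
  }))
  pw$p_fdr <- stats::p.adjust(pw$p, method = "BH")
  structure(list(statistic = unname(omnibus$statistic),
                 df = unname(omnibus$parameter),
                 p.value = omnibus$p.value, pairwise = pw),
            class = "bag_group_comparison")
}

#' @export
print.bag_group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi2(%d) = %.2f, p = %.3g\n",
              x$df, x$statistic, x$p.value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' Classic Levene test: one-way ANOVA on the absolute deviations of each
#' observation from its group mean. If all deviations are zero (every group
#' constant) the statistic is defined as 0 with p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels; every group needs at least 2 members.
#' @return List with `statistic` (W), `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("group with fewer than 2 members", call. = FALSE)
  ad <- abs(values - stats::ave(values, groups))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  if (all(ad == 0))
    return(list(statistic = 0, df1 = df1, df2 = df2, p.value = 1))
  aov_tab <- stats::anova(stats::lm(ad ~ groups))
  list(statistic = aov_tab[["F value"]][1], df1 = df1, df2 = df2,
       p.value = aov_tab[["Pr(>F)"]][1])
}

#' Mixed-effects biomarker association model
#'
#' Linear mixed model of a response (BAG) on a biomarker with a group-by-
#' biomarker interaction, linear/categorical covariates, and a family random
#' intercept. Terms are tested with Wald F statistics (Satterthwaite
#' denominator degrees of freedom); partial eta squared per term is
#' `F * df1 / (F * df1 + df2)`.
#'
#' @param table cohort table.
#' @param biomarker biomarker column name (non-missing rows >= 20).
#' @param response response column (default `"bag"`).
#' @param covariates covariate column names.
#' @param group_col grouping factor column for the interaction (default
#'   `"group"`, with unused levels dropped).
#' @param transform optional function applied to the biomarker (e.g. `log`).
#' @return Object of class `bag_lme`: tidy `terms` table (term, estimate, se,
#'   F, df1, df2, p, eta_p2), `family_var`, `n`, and the underlying
#'   `lmerTest` fit.
#' @export
fit_lme_biomarker <- function(table, biomarker, response = "bag",
                              covariates = c("sex", "education", "apoe4"),
                              group_col = "group", transform = NULL) {
  needed <- c(biomarker, response, covariates, group_col, "family_id")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  dat <- table[stats::complete.cases(table[needed]), needed, drop = FALSE]
  if (nrow(dat) < 20)
    stop(sprintf("fewer than 20 non-missing rows for biomarker '%s'", biomarker),
         call. = FALSE)
  dat[[group_col]] <- droplevels(as.factor(dat[[group_col]]))
  dat$family_id <- droplevels(as.factor(dat$family_id))
  if (nlevels(dat$family_id) < 2) stop("need at least 2 families", call. = FALSE)
  if (!is.null(transform)) dat[[biomarker]] <- transform(dat[[biomarker]])
  if (stats::var(dat[[biomarker]]) == 0)
    stop(sprintf("biomarker '%s' is constant", biomarker), call. = FALSE)

  inter <- if (nlevels(dat[[group_col]]) > 1)
    sprintf("%s * %s", biomarker, group_col) else biomarker
  fml <- stats::as.formula(paste(response, "~", inter, "+",
                                 paste(covariates, collapse = " + "),
                                 "+ (1 | family_id)"))
  # biomarkers stay in raw units (betas are reported per unit), so the
  # X-scale advisory check is off
  fit <- lmerTest::lmer(fml, data = dat,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          check.scaleX = "ignore"))
  at <- suppressMessages(stats::anova(fit, type = 3))
  terms_tab <- data.frame(term = rownames(at),
                          F = at[["F value"]],
                          df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                          p = at[["Pr(>F)"]])
  terms_tab$eta_p2 <- with(terms_tab, F * df1 / (F * df1 + df2))
  cf <- summary(fit)$coefficients
  est <- data.frame(coef = rownames(cf), estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"], p_wald = cf[, "Pr(>|t|)"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  family_var <- vc$vcov[vc$grp == "family_id"]
  structure(list(terms = terms_tab, coefficients = est,
                 family_var = family_var, n = nrow(dat),
                 biomarker = biomarker, response = response, fit = fit),
            class = "bag_lme")
}

#' @export
print.bag_lme <- function(x, ...) {
  cat(sprintf("Mixed-effects association: %s ~ %s (n = %d, family var = %.3f)\n",
              x$response, x$biomarker, x$n, x$family_var))
  tt <- x$terms
  tt$F <- round(tt$F, 3); tt$p <- signif(tt$p, 3); tt$eta_p2 <- round(tt$eta_p2, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Within-group Pearson correlation with BAG
#'
#' @param table cohort table.
#' @param biomarker biomarker column.
#' @param group group label to subset on (`group` column).
#' @param response response column (default `"bag"`).
#' @return List with `r`, `p`, `n`.
#' @export
group_correlations <- function(table, biomarker, group, response = "bag") {
  rows <- table[!is.na(table[[biomarker]]) & !is.na(table[[response]]) &
                  table$group == group, , drop = FALSE]
  if (nrow(rows) < 3) stop("fewer than 3 rows in group", call. = FALSE)
  if (stats::var(rows[[biomarker]]) == 0 || stats::var(rows[[response]]) == 0)
    stop("constant input", call. = FALSE)
  ct <- stats::cor.test(rows[[biomarker]], rows[[response]])
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(rows))
}

#' Log-transform sensitivity analysis for biomarker models
#'
#' Refits [fit_lme_biomarker()] for each biomarker on the natural-log scale
#' and returns the original and log fits side by side. All biomarker values
#' must be strictly positive.
#'
#' @param table cohort table.
#' @param biomarkers character vector of biomarker columns.
#' @param ... passed to [fit_lme_biomarker()].
#' @return Named list per biomarker with elements `original` and `log`.
#' @export
log_sensitivity <- function(table, biomarkers, ...) {
  for (bm in biomarkers) {
    bad <- which(!is.na(table[[bm]]) & table[[bm]] <= 0)
    if (length(bad))
      stop(sprintf("biomarker '%s' has non-positive values in rows: %s",
                   bm, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
  }
  out <- lapply(biomarkers, function(bm) {
    list(original = fit_lme_biomarker(table, bm, ...),
         log = fit_lme_biomarker(table, bm, transform = log, ...))
  })
  names(out) <- biomarkers
  out
}

#' Nonparametric bootstrap mediation analysis
#'
#' Tests whether a mediator (BAG) carries the association between an exposure
#' (a biomarker) and an outcome (the cognitive composite). Two linear models
#' are fit on complete cases: `m ~ x + covariates` (path a) and
#' `y ~ x + m + covariates` (paths b and c'). The indirect effect is `a * b`,
#' the total effect `c` comes from `y ~ x + covariates`, and
#' `c = c' + a * b` holds exactly for nested least-squares fits. The
#' percentile confidence interval for the indirect effect is computed from
#' `n_boot` participant resamples (family clustering optionally respected
#' with `resample = "family"`).
#'
#' @param table cohort table.
#' @param x exposure column (biomarker).
#' @param m mediator column (default `"bag"`).
#' @param y outcome column (default `"cognitive_composite"`).
#' @param covariates covariate columns entering both sub-models.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param resample `"participant"` (default) or `"family"`.
#' @return Object of class `bag_mediation` with paths `a`, `b`, `indirect`,
#'   `direct`, `total`, the bootstrap CI, a `label`
#'   (`"partial mediation"`, `"full mediation"` or `"no mediation"`), `n`,
#'   `n_boot`, `seed`.
#' @export
mediate <- function(table, x, m = "bag", y = "cognitive_composite",
                    covariates = c("sex", "education", "apoe4"),
                    n_boot = 1000L, seed = 1L, conf = 0.95,
                    resample = c("participant", "family")) {
  resample <- match.arg(resample)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  needed <- c(x, m, y, covariates, "family_id")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  dat <- table[stats::complete.cases(table[needed]), needed, drop = FALSE]
  if (nrow(dat) < 30) stop("fewer than 30 complete cases", call. = FALSE)

  cov_rhs <- paste(covariates, collapse = " + ")
  f_m <- stats::as.formula(paste(m, "~", x, "+", cov_rhs))
  f_y <- stats::as.formula(paste(y, "~", x, "+", m, "+", cov_rhs))
  f_t <- stats::as.formula(paste(y, "~", x, "+", cov_rhs))
  paths <- function(d) {
    a <- stats::coef(stats::lm(f_m, data = d))[[x]]
    fy <- stats::coef(stats::lm(f_y, data = d))
    c(a = a, b = fy[[m]], direct = fy[[x]],
      total = stats::coef(stats::lm(f_t, data = d))[[x]])
  }
  est <- paths(dat)
  indirect <- est[["a"]] * est[["b"]]

  set.seed(seed)
  fams <- split(seq_len(nrow(dat)), dat$family_id, drop = TRUE)
  boot_ind <- vapply(seq_len(n_boot), function(b) {
    idx <- if (resample == "participant")
      sample.int(nrow(dat), replace = TRUE)
    else unlist(fams[sample(seq_along(fams), length(fams), replace = TRUE)],
                use.names = FALSE)
    p <- tryCatch(paths(dat[idx, , drop = FALSE]), error = function(e) c(a = NA_real_, b = NA_real_, direct = NA, total = NA))
    p[["a"]] * p[["b"]]
  }, numeric(1))
  boot_ind <- boot_ind[is.finite(boot_ind)]
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot_ind, c(alpha / 2, 1 - alpha / 2)))

  direct_p <- summary(stats::lm(f_y, data = dat))$coefficients[x, "Pr(>|t|)"]
  sig_ind <- ci[1] > 0 || ci[2] < 0
  label <- if (sig_ind && direct_p < 0.05) "partial mediation"
  else if (sig_ind) "full mediation"
  else "no mediation"

  structure(list(a = est[["a"]], b = est[["b"]], indirect = indirect,
                 direct = est[["direct"]], total = est[["total"]],
                 ci_low = ci[1], ci_high = ci[2], conf = conf,
                 label = label, n = nrow(dat), n_boot = n_boot, seed = seed,
                 x = x, m = m, y = y),
            class = "bag_mediation")
}

#' @export
print.bag_mediation <- function(x, ...) {
  cat(sprintf("Mediation %s -> %s -> %s (n = %d):\n", x$x, x$m, x$y, x$n))
  cat(sprintf("  a = %.4f, b = %.4f, indirect = %.4f [%.4f, %.4f], direct = %.4f, total = %.4f\n",
              x$a, x$b, x$indirect, x$ci_low, x$ci_high, x$direct, x$total))
  cat(sprintf("  %s (%d bootstrap replicates)\n", x$label, x$n_boot))
  invisible(x)
}

#' Cohen's d with confidence interval
#'
#' Pooled-SD standardized mean difference (group1 minus group2) with a
#' normal-approximation confidence interval based on the large-sample
#' standard error `sqrt((n1+n2)/(n1*n2) + d^2 / (2*(n1+n2-2)))`.
#'
#' @param group1,group2 numeric vectors with at least 2 values each.
#' @param conf confidence level (default 0.95).
#' @return List with `d`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
cohens_d <- function(group1, group2, conf = 0.95) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD", call. = FALSE)
  d <- (mean(group1) - mean(group2)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(d = d, ci_low = d - z * se, ci_high = d + z * se, n1 = n1, n2 = n2)
}
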