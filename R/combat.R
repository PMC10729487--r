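#' Fit a single-variable ComBat batch model
#'
#' Location/scale empirical-Bayes harmonization of one continuous variable
#' (here: brain-predicted age) across batches (acquisition sites), preserving
#' covariate-related variance. The procedure is:
#'
#' 1. estimate covariate coefficients jointly with per-batch means by least
#'    squares on the design `[batch indicators, covariates]`; the grand mean
#'    is the batch-size-weighted mean of the batch coefficients;
#' 2. standardize residuals from the grand mean + covariate fit by the pooled
#'    residual SD;
#' 3. shrink the per-batch standardized locations and scales toward common
#'    values with parametric empirical Bayes (normal prior on locations,
#'    inverse-gamma on scales), solved by iterated conditional means.
#'
#' With a single variable the prior moments cannot be pooled across features
#' as in expression-array ComBat; they are estimated across batches instead,
#' which preserves the essential behaviour that small batches with extreme
#' means are shrunk harder toward the consensus than large batches.
#'
#' @param values numeric vector to harmonize (years).
#' @param batches factor (or coercible) of batch labels; every batch needs at
#'   least 2 members.
#' @param covariates optional `data.frame` or numeric matrix of covariates
#'   whose variance must be preserved (factors are expanded via
#'   `model.matrix`).
#' @param eb use empirical-Bayes shrinkage (`TRUE`, default) or raw
#'   method-of-moments batch estimates (`FALSE`).
#' @param tol,max_iter convergence tolerance and iteration cap for the EB
#'   conditional-means updates.
#' @return Object of class `bag_combat`.
#' @seealso [apply_combat()], [batch_difference_test()]
#' @export
fit_combat <- function(values, batches, covariates = NULL,
                       eb = TRUE, tol = 1e-6, max_iter = 200L) {
  batches <- droplevels(as.factor(batches))
  n <- length(values)
  if (length(batches) != n) stop("values and batches lengths differ", call. = FALSE)
  nb <- table(batches)
  if (any(nb < 2))
    stop(sprintf("every batch needs >= 2 members (offending: %s)",
                 paste(names(nb)[nb < 2], collapse = ", ")), call. = FALSE)
  B <- nlevels(batches)

  X <- expand_covariates(covariates, n)
  Z <- if (B == 1) matrix(1, n, 1) else stats::model.matrix(~ 0 + batches)
  D <- cbind(Z, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("rank-deficient design: batch indicators plus covariates are collinear",
         call. = FALSE)
  coefs <- qr.coef(qrD, values)
  gamma_batch <- coefs[seq_len(B)]
  beta <- coefs[-seq_len(B)]
  alpha <- sum((nb / n) * gamma_batch)
  cov_fit <- if (ncol(X)) drop(X %*% beta) else rep(0, n)
  resid_full <- values - drop(Z %*% gamma_batch) - cov_fit
  sigma2 <- sum(resid_full^2) / (n - qrD$rank)
  sigma <- sqrt(sigma2)

  model <- structure(list(
    levels = levels(batches), n_batch = as.numeric(nb),
    alpha = alpha, beta = beta, sigma = sigma,
    covariate_names = colnames(X), eb = eb,
    identity = FALSE), class = "bag_combat")

  if (B == 1) {
    model$identity <- TRUE
    model$gamma_hat <- model$gamma_star <- 0
    model$delta_hat <- model$delta_star <- 1
    return(model)
  }

  z <- (values - alpha - cov_fit) / sigma
  gamma_hat <- tapply(z, batches, mean)
  delta_hat <- tapply(z, batches, stats::var)
  delta_hat[!is.finite(delta_hat) | delta_hat <= 0] <- 1e-8

  if (!eb) {
    model$gamma_hat <- model$gamma_star <- as.numeric(gamma_hat)
    model$delta_hat <- model$delta_star <- as.numeric(delta_hat)
    return(model)
  }

  ## hyperpriors by method of moments across batches
  g_bar <- mean(gamma_hat)
  t2 <- stats::var(gamma_hat)
  m <- mean(delta_hat)
  s2 <- stats::var(delta_hat)
  a_prior <- if (s2 > 0) (2 * s2 + m^2) / s2 else Inf
  b_prior <- if (s2 > 0) (m * s2 + m^3) / s2 else Inf

  gamma_star <- as.numeric(gamma_hat)
  delta_star <- as.numeric(delta_hat)
  nb_num <- as.numeric(nb)
  ss_batch <- function(gs) {
    vapply(seq_len(B), function(b) {
      zi <- z[batches == model$levels[b]]
      sum((zi - gs[b])^2)
    }, numeric(1))
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g_new <- if (is.finite(t2) && t2 > 0)
      (nb_num * t2 * as.numeric(gamma_hat) + delta_star * g_bar) /
        (nb_num * t2 + delta_star)
    else as.numeric(gamma_hat)
    d_new <- if (is.finite(a_prior))
      (b_prior + 0.5 * ss_batch(g_new)) / (nb_num / 2 + a_prior - 1)
    else as.numeric(delta_hat)
    d_new[d_new <= 0] <- 1e-8
    delta_change <- max(abs(g_new - gamma_star), abs(d_new - delta_star))
    gamma_star <- g_new
    delta_star <- d_new
    if (delta_change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("ComBat EB estimation did not converge in %d iterations", max_iter),
         call. = FALSE)

  model$gamma_hat <- as.numeric(gamma_hat)
  model$delta_hat <- as.numeric(delta_hat)
  model$gamma_star <- gamma_star
  model$delta_star <- delta_star
  model$hyper <- list(gamma_bar = g_bar, tau2 = t2,
                      a_prior = a_prior, b_prior = b_prior)
  model$n_iter <- iter
  model
}

expand_covariates <- function(covariates, n) {
  if (is.null(covariates))
    return(matrix(numeric(0), nrow = n, ncol = 0))
  if (is.data.frame(covariates)) {
    X <- stats::model.matrix(~ ., data = covariates)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  } else {
    X <- as.matrix(covariates)
    if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  }
  if (nrow(X) != n) stop("covariate rows do not match values length", call. = FALSE)
  X
}

#' @export
print.bag_combat <- function(x, ...) {
  cat(sprintf("Single-variable ComBat model: %d batch(es), %s covariates, %s\n",
              length(x$levels),
              if (length(x$covariate_names)) length(x$covariate_names) else "no",
              if (x$eb) "parametric EB shrinkage" else "no shrinkage"))
  if (!x$identity) {
    tab <- data.frame(batch = x$levels, n = x$n_batch,
                      gamma_star = round(x$gamma_star, 4),
                      delta_star = round(x$delta_star, 4))
    print(tab, row.names = FALSE)
  } else cat("  single batch: identity adjustment\n")
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Standardizes with the stored grand mean, covariate fit and pooled SD,
#' removes the shrunken per-batch location, rescales by the shrunken per-batch
#' scale, and restores the covariate fit and pooled scale. The
#' covariate-explained part of each value is returned unchanged.
#'
#' @param model a [fit_combat()] result.
#' @param values,batches,covariates data on the same schema the model was fit
#'   with (batch labels must be known to the model).
#' @return Adjusted values (years).
#' @export
apply_combat <- function(model, values, batches, covariates = NULL) {
  stopifnot(inherits(model, "bag_combat"))
  batches <- as.factor(batches)
  unseen <- setdiff(levels(droplevels(batches)), model$levels)
  if (length(unseen))
    stop(sprintf("unseen batch label(s): %s", paste(unseen, collapse = ", ")),
         call. = FALSE)
  X <- expand_covariates(covariates, length(values))
  if (!identical(colnames(X), model$covariate_names))
    stop("covariates do not match the fitted model schema", call. = FALSE)
  cov_fit <- if (ncol(X)) drop(X %*% model$beta) else rep(0, length(values))
  if (model$identity) return(values)
  b <- match(as.character(batches), model$levels)
  z <- (values - model$alpha - cov_fit) / model$sigma
  z_adj <- (z - model$gamma_star[b]) / sqrt(model$delta_star[b])
  model$sigma * z_adj + model$alpha + cov_fit
}

#' Kruskal-Wallis batch-difference test
#'
#' Tie-corrected Kruskal-Wallis H across batches with a chi-square reference
#' on `(number of batches - 1)` degrees of freedom; the standard pre/post
#' check that harmonization removed site or scanner differences. If all
#' values are identical the statistic is defined as 0 with p = 1.
#'
#' @param values numeric vector.
#' @param batches batch labels; at least 2 non-empty batches.
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
batch_difference_test <- function(values, batches) {
  batches <- droplevels(as.factor(batches))
  if (nlevels(batches) < 2)
    stop("need at least 2 non-empty batches", call. = FALSE)
  if (any(table(batches) == 0)) stop("batch with 0 members", call. = FALSE)
  if (length(unique(values)) == 1)
    return(list(statistic = 0, df = nlevels(batches) - 1, p.value = 1))
  kt <- stats::kruskal.test(values, batches)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Harmonize predicted age across sites in a cohort table
#'
#' Convenience wrapper: fits ComBat on a predicted-age column with the
#' standard covariate set (age, sex, education, mutation group, EYO, APOE e4,
#' mutation variant), applies it, and optionally repeats the adjustment
#' sequentially for scanner model within the already site-harmonized values.
#'
#' @param table cohort table.
#' @param value_col column to harmonize (default the calibrated predicted
#'   age, `corrected_age`).
#' @param batch_col batch column (default `site_id`).
#' @param covariate_cols covariate columns preserved during harmonization.
#' @param then_scanner also harmonize by `scanner_id` after the site pass.
#' @param ... passed to [fit_combat()].
#' @return List with `values` (adjusted vector), `model` (site model) and
#'   optionally `scanner_model`.
#' @export
harmonize_predicted_age <- function(table, value_col = "corrected_age",
                                    batch_col = "site_id",
                                    covariate_cols = c("age", "sex", "education",
                                                       "group", "eyo", "apoe4",
                                                       "variant"),
                                    then_scanner = FALSE, ...) {
  missing_cols <- setdiff(c(value_col, batch_col, covariate_cols), names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  covs <- droplevels(table[covariate_cols])
  model <- fit_combat(table[[value_col]], table[[batch_col]], covs, ...)
  vals <- apply_combat(model, table[[value_col]], table[[batch_col]], covs)
  out <- list(values = vals, model = model)
  if (then_scanner) {
    sc_model <- fit_combat(vals, table$scanner_id, covs, ...)
    out$values <- apply_combat(sc_model, vals, table$scanner_id, covs)
    out$scanner_model <- sc_model
  }
  out
}
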