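#' Aggregate per-slice age predictions
#'
#' Collapses a vector of per-slice predicted ages to a single participant
#' prediction using the median; even-length inputs use the conventional
#' mean-of-the-two-middle-values median.
#'
#' @param slice_predictions non-empty numeric vector of per-slice predicted
#'   ages (years).
#' @return Single predicted age (years).
#' @export
#' @examples
#' aggregate_slices(c(30, 40, 50))  # 40
#' aggregate_slices(c(31, 33))      # 32
aggregate_slices <- function(slice_predictions) {
  if (length(slice_predictions) == 0)
    stop("slice_predictions must be non-empty", call. = FALSE)
  stats::median(slice_predictions)
}

#' Fit the regression-dilution calibration model
#'
#' Ordinary least squares of raw predicted age on chronological age, fit in
#' non-carrier controls only. The resulting slope/intercept define the linear
#' recalibration that re-centers control BAG at zero across the age range
#' (see [apply_calibration()]).
#'
#' @param nc_rows cohort rows restricted to the `NC` group, with columns
#'   `raw_predicted_age`, `age` and (if present) `group`, which must be all
#'   `"NC"`.
#' @return Object of class `bag_calibration` with fields `intercept`, `slope`,
#'   `n_fit`, `fit_group`.
#' @export
fit_calibration <- function(nc_rows) {
  if (!is.null(nc_rows$group) && any(nc_rows$group != "NC"))
    stop("calibration must be fit on NC rows only; non-NC rows present",
         call. = FALSE)
  age <- nc_rows$age
  raw <- nc_rows$raw_predicted_age
  if (length(age) < 3 || length(unique(age)) < 3)
    stop("need at least 3 NC rows with distinct ages", call. = FALSE)
  fit <- stats::lm(raw ~ age)
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta[2]) || beta[2] == 0)
    stop("degenerate calibration: slope is zero", call. = FALSE)
  structure(list(intercept = beta[1], slope = beta[2],
                 n_fit = length(age), fit_group = "NC"),
            class = "bag_calibration")
}

#' @export
print.bag_calibration <- function(x, ...) {
  cat(sprintf("BAG calibration (NC, n = %d): corrected = (raw - %.4f) / %.4f\n",
              x$n_fit, x$intercept, x$slope))
  invisible(x)
}

#' Apply the calibration to raw predicted ages
#'
#' Returns `(raw - intercept) / slope`, i.e. the raw prediction is rescaled so
#' that the control-group regression of corrected age on chronological age has
#' slope 1 and intercept 0.
#'
#' @param model a [fit_calibration()] result.
#' @param raw_predicted_age numeric vector of raw predicted ages (years).
#' @return Corrected predicted ages (years).
#' @export
apply_calibration <- function(model, raw_predicted_age) {
  stopifnot(inherits(model, "bag_calibration"))
  if (model$slope == 0) stop("calibration slope is zero", call. = FALSE)
  (raw_predicted_age - model$intercept) / model$slope
}

#' Brain age gap
#'
#' `corrected predicted age - chronological age`; positive values indicate an
#' older-appearing brain.
#'
#' @param corrected_age,chronological_age numeric vectors (years).
#' @return BAG in years.
#' @export
compute_bag <- function(corrected_age, chronological_age) {
  corrected_age - chronological_age
}

#' Age-prediction performance metrics
#'
#' Computes Pearson's r, the identity-line coefficient of determination
#' `R2 = 1 - sum((pred - true)^2) / sum((true - mean(true))^2)`, MAE and RMSE.
#' By convention these are evaluated on *uncorrected* predictions, since the
#' calibration is fit on the same controls and would inflate apparent
#' accuracy. Note `R2` here is relative to the identity line, not the squared
#' correlation, so `r` near 1 can coexist with much smaller (even negative)
#' `R2` when predictions are biased.
#'
#' @param raw_predictions,true_ages equal-length numeric vectors (years),
#'   `n >= 2`.
#' @return Object of class `bag_performance` with fields `r`, `r2`, `mae`,
#'   `rmse`, `n`.
#' @export
performance_metrics <- function(raw_predictions, true_ages) {
  if (length(raw_predictions) != length(true_ages))
    stop("raw_predictions and true_ages must have equal length", call. = FALSE)
  n <- length(true_ages)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  err <- raw_predictions - true_ages
  structure(list(
    r = stats::cor(raw_predictions, true_ages),
    r2 = 1 - sum(err^2) / sum((true_ages - mean(true_ages))^2),
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    n = n), class = "bag_performance")
}

#' @export
print.bag_performance <- function(x, ...) {
  cat(sprintf("Age prediction performance (n = %d): r = %.3f, R2 = %.3f, MAE = %.2f y, RMSE = %.2f y\n",
              x$n, x$r, x$r2, x$mae, x$rmse))
  invisible(x)
}

#' ICC(A,1): two-way, single measurement, absolute agreement
#'
#' Intraclass correlation for paired test-retest measurements from the
#' two-way ANOVA mean squares,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`
#' (rows = participants, columns = visits). The confidence interval follows
#' the standard F-distribution bounds with a Satterthwaite denominator
#' degrees-of-freedom approximation.
#'
#' @param visit1,visit2 paired numeric vectors, `n >= 3`.
#' @param conf confidence level for the interval (default 0.95).
#' @return Object of class `bag_icc` with fields `icc`, `ci_low`, `ci_high`,
#'   `n_pairs`.
#' @export
icc_a1 <- function(visit1, visit2, conf = 0.95) {
  if (length(visit1) != length(visit2))
    stop("visit1 and visit2 must be paired (equal length)", call. = FALSE)
  n <- length(visit1)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  k <- 2
  y <- cbind(visit1, visit2)
  gm <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  ## McGraw & Wong F-based bounds for ICC(A,1)
  alpha <- 1 - conf
  if (mse <= 0 && msc <= mse) {             # degenerate: perfect agreement
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(1, 1)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      low <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      up <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci <- c(low, up)
    }
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], n_pairs = n),
            class = "bag_icc")
}

#' @export
print.bag_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f, %.3f], n = %d pairs\n",
              x$icc, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}
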