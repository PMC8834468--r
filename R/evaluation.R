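#' Calibration / prediction statistics
#'
#' Computes the standard NIR validation statistics from reference and
#' predicted values. With errors `e_i = x_i - y_i` (reference minus
#' prediction):
#' \itemize{
#'   \item `bias = mean(e)`
#'   \item `rmse = sqrt(mean(e^2))` (RMSEC on a calibration set, RMSEP on a
#'     test set)
#'   \item `sep = sqrt(sum((e - bias)^2) / (n - 1))`, the standard error of
#'     prediction
#'   \item `r2`, the squared product-moment correlation between reference
#'     and prediction
#' }
#'
#' @param reference numeric vector of reference values.
#' @param predicted numeric vector of predictions, same length (>= 2).
#' @return A list with `r2`, `rmse`, `sep`, `bias` and `n`.
#' @export
regression_stats <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted), length(reference) >= 2)
  if (var(reference) == 0) {
    stop("reference values have zero variance; R^2 is undefined")
  }
  e <- reference - predicted
  n <- length(e)
  bias <- mean(e)
  r <- if (var(predicted) == 0) 0 else cor(reference, predicted)
  list(r2 = r^2,
       rmse = sqrt(mean(e^2)),
       sep = sqrt(sum((e - bias)^2) / (n - 1)),
       bias = bias,
       n = n)
}

#' Residual predictive deviation (RPD)
#'
#' Ratio of the test set's reference standard deviation to the prediction
#' error; larger is better.
#'
#' @param sd_ref standard deviation of the test-set reference values.
#' @param rmsep root mean square error of prediction (> 0).
#' @return `sd_ref / rmsep`.
#' @examples
#' rpd(3.00e-4, 0.105e-3)  # 2.86
#' @export
rpd <- function(sd_ref, rmsep) {
  if (rmsep <= 0) stop("`rmsep` must be positive")
  sd_ref / rmsep
}

#' Bias confidence limit (ISO 12099)
#'
#' `T_b = t(1 - alpha/2, n - 1) * SEP / sqrt(n)`: the two-sided limit
#' within which the bias of an accepted model must fall.
#'
#' @param sep standard error of prediction (>= 0).
#' @param n_effective number of independent test observations (>= 2).
#' @param alpha significance level (default 0.05).
#' @return The (positive) bias confidence limit.
#' @examples
#' bias_confidence_limit(0.164, 33)  # 0.058
#' @export
bias_confidence_limit <- function(sep, n_effective, alpha = 0.05) {
  stopifnot(sep >= 0)
  if (n_effective < 2) stop("`n_effective` must be >= 2")
  qt(1 - alpha / 2, df = n_effective - 1) * sep / sqrt(n_effective)
}

#' Unexplained-error confidence limit (ISO 12099)
#'
#' `T_UE = SEC * sqrt(F(1 - alpha; nu, M))` with `nu` the degrees of
#' freedom of the prediction error and `M = n_cal - LVs - 1` those of the
#' calibration error. The square root of the F quantile is the ISO 12099
#' practice; some tabulations render the product without the radical.
#'
#' @param sec standard (root mean square) error of calibration (>= 0).
#' @param nu,M degrees of freedom (>= 1).
#' @param alpha upper-tail significance level (default 0.05).
#' @return The unexplained-error confidence limit.
#' @export
unexplained_error_limit <- function(sec, nu, M, alpha = 0.05) {
  stopifnot(sec >= 0)
  if (nu < 1 || M < 1) stop("degrees of freedom must be >= 1")
  sec * sqrt(qf(1 - alpha, df1 = nu, df2 = M))
}

#' Accept / reject verdicts for a calibration model
#'
#' A model is accepted when `sep < t_ue` and `|bias| < t_b` (strict
#' inequalities), each reported separately.
#'
#' @param sep,bias observed test-set statistics.
#' @param t_ue,t_b confidence limits (>= 0).
#' @return A list with `verdict_sep` and `verdict_bias`, each `"accepted"`
#'   or `"rejected"`.
#' @export
model_verdict <- function(sep, bias, t_ue, t_b) {
  stopifnot(t_ue >= 0, t_b >= 0)
  list(verdict_sep = if (sep < t_ue) "accepted" else "rejected",
       verdict_bias = if (abs(bias) < t_b) "accepted" else "rejected")
}

#' Full evaluation report for a PLS-1 calibration model
#'
#' Predicts the test set, computes R-squared, RMSEP, SEP, bias and RPD, and
#' the ISO 12099 confidence limits `T_b` (with `n_effective` independent
#' observations) and `T_UE` (with `nu = n_effective - 1` and
#' `M = n_cal - LVs - 1`), then issues accept/reject verdicts.
#'
#' @param model a [pls1()] model.
#' @param test_spectra a [nir_spectra()] (or matrix) of test spectra.
#' @param test_reference numeric vector of test reference values.
#' @param n_effective number of independent observations backing the
#'   confidence limits; defaults to the number of test predictions. When
#'   subsamples of one sampling event share a reference value, the number
#'   of events is the defensible choice.
#' @param alpha significance level (default 0.05).
#' @return An object of class `nir_evaluation` with all statistics and
#'   verdicts.
#' @export
evaluate_model <- function(model, test_spectra, test_reference,
                           n_effective = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "pls1"))
  pred <- predict(model, test_spectra)
  st <- regression_stats(test_reference, pred)
  if (is.null(n_effective)) n_effective <- st$n
  t_b <- bias_confidence_limit(st$sep, n_effective, alpha)
  M <- model$n - model$ncomp - 1
  t_ue <- unexplained_error_limit(model$rmsec, nu = n_effective - 1, M = M,
                                  alpha = alpha)
  v <- model_verdict(st$sep, st$bias, t_ue, t_b)
  structure(list(r2 = st$r2, rmsec = model$rmsec, rmsep = st$rmse,
                 sep = st$sep, bias = st$bias,
                 rpd = rpd(sd(test_reference), st$rmse),
                 t_b = t_b, t_ue = t_ue,
                 n_cal = model$n, n_test = st$n,
                 n_effective = n_effective, lv_used = model$ncomp,
                 alpha = alpha,
                 verdict_sep = v$verdict_sep,
                 verdict_bias = v$verdict_bias,
                 predictions = pred),
            class = "nir_evaluation")
}

#' @export
print.nir_evaluation <- function(x, digits = 4, ...) {
  cat("NIR model evaluation (n_cal = ", x$n_cal, ", n_test = ", x$n_test,
      ", LVs = ", x$lv_used, ")\n", sep = "")
  cat(sprintf("  R^2   = %.*g\n  RMSEC = %.*g\n  RMSEP = %.*g\n  RPD   = %.*g\n",
              digits, x$r2, digits, x$rmsec, digits, x$rmsep, digits, x$rpd))
  cat(sprintf("  SEP   = %.*g   vs T_UE = %.*g  -> %s\n",
              digits, x$sep, digits, x$t_ue, x$verdict_sep))
  cat(sprintf("  bias  = %.*g   vs T_b  = +/-%.*g -> %s\n",
              digits, x$bias, digits, x$t_b, x$verdict_bias))
  invisible(x)
}

#' @export
as.data.frame.nir_evaluation <- function(x, ...) {
  data.frame(r2 = x$r2, rmsec = x$rmsec, rmsep = x$rmsep, sep = x$sep,
             bias = x$bias, rpd = x$rpd, t_b = x$t_b, t_ue = x$t_ue,
             n_cal = x$n_cal, n_test = x$n_test,
             n_effective = x$n_effective, lv_used = x$lv_used,
             verdict_sep = x$verdict_sep, verdict_bias = x$verdict_bias)
}
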