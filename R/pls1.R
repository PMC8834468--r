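#' PLS-1 calibration model
#'
#' Fits a single-response partial least squares regression by deterministic
#' NIPALS with deflation of X only. Data are mean-centered internally (no
#' variance scaling); for PLS-1 the weight vector of each factor has the
#' closed form `w = X'y`, so the fit is reproducible bit-for-bit on
#' identical input.
#'
#' @param X sample-by-channel matrix, or a [nir_spectra()] (whose region
#'   set is then stored on the model).
#' @param y numeric response (analyte concentration) vector.
#' @param ncomp number of latent variables `k`; must satisfy
#'   `1 <= k <= min(n - 1, ncol(X))`.
#' @return An object of class `pls1`: coefficients for `ncomp` latent
#'   variables, centering (`x_mean`, `y_mean`), fitted values, residuals,
#'   the RMSEC path over `1..ncomp`, scores/weights/loadings, and the
#'   training region set when fitted from a [nir_spectra()].
#' @seealso [predict.pls1()], [loo_rmsecv()], [pls1_ssr()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% c(1, -1, 0.5, 0, 0) + rnorm(12, sd = 0.01)
#' m <- pls1(X, y, ncomp = 3)
#' m$rmsec
#' @export
pls1 <- function(X, y, ncomp) {
  regions <- NULL
  if (inherits(X, "nir_spectra")) {
    regions <- X$regions
    X <- X$absorbance
  }
  stopifnot(is.matrix(X), is.numeric(y), length(y) == nrow(X))
  n <- nrow(X)
  if (var(y) == 0) stop("response has zero variance")
  kmax <- min(n - 1L, ncol(X))
  if (ncomp < 1 || ncomp > kmax) {
    stop("`ncomp` must lie in 1..", kmax, " (= min(n - 1, n_channels)), got ",
         ncomp)
  }
  fit <- cpp_pls1(X, y, as.integer(ncomp))
  b <- fit$B[, ncomp]
  fitted <- drop(X %*% b) - sum(fit$x_mean * b) + fit$y_mean
  structure(list(
    coefficients = b,
    x_mean = drop(fit$x_mean),
    y_mean = fit$y_mean,
    ncomp = as.integer(ncomp),
    k_eff = fit$k_eff,
    rmsec = sqrt(fit$ssr[ncomp] / n),
    rmsec_path = sqrt(fit$ssr / n),
    ssr = fit$ssr[ncomp],
    scores = fit$T,
    weights = fit$W,
    loadings = fit$P,
    q = fit$q,
    coef_path = fit$B,
    fitted.values = fitted,
    residuals = y - fitted,
    n = n,
    regions = regions,
    call = match.call()
  ), class = "pls1")
}

#' Predict from a PLS-1 model
#'
#' Applies `yhat = (X - x_mean) b + y_mean` with the centering stored in the
#' model.
#'
#' @param object a [pls1()] model.
#' @param newdata matrix with the model's channel count, or a
#'   [nir_spectra()]; when the model carries a region set and `newdata` has
#'   more channels, the model's regions are extracted first.
#' @param ncomp latent-variable count to predict with (default: the model's
#'   `ncomp`; any value up to `ncomp` is available from the stored path).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ncomp = NULL, ...) {
  if (inherits(newdata, "nir_spectra")) {
    if (!is.null(object$regions) &&
        ncol(newdata$absorbance) != length(object$coefficients)) {
      newdata <- extract_regions(newdata, object$regions)
    }
    newdata <- newdata$absorbance
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$coefficients))
  }
  b <- if (is.null(ncomp)) object$coefficients else {
    stopifnot(ncomp >= 1, ncomp <= object$ncomp)
    object$coef_path[, ncomp]
  }
  drop(newdata %*% b) - sum(object$x_mean * b) + object$y_mean
}

#' @export
coef.pls1 <- function(object, ...) object$coefficients

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS-1 calibration: ", x$ncomp, " latent variable(s), ",
      length(x$coefficients), " channels, n = ", x$n, "\n", sep = "")
  if (!is.null(x$regions)) cat("  regions:", format(x$regions), "cm^-1\n")
  cat("  RMSEC =", format(x$rmsec, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  cat("PLS-1 calibration model\n")
  print(object)
  cat("  RMSEC path (k = 1..", object$ncomp, "): ",
      paste(format(object$rmsec_path, digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(object)
}

#' Sum of squared calibration residues
#'
#' `SSR = sum(residual^2) = n * RMSEC^2` for a PLS-1 fit with `k` latent
#' variables.
#'
#' @inheritParams pls1
#' @param k latent-variable count.
#' @return Scalar SSR.
#' @export
pls1_ssr <- function(X, y, k) {
  m <- pls1(X, y, ncomp = k)
  m$ssr
}

#' Leave-one-out cross-validation of a PLS-1 model
#'
#' Computes RMSECV for every latent-variable count `1..k_max` from `n`
#' leave-one-out refits (centering recomputed per fold). The selected count
#' is the smallest `k` whose RMSECV is lower than at `k + 1` (the first
#' local minimum of the curve); when the curve is non-increasing through
#' `k_max` the selection falls back to the global minimizer (smallest such
#' `k`) with a warning.
#'
#' @inheritParams pls1
#' @param k_max largest latent-variable count to assess; must satisfy
#'   `k_max <= min(n - 2, ncol(X))`.
#' @return An object of class `pls1_cv`: `rmsecv` (vector over `1..k_max`),
#'   `chosen_lv`, and the per-fold prediction matrix `predictions`
#'   (n x k_max).
#' @export
loo_rmsecv <- function(X, y, k_max) {
  if (inherits(X, "nir_spectra")) X <- X$absorbance
  stopifnot(is.matrix(X), length(y) == nrow(X))
  n <- nrow(X)
  if (n < 3) stop("leave-one-out cross-validation needs n >= 3")
  if (k_max < 1 || k_max > min(n - 2L, ncol(X))) {
    stop("`k_max` must lie in 1..", min(n - 2L, ncol(X)), ", got ", k_max)
  }
  pred <- cpp_loo_pred(X, y, as.integer(k_max))
  rmsecv <- sqrt(colMeans((pred - y)^2))
  rises <- which(diff(rmsecv) > 0)
  if (length(rises) > 0) {
    chosen <- rises[1]
  } else {
    chosen <- which.min(rmsecv)[1]
    if (k_max > 1) {
      warning("RMSECV is non-increasing through k_max = ", k_max,
              "; selecting k = ", chosen)
    }
  }
  structure(list(rmsecv = rmsecv, chosen_lv = as.integer(chosen),
                 predictions = pred, k_max = as.integer(k_max), n = n),
            class = "pls1_cv")
}

#' @export
print.pls1_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation (n = ", x$n, ")\n", sep = "")
  cat("  RMSECV:", paste(format(x$rmsecv, digits = 4), collapse = ", "), "\n")
  cat("  chosen LVs:", x$chosen_lv, "\n")
  invisible(x)
}

#' Maximum useful latent-variable count for a region
#'
#' Walks the calibration RMSEC path and returns the smallest `k` at which
#' the relative improvement `(RMSEC(k) - RMSEC(k+1)) / RMSEC(k)` drops
#' below `rel_improvement` -- i.e. where adding factors stops paying --
#' capped at `k_cap` and at the feasible maximum `min(n - 1, width)`.
#'
#' @inheritParams pls1
#' @param k_cap hard upper bound on the returned count (default 10).
#' @param rel_improvement relative RMSEC improvement regarded as
#'   insignificant (default 0.02).
#' @return Integer latent-variable count, at least 1.
#' @export
max_lv_for_region <- function(X, y, k_cap = 10, rel_improvement = 0.02) {
  if (inherits(X, "nir_spectra")) X <- X$absorbance
  stopifnot(is.matrix(X))
  kmax <- min(k_cap, nrow(X) - 1L, ncol(X))
  if (kmax < 1) stop("region too narrow for a single latent variable")
  if (kmax == 1) return(1L)
  fit <- cpp_pls1(X, y, as.integer(kmax))
  rmsec <- sqrt(fit$ssr / nrow(X))
  for (k in seq_len(kmax - 1)) {
    if (rmsec[k] <= 0) return(as.integer(k))
    if ((rmsec[k] - rmsec[k + 1]) / rmsec[k] < rel_improvement) {
      return(as.integer(k))
    }
  }
  as.integer(kmax)
}
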