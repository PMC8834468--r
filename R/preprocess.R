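#' Savitzky-Golay second-derivative pretreatment
#'
#' Applies a Savitzky-Golay second derivative (local polynomial fit of order
#' `polyorder` in a centred window of `window` points) independently to each
#' contiguous segment of the spectra, so derivative windows never bridge an
#' excluded gap. The derivative is taken with respect to the channel index;
#' since the axis is uniform and PLS calibration after centering is
#' invariant to a global positive scaling of X, the `1/step^2` factor is
#' deliberately omitted. Edge policy is trim: each segment loses
#' `(window-1)/2` channels at either end and the axis shrinks accordingly.
#'
#' @param x a [nir_spectra()].
#' @param window odd full window length in points (default 7).
#' @param polyorder polynomial order of the local fit (default 2); must be
#'   smaller than `window`.
#' @return A [nir_spectra()] of second-derivative spectra on the trimmed
#'   axis.
#' @examples
#' \dontrun{
#' d2 <- sg_second_derivative(exclude_regions(s, region_set(5248, 4984)))
#' }
#' @export
sg_second_derivative <- function(x, window = 7, polyorder = 2) {
  stopifnot(inherits(x, "nir_spectra"))
  if (window %% 2 != 1 || window <= polyorder) {
    stop("`window` must be odd and larger than `polyorder`")
  }
  h <- (window - 1) / 2
  lens <- segment_lengths(x$regions)
  short <- which(lens < window)
  if (length(short) > 0) {
    stop("segment ", x$regions$high[short[1]], "-", x$regions$low[short[1]],
         " has ", lens[short[1]], " channels, fewer than the ", window,
         "-point derivative window")
  }
  # central row of the SG differentiation filter; includes the 2! factor so
  # a quadratic a*i^2 maps to the constant 2a exactly
  kern <- signal::sgolay(p = polyorder, n = window, m = 2)[h + 1, ]
  kern <- as.numeric(kern)

  step <- x$regions$step_cm1
  offsets <- c(0L, cumsum(lens))
  out <- vector("list", length(lens))
  for (s in seq_along(lens)) {
    cols <- (offsets[s] + 1L):(offsets[s] + lens[s])
    seg <- x$absorbance[, cols, drop = FALSE]
    p <- ncol(seg)
    d2 <- matrix(0, nrow(seg), p - window + 1)
    for (j in seq_len(window)) {
      d2 <- d2 + kern[j] * seg[, j:(p - window + j), drop = FALSE]
    }
    out[[s]] <- d2
  }
  regions <- region_set(x$regions$high - h * step, x$regions$low + h * step,
                        step)
  nir_spectra(do.call(cbind, out), regions, x$meta)
}

#' Apply a preprocessing specification
#'
#' Convenience dispatcher: `method = "none"` passes the spectra through
#' untouched; `method = "second_derivative"` applies
#' [sg_second_derivative()].
#'
#' @param x a [nir_spectra()].
#' @param method `"none"` or `"second_derivative"`.
#' @param window,polyorder forwarded to [sg_second_derivative()].
#' @return A [nir_spectra()].
#' @export
preprocess <- function(x, method = c("second_derivative", "none"),
                       window = 7, polyorder = 2) {
  method <- match.arg(method)
  if (method == "none") return(x)
  sg_second_derivative(x, window = window, polyorder = polyorder)
}

#' Mean-center a calibration matrix and response
#'
#' @param X sample-by-channel matrix with at least two rows.
#' @param y optional response vector of length `nrow(X)`.
#' @return A list with `X` (centered matrix), `y` (centered response or
#'   `NULL`), `x_mean` and `y_mean`.
#' @export
mean_center <- function(X, y = NULL) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2) stop("mean centering needs at least 2 samples")
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  if (is.null(y)) {
    list(X = Xc, y = NULL, x_mean = x_mean, y_mean = NULL)
  } else {
    stopifnot(length(y) == nrow(X))
    y_mean <- mean(y)
    list(X = Xc, y = y - y_mean, x_mean = x_mean, y_mean = y_mean)
  }
}
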