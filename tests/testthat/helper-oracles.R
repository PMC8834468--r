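# Independent oracles used across the suite. These deliberately avoid the
# package's NIPALS/deflation code paths.

# PLS-1 fitted values via orthogonalized Krylov projection: the k-factor
# fitted values are the projection of centered y onto K_k(M, M y) with
# M = Xc Xc'.
arnoldi_fitted <- function(X, y, k) {
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  M <- tcrossprod(xc)
  Q <- matrix(0, nrow(X), 0)
  v <- drop(M %*% yc)
  v0 <- sqrt(sum(v^2))
  for (j in seq_len(k)) {
    if (j > 1) v <- drop(M %*% Q[, j - 1])
    for (pass in 1:2) if (ncol(Q) > 0) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10 * v0) break
    Q <- cbind(Q, v / nv)
  }
  drop(Q %*% crossprod(Q, yc)) + mean(y)
}

# wrap a plain matrix as spectra on a descending 8 cm^-1 axis from `high`
as_spectra <- function(X, high = 8000, step = 8) {
  nir_spectra(X, region_set(high, high - step * (ncol(X) - 1), step))
}

# exhaustive single-region sub-window search via pls1(), with the package's
# tie-break (fewer channels, then higher starting wavenumber)
brute_best_subwindow <- function(sp, y, region, k_max = 10) {
  cols <- region_columns(sp, region)
  p <- length(cols)
  n <- nrow(sp$absorbance)
  kcap <- max_lv_for_region(sp$absorbance[, cols, drop = FALSE], y,
                            k_cap = k_max)
  best <- NULL
  for (w in 1:p) {
    for (st in 1:(p - w + 1)) {
      cc <- cols[st:(st + w - 1)]
      k <- min(kcap, w, n - 1)
      rm <- pls1(sp$absorbance[, cc, drop = FALSE], y, ncomp = k)$rmsec
      if (is.null(best) || rm < best$rm - 1e-12 ||
          (abs(rm - best$rm) <= 1e-12 &&
           (w < best$w || (w == best$w && st < best$st)))) {
        best <- list(rm = rm, w = w, st = st, cols = cc, k = k)
      }
    }
  }
  best
}

# exhaustive two-region combination: best sub-window of A, then all
# sub-intervals of B plus the empty interval on top of it
brute_two_region_combine <- function(sp, y, rA, rB, k_max = 10) {
  X <- sp$absorbance
  n <- nrow(X)
  bestA <- brute_best_subwindow(sp, y, rA, k_max)
  base <- bestA$cols
  colsB <- region_columns(sp, rB)
  pB <- length(colsB)
  kcap <- max(max_lv_for_region(X[, c(base, colsB), drop = FALSE], y,
                                k_cap = k_max),
              bestA$k)
  k0 <- min(kcap, length(base), n - 1)
  best <- list(rm = pls1(X[, base, drop = FALSE], y, ncomp = k0)$rmsec,
               w = 0, st = 0)
  for (w in 1:pB) {
    for (st in 1:(pB - w + 1)) {
      cc <- c(base, colsB[st:(st + w - 1)])
      k <- min(kcap, length(cc), n - 1)
      rm <- pls1(X[, cc, drop = FALSE], y, ncomp = k)$rmsec
      if (rm < best$rm - 1e-12 ||
          (abs(rm - best$rm) <= 1e-12 &&
           (w < best$w || (w == best$w && st < best$st)))) {
        best <- list(rm = rm, w = w, st = st)
      }
    }
  }
  best
}
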