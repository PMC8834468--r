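#' Moving-window PLS regression (MWPLSR) residue lines
#'
#' Slides a fixed-size window across every contiguous segment of the
#' spectra; at each position fits PLS-1 models with 1..`k_max` latent
#' variables on the window's columns (mean-centered) and records
#' `log10(SSR)`, the log sum of squared calibration residues. Plotted
#' against window position, the resulting residue lines expose informative
#' regions as low-SSR valleys.
#'
#' @param x a preprocessed [nir_spectra()].
#' @param y response vector (analyte concentrations).
#' @param window window size `H` in spectral points (default 20). Must be
#'   larger than `k_max`.
#' @param k_max maximum latent-variable count (default 10), giving one
#'   residue line per count.
#' @return An object of class `mwplsr`: `loss` (position-by-LV matrix of
#'   `log10(SSR)`), `positions` (data frame with the segment, global start
#'   column and window wavenumber span), `window`, `k_max` and the axis
#'   region set. Segments shorter than `window` are skipped with a warning.
#' @export
mwplsr <- function(x, y, window = 20, k_max = 10) {
  stopifnot(inherits(x, "nir_spectra"), length(y) == nrow(x$absorbance))
  if (window <= k_max) {
    stop("window size (", window, ") must be larger than k_max (", k_max,
         ") so every window supports the full model dimensionality")
  }
  lens <- segment_lengths(x$regions)
  offsets <- c(0L, cumsum(lens))
  values <- wavenumbers(x)
  loss <- NULL
  pos <- NULL
  for (s in seq_along(lens)) {
    if (lens[s] < window) {
      warning("segment ", x$regions$high[s], "-", x$regions$low[s],
              " has fewer channels (", lens[s], ") than the window (",
              window, "); skipped")
      next
    }
    cols <- (offsets[s] + 1L):(offsets[s] + lens[s])
    ssr <- cpp_mwplsr(x$absorbance[, cols, drop = FALSE], y,
                      as.integer(window), as.integer(k_max))
    starts <- cols[seq_len(lens[s] - window + 1L)]
    loss <- rbind(loss, log10(ssr))
    pos <- rbind(pos, data.frame(
      segment = s,
      start_col = starts,
      high_cm1 = values[starts],
      low_cm1 = values[starts + window - 1L]))
  }
  if (is.null(loss)) stop("no segment is wide enough for the window")
  colnames(loss) <- paste0("lv", seq_len(k_max))
  structure(list(loss = loss, positions = pos, window = as.integer(window),
                 k_max = as.integer(k_max), regions = x$regions),
            class = "mwplsr")
}

#' @export
print.mwplsr <- function(x, ...) {
  cat("MWPLSR residue lines: ", nrow(x$loss), " window positions (H = ",
      x$window, "), ", x$k_max, " latent-variable lines\n  axis: ",
      format(x$regions), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mwplsr <- function(x, ...) {
  cbind(x$positions, as.data.frame(x$loss))
}

#' @export
plot.mwplsr <- function(x, ...) {
  matplot(x$positions$high_cm1, x$loss, type = "l", lty = 1,
          xlim = rev(range(x$positions$high_cm1)),
          xlab = expression(Wavenumber ~ (cm^-1)),
          ylab = expression(log[10](SSR)),
          main = "MWPLSR residue lines", ...)
  invisible(x)
}

#' Identify informative spectral regions from residue lines
#'
#' Automates the reading of a residue-line plot: window positions whose
#' `log10(SSR)` at `lv_ref` latent variables falls below the given quantile
#' of that line are selected, and the union of the selected windows is
#' returned as wavenumber regions (merged where windows overlap, never
#' bridging segment gaps). A manual mode (`regions = ...`) accepts
#' hand-picked regions verbatim, the reproduction path for visually chosen
#' regions.
#'
#' @param x an [mwplsr()] object.
#' @param lv_ref latent-variable line to threshold (default 3).
#' @param quantile_threshold quantile of the `lv_ref` line used as the
#'   cut-off (default 0.25: residue-line distributions are typically
#'   bimodal -- informative valleys against a signal-free plateau -- and
#'   the lower quartile isolates the valleys).
#' @param regions optional [region_set()]; when supplied it is returned
#'   unchanged.
#' @return A [region_set()]; empty (with a warning) when no position falls
#'   below the threshold.
#' @export
informative_regions <- function(x, lv_ref = 3, quantile_threshold = 0.25,
                                regions = NULL) {
  if (!is.null(regions)) {
    stopifnot(inherits(regions, "region_set"))
    return(regions)
  }
  stopifnot(inherits(x, "mwplsr"))
  if (lv_ref < 1 || lv_ref > x$k_max) {
    stop("`lv_ref` must lie in 1..", x$k_max)
  }
  line <- x$loss[, lv_ref]
  thr <- quantile(line, quantile_threshold, names = FALSE)
  sel <- which(line < thr)
  if (length(sel) == 0) {
    warning("no window position falls below the threshold; ",
            "returning an empty region set")
    return(region_set(numeric(0), numeric(0), x$regions$step_cm1))
  }
  values <- region_values(x$regions)
  mask <- rep(FALSE, length(values))
  for (i in sel) {
    st <- x$positions$start_col[i]
    mask[st:(st + x$window - 1L)] <- TRUE
  }
  .runs_to_regions(values, mask, x$regions$step_cm1)
}

# centered design pieces for the covariance-form search
.center_xy <- function(X, y) {
  xm <- colMeans(X)
  ym <- mean(y)
  list(Xc = sweep(X, 2, xm), yc = y - ym, yy = sum((y - ym)^2))
}

#' Optimal sub-window of one informative region
#'
#' Enumerates every sub-interval of the region (all widths
#' `w_min..w_max`, all positions at the given stride; the defaults
#' reproduce the exhaustive search) and fits a mean-centered PLS-1 model on
#' each with `k = min(k_cap, width, n - 1)` latent variables, where `k_cap`
#' is chosen by [max_lv_for_region()]. Returns the sub-interval with the
#' smallest RMSEC. Ties within 1e-12 prefer fewer channels, then the higher
#' starting wavenumber.
#'
#' @param x a preprocessed [nir_spectra()].
#' @param y response vector.
#' @param region a single-region [region_set()] (or `c(high, low)` pair)
#'   lying inside one contiguous segment.
#' @param k_max latent-variable cap handed to [max_lv_for_region()].
#' @param w_min,w_max,stride search-grid controls; `w_max = NULL` means the
#'   full region width. Non-default values approximate the exhaustive
#'   search.
#' @param rel_improvement forwarded to [max_lv_for_region()].
#' @return A list with `region` (single-region [region_set()]), `lv`,
#'   `rmsec` and `n_models`.
#' @export
scmwpls_best_subwindow <- function(x, y, region, k_max = 10, w_min = 1,
                                   w_max = NULL, stride = 1,
                                   rel_improvement = 0.02) {
  stopifnot(inherits(x, "nir_spectra"))
  step <- x$regions$step_cm1
  if (!inherits(region, "region_set")) {
    region <- region_set(region[1], region[2], step)
  }
  if (length(region$high) != 1) stop("`region` must contain exactly one region")
  cols <- region_columns(x, region)
  p <- length(cols)
  if (p < 1) stop("region of width 0")
  w_max <- if (is.null(w_max)) p else min(w_max, p)
  Xr <- x$absorbance[, cols, drop = FALSE]
  kcap <- max_lv_for_region(Xr, y, k_cap = k_max,
                            rel_improvement = rel_improvement)
  cc <- .center_xy(Xr, y)
  res <- cpp_search_subwindows(cc$Xc, cc$yc, 0L,
                               as.integer(w_min), as.integer(w_max),
                               as.integer(stride), as.integer(kcap), FALSE)
  values <- wavenumbers(x)
  sel <- cols[res$start:(res$start + res$width - 1L)]
  list(region = region_set(values[sel[1]], values[sel[length(sel)]], step),
       lv = res$k, rmsec = res$rmsec, n_models = res$n_models)
}

#' Searching-combination moving-window PLS (SCMWPLS)
#'
#' Optimizes a combination of informative regions in two stages. Stage A
#' runs [scmwpls_best_subwindow()] on the first region (in the order given
#' by `order_policy`) to obtain the base region. Stage B then visits each
#' remaining region in turn: every sub-interval of that region -- plus the
#' empty interval, so whole regions can be discarded -- is combined with
#' the current base, a PLS-1 model is fitted on the union, and the
#' combination with the smallest RMSEC becomes the new base. The final base
#' is the optimized combination.
#'
#' The latent-variable count inside the search is
#' `k = min(k_cap, n_channels, n - 1)` with `k_cap` re-estimated by
#' [max_lv_for_region()] for each stage, which keeps RMSEC comparisons
#' across windows of different width at a fixed model dimensionality. The
#' published model's count is conventionally re-selected afterwards by
#' [loo_rmsecv()] on the optimized regions.
#'
#' @inheritParams scmwpls_best_subwindow
#' @param regions a [region_set()] of informative regions (at least one).
#' @param order_policy `"wavenumber"` processes regions in descending
#'   wavenumber order; `"rmsec"` in ascending order of each region's own
#'   full-width RMSEC.
#' @return An object of class `scmwpls`: `optimized_regions`
#'   ([region_set()]), `lv_used`, `rmsec`, `trace` (one row per accepted
#'   step with the base so far, the candidate adopted and its RMSEC),
#'   `n_models_total`, and the processing `order`.
#' @export
scmwpls <- function(x, y, regions, k_max = 10, w_min = 1, w_max = NULL,
                    stride = 1, rel_improvement = 0.02,
                    order_policy = c("wavenumber", "rmsec")) {
  stopifnot(inherits(x, "nir_spectra"), inherits(regions, "region_set"))
  order_policy <- match.arg(order_policy)
  nr <- length(regions$high)
  if (nr == 0) stop("`regions` is empty")
  step <- x$regions$step_cm1
  values <- wavenumbers(x)
  region_list <- lapply(seq_len(nr), function(i) {
    region_set(regions$high[i], regions$low[i], step)
  })
  ord <- seq_len(nr)
  if (order_policy == "rmsec" && nr > 1) {
    full_rmsec <- vapply(region_list, function(r) {
      Xr <- x$absorbance[, region_columns(x, r), drop = FALSE]
      kcap <- max_lv_for_region(Xr, y, k_cap = k_max,
                                rel_improvement = rel_improvement)
      pls1(Xr, y, ncomp = kcap)$rmsec
    }, 0)
    ord <- order(full_rmsec)
  }

  best <- scmwpls_best_subwindow(x, y, region_list[[ord[1]]], k_max = k_max,
                                 w_min = w_min, w_max = w_max,
                                 stride = stride,
                                 rel_improvement = rel_improvement)
  base_cols <- region_columns(x, best$region)
  trace <- data.frame(step = 1L,
                      base = format(best$region),
                      candidate = format(best$region),
                      rmsec = best$rmsec, lv = best$lv,
                      n_models = best$n_models,
                      stringsAsFactors = FALSE)
  n_models_total <- best$n_models
  last_rmsec <- best$rmsec
  last_lv <- best$lv

  if (nr > 1) {
    n <- nrow(x$absorbance)
    for (jj in seq(2, nr)) {
      r <- region_list[[ord[jj]]]
      cols_r <- region_columns(x, r)
      p <- length(cols_r)
      wmx <- if (is.null(w_max)) p else min(w_max, p)
      combined <- c(base_cols, cols_r)
      Xcomb <- x$absorbance[, combined, drop = FALSE]
      kcap <- max_lv_for_region(Xcomb, y, k_cap = k_max,
                                rel_improvement = rel_improvement)
      # the cap never decreases across steps: the empty candidate is then
      # always assessed at no fewer factors than the previous record, which
      # guarantees a non-increasing RMSEC trace
      kcap <- max(kcap, last_lv)
      cc <- .center_xy(Xcomb, y)
      res <- cpp_search_subwindows(cc$Xc, cc$yc,
                                   as.integer(length(base_cols)),
                                   as.integer(w_min), as.integer(wmx),
                                   as.integer(stride), as.integer(kcap),
                                   TRUE)
      n_models_total <- n_models_total + res$n_models
      if (res$width > 0) {
        sel <- cols_r[res$start:(res$start + res$width - 1L)]
        base_cols <- sort(c(base_cols, sel))
        cand <- paste0(values[sel[1]], "-", values[sel[length(sel)]])
      } else {
        cand <- "<none>"
      }
      mask <- rep(FALSE, length(values))
      mask[base_cols] <- TRUE
      base_rs <- .runs_to_regions(values, mask, step)
      trace <- rbind(trace, data.frame(step = jj, base = format(base_rs),
                                       candidate = cand, rmsec = res$rmsec,
                                       lv = res$k, n_models = res$n_models,
                                       stringsAsFactors = FALSE))
      last_rmsec <- res$rmsec
      last_lv <- res$k
    }
  }

  mask <- rep(FALSE, length(values))
  mask[base_cols] <- TRUE
  optimized <- .runs_to_regions(values, mask, step)
  structure(list(optimized_regions = optimized,
                 lv_used = as.integer(last_lv),
                 rmsec = last_rmsec,
                 trace = trace,
                 n_models_total = n_models_total,
                 order = ord,
                 call = match.call()),
            class = "scmwpls")
}

#' @export
print.scmwpls <- function(x, ...) {
  cat("SCMWPLS optimized combination\n")
  cat("  regions:", format(x$optimized_regions), "cm^-1 (",
      n_points(x$optimized_regions), "points )\n")
  cat("  RMSEC =", format(x$rmsec, digits = 5), "with", x$lv_used,
      "latent variable(s);", format(x$n_models_total, big.mark = ","),
      "models evaluated\n")
  invisible(x)
}
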