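#' NIR spectra set
#'
#' Container for a sample-by-channel absorbance matrix on a (possibly
#' segmented) descending wavenumber axis, together with per-sample metadata
#' (batch, sampling time, subsample).
#'
#' @param absorbance numeric matrix, samples in rows, channels in columns,
#'   no missing values. Column order follows `regions` (descending
#'   wavenumbers, region by region).
#' @param regions a [region_set()] describing the axis; its total point
#'   count must equal `ncol(absorbance)`.
#' @param meta optional `data.frame` with one row per sample; if it carries
#'   a `sample_id` column those become the row names. Typical columns:
#'   `sample_id`, `batch`, `time_h`, `subsample`.
#' @return An object of class `nir_spectra`.
#' @export
nir_spectra <- function(absorbance, regions, meta = NULL) {
  stopifnot(is.matrix(absorbance), inherits(regions, "region_set"))
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance matrix contains missing or non-finite values")
  }
  if (ncol(absorbance) != n_points(regions)) {
    stop("absorbance has ", ncol(absorbance), " columns but the region set ",
         format(regions), " holds ", n_points(regions), " points")
  }
  if (is.null(meta)) {
    ids <- rownames(absorbance)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(absorbance)))
    meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(meta), nrow(meta) == nrow(absorbance))
  if (is.null(meta$sample_id)) meta$sample_id <- rownames(absorbance)
  rownames(absorbance) <- meta$sample_id
  colnames(absorbance) <- format(region_values(regions), trim = TRUE,
                                 scientific = FALSE)
  structure(list(absorbance = absorbance, regions = regions, meta = meta),
            class = "nir_spectra")
}

#' @export
print.nir_spectra <- function(x, ...) {
  cat("<nir_spectra> ", nrow(x$absorbance), " spectra x ",
      ncol(x$absorbance), " channels\n  axis: ", format(x$regions),
      " cm^-1 (step ", x$regions$step_cm1, ")\n", sep = "")
  if (!is.null(x$meta$batch)) {
    cat("  batches:", paste(unique(x$meta$batch), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.nir_spectra <- function(x) dim(x$absorbance)

#' Wavenumber axis of a spectra set
#' @param x a [nir_spectra()].
#' @return Numeric vector of descending wavenumbers (cm^-1).
#' @export
wavenumbers <- function(x) {
  stopifnot(inherits(x, "nir_spectra"))
  region_values(x$regions)
}

#' Remove spectral regions from a spectra set
#'
#' Drops the channels covered by `exclusions` (e.g. a detector-saturated
#' band) and records the resulting contiguous segments, so that later
#' windowed operations never span the gap.
#'
#' @param x a [nir_spectra()].
#' @param exclusions a [region_set()] with endpoints on the grid of `x`.
#' @return A [nir_spectra()] on the complementary region set.
#' @examples
#' \dontrun{
#' s2 <- exclude_regions(s, region_set(5248, 4984, 8))
#' }
#' @export
exclude_regions <- function(x, exclusions) {
  stopifnot(inherits(x, "nir_spectra"), inherits(exclusions, "region_set"))
  if (length(exclusions$high) == 0) return(x)
  values <- wavenumbers(x)
  keep <- .kept_mask(values, exclusions)
  if (!any(keep)) stop("exclusions cover the whole grid")
  regions <- .runs_to_regions(values, keep, x$regions$step_cm1)
  nir_spectra(x$absorbance[, keep, drop = FALSE], regions, x$meta)
}

#' Extract the channels of a region set from a spectra set
#'
#' @param x a [nir_spectra()].
#' @param regions a [region_set()]; every region must be fully contained in
#'   one contiguous segment of `x`.
#' @return A [nir_spectra()] restricted to `regions`.
#' @export
extract_regions <- function(x, regions) {
  stopifnot(inherits(x, "nir_spectra"), inherits(regions, "region_set"))
  idx <- region_columns(x, regions)
  nir_spectra(x$absorbance[, idx, drop = FALSE], regions, x$meta)
}

#' Column indices of a region set within a spectra set
#'
#' @inheritParams extract_regions
#' @return Integer vector of column indices (ascending, i.e. descending in
#'   wavenumber).
#' @export
region_columns <- function(x, regions) {
  values <- wavenumbers(x)
  unlist(lapply(seq_along(regions$high), function(i) {
    span <- region_indices(values, regions$high[i], regions$low[i])
    cols <- span[1]:span[2]
    got <- values[cols]
    want <- seq(regions$high[i], regions$low[i], by = -regions$step_cm1)
    if (length(got) != length(want) || any(abs(got - want) > 1e-6)) {
      stop("region ", regions$high[i], "-", regions$low[i],
           " spans a gap in the spectra's axis")
    }
    cols
  }))
}
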