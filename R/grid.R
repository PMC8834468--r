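#' Uniform descending wavenumber grid
#'
#' Constructs the spectral abscissa used throughout the package: a uniform
#' grid of wavenumbers stored in acquisition order, high to low. The span
#' must be an exact multiple of the step; no snapping is performed.
#'
#' @param high_cm1,low_cm1 grid endpoints in cm^-1 (`high_cm1 >= low_cm1`).
#' @param step_cm1 positive sampling interval in cm^-1 (default 8, the
#'   FT-NIR acquisition interval the package is designed around).
#' @return An object of class `wn_grid` with fields `high_cm1`, `low_cm1`,
#'   `step_cm1` and `values` (descending wavenumbers).
#' @examples
#' g <- wn_grid(11536, 3952, 8)
#' n_points(g)  # 949
#' @export
wn_grid <- function(high_cm1, low_cm1, step_cm1 = 8) {
  stopifnot(is.numeric(high_cm1), is.numeric(low_cm1), is.numeric(step_cm1),
            length(high_cm1) == 1L, length(low_cm1) == 1L,
            length(step_cm1) == 1L)
  if (step_cm1 <= 0) {
    stop("`step_cm1` must be positive, got ", step_cm1)
  }
  span <- high_cm1 - low_cm1
  if (span < 0) {
    stop("`high_cm1` (", high_cm1, ") must be >= `low_cm1` (", low_cm1, ")")
  }
  k <- span / step_cm1
  if (abs(k - round(k)) > 1e-8) {
    stop("span ", span, " cm^-1 is not divisible by step ", step_cm1,
         " cm^-1 (remainder ", span - round(k) * step_cm1, ")")
  }
  n <- as.integer(round(k)) + 1L
  structure(
    list(high_cm1 = high_cm1, low_cm1 = low_cm1, step_cm1 = step_cm1,
         values = high_cm1 - step_cm1 * (seq_len(n) - 1)),
    class = "wn_grid")
}

#' @export
print.wn_grid <- function(x, ...) {
  cat("<wn_grid> ", x$high_cm1, "-", x$low_cm1, " cm^-1, step ", x$step_cm1,
      " cm^-1, ", length(x$values), " points\n", sep = "")
  invisible(x)
}

#' Ordered set of disjoint spectral regions
#'
#' A region set is an ordered sequence of closed wavenumber intervals
#' `high-low` on a common step, written in descending order (the field's
#' "high-low" notation). Both endpoints are included in the point count.
#' Regions must be pairwise disjoint and non-adjacent: two intervals whose
#' grid points would be contiguous belong in one region.
#'
#' @param high,low numeric vectors of interval endpoints in cm^-1.
#' @param step_cm1 common grid step in cm^-1.
#' @return An object of class `region_set`.
#' @examples
#' rs <- region_set(c(11536, 4976), c(5256, 3952), 8)
#' n_points(rs)  # 915
#' @export
region_set <- function(high, low, step_cm1 = 8) {
  stopifnot(is.numeric(high), is.numeric(low), length(high) == length(low),
            is.numeric(step_cm1), length(step_cm1) == 1L, step_cm1 > 0)
  if (length(high) > 0) {
    if (any(high < low)) {
      bad <- which(high < low)[1]
      stop("region ", high[bad], "-", low[bad], ": high < low")
    }
    spans <- (high - low) / step_cm1
    if (any(abs(spans - round(spans)) > 1e-8)) {
      bad <- which(abs(spans - round(spans)) > 1e-8)[1]
      stop("region ", high[bad], "-", low[bad], " is not aligned to step ",
           step_cm1, " cm^-1")
    }
    o <- order(high, decreasing = TRUE)
    high <- high[o]
    low <- low[o]
    if (length(high) > 1) {
      gap <- low[-length(low)] - high[-1]
      if (any(gap <= step_cm1 + 1e-8)) {
        bad <- which(gap <= step_cm1 + 1e-8)[1]
        stop("regions ", high[bad], "-", low[bad], " and ", high[bad + 1],
             "-", low[bad + 1], " overlap or touch on the grid")
      }
    }
  }
  structure(list(high = as.numeric(high), low = as.numeric(low),
                 step_cm1 = step_cm1),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", format(x), " (step ", x$step_cm1, " cm^-1, ",
      n_points(x), " points)\n", sep = "")
  invisible(x)
}

#' @export
format.region_set <- function(x, ...) {
  if (length(x$high) == 0) return("<empty>")
  paste(paste0(x$high, "-", x$low), collapse = ", ")
}

#' @export
length.region_set <- function(x) length(x$high)

#' Parse regions written in "high-low" notation
#'
#' Accepts strings such as `"9104-7984, 7752-6704"` (hyphen or en dash).
#'
#' @param text character scalar.
#' @param step_cm1 grid step in cm^-1.
#' @return A [region_set()].
#' @export
parse_regions <- function(text, step_cm1 = 8) {
  parts <- trimws(strsplit(text, ",")[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return(region_set(numeric(0), numeric(0), step_cm1))
  ends <- lapply(parts, function(p) {
    v <- as.numeric(strsplit(p, "[-–]")[[1]])
    if (length(v) != 2 || anyNA(v)) stop("cannot parse region '", p, "'")
    v
  })
  region_set(vapply(ends, `[`, 0, 1), vapply(ends, `[`, 0, 2), step_cm1)
}

#' Number of grid points in a grid or region set
#'
#' Regions are closed intervals: both endpoints count, so a region
#' contributes `(high - low)/step + 1` points.
#'
#' @param x a [wn_grid()] or [region_set()].
#' @return Integer point count.
#' @export
n_points <- function(x) UseMethod("n_points")

#' @export
n_points.wn_grid <- function(x) length(x$values)

#' @export
n_points.region_set <- function(x) {
  if (length(x$high) == 0) return(0L)
  sum(as.integer(round((x$high - x$low) / x$step_cm1)) + 1L)
}

#' Concatenated descending wavenumber values of a region set
#'
#' @param x a [region_set()].
#' @return Numeric vector of all grid values, region by region, descending.
#' @export
region_values <- function(x) {
  stopifnot(inherits(x, "region_set"))
  if (length(x$high) == 0) return(numeric(0))
  unlist(lapply(seq_along(x$high), function(i) {
    seq(x$high[i], x$low[i], by = -x$step_cm1)
  }))
}

#' Per-region point counts of a region set
#' @param x a [region_set()].
#' @return Integer vector, one entry per region.
#' @export
segment_lengths <- function(x) {
  stopifnot(inherits(x, "region_set"))
  if (length(x$high) == 0) return(integer(0))
  as.integer(round((x$high - x$low) / x$step_cm1)) + 1L
}

# exact match of a wavenumber in a value vector; -1 if absent
.wn_match <- function(value, values, tol = 1e-6) {
  i <- which(abs(values - value) < tol)
  if (length(i) == 0) -1L else i[1]
}

#' Inclusive index span of a region on a grid
#'
#' Maps a closed wavenumber interval to the 1-based inclusive column span it
#' occupies on a descending grid.
#'
#' @param grid a [wn_grid()] or numeric vector of descending wavenumbers.
#' @param high_cm1,low_cm1 region endpoints; both must lie on the grid.
#' @return Integer vector `c(first, last)`, both inclusive.
#' @export
region_indices <- function(grid, high_cm1, low_cm1) {
  values <- if (inherits(grid, "wn_grid")) grid$values else as.numeric(grid)
  i1 <- .wn_match(high_cm1, values)
  i2 <- .wn_match(low_cm1, values)
  if (i1 < 0 || i2 < 0) {
    off <- if (i1 < 0) high_cm1 else low_cm1
    nearest <- values[order(abs(values - off))[1:2]]
    stop("endpoint ", off, " cm^-1 is not on the grid; nearest grid values: ",
         paste(nearest, collapse = ", "))
  }
  if (i1 > i2) stop("region ", high_cm1, "-", low_cm1,
                    " is reversed relative to the descending grid")
  c(first = i1, last = i2)
}

#' Complement of a set of exclusion regions within a grid
#'
#' Returns the kept portion of `within` after removing every grid value
#' covered by `exclusions`, as a region set of maximal contiguous segments.
#'
#' @param exclusions a [region_set()] (endpoints must lie on the grid).
#' @param within a [wn_grid()] or [region_set()] defining the full axis.
#' @return A [region_set()].
#' @export
complement_regions <- function(exclusions, within) {
  step <- if (inherits(within, "wn_grid")) within$step_cm1 else within$step_cm1
  values <- if (inherits(within, "wn_grid")) within$values
            else region_values(within)
  keep <- .kept_mask(values, exclusions)
  if (!any(keep)) stop("exclusions cover the whole grid")
  .runs_to_regions(values, keep, step)
}

# logical mask of grid values NOT covered by the exclusion set
.kept_mask <- function(values, exclusions) {
  stopifnot(inherits(exclusions, "region_set"))
  keep <- rep(TRUE, length(values))
  for (i in seq_along(exclusions$high)) {
    hi <- exclusions$high[i]
    lo <- exclusions$low[i]
    if (.wn_match(hi, values) < 0 || .wn_match(lo, values) < 0) {
      stop("exclusion region ", hi, "-", lo, " has an endpoint off the grid")
    }
    keep[values <= hi + 1e-6 & values >= lo - 1e-6] <- FALSE
  }
  keep
}

# contiguous TRUE runs (contiguity judged on the wavenumber values, so runs
# never bridge pre-existing segment gaps) -> region_set
.runs_to_regions <- function(values, keep, step) {
  if (!any(keep)) return(region_set(numeric(0), numeric(0), step))
  idx <- which(keep)
  brk <- which(diff(idx) != 1 |
               abs(diff(values)[idx[-length(idx)]] + step) > 1e-6)
  starts <- idx[c(1, brk + 1)]
  ends <- idx[c(brk, length(idx))]
  region_set(values[starts], values[ends], step)
}

#' Jaccard overlap of two region sets
#'
#' Ratio of shared to total grid channels, used to score recovered
#' wavelength selections against planted ground-truth bands.
#'
#' @param a,b [region_set()] objects on the same step.
#' @return Numeric in `[0, 1]`; 0 when both are empty.
#' @export
region_jaccard <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  va <- round(region_values(a) / a$step_cm1)
  vb <- round(region_values(b) / b$step_cm1)
  u <- length(union(va, vb))
  if (u == 0) return(0)
  length(intersect(va, vb)) / u
}
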