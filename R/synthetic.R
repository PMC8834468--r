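#' Daily fermentation kinetics table
#'
#' Average ethanol (%), total soluble solids (degrees Brix), total acidity
#' (% as citric acid) and total volatile acids (% as acetic acid) over an
#' 11-day fruit-wine fermentation, used as the default concentration
#' kinetics of the synthetic generator. Ethanol and the acids rise, soluble
#' solids fall, as sugars are converted to ethanol.
#'
#' @return A `data.frame` with columns `day`, `ethanol`, `tss`, `ta`,
#'   `tva`.
#' @export
kinetics_table <- function() {
  data.frame(
    day = 0:10,
    ethanol = c(0.06, 0.40, 3.91, 5.54, 6.74, 7.75, 8.49, 9.06, 9.71,
                10.08, 10.76),
    tss = c(23.70, 23.17, 18.42, 15.88, 13.87, 12.33, 11.35, 10.83, 10.52,
            10.33, 10.25),
    ta = c(0.29, 0.32, 0.35, 0.38, 0.39, 0.41, 0.42, 0.44, 0.44, 0.45,
           0.46),
    tva = c(1.30, 1.30, 1.28, 1.50, 1.67, 1.65, 1.75, 1.80, 1.78, 1.78,
            1.80) * 1e-3)
}

#' Parametric (logistic) fermentation kinetics
#'
#' Alternative to the tabulated kinetics: each analyte follows
#' `floor + (ceiling - floor) / (1 + exp(-rate * (t - midpoint)))` in time
#' `t` (hours). A decreasing profile (soluble solids) simply has
#' `ceiling < floor`.
#'
#' @param ethanol,tss,ta,tva numeric vectors
#'   `c(rate, midpoint, floor, ceiling)` (rate in 1/h, midpoint in h,
#'   levels in the analyte's unit).
#' @return An object of class `parametric_kinetics`.
#' @export
parametric_kinetics <- function(
    ethanol = c(rate = 0.035, midpoint = 85, floor = 0.06, ceiling = 10.9),
    tss = c(rate = 0.035, midpoint = 80, floor = 23.7, ceiling = 10.2),
    ta = c(rate = 0.020, midpoint = 100, floor = 0.29, ceiling = 0.47),
    tva = c(rate = 0.020, midpoint = 120, floor = 1.25e-3,
            ceiling = 1.85e-3)) {
  structure(list(ethanol = ethanol, tss = tss, ta = ta, tva = tva),
            class = "parametric_kinetics")
}

#' Concentration profiles at given sampling times
#'
#' Table mode (a `data.frame` as from [kinetics_table()]) interpolates
#' linearly between daily values; times within one day past the last
#' tabulated day hold the final value (fermentation plateau), and times
#' outside that range are an error. Parametric mode evaluates the logistic
#' forms of [parametric_kinetics()]. A per-batch multiplicative factor can
#' be applied per analyte.
#'
#' @param times_h numeric vector of sampling times in hours.
#' @param kinetics a kinetics table or a [parametric_kinetics()] object.
#' @param batch_factors named multiplicative factors
#'   (`ethanol`, `tss`, `ta`, `tva`), default all 1.
#' @return A `data.frame` with `time_h` and the four analyte columns.
#' @export
kinetic_profiles <- function(times_h, kinetics = kinetics_table(),
                             batch_factors = c(ethanol = 1, tss = 1,
                                               ta = 1, tva = 1)) {
  stopifnot(is.numeric(times_h))
  analytes <- c("ethanol", "tss", "ta", "tva")
  out <- data.frame(time_h = times_h)
  if (inherits(kinetics, "parametric_kinetics")) {
    if (any(times_h < 0)) stop("sampling times must be non-negative")
    for (an in analytes) {
      p <- kinetics[[an]]
      out[[an]] <- p[3] + (p[4] - p[3]) /
        (1 + exp(-p[1] * (times_h - p[2])))
    }
  } else {
    stopifnot(is.data.frame(kinetics), all(analytes %in% names(kinetics)))
    grid_h <- kinetics$day * 24
    max_h <- max(grid_h)
    if (any(times_h < 0) || any(times_h > max_h + 24)) {
      stop("sampling times must lie in [0, ", max_h + 24,
           "] h for the tabulated kinetics")
    }
    tt <- pmin(times_h, max_h)
    for (an in analytes) {
      out[[an]] <- approx(grid_h, kinetics[[an]], xout = tt)$y
    }
  }
  for (an in analytes) {
    f <- batch_factors[[an]]
    if (!is.null(f) && !is.na(f)) out[[an]] <- out[[an]] * f
  }
  out
}

#' Default NIR absorption bands of the wine constituents
#'
#' Gaussian band models (center, width, amplitude per unit concentration)
#' for water and the four monitored constituents, placed at the overtone
#' and combination bands of O-H and C-H groups: water at ~6900 cm^-1 and at
#' the strong ~5100 cm^-1 combination feature that saturates the detector;
#' ethanol C-H first overtones inside 5976-5500 cm^-1 and C-H
#' stretch/deformation combinations inside 4504-4250 cm^-1 plus weaker
#' second-overtone (~8400) and O-H (~6800) features; sugar bands at 7056,
#' 6400, 5610 and ~4400 cm^-1; citric and acetic acid bands overlapping the
#' major constituents with small amplitudes, reproducing the low
#' signal-to-noise situation of the acids.
#'
#' Amplitudes are absorbance units per unit concentration (water is held at
#' concentration 1; ethanol and the acids in %, soluble solids in degrees
#' Brix).
#'
#' @return A named list of `data.frame`s (`center`, `width`, `amplitude`).
#' @export
default_bands <- function() {
  band <- function(center, width, amplitude) {
    data.frame(center = center, width = width, amplitude = amplitude)
  }
  list(
    water = band(c(8700, 6900, 5100), c(150, 120, 130), c(0.25, 1.2, 3.5)),
    ethanol = band(c(8400, 6800, 5900, 5780, 5650, 4450, 4340),
                   c(45, 55, 45, 40, 40, 35, 35),
                   c(0.004, 0.010, 0.018, 0.014, 0.012, 0.016, 0.014)),
    sugars = band(c(7056, 6400, 5610, 4400), c(60, 80, 45, 40),
                  c(0.006, 0.004, 0.008, 0.007)),
    citric = band(c(8400, 6896, 5800, 4350), c(50, 40, 45, 40),
                  c(0.010, 0.015, 0.012, 0.012)),
    acetic = band(c(8450, 6896, 5700, 4300), c(50, 40, 45, 40),
                  c(1.5, 2.0, 2.0, 2.0)))
}

#' Evaluate one component's spectrum on a grid
#'
#' Sum of Gaussian bands `amplitude * exp(-((v - center)/width)^2 / 2)`;
#' deterministic. An empty band list gives the zero spectrum.
#'
#' @param bands a `data.frame` with `center`, `width`, `amplitude`.
#' @param grid a [wn_grid()] or numeric vector of wavenumbers.
#' @return Numeric vector over the grid.
#' @export
component_spectrum <- function(bands, grid) {
  v <- if (inherits(grid, "wn_grid")) grid$values else as.numeric(grid)
  out <- numeric(length(v))
  if (is.null(bands) || nrow(bands) == 0) return(out)
  stopifnot(all(bands$width > 0))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-((v - bands$center[i]) / bands$width[i])^2 / 2)
  }
  out
}

#' Instrumental noise model for the generator
#'
#' @param additive_sd per-channel Gaussian noise sd (absorbance units).
#' @param offset_sd per-spectrum baseline offset sd.
#' @param slope_sd per-spectrum baseline slope sd (absorbance per channel).
#' @param scatter_sd sd of the per-spectrum multiplicative scatter factor.
#' @param clip_level detector saturation ceiling (absorbance); applied only
#'   inside `clip_high`-`clip_low`.
#' @param clip_high,clip_low wavenumber bounds of the saturated band.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(additive_sd = 1e-3, offset_sd = 5e-3,
                       slope_sd = 1e-5, scatter_sd = 0.01,
                       clip_level = 2.5, clip_high = 5248,
                       clip_low = 4984) {
  stopifnot(additive_sd >= 0, offset_sd >= 0, slope_sd >= 0, scatter_sd >= 0)
  structure(list(additive_sd = additive_sd, offset_sd = offset_sd,
                 slope_sd = slope_sd, scatter_sd = scatter_sd,
                 clip_level = clip_level, clip_high = clip_high,
                 clip_low = clip_low),
            class = "noise_spec")
}

#' Simulate one fermentation batch
#'
#' Generates a batch following the study design: `length(days)` sampling
#' days, `length(samplings_h)` sampling events per day at the given
#' within-day offsets, and `subsamples` replicate spectra per event (the
#' default 11 x 3 x 3 = 99 spectra). All subsamples of an event share the
#' event's concentrations but receive independent instrumental noise.
#' Each spectrum is
#' `scatter * (sum_c conc_c * component_c + water) + offset + slope * channel + noise`,
#' clipped at the saturation level inside the saturated band. The same seed
#' reproduces the batch bit for bit.
#'
#' @param seed integer seed for this batch.
#' @param batch batch identifier stored in the metadata.
#' @param grid acquisition [wn_grid()].
#' @param kinetics kinetics table or [parametric_kinetics()].
#' @param bands constituent band list, as [default_bands()].
#' @param noise a [noise_spec()].
#' @param days,samplings_h,subsamples sampling schedule. The default places
#'   three events per day at +0, +3 and +6 h, then an 18 h gap to the next
#'   day.
#' @param batch_effect_sd sd of the per-batch log-normal multiplicative
#'   concentration perturbation.
#' @return A list with `spectra` ([nir_spectra()]), `references`
#'   (`data.frame`), and `batch_factors`.
#' @export
simulate_batch <- function(seed, batch = 1, grid = wn_grid(11536, 3952, 8),
                           kinetics = kinetics_table(),
                           bands = default_bands(), noise = noise_spec(),
                           days = 0:10, samplings_h = c(0, 3, 6),
                           subsamples = 3, batch_effect_sd = 0.02) {
  sched <- expand.grid(sampling = seq_along(samplings_h), day = days)
  sched <- sched[order(sched$day, sched$sampling), ]
  times <- sched$day * 24 + samplings_h[sched$sampling]
  n <- length(times) * subsamples
  if (n < 2) stop("schedule produces fewer than 2 samples")
  set.seed(as.integer(seed))

  analytes <- c("ethanol", "tss", "ta", "tva")
  bf <- exp(rnorm(4, 0, batch_effect_sd))
  names(bf) <- analytes
  refs_event <- kinetic_profiles(times, kinetics, batch_factors = bf)

  v <- grid$values
  p <- length(v)
  comp <- sapply(c("ethanol", "sugars", "citric", "acetic"),
                 function(cn) component_spectrum(bands[[cn]], grid))
  water <- component_spectrum(bands$water, grid)
  clip_idx <- which(v <= noise$clip_high + 1e-6 & v >= noise$clip_low - 1e-6)

  ab <- matrix(0, n, p)
  meta <- data.frame(sample_id = character(n), batch = batch,
                     time_h = 0, subsample = 0L, stringsAsFactors = FALSE)
  refs <- refs_event[rep(seq_along(times), each = subsamples), analytes]
  row <- 0L
  for (e in seq_along(times)) {
    conc <- c(refs_event$ethanol[e], refs_event$tss[e], refs_event$ta[e],
              refs_event$tva[e])
    pure <- water + drop(comp %*% conc)
    for (r in seq_len(subsamples)) {
      row <- row + 1L
      scatter <- 1 + rnorm(1, 0, noise$scatter_sd)
      offset <- rnorm(1, 0, noise$offset_sd)
      slope <- rnorm(1, 0, noise$slope_sd)
      eps <- rnorm(p, 0, noise$additive_sd)
      spec <- scatter * pure + offset + slope * (seq_len(p) - 1) + eps
      if (length(clip_idx) > 0 && is.finite(noise$clip_level)) {
        spec[clip_idx] <- pmin(spec[clip_idx], noise$clip_level)
      }
      ab[row, ] <- spec
      meta$sample_id[row] <- sprintf("B%d_D%02d_T%d_R%d", batch,
                                     sched$day[e], sched$sampling[e], r)
      meta$time_h[row] <- times[e]
      meta$subsample[row] <- r
    }
  }
  rownames(ab) <- meta$sample_id
  references <- cbind(data.frame(sample_id = meta$sample_id,
                                 stringsAsFactors = FALSE), refs)
  rownames(references) <- NULL
  list(spectra = nir_spectra(ab, region_set(grid$high_cm1, grid$low_cm1,
                                            grid$step_cm1), meta),
       references = references,
       batch_factors = bf)
}

#' Combine spectra sets row-wise
#'
#' @param ... [nir_spectra()] objects on identical axes.
#' @return A [nir_spectra()].
#' @export
rbind_spectra <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "nir_spectra")))
  r0 <- xs[[1]]$regions
  for (x in xs[-1]) {
    if (!isTRUE(all.equal(region_values(x$regions), region_values(r0)))) {
      stop("spectra sets are on different axes")
    }
  }
  nir_spectra(do.call(rbind, lapply(xs, `[[`, "absorbance")), r0,
              do.call(rbind, lapply(xs, `[[`, "meta")))
}

#' Simulated multi-batch calibration / test study
#'
#' Generates three independent fermentation batches under the default
#' two-batch calibration / one-batch test design: batches 1 and 2 are
#' concatenated into the calibration set (198 spectra by default), batch 3
#' is the test set (99 spectra). Also returns, per analyte, the
#' ground-truth spectral regions actually carrying that analyte's signal
#' (the union of its band supports, center +/- 2 width, snapped to the
#' grid), for planted-region recovery checks.
#'
#' @param seed master seed; batch seeds are derived from it.
#' @param ... forwarded to [simulate_batch()].
#' @return A list with `calibration` and `test` (each `spectra` +
#'   `references`), `ground_truth` (named list of [region_set()]s), and
#'   `seed`.
#' @export
make_study_dataset <- function(seed = 1, ...) {
  args <- list(...)
  grid <- if (!is.null(args$grid)) args$grid else wn_grid(11536, 3952, 8)
  bands <- if (!is.null(args$bands)) args$bands else default_bands()
  b1 <- do.call(simulate_batch, c(list(seed = seed * 10 + 1, batch = 1),
                                  args))
  b2 <- do.call(simulate_batch, c(list(seed = seed * 10 + 2, batch = 2),
                                  args))
  b3 <- do.call(simulate_batch, c(list(seed = seed * 10 + 3, batch = 3),
                                  args))
  cal_refs <- rbind(b1$references, b2$references)
  rownames(cal_refs) <- NULL
  gt <- list(ethanol = .band_support(bands$ethanol, grid),
             tss = .band_support(bands$sugars, grid),
             ta = .band_support(bands$citric, grid),
             tva = .band_support(bands$acetic, grid))
  list(calibration = list(spectra = rbind_spectra(b1$spectra, b2$spectra),
                          references = cal_refs),
       test = list(spectra = b3$spectra, references = b3$references),
       ground_truth = gt,
       seed = seed)
}

# union of band supports (center +/- 2 width) snapped to the grid
.band_support <- function(bands, grid) {
  v <- grid$values
  mask <- rep(FALSE, length(v))
  for (i in seq_len(nrow(bands))) {
    mask[v <= bands$center[i] + 2 * bands$width[i] &
         v >= bands$center[i] - 2 * bands$width[i]] <- TRUE
  }
  .runs_to_regions(v, mask, grid$step_cm1)
}
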