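#' Run configuration for the end-to-end analysis
#'
#' Collects every tunable of the pipeline with defaults reproducing the
#' standard acquisition and modelling settings: 11,536-3,952 cm^-1 grid at
#' 8 cm^-1, exclusion of the saturated 5,248-4,984 cm^-1 band,
#' Savitzky-Golay second derivative (order 2, 7 points), MWPLSR window of
#' 20 points with up to 10 latent variables, exhaustive SCMWPLS search, and
#' 5% significance for the validation limits.
#'
#' @param analyte one of `"ethanol"`, `"tss"`, `"ta"`, `"tva"`.
#' @param seed master seed for the synthetic dataset.
#' @param grid_high,grid_low,grid_step acquisition grid (cm^-1).
#' @param exclusion [region_set()] removed before modelling.
#' @param preprocess_method `"second_derivative"` or `"none"`.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param mw_window,mw_k_max MWPLSR window size and residue-line count.
#' @param lv_ref,quantile_threshold informative-region detection settings.
#' @param w_min,w_max,stride,rel_improvement,order_policy SCMWPLS search
#'   controls (defaults: exhaustive).
#' @param alpha,n_effective evaluation settings; `n_effective = NULL` uses
#'   the test-set size.
#' @return A list of class `run_config`.
#' @export
run_config <- function(analyte = "ethanol", seed = 1,
                       grid_high = 11536, grid_low = 3952, grid_step = 8,
                       exclusion = region_set(5248, 4984, grid_step),
                       preprocess_method = "second_derivative",
                       sg_window = 7, sg_polyorder = 2,
                       mw_window = 20, mw_k_max = 10,
                       lv_ref = 3, quantile_threshold = 0.25,
                       w_min = 1, w_max = NULL, stride = 1,
                       rel_improvement = 0.02,
                       order_policy = "wavenumber",
                       alpha = 0.05, n_effective = NULL) {
  analyte <- match.arg(analyte, c("ethanol", "tss", "ta", "tva"))
  structure(list(analyte = analyte, seed = seed, grid_high = grid_high,
                 grid_low = grid_low, grid_step = grid_step,
                 exclusion = exclusion,
                 preprocess_method = preprocess_method,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 mw_window = mw_window, mw_k_max = mw_k_max,
                 lv_ref = lv_ref, quantile_threshold = quantile_threshold,
                 w_min = w_min, w_max = w_max, stride = stride,
                 rel_improvement = rel_improvement,
                 order_policy = order_policy, alpha = alpha,
                 n_effective = n_effective),
            class = "run_config")
}

#' End-to-end wavelength-selection and calibration run
#'
#' Executes the full analysis for one analyte: (optionally simulated)
#' calibration and test sets, saturated-band exclusion, second-derivative
#' pretreatment, MWPLSR residue lines, informative-region detection,
#' SCMWPLS optimization, final PLS-1 calibration with the latent-variable
#' count selected by leave-one-out cross-validation, and evaluation on the
#' test set -- for both the whole-region model and the SCMWPLS model, so
#' the two can be compared side by side.
#'
#' @param config a [run_config()].
#' @param data optional dataset shaped like [make_study_dataset()] output;
#'   simulated from `config$seed` when omitted.
#' @param regions optional [region_set()] of informative regions, taken
#'   verbatim instead of detection (the reproduction path for hand-picked
#'   regions).
#' @return An object of class `nir_run` containing the residue lines, the
#'   detected and optimized regions, both fitted models, both evaluations
#'   and a comparison table.
#' @export
run_pipeline <- function(config = run_config(), data = NULL,
                         regions = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) data <- make_study_dataset(seed = config$seed)
  an <- config$analyte
  y_cal <- data$calibration$references[[an]]
  y_test <- data$test$references[[an]]

  prep <- function(s) {
    s <- exclude_regions(s, config$exclusion)
    preprocess(s, config$preprocess_method, window = config$sg_window,
               polyorder = config$sg_polyorder)
  }
  cal <- prep(data$calibration$spectra)
  test <- prep(data$test$spectra)

  lines <- mwplsr(cal, y_cal, window = config$mw_window,
                  k_max = config$mw_k_max)
  informative <- informative_regions(lines, lv_ref = config$lv_ref,
                                     quantile_threshold =
                                       config$quantile_threshold,
                                     regions = regions)
  opt <- scmwpls(cal, y_cal, informative, k_max = config$mw_k_max,
                 w_min = config$w_min, w_max = config$w_max,
                 stride = config$stride,
                 rel_improvement = config$rel_improvement,
                 order_policy = config$order_policy)

  fit_and_eval <- function(spectra_cal, spectra_test, label, points) {
    kmax <- min(config$mw_k_max, nrow(spectra_cal$absorbance) - 2L,
                ncol(spectra_cal$absorbance))
    cv <- loo_rmsecv(spectra_cal, y_cal, k_max = kmax)
    model <- pls1(spectra_cal, y_cal, ncomp = cv$chosen_lv)
    ev <- evaluate_model(model, spectra_test, y_test,
                         n_effective = config$n_effective,
                         alpha = config$alpha)
    list(label = label, cv = cv, model = model, evaluation = ev,
         points = points)
  }

  whole <- fit_and_eval(cal, test, "whole region", n_points(cal$regions))
  sel_cal <- extract_regions(cal, opt$optimized_regions)
  sel_test <- extract_regions(test, opt$optimized_regions)
  selected <- fit_and_eval(sel_cal, sel_test,
                           paste0("SCMWPLS (",
                                  format(opt$optimized_regions), ")"),
                           n_points(opt$optimized_regions))

  comparison <- do.call(rbind, lapply(list(whole, selected), function(m) {
    e <- m$evaluation
    data.frame(method = m$label, lv = e$lv_used, r2 = e$r2,
               rmsec = e$rmsec, rmsep = e$rmsep, rpd = e$rpd,
               points = m$points, stringsAsFactors = FALSE)
  }))

  structure(list(analyte = an, config = config, residue_lines = lines,
                 informative_regions = informative, scmwpls = opt,
                 whole = whole, selected = selected,
                 comparison = comparison,
                 ground_truth = data$ground_truth[[an]]),
            class = "nir_run")
}

#' @export
print.nir_run <- function(x, ...) {
  cat("End-to-end NIR calibration run -- analyte:", x$analyte, "\n")
  cat("  informative regions:", format(x$informative_regions), "cm^-1\n")
  cat("  optimized regions: ", format(x$scmwpls$optimized_regions),
      "cm^-1\n\n")
  df <- x$comparison
  df$r2 <- round(df$r2, 4)
  for (cn in c("rmsec", "rmsep", "rpd")) df[[cn]] <- signif(df[[cn]], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
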