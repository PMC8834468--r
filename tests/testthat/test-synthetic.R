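test_that("tabulated kinetics interpolate the daily averages", {
  pr <- kinetic_profiles(c(0, 240))
  expect_equal(pr$ethanol, c(0.06, 10.76))
  expect_equal(pr$tss, c(23.70, 10.25))
  expect_equal(pr$ta, c(0.29, 0.46))
  expect_equal(pr$tva, c(1.30e-3, 1.80e-3))

  # midpoint of day 2 -> 3 is the average of the two daily values
  mid <- kinetic_profiles(60)
  expect_equal(mid$ethanol, (3.91 + 5.54) / 2)

  # ethanol never decreases, solids never increase, on a fine grid
  fine <- kinetic_profiles(seq(0, 246, by = 1.5))
  expect_true(all(diff(fine$ethanol) >= 0))
  expect_true(all(diff(fine$tss) <= 0))

  # plateau within one day past the table, error beyond
  expect_equal(kinetic_profiles(246)$ethanol, 10.76)
  expect_error(kinetic_profiles(300), "lie in")
  expect_error(kinetic_profiles(-1), "lie in")

  # parametric mode is monotone between floor and ceiling
  par <- kinetic_profiles(seq(0, 240, by = 6), parametric_kinetics())
  expect_true(all(diff(par$ethanol) > 0))
  expect_true(all(diff(par$tss) < 0))
  expect_true(all(par$ethanol >= 0.06 - 1e-9 & par$ethanol <= 10.9))
})

test_that("component spectra are Gaussian band sums with expected extrema", {
  g <- wn_grid(11536, 3952, 8)
  expect_equal(component_spectrum(data.frame(center = numeric(0),
                                             width = numeric(0),
                                             amplitude = numeric(0)), g),
               numeric(949))
  one <- component_spectrum(data.frame(center = 6000, width = 50,
                                       amplitude = 2), g)
  expect_equal(g$values[which.max(one)], 6000)
  expect_equal(max(one), 2, tolerance = 1e-6)

  # the strongest second-derivative ethanol features sit inside the C-H
  # first-overtone (5976-5500) and combination (4504-4250) windows
  eth <- component_spectrum(default_bands()$ethanol, g)
  sp <- nir_spectra(rbind(eth, eth), region_set(11536, 3952, 8))
  d2 <- sg_second_derivative(sp)
  v <- wavenumbers(d2)
  a <- abs(d2$absorbance[1, ])
  top2 <- v[order(a, decreasing = TRUE)[1:2]]
  inside <- (top2 <= 5976 & top2 >= 5500) | (top2 <= 4504 & top2 >= 4250)
  expect_true(all(inside))
})

test_that("a simulated batch follows the 11 x 3 x 3 design and seed contract", {
  b <- simulate_batch(seed = 7)
  expect_equal(nrow(b$spectra$absorbance), 99)
  expect_equal(ncol(b$spectra$absorbance), 949)
  expect_equal(nrow(b$references), 99)
  # subsamples of one event share concentrations
  expect_equal(b$references$ethanol[1], b$references$ethanol[3])

  b2 <- simulate_batch(seed = 7)
  expect_identical(b$spectra$absorbance, b2$spectra$absorbance)
  b3 <- simulate_batch(seed = 8)
  expect_false(identical(b$spectra$absorbance, b3$spectra$absorbance))
  expect_error(simulate_batch(seed = 1, days = 0, samplings_h = 0,
                              subsamples = 1), "fewer than 2")
})

test_that("noiseless spectra are exact linear mixtures of low rank", {
  ns0 <- noise_spec(additive_sd = 0, offset_sd = 0, slope_sd = 0,
                    scatter_sd = 0, clip_level = Inf)
  b <- simulate_batch(seed = 9, noise = ns0, batch_effect_sd = 0)
  g <- wn_grid(11536, 3952, 8)
  bands <- default_bands()
  C <- sapply(c("ethanol", "sugars", "citric", "acetic"),
              function(cn) component_spectrum(bands[[cn]], g))
  W <- component_spectrum(bands$water, g)
  for (i in c(1, 50, 99)) {
    fit <- lm.fit(cbind(1, C), b$spectra$absorbance[i, ] - W)
    expect_lt(max(abs(fit$coefficients[-1] -
                        as.numeric(b$references[i, c("ethanol", "tss",
                                                     "ta", "tva")]))),
              1e-8)
  }
  # rank <= number of components (water is constant, folded into the mean)
  sv <- svd(sweep(b$spectra$absorbance, 2,
                  colMeans(b$spectra$absorbance)))$d
  expect_lt(sv[5] / sv[1], 1e-10)
})

test_that("saturation clips only inside the excluded water band", {
  b <- simulate_batch(seed = 10)
  v <- wavenumbers(b$spectra)
  inside <- v <= 5248 & v >= 4984
  expect_true(all(b$spectra$absorbance[, inside] <= 2.5 + 1e-12))
  expect_gt(max(b$spectra$absorbance[, inside]), 2.5 - 1e-6)  # clip active
  expect_lt(max(b$spectra$absorbance[, !inside]), 2.5)
})

test_that("the study dataset has the two-batch / one-batch structure", {
  d <- make_study_dataset(seed = 4)
  expect_equal(nrow(d$calibration$spectra$absorbance), 198)
  expect_equal(nrow(d$test$spectra$absorbance), 99)
  expect_equal(unique(d$calibration$spectra$meta$batch), c(1, 2))
  expect_equal(unique(d$test$spectra$meta$batch), 3)

  # every planted ground-truth channel lies inside some band support
  gt <- d$ground_truth$ethanol
  bands <- default_bands()$ethanol
  for (v in region_values(gt)) {
    expect_true(any(abs(v - bands$center) <= 2 * bands$width + 8))
  }
})

test_that("calibration ranges cover test ranges up to the batch-effect margin", {
  # strict coverage of an i.i.d. batch's range is a coin flip; coverage
  # within a 3-sigma multiplicative batch-effect margin is the design
  # property the generator guarantees
  m <- exp(3 * 0.02)
  ok <- vapply(1:20, function(s) {
    d <- make_study_dataset(seed = s)
    all(vapply(c("ethanol", "tss", "ta", "tva"), function(an) {
      rc <- range(d$calibration$references[[an]])
      rt <- range(d$test$references[[an]])
      rc[1] / m <= rt[1] && rc[2] * m >= rt[2]
    }, NA))
  }, NA)
  expect_gte(sum(ok), 18)
})

test_that("more instrument noise never helps a fixed calibration model", {
  d <- make_study_dataset(seed = 3)
  prep <- function(s) preprocess(exclude_regions(s, region_set(5248, 4984)))
  model <- pls1(prep(d$calibration$spectra),
                d$calibration$references$ethanol, ncomp = 3)
  rmseps <- vapply(c(1e-3, 5e-3, 2e-2), function(sdv) {
    mean(vapply(1:10, function(s) {
      tb <- simulate_batch(seed = 1000 + s, batch = 9,
                           noise = noise_spec(additive_sd = sdv))
      pr <- predict(model, prep(tb$spectra))
      sqrt(mean((pr - tb$references$ethanol)^2))
    }, 0))
  }, 0)
  expect_true(all(diff(rmseps) > 0))
})
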