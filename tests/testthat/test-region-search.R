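test_that("moving-window sweep covers every admissible position", {
  set.seed(51)
  sp <- as_spectra(matrix(rnorm(30 * 100), 30, 100))
  y <- rnorm(30)
  lines <- mwplsr(sp, y, window = 20, k_max = 10)
  expect_equal(nrow(lines$loss), 100 - 20 + 1)
  expect_equal(ncol(lines$loss), 10)
  expect_equal(lines$positions$high_cm1[1], 8000)
  expect_error(mwplsr(sp, y, window = 10, k_max = 10), "larger than k_max")
})

test_that("residue lines equal direct per-window fits and are monotone in LVs", {
  set.seed(52)
  sp <- as_spectra(matrix(rnorm(25 * 40), 25, 40))
  t1 <- rnorm(25)
  y <- t1 + rnorm(25, sd = 0.3)
  sp$absorbance[, 15:20] <- sp$absorbance[, 15:20] + t1
  lines <- mwplsr(sp, y, window = 20, k_max = 5)
  for (i in c(1, 7, 21)) {
    cols <- lines$positions$start_col[i] + 0:19
    for (k in 1:5) {
      expect_equal(unname(lines$loss[i, k]),
                   log10(pls1_ssr(sp$absorbance[, cols], y, k)),
                   tolerance = 1e-8)
    }
  }
  expect_true(all(apply(lines$loss, 1, function(r) all(diff(r) <= 1e-10))))
})

test_that("windows are confined to contiguous segments", {
  set.seed(53)
  sp <- as_spectra(matrix(rnorm(30 * 60), 30, 60))
  gap <- exclude_regions(sp, region_set(7808, 7800, 8))  # 24 + 34 channels
  y <- rnorm(30)
  lines <- mwplsr(gap, y, window = 20, k_max = 5)
  expect_equal(nrow(lines$loss), (24 - 19) + (34 - 19))
  # no window spans the gap
  expect_true(all(lines$positions$high_cm1 - lines$positions$low_cm1 ==
                    19 * 8))
  short <- exclude_regions(sp, region_set(7856, 7824, 8))  # 18 + 37
  expect_warning(l2 <- mwplsr(short, y, window = 20, k_max = 5), "skipped")
  expect_equal(nrow(l2$loss), 37 - 19)
})

test_that("detection concentrates on planted signal but not on noise", {
  jac <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    p <- 100
    X <- matrix(rnorm(n * p), n, p)
    beta <- numeric(p)
    beta[40:60] <- 1
    y <- drop(X %*% beta) + rnorm(n, sd = 0.5)
    sp <- as_spectra(X)
    det <- informative_regions(mwplsr(sp, y), lv_ref = 3,
                               quantile_threshold = 0.25)
    planted <- region_set(8000 - 8 * 39, 8000 - 8 * 59, 8)
    region_jaccard(det, planted)
  }, 0)
  expect_gte(sum(jac >= 0.5), 18)

  # pure noise: selection exists (a quantile always selects) but stays
  # bounded and unconcentrated
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(80 * 120), 80, 120)
    sp <- as_spectra(X)
    det <- suppressWarnings(
      informative_regions(mwplsr(sp, rnorm(80)), lv_ref = 3,
                          quantile_threshold = 0.1))
    expect_lte(n_points(det), 60)
  }
})

test_that("manual mode returns hand-picked regions verbatim", {
  set.seed(54)
  sp <- as_spectra(matrix(rnorm(20 * 30), 20, 30))
  lines <- mwplsr(sp, rnorm(20), window = 20, k_max = 5)
  manual <- parse_regions("9200-5408, 4976-4008")
  out <- informative_regions(lines, regions = manual)
  expect_identical(out$high, manual$high)
  expect_identical(out$low, manual$low)
})

test_that("sub-window search matches exhaustive enumeration via pls1", {
  for (s in 1:4) {
    set.seed(s)
    n <- 25
    p <- sample(8:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    sp <- as_spectra(X, high = 6000)
    reg <- region_set(6000, 6000 - 8 * (p - 1), 8)
    got <- scmwpls_best_subwindow(sp, y, reg)
    bb <- brute_best_subwindow(sp, y, reg)
    exp_hi <- 6000 - 8 * (bb$st - 1)
    expect_equal(got$region$high, exp_hi)
    expect_equal(got$region$low, exp_hi - 8 * (bb$w - 1))
    expect_equal(got$rmsec, bb$rm, tolerance = 1e-8)
    # never worse than the full region at the same cap
    full <- pls1(X, y, ncomp = bb$k)$rmsec
    expect_lte(got$rmsec, full + 1e-10)
  }
  # single-channel region: only one candidate
  sp1 <- as_spectra(matrix(rnorm(40), 20, 2), high = 6000)
  got1 <- scmwpls_best_subwindow(sp1, rnorm(20), region_set(6000, 6000, 8))
  expect_equal(got1$region$high, 6000)
  expect_equal(got1$region$low, 6000)
})

test_that("sub-window search localizes a planted two-channel signal", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    p <- 60
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, 25] + X[, 26]) + rnorm(n, sd = 0.1)
    sp <- as_spectra(X, high = 6000)
    got <- scmwpls_best_subwindow(sp, y,
                                  region_set(6000, 6000 - 8 * (p - 1), 8))
    hi <- 6000 - 8 * 24
    lo <- 6000 - 8 * 25
    got$region$high >= hi && got$region$low <= lo
  }, NA)
  expect_gte(sum(hits), 18)
})

test_that("a single informative region degenerates to the sub-window search", {
  set.seed(55)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rnorm(30)
  sp <- as_spectra(X, high = 6000)
  reg <- region_set(6000, 6000 - 8 * 11, 8)
  a <- scmwpls_best_subwindow(sp, y, reg)
  b <- scmwpls(sp, y, reg)
  expect_equal(b$optimized_regions$high, a$region$high)
  expect_equal(b$optimized_regions$low, a$region$low)
  expect_equal(b$rmsec, a$rmsec, tolerance = 1e-12)
  expect_error(scmwpls(sp, y, region_set(numeric(0), numeric(0), 8)),
               "empty")
})

test_that("two-region combination matches the exhaustive oracle", {
  for (s in 1:3) {
    set.seed(s)
    n <- 30
    pA <- 10
    pB <- 9
    X <- matrix(rnorm(n * (pA + pB + 5)), n)
    sp <- as_spectra(X)
    y <- rnorm(n)
    rA <- region_set(8000, 8000 - 8 * (pA - 1), 8)
    hiB <- 8000 - 8 * (pA + 5)
    rB <- region_set(hiB, hiB - 8 * (pB - 1), 8)
    got <- scmwpls(sp, y, region_set(c(rA$high, rB$high),
                                     c(rA$low, rB$low), 8))
    bb <- brute_two_region_combine(sp, y, rA, rB)
    expect_equal(got$rmsec, bb$rm, tolerance = 1e-8)
  }
})

test_that("combination finds the signal region and its trace is consistent", {
  set.seed(56)
  n <- 300
  p <- 100
  X <- matrix(rnorm(n * p), n, p)
  sp <- as_spectra(X)
  rs <- region_set(c(8000, 7792, 7584, 7376), c(7856, 7648, 7440, 7232), 8)
  # signal lives inside the third region (7584-7440)
  y <- drop(X[, 58:63] %*% rep(1, 6)) + rnorm(n, sd = 0.3)
  got <- suppressWarnings(scmwpls(sp, y, rs))
  # accepted-step RMSEC never increases
  expect_true(all(diff(got$trace$rmsec) <= 1e-10))
  # a sub-interval of the signal region is part of the optimized set
  hit <- any(got$optimized_regions$high <= 7584 &
               got$optimized_regions$low >= 7440)
  expect_true(hit)
  # the final RMSEC is reproduced by an independent refit on the optimized
  # regions at the same factor count
  refit <- pls1(extract_regions(sp, got$optimized_regions), y,
                ncomp = got$lv_used)
  expect_equal(refit$rmsec, got$rmsec, tolerance = 1e-10)
  expect_lt(got$rmsec, sd(y))
})
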