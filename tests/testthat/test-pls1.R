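test_that("a single proportional column is fitted exactly with one factor", {
  set.seed(31)
  y <- rnorm(15) + 3
  X <- cbind(2 * y)
  m <- pls1(X, y, ncomp = 1)
  expect_lt(max(abs(residuals(m))), 1e-10)
  expect_lt(pls1_ssr(X, y, 1), 1e-18)
})

test_that("at full rank PLS-1 training predictions equal ordinary least squares", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(15:25, 1)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- pls1(X, y, ncomp = p)
    ols <- lm.fit(cbind(1, X), y)
    expect_lt(max(abs(fitted(m) - ols$fitted.values)), 1e-8)
  }
})

test_that("predictions agree with the Krylov-projection oracle at every factor count", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(12:20, 1)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    for (k in 1:p) {
      m <- pls1(X, y, ncomp = k)
      expect_lt(max(abs(fitted(m) - arnoldi_fitted(X, y, k))), 1e-8)
    }
  }
})

test_that("score vectors are mutually orthogonal and the fit is deterministic", {
  set.seed(34)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rnorm(30)
  m <- pls1(X, y, ncomp = 6)
  G <- crossprod(m$scores[, 1:6])
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  m2 <- pls1(X, y, ncomp = 6)
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("SSR obeys its algebraic identities", {
  set.seed(35)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- rnorm(15)
  for (k in c(1, 3, 5)) {
    m <- pls1(X, y, ncomp = k)
    expect_equal(pls1_ssr(X, y, k), sum(residuals(m)^2), tolerance = 1e-10)
    expect_equal(pls1_ssr(X, y, k) / 15, m$rmsec^2, tolerance = 1e-12)
  }
})

test_that("RMSEC is non-increasing in the factor count", {
  set.seed(36)
  for (i in 1:50) {
    n <- sample(10:25, 1)
    p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    path <- pls1(X, y, ncomp = min(n - 1, p))$rmsec_path
    expect_true(all(diff(path) <= 1e-12))
  }
})

test_that("predictions are invariant to a global positive rescaling of X", {
  set.seed(37)
  X <- matrix(rnorm(20 * 7), 20, 7)
  y <- rnorm(20)
  Xnew <- matrix(rnorm(5 * 7), 5, 7)
  for (k in c(1, 3, 5)) {
    m1 <- pls1(X, y, ncomp = k)
    m2 <- pls1(X * 1e3, y, ncomp = k)
    expect_lt(max(abs(predict(m1, Xnew) - predict(m2, Xnew * 1e3))), 1e-8)
  }
})

test_that("prediction applies the stored centering", {
  set.seed(38)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rnorm(12)
  m <- pls1(X, y, ncomp = 2)
  expect_equal(unname(predict(m, X)), unname(fitted(m)), tolerance = 1e-12)
  expect_equal(unname(predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-12)
  expect_error(predict(m, X[, 1:3]), "channels")
})

test_that("fit preconditions are enforced", {
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_error(pls1(X, rnorm(10), ncomp = 5), "ncomp")
  expect_error(pls1(X, rep(1, 10), ncomp = 1), "zero variance")
})

test_that("leave-one-out folds equal explicit refits on the remaining samples", {
  set.seed(39)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rnorm(12)
  cv <- suppressWarnings(loo_rmsecv(X, y, k_max = 3))
  for (i in c(1, 5, 12)) {
    for (k in 1:3) {
      m <- pls1(X[-i, ], y[-i], ncomp = k)
      expect_equal(cv$predictions[i, k],
                   unname(predict(m, X[i, , drop = FALSE])),
                   tolerance = 1e-10)
    }
  }
  rmsecv <- sqrt(colMeans((cv$predictions - y)^2))
  expect_equal(cv$rmsecv, rmsecv, tolerance = 1e-12)
})

test_that("the cross-validated factor count follows the first-rise rule", {
  # y driven by one latent direction: the curve rises after k = 1
  set.seed(40)
  n <- 40
  t1 <- rnorm(n)
  X <- cbind(t1, t1, t1) + matrix(rnorm(n * 3, sd = 0.01), n, 3)
  y <- 2 * t1 + rnorm(n, sd = 0.2)
  cv <- loo_rmsecv(X, y, k_max = 2)
  expect_equal(cv$chosen_lv, 1L)
  expect_lt(cv$rmsecv[1], cv$rmsecv[2])

  # strictly decreasing curve falls back to k_max with a warning
  set.seed(41)
  U <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  V <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
  Xs <- U %*% diag(c(8, 4, 2)) %*% t(V) +
    matrix(rnorm(60 * 8, sd = 0.01), 60, 8)
  ys <- drop(U %*% c(3, 2, 1.5)) + rnorm(60, sd = 0.01)
  expect_warning(cv2 <- loo_rmsecv(Xs, ys, k_max = 2), "non-increasing")
  expect_equal(cv2$chosen_lv, 2L)
  expect_error(loo_rmsecv(Xs, ys, k_max = 40), "k_max")
})

test_that("the within-search factor cap stops where RMSEC gains flatten", {
  # exact one-factor data
  set.seed(42)
  y <- rnorm(30)
  X <- cbind(y, 2 * y, -y) + matrix(rnorm(90, sd = 1e-8), 30, 3)
  expect_equal(max_lv_for_region(X, y), 1L)
  expect_equal(max_lv_for_region(matrix(rnorm(300), 30, 10), rnorm(30),
                                 k_cap = 1), 1L)

  # three well-separated latent directions demand exactly three factors
  for (s in 1:5) {
    set.seed(s)
    n <- 400
    U <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
    V <- qr.Q(qr(matrix(rnorm(10 * 3), 10, 3)))
    X3 <- U %*% diag(c(8, 4, 2)) %*% t(V) +
      matrix(rnorm(n * 10, sd = 0.01), n, 10)
    y3 <- drop(U %*% c(3, 2, 1.5)) + rnorm(n, sd = 0.1)
    expect_equal(max_lv_for_region(X3, y3), 3L)
  }
})
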