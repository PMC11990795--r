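test_that("one latent variable fits a single-factor response exactly", {
  set.seed(1)
  # orthonormal zero-mean columns (QR of a centered matrix): the
  # y-carrying column is then the exact first component and a single
  # latent variable reproduces y
  X <- qr.Q(qr(scale(matrix(rnorm(60), 20), scale = FALSE)))[, 1:2]
  y <- 3 * X[, 2] + 1
  m <- pls_fit(X, y, n_lv = 1)
  expect_lt(max(abs(pls_predict(m, X) - y)), 1e-8)
})

test_that("maximal-LV PLS equals the least-squares solution", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 8), 50)
    y <- X %*% rnorm(8) + rnorm(50)
    m <- pls_fit(X, y, n_lv = 8)
    b <- stats::coef(stats::lm(y ~ X))
    expect_lt(max(abs(c(m$intercept, m$coefficients) - b)), 1e-8)
  }
})

test_that("duplicated columns share coefficient weight symmetrically", {
  set.seed(2)
  x <- rnorm(30)
  X <- cbind(x, x, matrix(rnorm(60), 30))
  y <- 2 * x + rnorm(30, 0, 0.1)
  m <- pls_fit(X, y, n_lv = 2)
  expect_lt(abs(m$coefficients[1] - m$coefficients[2]), 1e-8)
})

test_that("prediction identities hold", {
  set.seed(3)
  X <- matrix(rnorm(80), 20)
  y <- rnorm(20, 22)
  m <- pls_fit(X, y, n_lv = 2)
  # at the column means the prediction is the response mean
  expect_equal(as.vector(pls_predict(m, rbind(colMeans(X)))), mean(y))
  # affine in the input
  X2 <- matrix(rnorm(80), 20)
  a <- 0.3
  expect_equal(pls_predict(m, a * X + (1 - a) * X2),
               a * pls_predict(m, X) + (1 - a) * pls_predict(m, X2),
               tolerance = 1e-10)
  expect_error(pls_predict(m, X[, 1:2]), "dimension mismatch")
})

test_that("rank and degenerate-input guards fire", {
  set.seed(4)
  X <- matrix(rnorm(30), 10)
  expect_error(pls_fit(X, rep(5, 10), 1), "zero-variance y")
  expect_error(pls_fit(X, rnorm(10), 4), "min\\(n - 1, p\\)")
  Xr <- cbind(X[, 1], X[, 1], X[, 1])       # rank 1
  expect_error(pls_fit(Xr, rnorm(10), 3), "rank")
})

test_that("internal autoscaling makes predictions scale-invariant", {
  set.seed(5)
  X <- matrix(rnorm(100), 25)
  y <- X %*% c(1, -1, 2, 0) + rnorm(25, 0, 0.2)
  m1 <- pls_fit(X, y, 2, scale = TRUE)
  Xs <- X; Xs[, 2] <- X[, 2] * 100
  m2 <- pls_fit(Xs, y, 2, scale = TRUE)
  Xn <- matrix(rnorm(40), 10); Xns <- Xn; Xns[, 2] <- Xn[, 2] * 100
  expect_equal(pls_predict(m1, Xn), pls_predict(m2, Xns), tolerance = 1e-8)
})

test_that("cross-validation selects, scores and reproduces", {
  set.seed(6)
  # rank-1 signal in a rank-1 X: noiseless single-factor world
  t_sc <- rnorm(40)
  X <- t_sc %*% t(c(1, 0.5, -2, 1, 0.2, 0.7))
  y <- 2 * t_sc
  cv <- cross_validate(X, y, max_lv = 1, k = 5, seed = 9)
  expect_lt(cv$rmsecv[1], 1e-8)
  expect_equal(cv$n_lv, 1L)

  Xr <- matrix(rnorm(40 * 6), 40)
  yr <- as.vector(Xr %*% c(2, 1, 0, 0, 0, 0)) + rnorm(40, 0, 0.2)
  cvr <- cross_validate(Xr, yr, max_lv = 4, k = 5, seed = 9)
  expect_identical(cvr$rmsecv, cross_validate(Xr, yr, max_lv = 4, k = 5,
                                              seed = 9)$rmsecv)
  # a different fold seed changes the folds but not reproducibility
  expect_false(identical(cvr$folds,
                         cross_validate(Xr, yr, max_lv = 4, k = 5,
                                        seed = 10)$folds))
})

test_that("pure-noise response cannot reach spuriously small RMSECV", {
  set.seed(7)
  X <- matrix(rnorm(40 * 10), 40)
  y <- rnorm(40)
  cv <- cross_validate(X, y, max_lv = 6, k = 5, seed = 1)
  expect_true(all(cv$rmsecv >= sd(y) * 0.8))
})

test_that("k = n equals the brute-force leave-one-out oracle", {
  set.seed(8)
  X <- matrix(rnorm(10 * 3), 10)
  y <- X %*% c(1, 2, -1) + rnorm(10, 0, 0.3)
  cv <- cross_validate(X, y, max_lv = 2, k = 10, fold_scheme = "blocks")
  oracle <- sapply(1:2, function(lv) {
    pred <- vapply(seq_len(10), function(i) {
      m <- pls_fit(X[-i, ], y[-i], lv)
      pls_predict(m, X[i, , drop = FALSE])
    }, numeric(1))
    rmse_of(pred, y)
  })
  expect_equal(as.vector(cv$rmsecv), oracle, tolerance = 1e-10)
  expect_error(cross_validate(X, y, max_lv = 2, k = 11), "<= n")
})
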