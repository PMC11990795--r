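fit_members <- function(n = 40, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 9), n)
  y <- as.vector(X %*% c(2, 1, 0.5, rep(0, 6))) + 22 + rnorm(n, 0, 0.5)
  members <- lapply(list(1:3, 4:6, 7:9), function(idx) {
    pls_fit(X[, idx, drop = FALSE], y, n_lv = 2, variable_indices = idx)
  })
  list(X = X, y = y, members = members)
}

test_that("identical members get exactly equal weights (one-shot mode)", {
  d <- fit_members()
  m <- d$members[[1]]
  preds <- pls_predict(m, d$X[, m$variable_indices])
  ens <- adaboost_fit(list(m, m, m), d$X, d$y,
                      cv_predictions = list(preds, preds, preds),
                      update_samples = FALSE)
  expect_identical(ens$weights, rep(1 / 3, 3))
})

test_that("constructed errors reproduce the closed-form weight ratio", {
  # deviations chosen so the graded losses give eps exactly 0.1 and 0.4
  n <- 10
  y <- rep(20, n)
  p1 <- y + 0.2   # loss = 0.5 * 0.2 / 1 = 0.1 each
  p2 <- y + 0.8   # loss = 0.4 each
  m <- pls_fit(matrix(rnorm(3 * n), n), rnorm(n, 20), 1)  # members unused by weighting
  ens <- adaboost_fit(list(m, m), matrix(0, n, 3), y,
                      cv_predictions = list(p1, p2), update_samples = FALSE)
  expect_equal(ens$training_errors, c(0.1, 0.4))
  # alpha = ln((1-eps)/eps): ln 9 and ln 1.5
  expect_equal(ens$weights[1] / ens$weights[2], log(9) / log(1.5),
               tolerance = 1e-12)
})

test_that("a single member gets weight one", {
  d <- fit_members(seed = 2)
  m <- d$members[[1]]
  ens <- adaboost_fit(list(m), d$X, d$y,
                      cv_predictions = list(pls_predict(m, d$X[, 1:3])))
  expect_identical(ens$weights, 1)
  expect_equal(ensemble_predict(ens, d$X),
               pls_predict(m, d$X[, 1:3]))
})

test_that("weights are a probability vector and order-symmetric one-shot", {
  d <- fit_members(seed = 3)
  preds <- lapply(d$members, function(m)
    pls_predict(m, d$X[, m$variable_indices]))
  ens <- adaboost_fit(d$members, d$X, d$y, cv_predictions = preds,
                      update_samples = FALSE)
  expect_true(all(ens$weights >= 0))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  ens2 <- adaboost_fit(d$members[perm], d$X, d$y, cv_predictions = preds[perm],
                       update_samples = FALSE)
  expect_equal(ens2$weights, ens$weights[perm], tolerance = 1e-12)
})

test_that("sequential mode re-emphasizes hard samples deterministically", {
  d <- fit_members(seed = 4)
  preds <- lapply(d$members, function(m)
    pls_predict(m, d$X[, m$variable_indices]))
  seq1 <- adaboost_fit(d$members, d$X, d$y, cv_predictions = preds)
  seq2 <- adaboost_fit(d$members, d$X, d$y, cv_predictions = preds)
  expect_identical(seq1$weights, seq2$weights)
  expect_equal(sum(seq1$weights), 1, tolerance = 1e-12)
})

test_that("high-error members are down-weighted toward zero with warning", {
  n <- 12
  y <- rep(20, n)
  good <- y + 0.1
  bad <- y + 5          # loss 1 for every sample -> eps 1
  m <- pls_fit(matrix(rnorm(3 * n), n), rnorm(n, 20), 1)
  expect_warning(
    ens <- adaboost_fit(list(m, m), matrix(0, n, 3), y,
                        cv_predictions = list(good, bad),
                        update_samples = FALSE),
    "down-weighted")
  expect_identical(ens$weights, c(1, 0))
})

test_that("ensemble predictions are convex combinations of member predictions", {
  d <- fit_members(seed = 5)
  preds <- lapply(d$members, function(m)
    pls_predict(m, d$X[, m$variable_indices]))
  ens <- adaboost_fit(d$members, d$X, d$y, cv_predictions = preds)
  set.seed(9)
  Xn <- matrix(rnorm(15 * 9), 15)
  yp <- ensemble_predict(ens, Xn)
  mp <- vapply(d$members, function(m)
    pls_predict(m, Xn[, m$variable_indices]), numeric(15))
  expect_true(all(yp >= apply(mp, 1, min) - 1e-12))
  expect_true(all(yp <= apply(mp, 1, max) + 1e-12))
  # constant members predict the constant
  expect_equal(unname(as.vector(mp %*% ens$weights)), yp)
  expect_error(ensemble_predict(ens, Xn[, 1:5]), "missing wavelength")
})

test_that("threshold validation", {
  d <- fit_members(seed = 6)
  expect_error(adaboost_fit(d$members, d$X, d$y, thresholds = c(2, 1)),
               "increasing")
  expect_error(adaboost_fit(d$members, d$X, d$y, thresholds = c(-1, 1)),
               "positive")
})
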