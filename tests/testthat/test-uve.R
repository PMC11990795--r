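make_planted <- function(seed = 1, n = 60, p_noise = 100) {
  set.seed(seed)
  x <- rnorm(n)
  y <- x + rnorm(n, 0, sqrt(1 / 0.99^2 - 1))   # corr(y, x) ~ 0.99
  X <- cbind(x, matrix(rnorm(n * p_noise), n))
  list(X = scale(X), y = y)
}

test_that("a strongly correlated planted column is selected", {
  d <- make_planted()
  res <- uve_run(d$X, d$y, uve_config(), run_seed = 5, n_lv = 2)
  expect_true(res$selected[1])
  # run result invariants
  expect_identical(res$selected, abs(res$stability) > res$cutoff)
  expect_length(res$noise_stability, 200)
})

test_that("identical run seeds give identical results", {
  d <- make_planted(2)
  a <- uve_run(d$X, d$y, uve_config(), run_seed = 7, n_lv = 2)
  b <- uve_run(d$X, d$y, uve_config(), run_seed = 7, n_lv = 2)
  expect_identical(a, b)
  c <- uve_run(d$X, d$y, uve_config(), run_seed = 8, n_lv = 2)
  expect_false(identical(a$cutoff, c$cutoff))
})

test_that("cutoff is driven by the noise columns alone", {
  d <- make_planted(3)
  res1 <- uve_run(d$X, d$y, uve_config(), run_seed = 11, n_lv = 2)
  # replace the real block by fresh noise: same seed => same appended noise
  set.seed(99)
  X2 <- scale(matrix(rnorm(length(d$y) * ncol(d$X)), length(d$y)))
  res2 <- uve_run(X2, d$y, uve_config(), run_seed = 11, n_lv = 2)
  expect_equal(res1$cutoff, res2$cutoff, tolerance = 0.5 * res1$cutoff)
})

test_that("raising confidence never grows the selected set", {
  d <- make_planted(4)
  masks <- lapply(c(0.95, 0.99), function(cf) {
    uve_run(d$X, d$y, uve_config(confidence = cf), run_seed = 13,
            n_lv = 2)$selected
  })
  expect_true(all(masks[[2]] <= masks[[1]]))   # 0.99 mask nested in 0.95
})

test_that("repeat counts, conservation and single-run degeneracy", {
  d <- make_planted(5, n = 40, p_noise = 30)
  cfg <- uve_config(n_runs = 5, seed = 3)
  rep5 <- uve_repeat(d$X, d$y, cfg)
  expect_equal(rep5$profile$counts,
               Reduce(`+`, lapply(rep5$runs, function(r) as.integer(r$selected))))
  expect_equal(sum(rep5$profile$counts > 0),
               sum(Reduce(`|`, lapply(rep5$runs, `[[`, "selected"))))
  cfg1 <- uve_config(n_runs = 1, seed = 3)
  rep1 <- uve_repeat(d$X, d$y, cfg1)
  expect_equal(rep1$profile$counts, as.integer(rep1$runs[[1]]$selected))
  expect_identical(uve_repeat(d$X, d$y, cfg)$profile$counts,
                   rep5$profile$counts)   # determinism from master seed
})

test_that("tier boundaries follow the >=90 / 30-89 / 1-29 convention", {
  profile <- structure(list(counts = c(95L, 90L, 89L, 30L, 29L, 0L),
                            n_runs = 100L, t_high = 90, t_low = 30,
                            tiers = nirboost:::tier_labels(
                              c(95, 90, 89, 30, 29, 0), 90, 30)),
                       class = "frequency_profile")
  tiers <- tier_partition(profile)
  expect_identical(tiers$high, c(1L, 2L))
  expect_identical(tiers$mid, c(3L, 4L))
  expect_identical(tiers$low, 5L)
  expect_false(6L %in% unlist(tiers))

  all100 <- structure(list(counts = rep(100L, 4), n_runs = 100L,
                           t_high = 90, t_low = 30,
                           tiers = nirboost:::tier_labels(rep(100, 4), 90, 30)),
                      class = "frequency_profile")
  expect_identical(tier_partition(all100)$high, 1:4)
})

test_that("tiers partition the ever-selected set on random profiles", {
  set.seed(6)
  for (i in 1:10) {
    counts <- sample(0:100, 50, replace = TRUE)
    profile <- structure(list(counts = counts, n_runs = 100L,
                              t_high = 90, t_low = 30,
                              tiers = nirboost:::tier_labels(counts, 90, 30)),
                         class = "frequency_profile")
    tiers <- suppressWarnings(tier_partition(profile))
    expect_length(intersect(tiers$high, tiers$mid), 0)
    expect_length(intersect(tiers$mid, tiers$low), 0)
    expect_setequal(unlist(tiers), which(counts >= 1))
  }
})

test_that("config validation and error paths", {
  expect_error(uve_config(n_noise = 5), "n_noise")
  expect_error(uve_config(confidence = 0.4), "confidence")
  expect_error(uve_config(n_runs = 0), "n_runs")
  d <- make_planted(7, n = 4, p_noise = 10)
  expect_error(uve_run(d$X, d$y, uve_config(), n_lv = 1), "folds")
})
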