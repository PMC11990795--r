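# small fixtures built in code; all randomness is seeded locally

random_spectra_set <- function(n = 5, p = 8, with_y = TRUE, seed = 1) {
  set.seed(seed)
  spectra_set(sort(runif(p, 1000, 2500)),
              matrix(rnorm(n * p), n),
              y = if (with_y) runif(n, 15, 29) else NULL)
}

# single-informative-band config in the noiseless limit (all stochastic
# terms off so the signal structure is exact)
noiseless_config <- function(n = 25, p = 120, seed = 3) {
  sim_config(n_samples = n, n_points = p, seed = seed,
             baseline_sd = 0, scatter_sd = 0, noise_sd = 0, y_noise_sd = 0,
             bands = data.frame(center = 1450, width = 50, amplitude = 0.3,
                                slope = 0.02, informative = TRUE))
}

# brute-force Kennard-Stone oracle: literal max-min greedy over the
# distance matrix, lowest index on ties
ks_oracle <- function(X, n_cal) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  best <- NULL; bestd <- -Inf
  for (j in 2:n) for (i in 1:(j - 1)) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    rem <- setdiff(seq_len(n), sel)
    md <- vapply(rem, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, rem[which.max(md)])
  }
  sel
}

rmse_of <- function(a, b) sqrt(mean((a - b)^2))
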