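#' Configuration for uninformative variable elimination
#'
#' Defaults follow the standard operating point for NIR work: 200 appended
#' noise variables, 5 cross-validation folds, a 99 percent confidence cutoff and
#' 100 repetitions for the frequency analysis.
#'
#' @param n_noise Number of appended noise columns (>= 10).
#' @param k_folds Cross-validation folds.
#' @param confidence Cutoff confidence level in (0.5, 1).
#' @param noise_scale Amplitude of the appended noise. Kept tiny (1e-10)
#'   so the noise cannot influence the fit itself, only the coefficient
#'   statistics; the stability statistic is scale-free.
#' @param noise_dist `"uniform"` (classic UVE) or `"gaussian"`.
#' @param n_runs Repetitions for [uve_repeat()].
#' @param t_high,t_low Frequency-tier thresholds. `NULL` defaults to
#'   90/30 when `n_runs = 100`, otherwise scaled as `0.9 * n_runs` and
#'   `0.3 * n_runs`.
#' @param cutoff_rule `"quantile"` (empirical `confidence`-quantile of the
#'   absolute noise stabilities, lower interpolation) or `"max"`.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return A list of class `uve_config`.
#' @export
uve_config <- function(n_noise = 200, k_folds = 5, confidence = 0.99,
                       noise_scale = 1e-10,
                       noise_dist = c("uniform", "gaussian"),
                       n_runs = 100, t_high = NULL, t_low = NULL,
                       cutoff_rule = c("quantile", "max"), seed = 1L) {
  noise_dist <- match.arg(noise_dist)
  cutoff_rule <- match.arg(cutoff_rule)
  if (n_noise < 10) stop("n_noise must be >= 10")
  if (confidence <= 0.5 || confidence >= 1) stop("confidence must be in (0.5, 1)")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (noise_scale <= 0) stop("noise_scale must be > 0")
  if (is.null(t_high)) t_high <- ceiling(0.9 * n_runs)
  if (is.null(t_low)) t_low <- ceiling(0.3 * n_runs)
  structure(list(n_noise = as.integer(n_noise), k_folds = as.integer(k_folds),
                 confidence = confidence, noise_scale = noise_scale,
                 noise_dist = noise_dist, n_runs = as.integer(n_runs),
                 t_high = t_high, t_low = t_low, cutoff_rule = cutoff_rule,
                 seed = as.integer(seed)),
            class = "uve_config")
}

uve_derive_seed <- function(seed, r) as.integer((seed + 7919 * r) %% 2147483647)

#' One run of UVE variable selection
#'
#' Appends `n_noise` random columns of tiny amplitude, fits PLS1 on each
#' cross-validation training fold at a fixed latent-variable count, and
#' forms the Centner-style stability (reliability) statistic for every
#' column: the mean of its fold-wise regression coefficients divided by
#' their SD. The cutoff is derived only from the noise columns' stability
#' distribution; real variables whose |stability| exceeds it are selected.
#'
#' @param X Standardized predictor matrix.
#' @param y Response vector.
#' @param config A [uve_config()].
#' @param run_seed Seed controlling this run's noise draw and folds.
#' @param n_lv Latent variables for the internal PLS fits; `NULL` uses the
#'   cross-validated optimum of the real-variable model (computed here;
#'   [uve_repeat()] computes it once and passes it down).
#' @return A `uve_run_result`: `stability`, `noise_stability`, `cutoff`,
#'   `selected` (logical mask over real variables), `n_lv_used`.
#' @export
uve_run <- function(X, y, config = uve_config(), run_seed = config$seed,
                    n_lv = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < config$k_folds) stop("fewer samples (", n, ") than folds (",
                               config$k_folds, ")")
  if (is.null(n_lv)) {
    n_lv <- cross_validate(X, y, max_lv = 15, k = config$k_folds,
                           seed = config$seed)$n_lv
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(run_seed)
  noise <- if (config$noise_dist == "uniform") {
    stats::runif(n * config$n_noise)
  } else stats::rnorm(n * config$n_noise)
  Xa <- cbind(X, matrix(noise * config$noise_scale, n, config$n_noise))
  folds <- make_folds(n, config$k_folds, "random",
                      seed = uve_derive_seed(run_seed, 13L))
  n_lv_fit <- min(n_lv, n - max(tabulate(folds, config$k_folds)) - 1)
  Bf <- vapply(seq_len(config$k_folds), function(f) {
    tr <- folds != f
    pls1_path(Xa[tr, , drop = FALSE], y[tr], n_lv_fit)$B[, n_lv_fit]
  }, numeric(p + config$n_noise))                      # (p + n_noise) x k
  mu <- rowMeans(Bf)
  sdv <- apply(Bf, 1, stats::sd)
  stab <- ifelse(sdv > 0, mu / sdv, ifelse(mu == 0, 0, Inf))
  noise_stab <- stab[(p + 1):(p + config$n_noise)]
  cutoff <- if (config$cutoff_rule == "max") {
    max(abs(noise_stab))
  } else {
    stats::quantile(abs(noise_stab), config$confidence, type = 1, names = FALSE)
  }
  selected <- abs(stab[seq_len(p)]) > cutoff
  if (!any(selected)) warning("UVE eliminated all variables")
  structure(list(stability = stab[seq_len(p)], noise_stability = noise_stab,
                 cutoff = cutoff, selected = selected,
                 n_lv_used = as.integer(n_lv_fit)),
            class = "uve_run_result")
}

#' Repeated UVE with selection-frequency profiling
#'
#' Runs [uve_run()] `n_runs` times with per-run seeds derived from the
#' master seed, counts how often each wavelength is selected, and buckets
#' wavelengths into frequency tiers (defaults for 100 runs: high >= 90,
#' mid 30-89, low 1-29; never-selected wavelengths belong to no tier).
#' The latent-variable count is fixed once, at the cross-validated
#' optimum of the full real-variable model.
#'
#' @inheritParams uve_run
#' @param lv_repeats Fold-seed repetitions used to estimate the
#'   latent-variable optimum: each replicate applies the one-standard-error
#'   parsimony rule to its RMSECV curve and the majority choice wins (ties
#'   to fewer latent variables). A single 5-fold argmin is noisy on
#'   collinear spectra and can wander into noise components, where
#'   fold-wise coefficients — and hence the UVE stability statistic —
#'   degenerate for every variable.
#' @return List with `runs` (list of `uve_run_result`) and `profile`
#'   (class `frequency_profile`: `counts`, `n_runs`, `tiers` label vector
#'   in \{high, mid, low, never\}, `t_high`, `t_low`, `n_lv_used`).
#' @export
uve_repeat <- function(X, y, config = uve_config(), lv_repeats = 5) {
  X <- as.matrix(X)
  picks <- vapply(seq_len(lv_repeats), function(r) {
    cross_validate(X, y, max_lv = 15, k = config$k_folds,
                   seed = uve_derive_seed(config$seed, 7000L + r),
                   parsimony = TRUE)$n_lv
  }, integer(1))
  tab <- table(picks)
  n_lv <- min(as.integer(names(tab)[tab == max(tab)]))
  runs <- lapply(seq_len(config$n_runs), function(r) {
    uve_run(X, y, config, run_seed = uve_derive_seed(config$seed, r),
            n_lv = n_lv)
  })
  counts <- Reduce(`+`, lapply(runs, function(r) as.integer(r$selected)))
  profile <- structure(list(counts = counts, n_runs = config$n_runs,
                            t_high = config$t_high, t_low = config$t_low,
                            tiers = tier_labels(counts, config$t_high,
                                                config$t_low),
                            n_lv_used = as.integer(n_lv)),
                       class = "frequency_profile")
  list(runs = runs, profile = profile)
}

tier_labels <- function(counts, t_high, t_low) {
  lab <- rep("never", length(counts))
  lab[counts >= 1 & counts < t_low] <- "low"
  lab[counts >= t_low & counts < t_high] <- "mid"
  lab[counts >= t_high] <- "high"
  lab
}

#' Partition wavelengths by selection-frequency tier
#'
#' @param profile A `frequency_profile` from [uve_repeat()].
#' @return List of integer index vectors `high`, `mid`, `low` (disjoint;
#'   union = every wavelength selected at least once).
#' @export
tier_partition <- function(profile) {
  stopifnot(inherits(profile, "frequency_profile"))
  out <- list(high = which(profile$tiers == "high"),
              mid = which(profile$tiers == "mid"),
              low = which(profile$tiers == "low"))
  if (length(out$high) == 0) {
    warning("empty high tier: member model M1 would have no variables")
  }
  out
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("<frequency_profile> ", x$n_runs, " runs; tiers (>=", x$t_high,
      " / ", x$t_low, "-", x$t_high - 1, " / <", x$t_low, "): ",
      sum(x$tiers == "high"), " high, ", sum(x$tiers == "mid"), " mid, ",
      sum(x$tiers == "low"), " low, ", sum(x$tiers == "never"),
      " never selected\n", sep = "")
  invisible(x)
}
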