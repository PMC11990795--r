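#' Fit and apply z-score standardization
#'
#' Column-wise standardization with sample SD (denominator n - 1), the
#' conventional chemometrics pretreatment. The fitted state is reused on
#' prediction data via [zscore_apply()] so test-set statistics never leak
#' into the model.
#'
#' @param X Numeric matrix, `n >= 2` rows, no constant column.
#' @return List with `X_std` (standardized matrix) and `state` (class
#'   `zscore_state`: `mean`, `sd`, `p`).
#' @examples
#' zscore_fit_transform(cbind(a = c(1, 2, 3)))$X_std
#' @export
zscore_fit_transform <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("z-score requires n >= 2")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    nm <- colnames(X)[bad[1]] %||% as.character(bad[1])
    stop("constant column (SD = 0): ", nm)
  }
  state <- structure(list(mean = mu, sd = sdv, p = ncol(X)),
                     class = "zscore_state")
  list(X_std = sweep(sweep(X, 2, mu), 2, sdv, "/"), state = state)
}

#' Apply a fitted z-score state to new data
#'
#' @param X_new Numeric matrix with the same column count as the training
#'   data.
#' @param state A `zscore_state` from [zscore_fit_transform()].
#' @return `(X_new - mean) / sd` using the training statistics only.
#' @export
zscore_apply <- function(X_new, state) {
  stopifnot(inherits(state, "zscore_state"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != state$p) {
    stop("dimension mismatch: X_new has ", ncol(X_new),
         " columns, state expects ", state$p)
  }
  sweep(sweep(X_new, 2, state$mean), 2, state$sd, "/")
}

# projection-pursuit (Stahel-Donoho style) outlyingness: directions through
# pairs of observations plus each observation minus the coordinatewise
# median. All pairs are used up to max_pairs; beyond that a deterministic
# seeded subsample keeps cost bounded.
pp_outlyingness <- function(X, max_pairs = 2000L) {
  n <- nrow(X)
  med <- apply(X, 2, stats::median)
  dirs <- sweep(X, 2, med)
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(20231L)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  dirs <- rbind(dirs, X[pairs[1, ], , drop = FALSE] - X[pairs[2, ], , drop = FALSE])
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs[nrm > 1e-12, , drop = FALSE] / nrm[nrm > 1e-12]
  P <- X %*% t(dirs)                                   # n x n_dirs projections
  ctr <- apply(P, 2, stats::median)
  scl <- apply(P, 2, stats::mad)
  ok <- scl > 1e-12
  if (!any(ok)) stop("degenerate (zero-variance) data")
  O <- abs(sweep(P[, ok, drop = FALSE], 2, ctr[ok])) /
    rep(scl[ok], each = n)
  apply(O, 1, max)
}

# consistency factor for radially trimmed k-variate Gaussian second
# moments: keeping the central fraction alpha shrinks the variance by
# P(chi2_{k+2} <= q_alpha) / alpha; dividing restores Fisher consistency
trim_consistency <- function(alpha, k) {
  if (alpha >= 1) return(1)
  stats::pchisq(stats::qchisq(alpha, k), k + 2) / alpha
}

robust_pca_core <- function(X, rows, k, trim_df = NULL) {
  mu <- colMeans(X[rows, , drop = FALSE])
  Xc_h <- sweep(X[rows, , drop = FALSE], 2, mu)
  sv <- svd(Xc_h)
  ev <- sv$d^2 / (length(rows) - 1)
  alpha <- length(rows) / nrow(X)
  kmax <- sum(ev > max(ev) * 1e-12)
  if (kmax < 1) stop("degenerate (zero-variance) data")
  if (identical(k, "auto")) {
    # scree-gap rule: cut at the largest log-eigenvalue drop within the
    # first components; robust in the p >> n regime where cumulative
    # variance shares are meaningless (noise dominates the trace)
    jmax <- min(10L, kmax - 1L)
    k <- if (jmax < 1) kmax else which.max(diff(-log(ev[seq_len(jmax + 1)])))
  }
  k <- as.integer(k)
  list(mu = mu, V = sv$v[, seq_len(k), drop = FALSE],
       ev = ev[seq_len(k)] / trim_consistency(alpha, trim_df %||% k), k = k)
}

distances_and_cutoffs <- function(X, core, significance, joint) {
  Xc <- sweep(X, 2, core$mu)
  Tsc <- Xc %*% core$V
  sd_vec <- sqrt(rowSums(sweep(Tsc^2, 2, core$ev, "/")))
  resid <- Xc - Tsc %*% t(core$V)
  od_vec <- sqrt(rowSums(resid^2))
  od_active <- max(od_vec) > 1e-10
  # when the model plane spans the data (no residual space) the whole
  # significance budget goes to the score axis
  s_sd <- if (joint && od_active) sqrt(significance) else significance
  s_od <- if (joint) sqrt(significance) else significance
  sd_cut <- sqrt(stats::qchisq(s_sd, df = core$k))
  # Wilson-Hilferty: OD^(2/3) approximately normal; robust location/scale
  # from median and MAD so contaminated rows do not inflate the cutoff
  od_cut <- if (!od_active) Inf else {
    od23 <- od_vec^(2 / 3)
    (stats::median(od23) + stats::mad(od23) * stats::qnorm(s_od))^(3 / 2)
  }
  list(score_distance = as.vector(sd_vec), orthogonal_distance = as.vector(od_vec),
       sd_cutoff = sd_cut, od_cutoff = od_cut,
       flags = as.vector(sd_vec) > sd_cut | as.vector(od_vec) > od_cut)
}

#' Robust-PCA outlier screening
#'
#' A simplified ROBPCA scheme: projection-pursuit outlyingness selects an
#' h-subset of the least outlying rows; classical PCA on that subset gives
#' a robust center and loadings; every sample is then diagnosed by its
#' score distance (robust Mahalanobis distance in the k-dimensional score
#' space, chi-squared cutoff) and its orthogonal distance (Euclidean
#' residual to the PCA plane, Wilson-Hilferty normal approximation on
#' OD^(2/3)). One reweighting pass refits the PCA on the unflagged rows.
#'
#' A sample is flagged when it exceeds either cutoff. Because that is a
#' union of two tests, the default `joint_calibration = TRUE` runs each
#' axis at the Sidak-split level `sqrt(significance)` so the overall
#' false-alarm rate on clean data is `1 - significance`; set it to `FALSE`
#' for the literal per-axis convention.
#'
#' @param ds A `spectra_set` or a numeric matrix (`n >= 10`).
#' @param k Number of principal components, or `"auto"`: the scree-gap
#'   rule, cutting at the largest log-eigenvalue drop within the first
#'   ten components (cumulative-variance rules are meaningless for
#'   spectra with far more wavelengths than samples, where measurement
#'   noise dominates the trace).
#' @param significance Confidence level for the cutoffs (default 0.95).
#' @param h_frac Fraction of rows in the clean h-subset (default 0.75).
#' @param joint_calibration Calibrate the union flag rate (default TRUE).
#' @return An `outlier_report`: `score_distance`, `orthogonal_distance`,
#'   `sd_cutoff`, `od_cutoff`, `flags`, `k`, `significance`, plus a
#'   2-component `map` (scores for plotting parity with the usual
#'   SD/OD diagnostic display).
#' @export
robust_outlier_detect <- function(ds, k = "auto", significance = 0.95,
                                  h_frac = 0.75, joint_calibration = TRUE) {
  X <- if (inherits(ds, "spectra_set")) ds$X else as.matrix(ds)
  n <- nrow(X)
  if (n < 10) stop("robust outlier detection requires n >= 10")
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k >= min(n, ncol(X))) stop("k must be < min(n, p)")
    if (k < 1) stop("k must be >= 1")
  }
  outl <- pp_outlyingness(X)
  h <- max(floor(h_frac * n), 3L)
  rows <- order(outl)[seq_len(h)]
  # pass-1 trimming happens in full-dimensional outlyingness space, hence
  # the consistency correction uses df = p
  core <- robust_pca_core(X, rows, k, trim_df = ncol(X))
  d <- distances_and_cutoffs(X, core, significance, joint_calibration)
  # one reweighting refinement on the unflagged rows (keep k fixed)
  keep <- which(!d$flags)
  if (length(keep) > core$k + 2 && length(keep) < n) {
    core <- robust_pca_core(X, keep, core$k)
    d <- distances_and_cutoffs(X, core, significance, joint_calibration)
  }
  map_core <- if (core$k >= 2) core$V[, 1:2, drop = FALSE] else core$V
  structure(c(d, list(k = core$k, significance = significance,
                      map = sweep(X, 2, core$mu) %*% map_core)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> k =", x$k, " significance =", x$significance, "\n")
  cat("  flagged:", sum(x$flags), "of", length(x$flags), "samples\n")
  cat(sprintf("  cutoffs: SD %.4g, OD %.4g\n", x$sd_cutoff, x$od_cutoff))
  invisible(x)
}
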