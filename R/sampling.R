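#' Kennard-Stone sample selection
#'
#' Deterministic max-min greedy selection: the first two picks are the
#' pair at maximal Euclidean distance; every subsequent pick maximizes its
#' minimum distance to the already-selected set. Ties are broken by the
#' lowest index at every argmax, so the result is fully reproducible.
#'
#' @param X Numeric matrix of sample coordinates (rows = samples).
#' @param n_cal Number of samples to select, `2 <= n_cal <= n`.
#' @return A `split_result`: `calibration_indices` (in selection order),
#'   `prediction_indices`, `metric = "euclidean"`.
#' @examples
#' kennard_stone(matrix(0:4, ncol = 1), 3)$calibration_indices
#' @export
kennard_stone <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_cal < 2) stop("n_cal must be >= 2")
  if (n_cal > n) stop("n_cal must be <= n")
  D <- as.matrix(stats::dist(X))
  # initial pair: maximal distance, smallest (i, j) on ties (column-major
  # scan of the upper triangle ordered by i then j)
  best <- c(1L, 2L); bestd <- -Inf
  for (j in 2:n) for (i in 1:(j - 1)) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  remaining <- setdiff(seq_len(n), sel)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    pick <- remaining[which.max(mind[remaining])]
    sel <- c(sel, pick)
    remaining <- remaining[remaining != pick]
    mind <- pmin(mind, D[, pick])
  }
  structure(list(calibration_indices = sel,
                 prediction_indices = sort(remaining),
                 metric = "euclidean"),
            class = "split_result")
}

round_half_away <- function(x) floor(x + 0.5)

#' Split a spectra set into calibration and prediction subsets
#'
#' Kennard-Stone partitioning on the z-score-standardized spectra (the
#' algorithm is scale-sensitive and modeling happens on standardized
#' data). The calibration size is `round(ratio * n)` with
#' round-half-away-from-zero, or an explicit `n_cal`.
#'
#' @param ds A `spectra_set` with a response `y`.
#' @param ratio Calibration fraction (default 0.7).
#' @param n_cal Optional explicit calibration size (overrides `ratio`).
#' @return List with `cal` and `pred` (`spectra_set`s) and `split`
#'   (the `split_result`).
#' @export
split_dataset <- function(ds, ratio = 0.7, n_cal = NULL) {
  validate_spectra_set(ds)
  if (is.null(ds$y)) stop("split_dataset requires a response y")
  n <- nrow(ds$X)
  if (is.null(n_cal)) n_cal <- round_half_away(ratio * n)
  n_cal <- as.integer(n_cal)
  if (n_cal >= n) {
    warning("calibration set takes all samples; prediction set is empty")
    n_cal <- n
  }
  keep <- apply(ds$X, 2, stats::sd) > 0
  Xs <- zscore_fit_transform(ds$X[, keep, drop = FALSE])$X_std
  sp <- kennard_stone(Xs, n_cal)
  list(cal = subset_samples(ds, sp$calibration_indices),
       pred = subset_samples(ds, sp$prediction_indices),
       split = sp)
}
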