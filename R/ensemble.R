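# graded prediction-deviation loss in [0, 1]: piecewise linear through the
# two error thresholds (default 1.0 and 1.5 degrees Brix)
graded_loss <- function(d, t1, t2) {
  ifelse(d <= t1, 0.5 * d / t1,
         ifelse(d <= t2, 0.5 + 0.5 * (d - t1) / (t2 - t1), 1))
}

#' Combine pre-built PLS member models with AdaBoost-style weighting
#'
#' Sample weights start uniform; members are processed in a fixed order
#' (high, mid, low frequency tier). For member m the per-sample absolute
#' deviation of its cross-validated calibration predictions is graded into
#' a loss in \[0, 1\] by a two-knot piecewise-linear rule through the error
#' thresholds (default 1.0 and 1.5 degrees Brix); the weighted error
#' `eps = sum(w * loss)` gives `beta = eps / (1 - eps)` and the member
#' weight `alpha = log(1 / beta)`. With `update_samples = TRUE` (default)
#' sample weights are then re-emphasized toward high-error samples,
#' `w <- w * beta^(1 - loss)`, before the next member — the sequential
#' boosting sweep. With `update_samples = FALSE` every member is scored
#' against the uniform distribution (one-shot mode), which makes the
#' weights exactly symmetric under member permutation and exactly equal
#' for members with identical predictions.
#'
#' @param members List of >= 1 `pls_model`s (tier order).
#' @param X_cal Calibration spectra on the full grid (standardized scale
#'   the members were fitted on).
#' @param y_cal Calibration response.
#' @param thresholds Error-grading knots `(t1, t2)`, default `c(1, 1.5)`.
#' @param cv_predictions Optional list of out-of-fold calibration
#'   prediction vectors, one per member (the pipeline passes the ones from
#'   latent-variable selection). If `NULL` they are recomputed by k-fold
#'   refitting of each member on its variable subset.
#' @param k,seed Fold count and seed for that recomputation.
#' @param update_samples Sequential sample-weight updating (default TRUE).
#' @return An `ensemble_model`: `members`, `weights` (non-negative, sum
#'   1), `error_thresholds`, `training_errors` (per-member weighted
#'   errors).
#' @export
adaboost_fit <- function(members, X_cal, y_cal, thresholds = c(1, 1.5),
                         cv_predictions = NULL, k = 5, seed = 1L,
                         update_samples = TRUE) {
  stopifnot(length(members) >= 1, all(vapply(members, inherits, TRUE, "pls_model")))
  if (length(thresholds) != 2 || any(thresholds <= 0) ||
      thresholds[2] <= thresholds[1]) {
    stop("thresholds must be two increasing positive scalars")
  }
  X_cal <- as.matrix(X_cal)
  n <- length(y_cal)
  if (is.null(cv_predictions)) {
    cv_predictions <- lapply(members, function(m) {
      idx <- m$variable_indices
      if (max(idx) > ncol(X_cal)) stop("member variable_indices exceed calibration grid")
      cross_validate(X_cal[, idx, drop = FALSE], y_cal,
                     max_lv = m$n_lv, k = k, seed = seed)$predictions
    })
  }
  stopifnot(length(cv_predictions) == length(members))

  w <- rep(1 / n, n)
  alphas <- numeric(length(members))
  errs <- numeric(length(members))
  for (m in seq_along(members)) {
    d <- abs(cv_predictions[[m]] - y_cal)
    l <- graded_loss(d, thresholds[1], thresholds[2])
    eps <- sum(w * l)
    eps <- max(eps, 1 / (2 * n))               # keep alpha finite at eps = 0
    errs[m] <- eps
    if (eps >= 0.5) {
      warning("member ", m, " has weighted error >= 0.5; down-weighted to 0")
      alphas[m] <- 0
    } else {
      beta <- eps / (1 - eps)
      alphas[m] <- log(1 / beta)
      if (update_samples) {
        w <- w * beta^(1 - l)
        w <- w / sum(w)
      }
    }
  }
  if (sum(alphas) == 0) {
    warning("all members down-weighted; falling back to equal weights")
    alphas <- rep(1, length(members))
  }
  weights <- if (all(alphas == alphas[1])) {
    rep(1 / length(alphas), length(alphas))   # exact under exact symmetry
  } else alphas / sum(alphas)
  structure(list(members = members, weights = weights,
                 error_thresholds = thresholds, training_errors = errs),
            class = "ensemble_model")
}

#' Predict from an AdaBoost PLS ensemble
#'
#' The prediction is the weight-convex combination of the member
#' predictions, each member seeing only its own wavelength subset of
#' `X_new`; every ensemble prediction therefore lies within the member
#' min/max envelope.
#'
#' @param model An `ensemble_model`.
#' @param X_new Matrix on the full calibration grid (columns must cover
#'   the union of the members' variable indices).
#' @return Numeric vector of predictions.
#' @export
ensemble_predict <- function(model, X_new) {
  stopifnot(inherits(model, "ensemble_model"))
  X_new <- as.matrix(X_new)
  need <- sort(unique(unlist(lapply(model$members, `[[`, "variable_indices"))))
  missing <- need[need > ncol(X_new)]
  if (length(missing)) {
    stop("missing wavelength columns: ", paste(missing, collapse = ", "))
  }
  preds <- vapply(model$members, function(m) {
    pls_predict(m, X_new[, m$variable_indices, drop = FALSE])
  }, numeric(nrow(X_new)))
  if (nrow(X_new) == 1) preds <- matrix(preds, nrow = 1)
  as.vector(preds %*% model$weights)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$members), " members; weights: ",
      paste(sprintf("%.4f", x$weights), collapse = ", "), "\n", sep = "")
  invisible(x)
}
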