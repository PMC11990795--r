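# NIPALS PLS1 coefficient path: coefficients (original variable space) and
# intercepts for 1..max_lv components in one decomposition. Deflation on X
# only, the standard PLS1 scheme. Stops early (with error) if the requested
# number of components exceeds the effective rank.
pls1_path <- function(X, y, max_lv, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0) stop("zero-variance y")
  if (max_lv < 1) stop("n_lv must be >= 1")
  if (max_lv > min(n - 1, p)) {
    stop("n_lv (", max_lv, ") exceeds min(n - 1, p) = ", min(n - 1, p))
  }
  x_mean <- colMeans(X)
  x_sd <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (scale && any(x_sd == 0)) stop("constant column: cannot autoscale")
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  yc <- y - y_mean

  W <- matrix(0, p, max_lv); P <- matrix(0, p, max_lv); Q <- numeric(max_lv)
  B <- matrix(0, p, max_lv)
  sst <- sum(Xc^2)
  for (a in seq_len(max_lv)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14 * max(1, sqrt(sst)) || sum(Xc^2) < 1e-24 * max(1, sst)) {
      stop("n_lv (", max_lv, ") exceeds the effective rank of X (", a - 1, ")")
    }
    w <- w / wn
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-28 * max(1, sst)) {
      stop("n_lv (", max_lv, ") exceeds the effective rank of X (", a - 1, ")")
    }
    p_load <- crossprod(Xc, t_sc) / tt
    q <- sum(yc * t_sc) / tt
    Xc <- Xc - t_sc %*% t(p_load)
    W[, a] <- w; P[, a] <- p_load; Q[a] <- q
    Wa <- W[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(t(P[, seq_len(a), drop = FALSE]) %*% Wa,
                      diag(a))                       # p x a, X-space rotation
    B[, a] <- (R %*% Q[seq_len(a)]) / x_sd
  }
  list(B = B, intercepts = y_mean - as.vector(crossprod(B, x_mean)),
       x_mean = x_mean, x_sd = x_sd, y_mean = y_mean)
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares for a single response, the base learner
#' throughout the package. Deflation is performed on X only; coefficients
#' are returned in the original (uncentered) variable space plus an
#' intercept, so `predict = intercept + X %*% coefficients`. At maximal
#' latent-variable count on a full-rank tall matrix, the solution equals
#' ordinary least squares.
#'
#' @param X Predictor matrix (`n x p`), typically standardized upstream.
#' @param y Response vector.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param scale Autoscale columns internally (default FALSE; the pipeline
#'   standardizes once upstream).
#' @param variable_indices Optional integer columns of a parent grid that
#'   this model uses (bookkeeping for tier-specific member models).
#' @return A `pls_model`: `n_lv`, `coefficients`, `intercept`, `x_mean`,
#'   `x_sd`, `y_mean`, `variable_indices`.
#' @examples
#' X <- matrix(rnorm(60), 20); y <- X[, 1] * 2 + 1
#' m <- pls_fit(X, y, n_lv = 1)
#' max(abs(pls_predict(m, X) - y)) < 1e-8
#' @export
pls_fit <- function(X, y, n_lv, scale = FALSE, variable_indices = NULL) {
  path <- pls1_path(X, y, n_lv, scale = scale)
  structure(list(
    n_lv = as.integer(n_lv),
    coefficients = path$B[, n_lv],
    intercept = path$intercepts[n_lv],
    x_mean = path$x_mean, x_sd = path$x_sd, y_mean = path$y_mean,
    variable_indices = as.integer(variable_indices %||% seq_len(ncol(as.matrix(X))))
  ), class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param model A `pls_model`.
#' @param X_new Matrix whose columns match the model's variables.
#' @return Numeric vector of predictions.
#' @export
pls_predict <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$coefficients)) {
    stop("dimension mismatch: X_new has ", ncol(X_new),
         " columns, model expects ", length(model$coefficients))
  }
  as.vector(model$intercept + X_new %*% model$coefficients)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$coefficients), " variables, ", x$n_lv,
      " latent variables\n", sep = "")
  invisible(x)
}

make_folds <- function(n, k, scheme = c("random", "blocks"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (k > n) stop("k (", k, ") must be <= n (", n, ")")
  if (k < 2) stop("k must be >= 2")
  if (scheme == "blocks") {
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    return(rep(seq_len(k), sizes))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation with latent-variable selection
#'
#' Computes the RMSECV curve over 1..max_lv from concatenated out-of-fold
#' predictions and selects the latent-variable count minimizing it (ties
#' go to the smaller count; a parsimony one-standard-error rule is
#' available behind `parsimony`).
#'
#' @param X,y Calibration data.
#' @param max_lv Maximum latent variables to scan (default 15; capped at
#'   what the smallest training fold supports).
#' @param k Number of folds (default 5).
#' @param fold_scheme `"random"` (seeded) or `"blocks"` (contiguous).
#' @param seed Seed for the random fold assignment (recorded in the result).
#' @param scale Autoscale within each fold fit.
#' @param parsimony Use the 1-SE rule instead of the minimum (default
#'   FALSE).
#' @return A `cv_result`: `rmsecv` (per-LV curve), `n_lv` (chosen),
#'   `folds`, `r_cv`, `mae_cv`, `predictions` (out-of-fold, at the chosen
#'   LV), `seed`.
#' @export
cross_validate <- function(X, y, max_lv = 15, k = 5,
                           fold_scheme = c("random", "blocks"), seed = 1L,
                           scale = FALSE, parsimony = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- make_folds(n, k, match.arg(fold_scheme), seed)
  min_train <- min(tabulate(folds, k))
  max_lv <- min(max_lv, n - max(tabulate(folds, k)) - 1, ncol(X))
  if (max_lv < 1) stop("not enough samples per fold for even 1 latent variable")
  oof <- matrix(NA_real_, n, max_lv)
  for (f in seq_len(k)) {
    tr <- folds != f
    path <- pls1_path(X[tr, , drop = FALSE], y[tr], max_lv, scale = scale)
    oof[!tr, ] <- sweep(X[!tr, , drop = FALSE] %*% path$B, 2,
                        path$intercepts, "+")
  }
  rmsecv <- sqrt(colMeans((oof - y)^2))
  if (parsimony) {
    lo <- which.min(rmsecv)
    se <- stats::sd((oof[, lo] - y)^2) / sqrt(n) / (2 * rmsecv[lo])
    n_lv <- min(which(rmsecv <= rmsecv[lo] + se))
  } else {
    n_lv <- which.min(rmsecv)          # first minimum = smallest LV on ties
  }
  structure(list(rmsecv = rmsecv, n_lv = as.integer(n_lv), folds = folds,
                 r_cv = stats::cor(y, oof[, n_lv]),
                 mae_cv = mean(abs(oof[, n_lv] - y)),
                 predictions = oof[, n_lv], seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> chosen LV =", x$n_lv,
      sprintf(" RMSECV = %.4g  Rcv = %.4g\n", x$rmsecv[x$n_lv], x$r_cv))
  invisible(x)
}
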