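#' Configuration for the full calibration workflow
#'
#' @param significance Outlier-screening confidence level.
#' @param k Outlier-screening component count or `"auto"`.
#' @param ratio Calibration fraction for the Kennard-Stone split.
#' @param n_cal Optional explicit calibration size (overrides `ratio`).
#' @param uve A [uve_config()]; its seed is overwritten with one derived
#'   from `seed`.
#' @param thresholds AdaBoost error-grading knots (degrees Brix).
#' @param max_lv Latent-variable scan ceiling for every model.
#' @param parsimony Use the one-standard-error rule for every model's
#'   latent-variable choice (default TRUE; FALSE takes the plain RMSECV
#'   argmin).
#' @param k_folds Cross-validation folds for model selection.
#' @param update_samples Sequential AdaBoost sample-weight updating.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it, so the whole run is reproducible.
#' @param output_dir Optional directory for artifacts (comparison table,
#'   frequency profile, models).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(significance = 0.95, k = "auto",
                            ratio = 0.7, n_cal = NULL,
                            uve = uve_config(),
                            thresholds = c(1, 1.5),
                            max_lv = 15, parsimony = TRUE, k_folds = 5,
                            update_samples = TRUE,
                            seed = 1L, output_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

fit_report_model <- function(Xc, yc, Xp, yp, max_lv, k, seed,
                             variable_indices = NULL, parsimony = TRUE) {
  cv <- cross_validate(Xc, yc, max_lv = max_lv, k = k, seed = seed,
                       parsimony = parsimony)
  model <- pls_fit(Xc, yc, n_lv = cv$n_lv,
                   variable_indices = variable_indices)
  list(model = model, cv = cv,
       cal = evaluate(yc, cv$predictions, "calibration_cv"),
       pred = if (nrow(Xp) >= 2) evaluate(yp, pls_predict(model, Xp)) else NULL,
       n_var = ncol(as.matrix(Xc)))
}

#' Run the complete calibration workflow
#'
#' Orchestrates: robust-PCA outlier screening (flag-then-filter), z-score
#' pretreatment fitted on the calibration set only, Kennard-Stone
#' splitting, three baseline PLS models (raw spectra, z-scored spectra,
#' single-run UVE selection), repeated UVE with frequency-tier
#' stratification, tier-specific member models M1/M2/M3, and the AdaBoost
#' ensemble — evaluating every model by k-fold cross-validation on the
#' calibration set and on the held-out prediction set. Nothing from the
#' prediction set enters any fitted statistic.
#'
#' @param ds A `spectra_set` with response `y`.
#' @param config A [pipeline_config()].
#' @return A `pipeline_bundle`: `screen` (outlier report), `clean`
#'   (filtered dataset), `split`, `zscore` state, `models` (named list of
#'   per-model fits and eval reports), `profile`, `tiers`, `ensemble`,
#'   `config`.
#' @export
run_full <- function(ds, config = pipeline_config()) {
  validate_spectra_set(ds)
  if (is.null(ds$y)) stop("stage[input]: dataset must carry a response y")
  seed <- as.integer(config$seed)

  report <- tryCatch(
    robust_outlier_detect(ds, k = config$k, significance = config$significance),
    error = function(e) stop("stage[screen]: ", conditionMessage(e)))
  clean <- subset_samples(ds, !report$flags)

  sp <- tryCatch(split_dataset(clean, ratio = config$ratio, n_cal = config$n_cal),
                 error = function(e) stop("stage[split]: ", conditionMessage(e)))
  cal <- sp$cal; pred <- sp$pred

  zs <- zscore_fit_transform(cal$X)
  Xc <- zs$X_std
  Xp <- zscore_apply(pred$X, zs$state)

  models <- list()
  models$raw <- fit_report_model(cal$X, cal$y, pred$X, pred$y,
                                 config$max_lv, config$k_folds,
                                 uve_derive_seed(seed, 1L),
                                 parsimony = config$parsimony)
  models$zscore <- fit_report_model(Xc, cal$y, Xp, pred$y,
                                    config$max_lv, config$k_folds,
                                    uve_derive_seed(seed, 2L),
                                    parsimony = config$parsimony)

  ucfg <- config$uve
  ucfg$seed <- uve_derive_seed(seed, 3L)
  single <- tryCatch(
    uve_run(Xc, cal$y, ucfg, run_seed = uve_derive_seed(seed, 4L),
            n_lv = models$zscore$cv$n_lv),
    error = function(e) stop("stage[uve]: ", conditionMessage(e)))
  sel <- which(single$selected)
  if (length(sel) >= 2) {
    models$uve_single <- fit_report_model(
      Xc[, sel, drop = FALSE], cal$y, Xp[, sel, drop = FALSE], pred$y,
      config$max_lv, config$k_folds, uve_derive_seed(seed, 5L),
      variable_indices = sel, parsimony = config$parsimony)
  }

  rep_res <- tryCatch(uve_repeat(Xc, cal$y, ucfg),
                      error = function(e) stop("stage[uve]: ", conditionMessage(e)))
  profile <- rep_res$profile
  tiers <- withCallingHandlers(
    tier_partition(profile),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(tiers$high) == 0) warning("stage[tiers]: empty high tier")
  if (config$uve$n_runs == 1) warning("stage[tiers]: n_runs = 1, tiers are degenerate")

  member_names <- c(high = "M1", mid = "M2", low = "M3")
  members <- list()
  for (tier in names(member_names)) {
    idx <- tiers[[tier]]
    if (length(idx) >= 2) {
      members[[member_names[[tier]]]] <- fit_report_model(
        Xc[, idx, drop = FALSE], cal$y, Xp[, idx, drop = FALSE], pred$y,
        config$max_lv, config$k_folds, uve_derive_seed(seed, 6L),
        variable_indices = idx, parsimony = config$parsimony)
    } else {
      warning("stage[members]: tier '", tier, "' has fewer than 2 variables; ",
              member_names[[tier]], " skipped")
    }
  }
  models <- c(models, members)

  ens <- NULL
  if (length(members) >= 1) {
    ens <- adaboost_fit(lapply(members, `[[`, "model"), Xc, cal$y,
                        thresholds = config$thresholds,
                        cv_predictions = lapply(members, function(m) m$cv$predictions),
                        update_samples = config$update_samples)
    cal_pred <- as.vector(
      vapply(members, function(m) m$cv$predictions, numeric(nrow(Xc))) %*%
        ens$weights)
    models$adaboost <- list(
      model = ens, cv = NULL,
      cal = evaluate(cal$y, cal_pred, "calibration_cv"),
      pred = if (nrow(Xp) >= 2) evaluate(pred$y, ensemble_predict(ens, Xp)) else NULL,
      n_var = NA_integer_)
  }

  bundle <- structure(list(
    screen = report, clean = clean, split = sp, zscore = zs$state,
    models = models, profile = profile, tiers = tiers, ensemble = ens,
    config = config
  ), class = "pipeline_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

model_display_names <- c(raw = "Raw spectra", zscore = "z-score",
                         uve_single = "UVE (single run)",
                         M1 = "M1: high tier", M2 = "M2: mid tier",
                         M3 = "M3: low tier", adaboost = "AdaBoost ensemble")

#' Tabulate a completed pipeline run
#'
#' One row per model in the canonical comparison layout (Methods,
#' Variables, LV, then calibration RMSECV/Rcv/MAE and prediction
#' RMSEP/Rp/MAE/Bias). The ensemble member weights are attached as the
#' `"weights"` attribute and echoed as a footnote by `print`.
#'
#' @param bundle A `pipeline_bundle` from [run_full()].
#' @return A data.frame with attribute `weights`.
#' @export
report_table <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  rows <- lapply(names(bundle$models), function(nm) {
    m <- bundle$models[[nm]]
    data.frame(
      Methods = model_display_names[[nm]] %||% nm,
      Variables = m$n_var,
      LV = if (!is.null(m$cv)) m$cv$n_lv else NA_integer_,
      RMSECV = m$cal$rmse, Rcv = m$cal$r, MAE_cal = m$cal$mae,
      RMSEP = if (!is.null(m$pred)) m$pred$rmse else NA_real_,
      Rp = if (!is.null(m$pred)) m$pred$r else NA_real_,
      MAE_pred = if (!is.null(m$pred)) m$pred$mae else NA_real_,
      Bias = if (!is.null(m$pred)) m$pred$bias else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(bundle$ensemble)) attr(out, "weights") <- bundle$ensemble$weights
  class(out) <- c("nirboost_table", "data.frame")
  out
}

#' @export
print.nirboost_table <- function(x, digits = 4, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  w <- attr(x, "weights")
  if (!is.null(w)) {
    cat("AdaBoost member weights:", paste(sprintf("%.4f", w), collapse = ", "),
        sprintf("(sum = %.6g)\n", sum(w)))
  }
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report_table(bundle)
  utils::write.csv(tab, file.path(dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = bundle$config$seed,
         significance = bundle$config$significance,
         n_outliers = sum(bundle$screen$flags),
         score_distance = bundle$screen$score_distance,
         orthogonal_distance = bundle$screen$orthogonal_distance,
         sd_cutoff = bundle$screen$sd_cutoff,
         od_cutoff = bundle$screen$od_cutoff,
         flags = bundle$screen$flags),
    file.path(dir, "screen.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(counts = bundle$profile$counts, n_runs = bundle$profile$n_runs,
         t_high = bundle$profile$t_high, t_low = bundle$profile$t_low,
         tiers = bundle$profile$tiers,
         high = bundle$tiers$high, mid = bundle$tiers$mid,
         low = bundle$tiers$low),
    file.path(dir, "frequency_profile.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$ensemble)) {
    save_model(bundle$ensemble, file.path(dir, "ensemble.model.json"))
  }
  invisible(dir)
}
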