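#' Construct a spectra set
#'
#' The central data container: a wavelength grid, a spectra matrix
#' (samples x wavelengths), an optional response vector (TSS, degrees Brix)
#' and unique sample identifiers. The grid length is data-driven; nothing in
#' the package assumes a particular number of points.
#'
#' @param wavelengths Numeric vector of strictly increasing positions (nm).
#' @param X Numeric matrix, `n_samples x length(wavelengths)`, unitless
#'   reflectance or absorbance.
#' @param y Optional numeric response vector (degrees Brix), length
#'   `nrow(X)`.
#' @param ids Optional character vector of unique sample identifiers;
#'   defaults to `S001, S002, ...`.
#' @return An object of class `spectra_set` with elements `wavelengths`,
#'   `X`, `y`, `ids`.
#' @examples
#' ds <- spectra_set(c(1000, 1100, 1200), matrix(rnorm(6), 2), y = c(20, 24))
#' ds
#' @export
spectra_set <- function(wavelengths, X, y = NULL, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  wavelengths <- as.numeric(wavelengths)
  if (is.null(ids)) {
    ids <- if (nrow(X) > 0) sprintf("S%03d", seq_len(nrow(X))) else character(0)
  }
  ids <- as.character(ids)
  if (!is.null(y)) y <- as.numeric(y)
  obj <- structure(
    list(wavelengths = wavelengths, X = X, y = y, ids = ids),
    class = "spectra_set"
  )
  validate_spectra_set(obj)
  obj
}

validate_spectra_set <- function(ds) {
  stopifnot(inherits(ds, "spectra_set"))
  if (ncol(ds$X) != length(ds$wavelengths)) {
    stop("number of columns of X (", ncol(ds$X),
         ") must equal length of wavelengths (", length(ds$wavelengths), ")")
  }
  if (length(ds$wavelengths) > 1 && any(diff(ds$wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (anyNA(ds$X) || any(!is.finite(ds$X))) {
    stop("X contains NA or non-finite values")
  }
  if (!is.null(ds$y)) {
    if (length(ds$y) != nrow(ds$X)) {
      stop("length(y) (", length(ds$y), ") must equal n_samples (",
           nrow(ds$X), ")")
    }
    if (anyNA(ds$y) || any(!is.finite(ds$y))) stop("y contains NA or non-finite values")
  }
  if (length(ds$ids) != nrow(ds$X)) stop("ids length must equal n_samples")
  if (anyDuplicated(ds$ids)) {
    stop("duplicate sample ID: ", ds$ids[duplicated(ds$ids)][1])
  }
  invisible(ds)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$X), " samples x ", ncol(x$X), " wavelengths",
      sep = "")
  if (length(x$wavelengths)) {
    cat(sprintf(" (%.6g-%.6g nm)", min(x$wavelengths), max(x$wavelengths)))
  }
  cat("\n")
  if (!is.null(x$y)) {
    cat(sprintf("  response y: range %.6g-%.6g, mean %.6g\n",
                min(x$y), max(x$y), mean(x$y)))
  } else cat("  response y: absent\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$X)

#' Subset a spectra set by sample
#'
#' @param ds A `spectra_set`.
#' @param i Integer or logical index over samples.
#' @return A `spectra_set` restricted to the selected samples.
#' @export
subset_samples <- function(ds, i) {
  validate_spectra_set(ds)
  spectra_set(ds$wavelengths, ds$X[i, , drop = FALSE],
              y = if (!is.null(ds$y)) ds$y[i] else NULL,
              ids = ds$ids[i])
}

# full-precision decimal rendering that parses back to the identical double
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a spectra set from a wide CSV file
#'
#' Canonical on-disk layout: one row per sample; first column `id`; one
#' numeric-named column per wavelength in ascending order; optional final
#' response column `y`. UTF-8, comma delimiter, `.` decimal separator,
#' header mandatory.
#'
#' @param path Path to an existing CSV file.
#' @return A validated `spectra_set`; row order preserved.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  nm <- names(df)
  if (length(nm) < 2 || nm[1] != "id") {
    stop("malformed header: first column must be 'id' (got '",
         paste(utils::head(nm, 1), collapse = ","), "')")
  }
  has_y <- nm[length(nm)] == "y"
  wl_cols <- nm[-c(1, if (has_y) length(nm) else integer(0))]
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    stop("malformed header: non-numeric wavelength column name '",
         wl_cols[which(is.na(wl))[1]], "'")
  }
  parse_col <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(col %in% c("NA", "")))
    if (length(bad)) {
      stop("parse error: non-numeric cell at row ", bad[1], ", column '",
           name, "' (value '", col[bad[1]], "')")
    }
    if (anyNA(v)) {
      stop("parse error: missing value at row ", which(is.na(v))[1],
           ", column '", name, "'")
    }
    v
  }
  n <- nrow(df)
  Xcols <- wl_cols
  X <- if (n == 0) {
    matrix(numeric(0), nrow = 0, ncol = length(Xcols))
  } else {
    vapply(Xcols, function(cn) parse_col(df[[cn]], cn), numeric(n))
  }
  if (n == 1) X <- matrix(X, nrow = 1)
  y <- if (has_y && n > 0) parse_col(df[["y"]], "y") else if (has_y) numeric(0) else NULL
  spectra_set(wl, X, y = y, ids = if (n > 0) df[["id"]] else character(0))
}

#' Write a spectra set to a wide CSV file
#'
#' Deterministic column order (`id`, wavelengths ascending, `y` last when
#' present); numbers written at full precision so
#' `read_spectra(write_spectra(ds))` reproduces `ds` bitwise.
#'
#' @param ds A valid `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  validate_spectra_set(ds)
  header <- c("id", fmt_full(ds$wavelengths), if (!is.null(ds$y)) "y")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (nrow(ds$X) > 0) {
    body <- cbind(ds$ids, matrix(fmt_full(ds$X), nrow = nrow(ds$X)))
    if (!is.null(ds$y)) body <- cbind(body, fmt_full(ds$y))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

ARTIFACT_FORMAT <- "nirboost/1"

# numeric payloads are stored as %.17g strings inside the JSON artifact so the
# round-trip is exact; jsonlite's own numeric serialization is not
num_out <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) list(dim = dim(x), data = fmt_full(as.vector(x)))
  else fmt_full(x)
}
num_in <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && !is.null(x$dim)) {
    matrix(as.numeric(unlist(x$data)), nrow = as.integer(unlist(x$dim))[1])
  } else as.numeric(unlist(x))
}

#' Save a fitted model artifact
#'
#' Serializes a [pls_fit()] model or an [adaboost_fit()] ensemble into a
#' single self-describing, versioned JSON file. The contract is exact
#' round-trip: a reloaded model reproduces the original's predictions
#' bitwise on any input.
#'
#' @param model A `pls_model` or `ensemble_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  payload <- serialize_model(model)
  payload$format <- ARTIFACT_FORMAT
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "pls_model")) {
    list(type = "pls_model",
         n_lv = model$n_lv,
         x_mean = num_out(model$x_mean),
         x_sd = num_out(model$x_sd),
         y_mean = num_out(model$y_mean),
         intercept = num_out(model$intercept),
         coefficients = num_out(model$coefficients),
         variable_indices = model$variable_indices)
  } else if (inherits(model, "ensemble_model")) {
    list(type = "ensemble_model",
         weights = num_out(model$weights),
         error_thresholds = num_out(model$error_thresholds),
         training_errors = num_out(model$training_errors),
         members = lapply(model$members, serialize_model))
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
}

#' Load a model artifact written by [save_model()]
#'
#' @param path Path to a model artifact file.
#' @return The reconstructed `pls_model` or `ensemble_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("load error: corrupt artifact (",
                                               conditionMessage(e), ")"))
  if (is.null(payload$format) || !identical(payload$format, ARTIFACT_FORMAT)) {
    stop("load error: artifact format version mismatch (expected '",
         ARTIFACT_FORMAT, "', got '", payload$format %||% "<missing>", "')")
  }
  deserialize_model(payload)
}

deserialize_model <- function(p) {
  if (identical(p$type, "pls_model")) {
    structure(list(
      n_lv = as.integer(p$n_lv),
      x_mean = num_in(p$x_mean),
      x_sd = num_in(p$x_sd),
      y_mean = num_in(p$y_mean),
      intercept = num_in(p$intercept),
      coefficients = num_in(p$coefficients),
      variable_indices = as.integer(unlist(p$variable_indices))
    ), class = "pls_model")
  } else if (identical(p$type, "ensemble_model")) {
    structure(list(
      members = lapply(p$members, deserialize_model),
      weights = num_in(p$weights),
      error_thresholds = num_in(p$error_thresholds),
      training_errors = num_in(p$training_errors)
    ), class = "ensemble_model")
  } else stop("load error: unknown artifact type '", p$type, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
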