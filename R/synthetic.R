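#' Default absorption bands for the synthetic fruit spectra
#'
#' Band loci follow the NIR assignments that dominate fruit spectra: C-H
#' third overtone / O-H first overtone near 1200 nm, O-H bending near
#' 1450 nm, C-H first overtone near 1650 nm and the sugar-associated
#' C-H/C-O combination region near 1950 nm. The three longer-wavelength
#' bands carry the analyte signal (amplitude affine in y, Beer-Lambert
#' style); the 1200 nm water band is constant, i.e. uninformative.
#'
#' @return A data.frame with columns `center` (nm), `width` (nm, Gaussian
#'   sigma), `amplitude` (baseline absorbance), `slope` (absorbance per
#'   degree Brix) and `informative` (logical).
#' @export
default_bands <- function() {
  data.frame(
    center      = c(1200, 1450, 1650, 1950),
    width       = c(60, 50, 45, 55),
    amplitude   = c(0.25, 0.30, 0.28, 0.32),
    slope       = c(0.000, 0.020, 0.020, 0.020),
    informative = c(FALSE, TRUE, TRUE, TRUE)
  )
}

#' Configuration for the synthetic NIR spectra generator
#'
#' Defaults emulate a post-screening apricot-style dataset: 189 samples,
#' a 1000-2500 nm grid with 1557 points, TSS uniform on 14.6-28.5 degrees
#' Brix, sample-wise baseline offset and multiplicative scatter, and
#' heteroscedastic noise.
#'
#' @param n_samples Number of samples.
#' @param wl_start,wl_end,n_points Wavelength grid (nm).
#' @param bands Band table as returned by [default_bands()].
#' @param y_range Response range (degrees Brix); drawn uniformly.
#' @param baseline_sd SD of the additive per-sample baseline offset.
#' @param scatter_sd SD (log scale) of the multiplicative scatter factor;
#'   log-normal with median 1 so spectra stay positive.
#' @param noise_sd Measurement noise scale; per-cell SD is
#'   `noise_sd * (1 + signal)` (heteroscedastic, proportional-plus-floor).
#' @param y_noise_sd SD of the reference-measurement error added to the
#'   recorded response (refractometer repeatability plus juice-sampling
#'   variability, degrees Brix). The spectra are driven by the latent
#'   response; the recorded `y` carries this error, which sets the
#'   irreducible calibration error floor at the ~1.2 degrees Brix scale
#'   typical of fruit TSS reference data.
#' @param outlier_fraction Fraction of rows perturbed into gross outliers
#'   (0 disables; see [plant_outliers()]).
#' @param outlier_magnitude Magnitude passed to [plant_outliers()].
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 189,
                       wl_start = 1000, wl_end = 2500, n_points = 1557,
                       bands = default_bands(),
                       y_range = c(14.6, 28.5),
                       baseline_sd = 0.005,
                       scatter_sd = 0.005,
                       noise_sd = 0.05,
                       y_noise_sd = 0.8,
                       outlier_fraction = 0,
                       outlier_magnitude = 1,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1, cfg$wl_end > cfg$wl_start)
  if (cfg$n_points < nrow(cfg$bands)) {
    stop("config error: n_points (", cfg$n_points,
         ") must be at least the number of bands (", nrow(cfg$bands), ")")
  }
  if (cfg$baseline_sd < 0 || cfg$scatter_sd < 0 || cfg$noise_sd < 0 ||
      cfg$y_noise_sd < 0) {
    stop("config error: all SDs must be >= 0")
  }
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction >= 1) {
    stop("config error: outlier_fraction must be in [0, 1)")
  }
  if (diff(range(cfg$y_range)) > 0 && !any(cfg$bands$informative)) {
    stop("config error: at least one band must be informative when y_range is non-degenerate")
  }
  invisible(cfg)
}

# evaluate Gaussian band profiles on the grid: p x n_bands
band_profiles <- function(wl, bands) {
  vapply(seq_len(nrow(bands)),
         function(b) exp(-0.5 * ((wl - bands$center[b]) / bands$width[b])^2),
         numeric(length(wl)))
}

#' Simulate synthetic NIR fruit spectra with a known analyte signal
#'
#' Each spectrum is
#' `baseline_i + scatter_i * sum_b amp_b(y_i) * gauss(lambda; c_b, w_b) + noise`,
#' with informative-band amplitudes affine in the response
#' (`amp = amplitude + slope * y`) and uninformative bands constant. The
#' returned ground truth lists the informative grid points (within one
#' width of an informative band center) and any planted outlier rows, so
#' downstream selection and screening stages can be scored.
#'
#' @param config A [sim_config()].
#' @return A list of class `nir_simulation`: `data` (a [spectra_set()]),
#'   `truth` (list with `informative_idx`, `outlier_idx`, `clean_X`,
#'   `bands`), and `config`.
#' @examples
#' sim <- simulate_spectra(sim_config(n_samples = 20, n_points = 100))
#' sim$data
#' @export
simulate_spectra <- function(config) {
  validate_sim_config(config)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_samples
  wl <- seq(config$wl_start, config$wl_end, length.out = config$n_points)
  G <- band_profiles(wl, config$bands)                       # p x B
  y <- stats::runif(n, config$y_range[1], config$y_range[2])

  amp <- outer(y, config$bands$slope) +
    matrix(config$bands$amplitude, n, nrow(config$bands), byrow = TRUE)  # n x B
  clean <- amp %*% t(G)                                      # n x p
  baseline <- stats::rnorm(n, 0, config$baseline_sd)
  scatter <- exp(stats::rnorm(n, 0, config$scatter_sd))
  signal <- clean * scatter
  X <- baseline + signal +
    matrix(stats::rnorm(n * ncol(clean)), n) * config$noise_sd * (1 + signal)

  inf_idx <- integer(0)
  for (b in which(config$bands$informative)) {
    inf_idx <- union(inf_idx,
                     which(abs(wl - config$bands$center[b]) <= config$bands$width[b]))
  }
  y_obs <- y + stats::rnorm(n, 0, config$y_noise_sd)
  ds <- spectra_set(wl, X, y = y_obs)
  out_idx <- integer(0)
  if (config$outlier_fraction > 0) {
    planted <- plant_outliers(ds, config$outlier_fraction,
                              config$outlier_magnitude,
                              seed = config$seed + 99991L)
    ds <- planted$data
    out_idx <- planted$outlier_idx
  }
  structure(list(
    data = ds,
    truth = list(informative_idx = sort(inf_idx), outlier_idx = out_idx,
                 y_latent = y, bands = config$bands),
    config = config
  ), class = "nir_simulation")
}

#' Plant gross outliers into a spectra set
#'
#' Perturbs `ceiling(fraction * n)` rows, alternating two contamination
#' classes: a gross baseline jump (bad-leverage direction) and an alien
#' absorption band at 2250 nm (orthogonal direction), so both distance
#' axes of robust PCA screening are exercised.
#'
#' @param ds A `spectra_set`.
#' @param fraction Contamination fraction, `0 < fraction < 0.5` (robust
#'   methods assume minority contamination).
#' @param magnitude Perturbation size in absorbance units; 0 returns the
#'   input unchanged (with an empty index list).
#' @param seed Integer seed for the row draw.
#' @return List with `data` (perturbed `spectra_set`) and `outlier_idx`
#'   (exact sorted indices of perturbed rows).
#' @export
plant_outliers <- function(ds, fraction, magnitude, seed = 1L) {
  validate_spectra_set(ds)
  if (fraction <= 0 || fraction >= 0.5) {
    stop("fraction must be in (0, 0.5): robust screening assumes minority contamination")
  }
  n <- nrow(ds$X)
  n_out <- ceiling(fraction * n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sort(sample.int(n, n_out))
  if (magnitude == 0) return(list(data = ds, outlier_idx = idx))
  X <- ds$X
  alien <- exp(-0.5 * ((ds$wavelengths - 2250) / 30)^2)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (j %% 2 == 1) X[i, ] <- X[i, ] + magnitude          # baseline jump
    else X[i, ] <- X[i, ] + magnitude * alien              # shape distortion
  }
  list(data = spectra_set(ds$wavelengths, X, y = ds$y, ids = ds$ids),
       outlier_idx = idx)
}
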