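# nirboost

Robust near-infrared (NIR) calibration for fruit total soluble solids
(TSS, °Brix): repeated uninformative-variable elimination (UVE) with
frequency-tier stratification of wavelengths, tier-specific PLS member
models, and an AdaBoost-style weighted ensemble — plus the preparation
stages that make such a calibration trustworthy (robust-PCA outlier
screening, z-score pretreatment, Kennard–Stone partitioning) and a
synthetic NIR spectra generator with known ground truth so the whole
workflow is testable without proprietary instrument data.

## Who this is for

Chemometricians and postharvest scientists building regression models
from diffuse-reflectance NIR spectra (1000–2500 nm) against a
wet-chemistry reference such as refractometric °Brix, who want a
reproducible, scriptable version of the UVE → tiers → ensemble workflow,
or a test bench with planted signal for method development.

## The method in brief

Given spectra `X` (n samples × p wavelengths) and reference values `y`:

1. **Screening** — a simplified ROBPCA: projection-pursuit outlyingness
   selects a clean h-subset, classical PCA on it gives a robust center
   and loadings, and each sample is diagnosed by its score distance
   `SD_i = sqrt(Σ_j t_ij²/λ_j)` (χ²-based cutoff) and its orthogonal
   distance `OD_i` (Wilson–Hilferty cutoff on `OD^{2/3}`). Flagged rows
   are removed.
2. **Pretreatment** — column-wise z-score with sample SD, fitted on the
   calibration set only.
3. **Partition** — Kennard–Stone max–min Euclidean selection of a
   calibration set (default 70%), deterministic with lowest-index ties.
4. **Repeated UVE** — each run appends 200 tiny uniform noise variables,
   fits PLS1 on each of 5 cross-validation folds at a fixed latent-variable
   count, and scores every column by the stability
   `c_j = mean_f(b_jf) / SD_f(b_jf)`; columns whose |stability| exceeds
   the 99% quantile of the noise columns' |stability| are selected. Over
   100 runs, wavelengths are bucketed by selection count: high (≥ 90),
   mid (30–89), low (1–29).
5. **Members and ensemble** — PLS models M1/M2/M3 on the three tiers;
   AdaBoost-style weighting grades each member's cross-validated
   deviations through a piecewise-linear loss with knots at 1.0 and
   1.5 °Brix, giving weighted error ε, β = ε/(1−ε) and member weight
   α = ln(1/β); sample weights are re-emphasized between members.
   Prediction is the weight-convex combination of member predictions.
6. **Evaluation** — RMSECV/RMSEP, Pearson Rcv/Rp, MAE and Bias
   (bias = mean(predicted − measured), so over-prediction is positive).

## Worked example

```r
library(nirboost)

sim <- simulate_spectra(sim_config(n_samples = 150, n_points = 400, seed = 7))
sim$data
#> <spectra_set> 150 samples x 400 wavelengths (1000-2500 nm)
#>   response y: range 14.5296-29.104, mean 21.9992

bundle <- run_full(sim$data, pipeline_config(
  seed = 7, uve = uve_config(n_runs = 50, seed = 7)))

bundle$screen
#> <outlier_report> k = 1  significance = 0.95
#>   flagged: 4 of 150 samples
#>   cutoffs: SD 2.236, OD 1.329

bundle$profile
#> <frequency_profile> 50 runs; tiers (>=45 / 15-44 / <15): 78 high, 59 mid, 83 low, 180 never selected

report_table(bundle)
#>            Methods Variables LV RMSECV    Rcv MAE_cal  RMSEP     Rp MAE_pred   Bias
#>        Raw spectra       400  1 1.0225 0.9664  0.8254 0.7797 0.9764   0.6002 0.1729
#>            z-score       400  1 1.0629 0.9660  0.8551 0.8172 0.9750   0.6378 0.2372
#>   UVE (single run)       132  1 0.9992 0.9674  0.8072 0.8239 0.9743   0.6590 0.1989
#>      M1: high tier        78  1 0.9911 0.9679  0.8062 0.8089 0.9750   0.6410 0.1895
#>       M2: mid tier        59  1 1.4568 0.9294  1.1387 1.2721 0.9394   1.1121 0.3514
#>       M3: low tier        83  1 2.7935 0.7058  2.2390 2.6063 0.7394   2.2062 0.9586
#>  AdaBoost ensemble        NA NA 0.9911 0.9679  0.8062 0.8089 0.9750   0.6410 0.1895
#> AdaBoost member weights: 1.0000, 0.0000, 0.0000 (sum = 1)
```

Reading the table: RMSECV/Rcv/MAE_cal come from out-of-fold calibration
predictions; RMSEP/Rp/MAE_pred/Bias from the held-out Kennard–Stone
prediction set, all in °Brix (correlations unitless). Here the
high-frequency tier (M1, 78 of 400 wavelengths) matches the full-grid
model with a fifth of the variables; because the mid and low tiers carry
substantially larger errors, the boosting sweep concentrates the weight
on M1. When members are closer in quality the weights spread toward
equal. Against the generator's ground truth, the high tier recovers the
informative bands with precision 0.90 and recall 0.88 in this run.

A command-line wrapper with per-stage subcommands (`simulate`, `screen`,
`split`, `uve`, `fit`, `boost`, `run`, `report`) lives in
`inst/cli/nirboost.R`:

```sh
Rscript inst/cli/nirboost.R simulate --n 150 --seed 7 --out spectra.csv --truth truth.json
Rscript inst/cli/nirboost.R run --in spectra.csv --seed 7 --out results/
```

## Package layout

- `R/spectra.R` — `spectra_set` container, wide-CSV I/O, versioned JSON
  model artifacts with exact round-trip.
- `R/synthetic.R` — the spectra generator and outlier planting.
- `R/preprocess.R` — z-score state and robust-PCA screening.
- `R/sampling.R` — Kennard–Stone and ratio-based splitting.
- `R/pls.R` — NIPALS PLS1, prediction, k-fold cross-validation.
- `R/uve.R` — single-run and repeated UVE, frequency tiers.
- `R/ensemble.R` — AdaBoost weighting and ensemble prediction.
- `R/metrics.R` — evaluation statistics.
- `R/pipeline.R` — the full workflow and the comparison table.
- `vignettes/nirboost-methods.Rmd` — model assumptions, parameter
  choices, and what the synthetic tests do and do not establish.
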