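# tofanomaly

Outlier detection for acceleromyographic train-of-four (TOF) neuromuscular
monitoring.

Quantitative monitoring of neuromuscular block measures the four evoked
thumb twitches T1–T4 after train-of-four nerve stimulation; the TOF ratio
(TOFR = T4/T1) guides dosing and extubation decisions. Kinetic
(accelerometer + gyroscope) recordings of these twitches are prone to
artifacts — rebound bursts, oscillation trains, missing twitches, wide
inter-twitch gaps, non-monotone fade — that corrupt the displayed ratio and
erode trust in the monitor. `tofanomaly` is a pipeline for flagging such
artifactual measurements offline, aimed at researchers developing
quantitative monitoring devices and at anyone who wants a fully reproducible
benchmark for imbalanced waveform-outlier detection.

The package provides:

* a **synthetic cohort generator** (`simulate_dataset()`) producing labelled
  six-channel TOF recordings — 533 measurements from 35 patients with 30
  anomalies in 18 patients by default — whose extracted-feature marginals
  are calibrated to published clinical summary statistics
  (`calibration_report()`), with a seven-class anomaly taxonomy;
* **feature extraction** (`build_feature_table()`): a combined RMS movement
  envelope, four-twitch peak detection, and 15 features — 7 basic
  (T1–T4, TOFR, envelope mean/SD) and 8 engineered pattern features
  (inter-peak time deltas and twitch-to-envelope-mean ratios);
* **cost-sensitive logistic regression** (`cslr_fit()`): the class-weighted
  L2-penalised negative log-likelihood

  $$J(\beta_0,\beta)=\textstyle\sum_i w_{y_i}\,\ell_i(\beta_0,\beta)
    +\lambda\lVert\beta\rVert_2^2,$$

  minimised by damped Newton iteration, with broom-style `tidy()` /
  `glance()` methods;
* the **evaluation protocol** (`run_experiment()`): stratified 60/40 split,
  stratified 5-fold grid search over λ and class weights, F1 / precision /
  recall / rank ROC-AUC with stratified bootstrap CIs, learning curves, and
  a paired Wilcoxon signed-rank comparison of the basic- versus
  engineered-feature models.

## Worked example

Everything chains from one master seed:

```r
library(tofanomaly)

cfg <- generator_config(seed = 42)
recordings <- simulate_dataset(cfg)
features <- build_feature_table(recordings)
features[1:3, c("T1", "T4", "TOFR", "deltaT4_T1", "ratioT1", "label")]
#> # A tibble: 3 × 6
#>      T1    T4  TOFR deltaT4_T1 ratioT1 label
#>   <dbl> <dbl> <dbl>      <dbl>   <dbl> <chr>
#> 1 0.894 1.27  1.42          42    5.05 normal
#> 2 0.307 0.223 0.725         40    6.73 normal
#> 3 1.70  1.50  0.883         43    6.36 normal
```

Row 1 is a supra-physiological measurement (TOFR > 1, a known AMG artifact
that is still labelled normal); row 2 shows mild fade. `deltaT4_T1` is the
T1-to-T4 peak distance in centiseconds and `ratioT1` the first twitch
relative to the whole-measurement envelope mean.

The full experiment — simulate, extract, split, grid-search both feature
sets, refit, evaluate on the held-out 40% — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 42), with_ci = FALSE,
                    with_learning_curves = FALSE)
res
#> <tof_pipeline_result> 533 recordings -> 533 feature rows (master seed 42)
#> <tof_experiment>
#>   split: train n = 319 (18 outliers), test n = 214 (12 outliers)
#>   basic (test): F1 0.70, precision 0.88, recall 0.58, ROC-AUC 0.78
#>   engineered (test): F1 0.86, precision 1.00, recall 0.75, ROC-AUC 0.96
#>   Wilcoxon (basic vs engineered): V = 6, p = 9.08e-05 over 22 pairs
```

The engineered pattern features dominate the raw amplitude features on the
held-out set: at this seed they recover 9 of the 12 test anomalies with no
false alarms (precision 1.00, recall 0.75, F1 0.86), and the paired Wilcoxon
test over shared repeated-CV folds calls the difference significant. With 12
held-out outliers a single split's F1 is a coarse draw (steps of ~0.035), so
expect seed-to-seed variation around these values.

`tidy(res$experiment)` returns the full metric table,
`plot_experiment_roc(res$experiment)` the ROC curves, and
`autoplot(res$experiment$learning_curves)` the learning curves when they are
computed. `calibration_report(features)` compares the simulated feature
marginals against their clinical reference values.

## Command line

A thin CLI over the same functions lives at `inst/cli/tofanomaly.R`
(subcommands `simulate`, `extract`, `train`, `evaluate`, `pipeline`), e.g.

```sh
Rscript inst/cli/tofanomaly.R simulate --seed 42 --out recs.jsonl
Rscript inst/cli/tofanomaly.R extract --in recs.jsonl --out features.csv
Rscript inst/cli/tofanomaly.R pipeline --seed 42 --out out/
```

Recordings are read and written as JSON-lines or long CSV, feature tables as
CSV with full-precision floats, fitted models and reports as JSON.

## Further reading

The methods vignette (`vignettes/tof-outlier-detection.Rmd`) documents the
signal model, the feature definitions and their invariants, the CSLR
objective and optimiser, the evaluation protocol, what the synthetic cohort
does and does not emulate, and known limitations.
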