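# cyclemg

Cyclostationary surface-EMG analysis for predicting blood lactate
concentration and oxygen uptake during cycling exercise.

## The problem

Surface electromyography (sEMG) recorded during dynamic exercise is
non-stationary: muscle force, length and electrode geometry change within
every pedal revolution, which defeats the classical stationary-signal
fatigue indices such as the median power frequency.  Pedalling is
mechanically repetitive, though, so if the signal is segmented into
corresponding phases of successive revolutions, segment statistics can be
assumed to repeat from cycle to cycle (*cyclic stationarity*) and
segment-wise spectra become comparable.

`cyclemg` is for exercise physiologists and biosignal engineers who want a
tested, reusable implementation of that full pipeline:

1. **Pre-process** — causal 10th-order Butterworth band-pass (20–400 Hz,
   ≥ 60 dB at the 10/450 Hz stop edges), applied as second-order sections.
2. **Segment** — one burst onset per pedal revolution from the variability
   ratio V꜀ₒₘ(t) = V(t−N)/V(t), where V(t) = Σ|ΔS| over an N = 256-sample
   window; onsets are its local minima, and each segment is the 256 samples
   of filtered signal that follow.
3. **Characterise** — 36 variables per segment: RMS, dRMS, IF
   (zero-crossings/2); mode, mean, SD, skewness, excess kurtosis of the
   unit-area power distribution D(f); percentiles q10…q90 (q50 = MPF); and
   19 overlapping 23.44-Hz relative band powers (p23_47 … p234_258).  An
   11-point running median smooths each variable over time.
4. **Model** — ridge regression on z-scores, β = (XᵀX + λI)⁻¹Xᵀy, with λ
   selected on the integer grid 1–100 by cross-validation (smoothed, ties
   to the smaller λ), and a 100-tree random forest (mtry = 12) evaluated
   out-of-bag over 10 seeds with permutation variable importance.
5. **Evaluate** — R² = 1 − SS_res/SS_tot, Spearman rank correlations,
   stacked 0.2-quantile summaries of weights/importances with one-sample
   t-tests, and a paired t-test comparing forest vs ridge across datasets.

Because datasets of this kind are not publicly deposited, the package
includes a protocol-driven synthetic generator (three-phase constant-load
protocol, lactate accumulation/clearance around a threshold, first-order
VO2 lag, cyclostationary bursts with known onsets), so the whole pipeline
is reproducible and testable offline.

## Worked example

A shortened three-phase protocol (1 min at 60%, 1 min at 92.5%, 1 min at
60% of VO2max power, 90 rpm) on two right-leg muscles:

```r
library(cyclemg)

cfg <- pipeline_config(seed = 42)
cfg$simulate$phases <- list(
  list(duration_s = 60, load_frac = 0.60),
  list(duration_s = 60, load_frac = 0.925),
  list(duration_s = 60, load_frac = 0.60)
)
cfg$simulate$channels <- c("VL_right", "RF_right")
cfg$model$n_seeds <- 5

rep <- run_pipeline(cfg)
rep
#> <cyclemg_report>
#> Mean cross-validated / out-of-bag R^2:
#> # A tibble: 6 × 4
#>   target  channel  ridge forest
#>   <chr>   <chr>    <dbl>  <dbl>
#> 1 lactate RF_right 0.885  0.982
#> 2 lactate VL_right 0.851  0.981
#> 3 lactate All      0.831  0.983
#> 4 vo2     RF_right 0.879  0.980
#> 5 vo2     VL_right 0.849  0.984
#> 6 vo2     All      0.822  0.981

rep$segmentation
#> # A tibble: 2 × 4
#>   channel  n_true n_detected median_error_ms
#>   <chr>     <int>      <int>           <dbl>
#> 1 RF_right    270        270            14.1
#> 2 VL_right    270        270            14.0
```

Every one of the 270 planted bursts per channel is recovered, with ~14 ms
median onset error (a 256-ms analysis window).  The forest's out-of-bag R²
(≈ 0.98) exceeds the ridge cross-validated R² (≈ 0.85) on every dataset —
the non-linear model tracks the lactate/VO2 trajectories more closely, and
`rep$comparison` quantifies that difference with a paired t-test.
`rep$weights`, `rep$importances` and their `*_summary` tables hold the
standardized ridge weights and normalised permutation importances per
channel; `plot_quantile_segments()`, `autoplot()` on fitted models,
`plot_physio()` and `plot_shrinkage_curve()` draw the standard displays.

Lower-level entry points compose with the pipe:

```r
sim   <- simulate_dataset(default_protocol(), seed = 1)
feats <- sim$sim$emg |>
  bandpass_emg() |>
  segment_emg(cadence_rpm = 90) |>
  assemble_features() |>
  median_smooth()
dat   <- align_features(feats, sim$truth$lactate, target = "lactate")
fit   <- ridge_fit(dat, "lactate", lambda = 32)
tidy(fit)      # 36 standardized weights
glance(fit)
```

A thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R`
(`Rscript run-pipeline.R --config cfg.yaml --seed 42 --out dir/`).

## Package layout

* `R/protocol.R`, `R/simulate-*.R` — protocol spec and synthetic generator
* `R/physio-io.R` — CSV IO and Catmull–Rom interpolation
* `R/preprocess.R` — Butterworth band-pass (second-order sections)
* `R/segmentation.R` — variability-ratio onset detection and segment cutting
* `R/features.R` — the 36 variables and median smoothing
* `R/scaler.R`, `R/ridge.R`, `R/forest.R` — models
* `R/evaluation.R` — R², Spearman, CV, distribution summaries, paired tests
* `R/align.R`, `R/pipeline.R`, `R/plots.R` — orchestration and graphics
* `vignettes/cyclemg-methods.Rmd` — the methods vignette (model, parameters,
  generator scope, numerical conventions)
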