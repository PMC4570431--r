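---
title: "Methods: cyclostationary sEMG analysis for metabolic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclostationary sEMG analysis for metabolic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During dynamic exercise such as cycling, surface electromyography (sEMG) is
non-stationary: muscle force, muscle length and electrode geometry all change
within each pedal revolution, so classical stationary-signal spectral
estimates (and the fatigue indices built on them, like the median power
frequency) are unreliable.  Pedalling is, however, mechanically repetitive.
If the signal is cut so that only corresponding phases of different
revolutions are compared, the statistics of those segments can be assumed to
repeat from cycle to cycle — *cyclic stationarity* — and segment-wise spectra
become comparable.

`cyclemg` implements that programme end to end:

1. band-limit the raw recording (20–400 Hz band-pass);
2. find one activity-burst onset per pedal revolution per muscle with a
   variability-ratio detector, and cut a fixed 256-sample segment at each
   onset;
3. characterise each segment by 36 time- and frequency-domain variables;
4. median-smooth each variable over time;
5. relate the smoothed variables to sparse physiological targets — blood
   lactate concentration and oxygen uptake (VO2) — with a ridge (Tikhonov)
   linear model and a random-forest regressor, evaluated by cross-validation
   and out-of-bag (OOB) prediction respectively.

Because no public recording of this kind exists, the package ships a
synthetic-data generator that produces protocol-driven, coupled sEMG +
lactate + VO2 datasets with known ground truth, making every downstream
stage testable.

# Pre-processing

Two causal Butterworth stages: a 10th-order low-pass with 400 Hz cutoff
(≥ 60 dB attenuation by 450 Hz; electronic noise) followed by a 10th-order
high-pass with 20 Hz cutoff (≥ 60 dB by 10 Hz; motion artifacts).  At order
10 the direct-form transfer function is numerically fragile — coefficient
sensitivity costs about five significant digits — so each stage is designed
and applied as a cascade of five second-order sections (analog prototype
poles, bilinear transform, conjugate pairs as biquads).  The achieved
attenuations are 62.4 dB at 450 Hz and 60.3 dB at 10 Hz.

Filtering is single-pass (causal) rather than zero-phase.  The group delay
this introduces is identical for every channel and every cycle, so it
cancels in all between-segment comparisons; zero-phase filtering would
require a second, acausal pass that the rest of the pipeline does not need.

# Segmentation

For a filtered signal $S(t)$, the backward difference is
$\Delta S(t) = S(t) - S(t-1)$.  Windowed variability over $N$ samples
(default $N = 256$, i.e. 256 ms at 1000 Hz, roughly a third of a pedal
cycle at 90 rpm) is

$$V(t) = \sum_{\tau=t}^{t+N-1} \lvert \Delta S(\tau)\rvert ,$$

a windowed total variation: large inside a burst, small in the inter-burst
baseline.  (The *signed* sum, available via `mode = "signed"`, telescopes to
the two-point difference $S(t+N)-S(t)$ and is kept only for comparison — it
does not measure variability.)  The variability ratio compares the window
ending just before $t$ with the window starting at it:

$$V_{\mathrm{com}}(t) = \frac{V(t-N)}{V(t)}.$$

At a burst onset the trailing window is quiet and the leading window active,
so $V_{\mathrm{com}}$ attains a local minimum; burst ends produce maxima
(computed but unused downstream).  Segments are the 256 samples of $S$
following each detected minimum.

## Onset-detection design choices

$V_{\mathrm{com}}$ is a *ratio* statistic and therefore heavy-tailed: over a
quiet denominator window it can reach many orders of magnitude above its
typical value.  Selection rules tied to the global range are dominated by
those few peaks, so the detector uses scale-free criteria throughout:

* **Candidates** are local minima (plateaus count once, at their right
  edge) with $V_{\mathrm{com}} \le 0.5$ (`max_onset_ratio`): at a genuine
  onset the leading window is substantially more variable than the trailing
  one, while the shallow dips of a noise-only stretch hover near 1.
* **Separation**: no two onsets closer than 0.7 of the expected cycle
  (deeper minima win), which collapses the many micro-minima on a valley
  floor to one onset per revolution.
* **Relative prominence**: a retained minimum must dip at least
  `prominence_frac` (default 0.2) below the lower of its enclosing maxima,
  *relative to that maximum*.  A side on which no point could ever satisfy
  the dip (a valley clipped at the vector edge) is ignored rather than
  scored.
* **Valley-edge refinement**: under noise the argmin wanders across the
  quiet stretch before the burst, while the true onset is where
  $V_{\mathrm{com}}$ starts to rise (the leading window filling with burst
  energy).  Each detected minimum is therefore moved to the right edge of
  its flat valley (values within 15% of the minimum, isolated bumps
  skipped).  A minimum never followed by a rise is a clipped valley with no
  burst behind it and is discarded.
* **Recording head**: inside `segment_emg()` the trailing window may
  truncate at the start of the recording (length-normalised, minimum
  support $N/2$), so bursts in the first two window-lengths are detectable.
  The exported `variability()`/`variability_ratio()` keep the strict
  full-window definitions.

On jitter-free synthetic recordings with silent inter-burst baselines the
detector recovers every planted onset with ~2 ms median error; at the
generator's default noise and ±5 ms onset jitter, counts remain exact with
median errors well under the 32-ms (⅛ window) acceptance bound.

# The 36 segment variables

Each segment is multiplied by a Hamming window
($0.54 - 0.46\cos$) and the squared magnitude of the one-sided DFT gives
the power spectrum $P(f)$ on bins of width $f_s/N = 3.90625$ Hz.  The
*power distribution* $D(f)$ is $P$ normalised to unit area over
0–Nyquist (Riemann sum).  The variables, in canonical order:

| # | Name | Definition |
|---|------|------------|
| 1–2 | RMS, dRMS | root mean square of the segment and of its backward difference |
| 3 | IF | zero-crossing count / 2 (a count per segment; strict sign changes, exact zeros skipped) |
| 4–8 | ModF, MnF, StD, Skew, Kurt | mode, mean, sd, skewness and *excess* kurtosis of frequency under $D(f)$ |
| 9–17 | q10 … q90 | every tenth percentile of $D(f)$; q50 is the median power frequency (MPF) |
| 18–36 | p23_47 … p234_258 | relative power in 19 overlapping bands |

The bands are defined directly on DFT bins — six bins wide, starting every
three bins from bin 6 — which with the default geometry gives 23.44-Hz-wide
bands with 11.72-Hz overlap, the first spanning 23.44–46.88 Hz and the last
ending at 257.8 Hz.  Other $(N, f_s)$ combinations that cannot reproduce
this plan raise an error rather than silently shifting the bands.

Numerical conventions:

* the DC bin participates in the normalisation of $D(f)$ but is excluded
  from the mode (the high-pass stage makes it ≈ 0; excluding it avoids a
  spurious 0 Hz mode);
* percentiles invert the cumulative distribution with each bin's mass
  uniform over the bin (centre ± half a width, clipped to 0–Nyquist), the
  crossing bin resolved by linear interpolation — so a point-mass spectrum
  localises every percentile to within half a bin;
* a degenerate distribution (all mass in one bin) reports StD = 0 and
  Skew = Kurt = 0; an all-zero segment yields all-zero features with a
  warning instead of NaN propagation;
* IF is reported as the raw half-count, not rescaled to Hz; the z-scoring
  applied before modelling makes affine units irrelevant.

Each variable is then passed through an 11-point centred running median per
channel (≈ 9–10 s of pedalling), which suppresses segment-to-segment
variability without masking slower physiological trends; edge positions use
the median of the available shrunken window so no rows are lost.

# Aligning targets

Lactate is measured every 60 s and VO2 every 10 s, far sparser than one
sample per pedal revolution.  Targets are interpolated *to segment
timestamps* (not features aggregated to measurement times), preserving the
sampling density the models are built on.  Interpolation is cubic Hermite
with Catmull–Rom tangents — at interior knot $i$ the tangent is the centred
finite difference $(v_{i+1}-v_{i-1})/(t_{i+1}-t_{i-1})$, one-sided at the
ends — which is $C^1$, exact at knots, and reproduces linear data exactly.
Queries outside the measured span are an error: segments before the first
or after the last measurement are dropped rather than extrapolated.

# Models

**Ridge.** Predictors and the response are z-scored (scaler fit on training
rows only, applied to validation rows — no leakage), so the linear model
needs no intercept and the magnitude of a standardized weight measures its
variable's influence.  The weights solve the penalized normal equations
$(X^\top X + \lambda I)\beta = X^\top y$ by direct solve; an exactly
singular system at $\lambda = 0$ raises an error advising $\lambda > 0$.
The shrinkage $\lambda$ is selected on the integer grid 1–100: per-dataset
10-fold cross-validated $R^2$ curves are averaged across datasets, smoothed
with a centred moving average of width 9 (a mild smoother; edges shrink),
and the argmax taken with ties broken towards the smaller, more
parsimonious value.  The grid search is computed via one SVD per training
fold, so the full 100-value grid costs no more than a handful of fits.  The
defaults carried by the pipeline are $\lambda = 32$ for lactate and 18 for
VO2, the values this selection procedure produces on the reference data
the package emulates.

**Random forest.** 100 trees, `mtry` = ⌊p/3⌋ = 12 for the 36-variable set,
grown on bootstrap samples, backed by the `randomForest` package (which
honours bootstrap, mtry, OOB access and permutation importance, all
seedable).  Performance is the $R^2$ of out-of-bag predictions — each row
predicted only by trees whose bootstrap missed it (about $1/e \approx 37\%$
of trees per row) — averaged over 10 seeds to reduce Monte-Carlo variance.
Permutation importance is the increase in OOB mean-squared error when a
variable is scrambled, optionally normalised to sum to one so values are
comparable with the equal-importance reference $1/36$.  Targets enter the
forest on their raw scale (forests are invariant to monotone transforms);
the z-scored route is used only by the linear model.

**Evaluation.** $R^2 = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ (0 for the
mean predictor, negative allowed; constant-response degenerate case defined
as 0 with a warning).  Monotone association uses Spearman's rank
correlation with average ranks for ties (Pearson on ranks; on tie-free data
this equals the classical $1 - 6\sum d_i^2 / (n(n^2-1))$ closed form, and
purely monotone data return exactly ±1).  Distributions of per-dataset
weights or importances are summarised as stacked 0.2-quantile segments with
a two-sided one-sample t-test of mean ≠ 0 at $p < 0.05$; no multiple-testing
correction is applied to these flags, deliberately, and the plots should be
read as descriptive.  Linear and forest models are compared by a two-sided
paired t-test on per-dataset $R^2$ differences.

The evaluation fold assignment is independent of the folds used inside the
shrinkage search (different seeds).  Folds are random by default; a
`contiguous` flag provides time-blocked folds for users worried about
temporal leakage in slowly-varying targets.

# The synthetic-data generator

The generator emulates a three-phase constant-load protocol on a cycle
ergometer: 6 min at 60% of VO2max power, a high-intensity phase at 92.5%
(midpoint of the 90–95% band) ridden to exhaustion — time to task failure at
that intensity is subject-dependent; the default is fixed once at 300 s, a
realistic value — and 6 min of active recovery at 60%, pedalled at 90 rpm
and sampled at 1000 Hz.

**Metabolics.** Blood lactate follows a linear accumulation/clearance ODE
around a threshold load $\theta$ (default 0.75 of VO2max power):

$$\frac{dL}{dt} = a\,\max(0, \mathrm{load}-\theta) - c\,(L - L_{rest}),$$

with $a = 0.18$ mmol L⁻¹ s⁻¹ per unit excess load, $c = 0.003$ s⁻¹ and
$L_{rest} = 1$ mmol/L — chosen once so the default protocol produces a
realistic peak of ~8–9 mmol/L that declines through recovery.  Clearance
pulls towards the resting baseline (not zero), so below-threshold exercise
relaxes to $L_{rest}$.  This is the simplest mechanism producing the
characteristic rise-and-fall; it is a generator, not a physiological claim.
VO2 follows a first-order lag (τ = 30 s, typical oxygen-uptake kinetics)
towards a load-proportional setpoint (0.5 + 3.0·load L/min).  Both are
integrated exactly per 1-s step (piecewise-constant load makes the ODEs
linear), then sampled on the instrument grids — lactate every 60 s, VO2
every 10 s — with additive Gaussian observation noise truncated at zero
(sd 0.2 mmol/L and 0.08 L/min).  A latent dimensionless *exertion*
trajectory (load lagged by 45 s plus a small lactate-coupled fatigue term)
drives the EMG.

**EMG.** One burst per pedal revolution per channel: band-limited coloured
Gaussian noise (flat support 20–400 Hz split at 180 Hz into a body and a
tail band) under a Tukey activation envelope with 20% taper.  The Tukey
shape makes burst energy start essentially at the nominal onset, so the
ground-truth onset marks where energy actually begins — a raised-cosine
envelope would leave ~25 ms of near-silence after it and make any detector
look biased.  Burst RMS is `amp_base * (0.25 + amp_gain · exertion)`, an
exact linear gain in `amp_base`; the fraction of spectral power in the tail
band is `tail_mass + tail_drift · exertion`, so a positive `tail_drift`
plants a rising high-frequency tail that moves the upper percentiles (q80,
q90) upward with exertion — the knob used by the feature-importance
recovery experiments.  Onsets sit on the cadence grid with muscle-specific
within-cycle phases (VL 0.30, RF 0.38, ST 0.85, BF 0.92 of the cycle; left
leg half a cycle out of phase) and uniform jitter up to ±10 ms (default
±5 ms).  White baseline noise (default sd 0.01 mV against burst RMS ~0.25
mV) fills the gaps; setting it to zero yields digital silence between
bursts.  All randomness flows from one explicit seed: identical arguments
give bit-identical recordings.

**What the generator does not emulate** — and hence what green tests do
*not* demonstrate about real recordings: motor-unit recruitment and firing
statistics, electrode displacement and skin-impedance drift, power-line
interference, cross-talk between muscles, within-burst non-stationarity
beyond the fixed envelope, cadence drift and pedalling technique breakdown
near exhaustion, and any true physiology linking spectra to lactate.  The
recovery experiments show that *if* a monotone or non-linear relationship
between segment features and a target exists, the pipeline finds it,
ranks the responsible variable first, and the forest exploits
non-linearity better than the linear model.  They do not show that such
relationships hold in vivo.

# Numerical and degenerate-input conventions

* The variability-ratio denominator is guarded by
  $\varepsilon = \max(V)\cdot 10^{-12}$, which scales with the signal, so
  onset detection is exactly amplitude-invariant.
* An amplitude-constant signal has zero $V_{\mathrm{com}}$ range and yields
  zero onsets rather than an error.
* CSV writers emit doubles with 17 significant digits and the readers use
  correctly-rounded parsing, so write → read round-trips are bit-exact.
* Zero-variance feature columns are dropped by the scaler with a warning (a
  constant has no z-score); a constant response gives zero ridge weights.
* Rows never out-of-bag (in every bootstrap) are excluded from OOB $R^2$
  with a warning.

# Problem sizes

The test-suite recovery experiment uses the full three-phase protocol
scaled to ~1000 pedal cycles per channel with eight replicate channels and
10 forest seeds; segmentation oracles run at 30 and 300 cycles; the
acceptance script runs the pipeline on a half-length protocol (510 s, four
channels) plus a four-channel recovery experiment.  These sizes were chosen
as the smallest at which the quantities of interest (seed-averaged OOB
$R^2$, paired model comparisons across replicates, onset-detection rates)
are stable; all of them are package choices and can be scaled up freely
through `pipeline_config()`.

# Known limitations

* The onset detector assumes one burst per cycle and a known nominal
  cadence; co-contractions producing two activity bouts per cycle in one
  muscle would be merged by the separation rule.
* Segment length is fixed at 256 samples; cadences far from 90–100 rpm
  change the fraction of the cycle a segment covers, and the band plan is
  tied to the 256/1000 Hz bin geometry.
* The linear-vs-forest comparison inherits the usual caveat of paired
  t-tests on few replicates; with fewer than ~5 datasets the test is
  underpowered.
* Ridge defaults (λ = 32 / 18) are sensible for z-scored 36-variable
  problems of this shape but should be re-selected via
  `select_shrinkage()` for substantially different data.
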