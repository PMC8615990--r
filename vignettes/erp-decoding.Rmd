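---
title: "Time-resolved decoding of two-condition ERP studies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of two-condition ERP studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

## The analysis problem

`erpdecode` implements a complete analysis chain for a classic question in
cognitive neurophysiology: *when* does the brain's response to a visual
stimulus carry information about an experimental manipulation, and *where*
on the scalp (and plausibly in the brain) does that information live? The
concrete setting is a two-condition event-related potential (ERP) study
with a go/no-go priming structure: on each trial a prime picture of an
environment framed from either a near/restricted or a far/panoramic
viewpoint is followed, after a fixed interval, by a target picture; the
participant executes a footstep response when prime and target match.
Epochs are cut around target onset, and the scientific question is whether
single-trial multichannel EEG discriminates the near from the far framing
at any point of the prime–target–response sequence.

The package answers it with a time-resolved multivariate decoding analysis
(MVPA): at each time point an independent linear classifier is trained on
the spatial pattern of channel amplitudes and evaluated out of sample,
yielding an accuracy time course; a label-permutation test turns that
curve into significant time intervals; channel-space paired t-tests inside
those intervals give the difference topography; and a distributed inverse
solution maps the topography into source space.

Because multi-subject EEG data of this kind are rarely depositable, the
package also contains a first-class forward simulator whose defaults
reproduce the design above, so that every stage of the pipeline can be
exercised — and its statistical calibration measured — without any
external data.

## The synthetic study generator

`simulate_study()` draws, per subject, a continuous recording that is the
sum of four components:

1. **Background noise.** A small set of latent $1/f$ ("pink",
   `pink_noise()`, spectral exponent $-1$) sources is mixed into the
   montage through a random unit-norm mixing matrix, giving
   channel-correlated background activity with 10 µV rms per channel,
   plus 2 µV of independent sensor white noise. The pink spectrum matters:
   it produces the temporal autocorrelation that any permutation test on a
   time course must be calibrated against.
2. **Condition-independent evoked activity.** A modest P1/N1-like response
   (≈2 µV, 400 ms) is emitted at every picture onset, identically for both
   conditions, so decoders face realistic evoked structure that carries no
   label information.
3. **Condition effects.** Each `effect_spec()` is a Hann-envelope source
   waveform inside a window relative to target onset, projected through
   the head model's gain and added on far-condition trials only; a signed
   amplitude of $a$ µV therefore makes the expected far-minus-near evoked
   difference exactly $a \cdot \mathbf{g}_j \cdot w(t)$, which the test
   suite verifies against closed form. `default_effects()` places a
   positive fronto-central effect at −550..−450 ms and a negative
   posterior effect at 600..700 ms, at ±2.5 µV — a typical ERP
   condition-difference magnitude.
4. **Artifacts.** With 2 % probability per trial a 300 µV transient is
   added on one channel, so peak-to-peak rejection has something to do.

Timing defaults mirror the emulated design: 250 Hz sampling, epochs
−1500..+1500 ms around target onset, prime at −1200 ms, 700 ms picture
presentations, 500 ms inter-stimulus and 2500 ms inter-trial intervals;
30 subjects with 84 go trials per condition and a 1:4 no-go:go ratio.
Reaction times are shifted-lognormal (shift 300 ms; near mean 940 ms, far
900 ms, sd 100 ms, between-subject sd 80 ms), making the far condition
faster — the behavioural facilitation the paired t-test in
`rt_comparison()` is meant to detect.

The head model (`build_toy_headmodel()`) is deliberately parametric:
sensors on a Fibonacci lattice of the upper unit hemisphere, sources in an
inner ball with a minimal pairwise separation, and a Gaussian-decay gain
$g_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)$ with columns scaled to 1 µV peak.
Any injective lead field supports the inverse-solution property tests; an
anatomical volume conductor would add realism but no testable structure.

**What the simulator does not emulate:** ocular/cardiac artifacts and
their ICA-based removal, bad channels, inter-subject montage variability,
non-stationary noise, and latency jitter of the evoked components. Passing
tests on synthetic data therefore demonstrate the *statistical
machinery* — calibration, recovery, invariances — not robustness to every
pathology of real recordings.

## Preprocessing

`preprocess_study()` chains the standard ERP steps, each exported on its
own:

- `bandpass()`: 1–40 Hz Butterworth of order 2, applied forward and
  backward (`signal::filtfilt`), i.e. zero phase with the squared
  magnitude response. The design is applied to the *continuous* recording,
  before epoching, so filter transients stay away from the analysis
  window; edges are handled by reflection padding of
  $3 f_s / f_{\mathrm{low}}$ samples (the underlying literature is
  typically silent on padding; reflection is the conventional choice).
- `common_average()`: re-reference to the instantaneous channel mean. All
  channels participate; bad-channel exclusion is deliberately not
  modelled.
- `epoch_trials()`: one epoch per **go** event (no-go trials exist only to
  enforce attention and never enter the decoding analyses), covering the
  half-open window [−1500, +1500) ms — `round((tmax−tmin)/1000·f_s)`
  samples, with 0 ms = target onset, sample times on the
  $t_{\min} + k/f_s$ grid. Events too close to the recording edge are
  dropped with a warning.
- `baseline_correct()`: subtract the per-trial per-channel mean over
  [−1500, −1200) ms — the 300 ms preceding prime onset, the only segment
  guaranteed free of stimulus processing. Baseline correction and common
  averaging are both linear projections and commute; the suite asserts
  this to 1e−10.
- `reject_artifacts()`: trials whose peak-to-peak amplitude exceeds 150 µV
  on any channel are removed — a deterministic, reproducible stand-in for
  visual-plus-ICA cleaning, which belongs to a different line of work. A
  subject falling below `min_epochs` (default 40) per condition is a hard
  error naming subject and condition, because subject-level means and the
  leave-one-subject-out folds both assume adequately estimated conditions.

Labels follow the convention near = +1, far = −1.

## The decoder

At one time point, with trials $\mathbf{x}_i \in \mathbb{R}^{p}$ and
labels $y_i \in \{+1,-1\}$, the classifier is linear discriminant
analysis with a shrinkage covariance:

$$
\hat\Sigma = (1-\lambda)\, S + \lambda \nu I, \qquad
\mathbf{w} = \hat\Sigma^{-1}(\boldsymbol\mu_+ - \boldsymbol\mu_-), \qquad
b = -\tfrac12\, \mathbf{w}^\top (\boldsymbol\mu_+ + \boldsymbol\mu_-),
$$

where $S$ is the class-mean-centered pooled covariance (normalized by
$n-1$) and $\nu = \operatorname{tr}(S)/p$ preserves total variance in the
regularization target. The decision value is
$d = \mathbf{w}^\top \mathbf{x} + b$ and the predicted class
$\operatorname{sign}(d)$, with the measure-zero tie $d = 0$ mapped to
$+1$ (documented, asserted, irrelevant in practice). Equal priors are
assumed — the simulator balances conditions exactly and the emulated
design nearly so.

Shrinkage is essential, not cosmetic: with 128 channels and a few dozen
training trials the pooled covariance is singular. The default
`shrinkage = "auto"` computes the analytic Ledoit–Wolf-style intensity per
training split,

$$
\lambda^\* = \frac{\tfrac{n}{(n-1)^2}\sum_{ij}
  \widehat{\operatorname{Var}}_k\!\left(z_{ki} z_{kj}\right)}
  {\lVert S - \nu I\rVert_F^2},
$$

clipped to $[0,1]$; a fixed $\lambda$ is accepted for reproducing
specific fits. At $\lambda = 0$ a rank-deficient $\hat\Sigma$ is inverted
in the least-squares (pseudo-inverse) sense, so the textbook
zero-shrinkage examples still work.

`decode_timecourse()` fits this classifier independently at every sample
of the analysis window (default −1200..1000 ms: prime onset to the
approximate time of movement), under one of two cross-validation schemes.
The default, **leave-one-subject-out**, defines one fold per subject — all
of a subject's trials are held out together, the classifier trains on the
pooled trials of the others — which tests across-subject generalization
and never leaks a subject's statistics into its own test fold. The
alternative `cv = "trial"` (leave-one-trial-out) serves single-subject
use. Features are the raw baseline-corrected channel amplitudes at the
single sample — no temporal smoothing or window stacking — which is what
"a classifier per time point" means operationally. Fold accuracies are
averaged unweighted (folds are balanced by construction) and their
standard error across folds is reported. The hot loop (a classifier per
time point × fold × permutation) is compiled (RcppArmadillo); the R-level
`fit_lda()`/`predict()` implement the identical estimator and the test
suite holds the two paths together to 1e−10, alongside an independently
coded brute-force CV oracle.

## Permutation inference

`permutation_null()` re-runs the *entire* cross-validated decode after
shuffling the labels across the pooled trial set — trial-to-subject
assignment, and hence the fold structure, stays fixed — giving an
empirical null accuracy distribution per time point.
`significant_mask()` then flags time points where the observed accuracy
exceeds the 99th percentile of its null (pointwise p < 0.01, empirical
order statistic with linear interpolation) **and** exceeds an absolute
60 % chance threshold; the two criteria are combined with AND, and each
can be disabled — the calibration analyses below disable the absolute
threshold precisely because it would mask the quantity being calibrated.
Thresholding is pointwise by design; no across-time family-wise
correction is applied, and none is claimed.

`extract_intervals()` converts the mask into maximal runs of consecutive
significant samples, reported as half-open `[start_ms, end_ms)` intervals.
`min_duration_ms` defaults to 0, but at pointwise p = 0.01 over ~550 time
points a handful of 1-sample blips is *expected*; interval-level analyses
in the package's own validation use `min_duration_ms = 20` (5 samples at
250 Hz) to separate sustained decodability from those blips.

The default desk-scale `n_perm` is 500; the percentile estimate at
p = 0.01 needs a few hundred shuffles: the interpolated percentile of an n-draw null is biased low at small n, so rate-calibration analyses use the full 500 (the suite warns below 100). Nothing
prevents running 10^5 permutations — the implementation only loops — but
the calibration properties are measurable at desk scale.

## Channel topography and behavioural statistics

Inside a significant interval, `interval_channel_means()` averages each
subject's trials of each condition, then the samples of the interval —
subject-level means, because the subject is the exchangeable unit.
`topo_difference()` runs a per-channel two-tailed paired t-test of far
vs. near across subjects (`paired_ttest()` implements the hand formula
$t = \bar d / (s_d/\sqrt n)$, df = $n-1$) and reports the signed
far-minus-near map with channels flagged at α = 0.05, uncorrected —
matching the usual starred-topography convention; a Bonferroni option
exists but is off by default. Channels whose differences are identically
zero (possible only in degenerate synthetic data) report t = 0, p = 1
rather than erroring, so the all-zero-difference case remains
well-defined. The same `paired_ttest()` serves the behavioural
reaction-time comparison (`rt_comparison()`).

## Source localization

`eloreta_weights()` implements the scalar (fixed-orientation) eLORETA
weight iteration: with the average-referenced lead field $K$, centering
matrix $H$, and $W = \operatorname{diag}(w_j)$,

$$
w_j \leftarrow \sqrt{\mathbf{k}_j^\top
  \left(K W^{-1} K^\top + \alpha H\right)^{+} \mathbf{k}_j},
$$

iterated from $w = 1$ until the maximal relative change is below `tol`
(1e−6), then the inverse mapping
$W^{-1} K^\top (K W^{-1} K^\top + \alpha H)^{+}$. This family's defining
property — exact localization of noiseless point sources — is preserved by
the scalar formulation and verified exhaustively in the tests; free
3-D source orientations on an anatomical grid would not add anything to
that property at toy scale and are out of scope, as is anatomical
labelling of sources.

Numerical choices: the pseudo-inverse is an eigen-decomposition with
relative tolerance 1e−12 (the matrix is rank-deficient by one on the
average-reference subspace, by construction); the default
$\alpha = 10^{-4} \times$ mean eigenvalue of $KK^\top$ suits near-noiseless
topographies. For *noisy* grand averages a substantially larger α
(≈$10^{-1} \times$ mean eigenvalue) is appropriate — weighted minimum-norm
solutions amplify channel noise into deep, low-gain sources, and
regularization is the instrument that controls it; the package's own
validation uses exactly that for condition differences on simulated data.
`apply_inverse()` centers non-centered topographies with a warning, and
`condition_difference_sources()` differences the two condition estimates —
by linearity identical to localizing the difference topography.

## Calibration and recovery at desk scale

The package's validation suite measures, among others:

- **Chance-level calibration**: a zero-effect study (8 subjects × 40
  trials/condition, 16 channels) decodes at 50 % on average across the
  550-point analysis window (tolerance ±2 percentage points).
- **Type-I calibration**: on the same null data the percentile criterion
  alone flags at most the nominal 1 % of time points plus a one-sided
  binomial 95 % margin (500 permutations — the interpolated 99th percentile of a small empirical null undercovers, so the upper end of the desk range is used for rate estimation).
- **Effect recovery**: with the default two-window configuration at
  ±10 µV (a single pilot power analysis showed ±5 µV sits at the
  detection threshold at this reduced scale — 6 subjects × 24
  trials/condition), the detected intervals overlap both ground-truth
  windows, nothing disjoint is detected, and the channel-level difference
  signs match the injected signs, in at least 9 of 10 seeded runs.

These problem sizes are the package's chosen desk scale: large enough for
stable percentile and accuracy estimates, small enough that the full
suite runs in minutes on one core. The same code paths run unchanged at
the emulated design's full scale (30 subjects, 128 channels, 10^5
permutations); only wall-clock time changes.

## Known limitations

- The permutation test is pointwise; sustained-interval inference relies
  on the duration filter, not on cluster-level correction.
- The analytic shrinkage target is $\nu I$; montages with wildly
  heterogeneous channel variances might prefer a diagonal target.
- The toy head model supports property testing, not anatomical inference;
  source estimates are positions in an abstract ball, not brain regions.
- Leave-one-subject-out decoding pools trials across subjects during
  training; strong inter-subject amplitude differences (not simulated)
  would argue for per-subject standardization, which the package does not
  currently perform.

## A minimal run

```{r example, eval = FALSE}
head_model <- build_toy_headmodel(n_channels = 16, n_sources = 8, seed = 1)
cfg <- study_config(n_subjects = 6, n_trials_per_condition = 24,
                    n_channels = 16, artifact_rate = 0,
                    effects = default_effects(head_model, amplitude_uv = 10),
                    seed = 7)
epochs <- simulate_study(cfg, head_model) |> preprocess_study(min_epochs = 20)

acc <- decode_timecourse(epochs, cv = "subject")
null <- permutation_null(epochs, n_perm = 200, seed = 8)
intervals <- significant_mask(acc, null) |>
  extract_intervals(min_duration_ms = 20)

autoplot(acc, intervals = intervals)
topo <- topo_difference(interval_channel_means(epochs, intervals[1, ]))
inv <- eloreta_weights(head_model,
                       alpha = 0.1 * sum(common_average(head_model$gain)^2) /
                         nrow(head_model$gain))
sources <- condition_difference_sources(
  grand_average_topography(epochs, intervals[1, ], "far"),
  grand_average_topography(epochs, intervals[1, ], "near"), inv)
```
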