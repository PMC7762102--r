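---
title: "Complexity analysis of concurrent EEG-fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity analysis of concurrent EEG-fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nvcomplexity` implements an entropy-based analysis of concurrent
EEG and functional near-infrared spectroscopy (fNIRS) recordings made
during working-memory testing (Rey-Osterrieth complex figure copy and
recall, Raven's progressive matrices), aimed at separating early
Alzheimer's disease (AD) patients from healthy controls (HC). Three
families of per-subject, per-phase features are computed:

* **EEG sample entropy** (5 features): SampEn of the global field power
  (GFP) of the Hilbert power envelope in each of five frequency bands
  (delta 1-4, theta 3.5-8.2, alpha 7.4-13, beta 13-30, gamma 26-40 Hz;
  theta and alpha deliberately overlap, each band being filtered
  independently).
* **fNIRS sample entropy** (2 features): SampEn of the averaged
  long-channel oxy- and deoxy-hemoglobin series.
* **Neurovascular coupling (NC) conditional entropy** (10 features):
  H(hemoglobin | HRF-convolved band envelope) for each hemoglobin form
  x each EEG band — the residual entropy of the hemodynamic signal once
  the electrical signal is known. Intact coupling means the hemodynamics
  are predictable from the EEG, i.e. low conditional entropy.

Group inference reproduces the study design: per-group bootstrap
confidence-interval filtering, pooled-variance t-tests with
Benjamini-Hochberg FDR correction and Cohen's d, and a GLM (ordinary
least squares on the 0/1 disease label) classifier per feature family
scored by leave-one-out cross-validation with ROC/AUC analysis and
paired DeLong AUC comparisons.

Because no recordings are deposited with the study, the package ships a
synthetic cohort generator whose forward model realizes exactly the
structure the analysis assumes; every stage is tested against it.

# Models and estimators

## Sample entropy

For a series of length $N$, embedding dimension $m$, delay $\tau$ and
tolerance $r$, templates $X_i = (x_i, x_{i+\tau}, \dots,
x_{i+(m-1)\tau})$ are compared under the Chebyshev distance. With $B$
the number of ordered pairs $i \ne j$ of length-$m$ templates within
$r$ and $A$ the same count at length $m+1$,

$$\mathrm{SampEn} = -\ln(A/B).$$

Both counts run over the same index range $i \le N - m\tau$, the
Richman-Moorman convention: published renderings of the normalizing
denominators are sometimes inconsistent between the two template
levels, and this convention (self-matches excluded, identical index
ranges) is the one the standard implementations follow. The package's
C++ implementation is validated to $10^{-12}$ against a brute-force
enumeration oracle in the test suite. Defaults are $m = 2$,
$r = 0.2\,\mathrm{SD}$, $\tau = 1$; with an SD-relative tolerance the
estimate is invariant under affine rescaling of the input. $A = 0$
(no $m+1$ matches) leaves the logarithm undefined and raises an error
rather than returning an arbitrary value.

## Conditional entropy

$$H(Y \mid X) = -\sum_{x}\sum_{y} p(x, y)\,\ln p(y \mid x)$$

estimated from a joint histogram after per-variable quantile
(equal-mass) discretization, 8 bins per variable by default. Quantile
binning makes the estimate invariant under strictly monotone transforms
of either series and fixes the marginal entropy near $\ln 8$, so
subject-to-subject differences in H(Y|X) reflect the mutual information
between the series rather than amplitude-scale effects. The direction
is fixed: $X$ is the HRF-convolved EEG envelope (predictor), $Y$ the
hemoglobin series (target). A constant predictor gives
$H(Y\mid X) = H(Y)$ exactly; $0 \le H(Y\mid X) \le H(Y)$ always.

## Timescale matching

EEG envelopes live at 250 Hz, hemodynamics at 10.42 Hz and ~0.1 Hz
effective bandwidth. Each band's GFP envelope is convolved with a
canonical double-gamma hemodynamic response (peak at 6 s, undershoot at
16 s, ratio 6, 32 s support, peak-normalized; the gamma shape is
parameterized so the nominal delay is the kernel mode). The convolved
series is low-passed at $0.4 \times$ the target rate (4th-order
zero-phase Butterworth) and linearly interpolated onto the fNIRS time
grid. A polyphase resampler at the exact rational ratio 521/12500 would
need thousands of phases for the same anti-aliased result; the
filter-plus-interpolation route is numerically equivalent here because
the convolved signal has no content near the target Nyquist. The first
32 s (one kernel length) of the convolved series are discarded as
start-up transient, and the hemoglobin series is aligned to the same
wall-clock start.

The convolution is applied per band rather than once to the broadband
GFP: the coupling features are defined per band, and the band envelope
is the activity proxy entering each pair.

## fNIRS conversion chain

Intensities $\to$ optical densities $\mathrm{OD} = -\ln(I/\bar I)$
$\to$ wavelet despiking $\to$ 0.01-0.4 Hz band-pass $\to$ modified
Beer-Lambert law $\to$ short-channel scalp regression $\to$
long-channel average.

* **Despiking**: 4-level periodized Daubechies-5 transform; detail
  coefficients outside the central $1-\alpha$ mass of a per-level
  Gaussian fit are zeroed ($\alpha = 0.1$). Traces are extended
  antisymmetrically (point reflection, continuous value and slope) by
  twice the coarsest-level filter footprint so that joint artifacts at
  the boundaries stay out of the retained region; a clean smooth signal
  passes through essentially unchanged while an isolated spike loses
  over 90% of its amplitude.
* **Band-pass**: the 4th-order Butterworth band-pass is realized as
  cascaded high-pass and low-pass sections. At a 10.42 Hz rate the
  0.01 Hz edge puts the band-pass poles so close to the unit circle
  that a single direct-form recursion loses several digits; the
  cascade is well-conditioned and, with edges 1.5 decades apart, has
  the same response. Zero-phase filtering uses forward-backward passes
  with odd-reflection padding.
* **Beer-Lambert**: per channel,
  $(\Delta O_2Hb, \Delta HHb)^T = d^{-1} M^{-1}
  (\Delta OD_{\lambda_1}, \Delta OD_{\lambda_2})^T$ with
  $M_{ij} = \varepsilon_j(\lambda_i)\,\mathrm{DPF}(\lambda_i, a)$,
  $d$ the source-detector distance in mm and concentrations in uM.
  Extinction coefficients (690/830 nm, Prahl/Cope compilation) ship as
  a plain-text table in base-10 molar units and are converted to
  natural-log-basis uM^-1 mm^-1. The differential pathlength factor
  uses the general age/wavelength equation
  $\mathrm{DPF} = \alpha + \beta a^{\gamma} + \delta\lambda^3 +
  \epsilon\lambda^2 + \zeta\lambda$, coefficients overridable through
  `chromophore_constants()`. Because optical densities are referenced
  to their own mean, absolute concentration baselines are arbitrary:
  round-trip identities are stated (and tested, to $10^{-10}$) on
  mean-centered series.
* **Scalp regression**: the first principal component of the
  short-channel traces defines the global scalp-hemodynamic model; each
  long channel's least-squares loading on it is subtracted, per
  chromophore. Applied after the Beer-Lambert step (the cited method
  operates on hemoglobin series; the alternative OD-domain ordering is
  algebraically close since both steps are linear).

## Stationarity gate

Before any entropy estimate, each series passes a Phillips-Perron
unit-root test at $\alpha = 0.05$; non-rejections are linearly
detrended and retested, and series still failing are marked invalid (the
feature is excluded, not zeroed). Two practical points:

* The hemodynamic-scale series (0.01-0.4 Hz content at 10.42 Hz) are
  ~25x oversampled relative to their bandwidth, and such series mimic a
  unit root at the native rate regardless of their true dynamics. The
  unit-root statistic is therefore evaluated on a copy subsampled to
  ~1.5 Hz (still nearly 4x the band edge, so no aliasing); detrending
  decisions apply to the full-rate series. EEG envelopes at 25 Hz (or
  12.5 Hz) carry broadband content and are tested unsubsampled.
* R's Phillips-Perron regression includes a linear trend, so a ramp
  plus noise is judged trend-stationary directly; since the entropy
  estimators need the level series, a clearly significant linear slope
  (at $\alpha/5$, strict because OLS slope p-values are
  anti-conservative under autocorrelation) also triggers detrending.
* The EEG-side verdict is made on the band envelope itself and then
  carried to its HRF-convolved copy: convolution with a fixed kernel is
  deterministic smoothing and does not change whether the underlying
  process is stationary, while testing the heavily smoothed copy
  directly would mostly measure the kernel, not the data.

## Epoch handling

Phases are sliced half-open in time; epochs across subjects and phases
are cut to the common shortest duration (complexity estimates are
length-sensitive). One second is trimmed at each epoch edge after the
Hilbert transform (analytic-signal edge transients). EEG envelopes may
be decimated (anti-aliased, default to 25 Hz) before SampEn to keep the
O(N^2) template search tractable; the decimation target is a config
knob and is recorded with the run.

## Group inference

* **CI filter**: percentile bootstrap (1000 resamples) of each group's
  value distribution per metric; subject values outside the mean
  [2.5, 97.5] percentile bounds are excluded for the descriptive
  statistics. Filtering is per metric and per group (degrees of freedom
  then vary per metric, as in the study's tables), and is *not* applied
  to the classifier inputs.
* **t-tests**: two-sample pooled-variance (Student) tests, AD minus HC;
  BH-FDR within each phase's 17 metrics; Cohen's d on the pooled SD.
* **Classifier**: OLS of the 0/1 label on one family's features with
  intercept (the GLM of the study); out-of-sample scores by
  leave-one-out; rank-deficient designs fall back to the
  pseudo-inverse. The families are kept separate (5 + 2 + 10) because
  17 features would match the AD group size and overfit.
* **ROC**: threshold sweep for the curve; AUC by the Mann-Whitney
  midrank formulation, which equals the sweep's trapezoidal area to
  machine precision (a tested invariant). Operating thresholds are
  inputs; a Youden-optimal helper exists but is explicitly an
  optimizer, not a default. Paired AUC comparison uses DeLong's test.

# The synthetic cohort generator

The generator is a first-class, tested module that realizes the
generative structure the analysis assumes:

* **EEG**: per band, a shared band-limited Gaussian source (spectral
  synthesis with raised-cosine edges) with random per-channel gains
  (0.5-1.5), plus per-channel narrowband noise (relative amplitude 0.3)
  and 1/f broadband noise. Default band amplitudes (delta 8, theta 6,
  alpha 10, beta 4, gamma 2 a.u.) follow the usual resting power
  ordering. All shared sources are multiplied by a common slow
  amplitude modulation (0.02-0.2 Hz, depth 0.5): task engagement
  modulates broadband power coherently, and this co-modulation is what
  makes each band's envelope informative about the common hemodynamic
  drive. Without it, five independent band sources would each carry
  only a fraction of the drive and per-band coupling features would be
  diluted by construction.
* **Neurovascular coupling**: the latent drive is the Hilbert envelope
  of the summed band sources, low-passed at 0.5 Hz, convolved with the
  same canonical HRF, standardized, scaled by the group's coupling gain
  (HC 1.0, AD 0.3 by default — impaired coupling in disease) and by
  0.4 uM, and injected into long channels only as dO2Hb with
  dHHb = -0.3 dO2Hb (functional hyperemia polarity; the ratio keeps
  both hemoglobin features informative).
* **Scalp physiology**: Mayer (~0.1 Hz, 0.25 uM), respiratory
  (~0.3 Hz, 0.12 uM) and cardiac (~1 Hz, 0.2 uM) oscillations, one
  global waveform entering every optical channel with per-channel
  gains 0.5-1.5 — the structure the short-channel regression assumes.
* **Cortical vasomotion**: 0.05-0.15 Hz narrowband, 0.5 uM,
  half-global/half-local across long channels. This term matters: an
  HRF-convolved drive is almost entirely below 0.07 Hz, and a signal
  that slow looks like a unit root over a 4-minute epoch. Real cortical
  hemodynamics always carry spontaneous in-band oscillations on top of
  the task-coupled response (task-evoked content is a minority of
  single-channel fNIRS variance), and with them the stationarity gate
  behaves as designed.
* **Optics**: concentrations map to two-wavelength optical densities
  through the same Beer-Lambert matrix the analysis inverts
  (d = 35 mm long / 15 mm short), then to intensities
  $I = I_0 e^{-\mathrm{OD}}$ with random per-channel baselines;
  optional Poisson-timed motion spikes are added to the ODs. With all
  nuisance terms disabled the generator composed with the preprocessing
  chain is the identity on (mean-centered) concentrations to machine
  precision.
* **Cohort**: 17 AD + 18 HC by default; ages normal with means
  67.6/69.2 and SDs 9.3/9.1 years (AD/HC), truncated to [50, 90] — the
  DPF depends on age, so ages must be realistic. Per-subject seeds
  derive deterministically from the master seed; the same configuration
  reproduces the cohort bit for bit.

What the generator does **not** emulate: realistic head-geometry photon
transport, ocular/muscular/cardiac EEG artifacts (the ICA cleaning
stage of real pipelines is out of scope and the synthetic data are
generated artifact-free), frequency-domain NIRS observables, and any
spatial topography beyond channel gains. Passing tests therefore
validate the estimators and the pipeline plumbing, not claims about
real patient data.

# Problem sizes and numerical choices

Default phases last 240 s each, matching the ~4 min analyzed epochs of
the study design; at 240 s the stationarity gate has adequate power,
while much shorter epochs genuinely cannot support a unit-root test of
a 0.01 Hz high-passed signal (this is a property of the method, not of
the implementation).

The end-to-end recovery checks (acceptance suite and
`scripts/acceptance.R`) run 20 cohort seeds per condition with
17 + 18 subjects, one 240 s phase, 2 EEG channels, 3 long + 2 short
optical channels, and envelopes decimated to 12.5 Hz: a design chosen
so forty full cohort pipelines complete on one CPU in minutes while
keeping the study's group sizes and epoch length. The full default
configuration (16 EEG channels, 16 + 4 optical channels, three phases)
runs through `run_all()` in a few minutes per cohort.

Other numerical choices: filters are designed with `signal::butter` and
applied forward-backward through a compiled IIR routine with
odd-reflection padding; ties in quantile binning collapse bins (a
constant series occupies one bin); the LOOCV design matrix falls back
to an SVD pseudo-inverse below numerical rank; DeLong comparisons of a
result with itself return z = 0, p = 1 by convention.

# Known limitations

* Conditional entropy from an 8 x 8 histogram at ~2000 samples carries
  a plugin bias of order 0.01 nats; it cancels in group comparisons
  (all subjects share the discretization) but absolute values should
  not be over-interpreted.
* The bootstrap CI filter trims each group's tails before the t-tests,
  which shrinks the group SDs and makes the test mildly
  anticonservative: on null cohorts, BH-FDR alone leaves ~90-95% of
  cohorts without any significant metric, while the filtered pipeline
  leaves ~65-85% (seed-dependent). The acceptance script reports both
  fractions. This is a property of the filtering-then-testing design
  itself, and one reason the filter is not applied to classifier
  inputs.
* The LOOCV-OLS null distribution of the AUC is left-shifted below 0.5
  for feature counts approaching the sample size (leaving a subject
  out moves the training labels away from it, anti-correlating null
  scores with labels). The effect is inherent to the published design,
  strongest for the 10-feature NC family at n = 35, and visible in the
  package's own null calibration runs.
* EDF serialization quantizes to 16 bits over the per-channel range;
  optical recordings use a plain-text CSV + JSON container mirroring
  the continuous-wave SNIRF structure.
* The Phillips-Perron subsampling rate (1.5 Hz) is a pragmatic
  bandwidth-matching choice; any value between ~1 and ~3 Hz behaves
  equivalently for 0.4 Hz-limited signals.
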