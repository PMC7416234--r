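---
title: "Channel and feature selection for motor-imagery BCI with multilevel binary PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel and feature selection for motor-imagery BCI with multilevel binary PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipso)
```

## The problem

A two-class motor-imagery brain-computer interface records multichannel
brain activity (here modelled on an 8 x 8 ECoG grid: 64 channels, 3-s
trials) while a subject imagines one of two movements, and must decide the
imagined class from a single trial. Two practical obstacles dominate:
channels unrelated to the task add noise dimensions, and even on relevant
channels most spectral features are uninformative. Both inflate test-time
cost and can depress accuracy. `mipso` implements a complete
selection-classification pipeline for this setting:

1. **Features** — modified Stockwell-transform (MST) power spectral
   density, one feature per (channel, integer frequency) pair on a 1–35 Hz
   grid;
2. **Classifier** — Bayesian linear discriminant analysis (BLDA) with
   evidence-maximised regularisation;
3. **Selection** — multilevel binary particle swarm optimization (MLPSO)
   wrapped around the classifier, at channel granularity, feature
   granularity, or channels first and then features.

## The modified Stockwell transform

The S-transform of a signal $x(t)$ is

$$S(\tau, f) = \int x(t)\, g(\tau - t, f)\, e^{-i 2 \pi f t}\, dt,$$

with a unit-area Gaussian window $g$ whose standard deviation shrinks with
frequency, $\sigma(f) = 1/f$. The modified transform generalises the window
to $\sigma'(f) = p / f^{q}$: with $p < 1$ the window is narrower in time,
concentrating energy for transient oscillations at the cost of frequency
resolution. Defaults are $p = 0.85$, $q = 1$ — the setting at which the
downstream classifier performed best in the motivating study — and the
grid is 1–35 Hz in 1-Hz steps, covering the mu and beta rhythms that
motor imagery modulates.

Numerical conventions:

* The transform is computed with the standard frequency-domain algorithm
  (FFT of the signal, spectral shift per voice, multiplication by the
  Gaussian's transform, inverse FFT), $O(N \log N)$ per frequency. Because
  it is built on the DFT, the signal — and hence the analysis window — is
  treated as periodic over the trial. The test suite checks this fast path
  against a direct double-loop discretization of the analysis integral
  with a periodized window, to $10^{-6}$ relative error.
* The $f = 0$ voice is never computed: it is simply the signal mean and
  lies outside the analysis band, which starts at 1 Hz.
* The PSD feature is the time-averaged squared magnitude of the voice,
  $\mathrm{feature}(c, f) = \frac{1}{N}\sum_\tau |S_c(\tau, f)|^2$. The
  mean (rather than the sum) makes features invariant to trial length. By
  Parseval's identity this equals $\frac{1}{N^2}\sum_m |Y_m G_m|^2$ in the
  frequency domain, so extraction needs one FFT per channel-signal; the
  identity is verified against the full map in the tests.
* No window is applied to trial edges; the wrap-around convention above
  is the edge treatment.
* Downsampling (1000 Hz recordings are analysed at 100 Hz) low-pass
  filters with a zero-phase order-4 Butterworth at 0.8 x the target
  Nyquist before decimating, so trial-locked latencies are not shifted.

## The Bayesian linear discriminant

Classification is regression onto the $\pm 1$ labels under a Gaussian
likelihood with noise precision $\beta$ and an isotropic zero-mean Gaussian
prior with precision $\alpha$ on the weights (the bias is unpenalised).
Both hyperparameters are set by fixed-point maximisation of the marginal
likelihood: with the eigenvalues $s_i^2$ of the centred feature Gram
matrix,

$$\gamma = \sum_i \frac{\beta s_i^2}{\beta s_i^2 + \alpha}, \qquad
  \alpha \leftarrow \frac{\gamma}{\lVert w \rVert^2}, \qquad
  \beta \leftarrow \frac{n - 1 - \gamma}{\lVert y - Xw - b \rVert^2},$$

iterated to a relative tolerance of $10^{-6}$ on both hyperparameters
(at most 200 iterations); $\gamma$ is the effective number of
well-determined weights and the $-1$ accounts for the bias. Because
features are column-centred, the optimal bias is exactly the target mean,
and the remaining ridge problem is solved through the eigendecomposition
of the smaller Gram matrix — one decomposition per fit, $O(1)$ per
hyperparameter iteration — which is what makes a classifier fitted tens of
thousands of times inside the wrapper loop affordable.

Predictions threshold the real-valued output at zero, with scores exactly
zero mapped to $+1$. Two documented choices are exposed as options:
features are z-scored from the training split by default (PSD magnitudes
vary by orders of magnitude across frequencies, which otherwise biases
wrapper selection toward high-power bands), and regression targets are the
raw $\pm 1$ labels by default with a `"balanced"` class-size-scaled
alternative.

## Binary PSO and the multilevel scheme

Selection masks are bit vectors: one bit per channel (a set channel
activates its whole 35-frequency block) or per feature column. The swarm
updates velocities with the standard two-attractor rule (inertia weight
decreasing linearly from 0.8 to 0.4, $c_1 = c_2 = 1.5$), clamps them to
$\pm 20$ (boundary absorption), and redraws each bit as 1 with probability
$s(v)$, the logistic sigmoid of its velocity. Defaults ($N = 100$ particles,
$T = 100$ iterations) are the tuned values of the motivating study. One
iteration is synchronous: all velocities from the previous global best,
then all positions, then all fitnesses, then the best-position bookkeeping.
Ties on fitness resolve toward fewer selected coordinates, then the lower
particle index; all-zero masks score $-\infty$ and can never become a best
position. The whole trajectory is a deterministic function of (seed,
configuration, fitness).

The wrapper fitness is the inverse mean squared error of the classifier's
predictions on evaluation data, $1 / (\sum_i (\hat y_i - y_i)^2 +
\varepsilon)$ with $\varepsilon = 10^{-12}$ capping the value at perfect
prediction. Three evaluation-protocol choices were genuinely open and are
configurable:

* **Where the evaluation labels come from.** Scoring masks on the final
  evaluation set itself leaks its labels into the selection. The default
  here is a seeded stratified 25% validation split carved from the
  training set; `fitness_on_holdout = TRUE` scores masks on the supplied
  evaluation set instead, for studies of that leaky-but-common protocol.
* **Thresholded labels vs raw scores.** With thresholded $\pm 1$
  predictions (the default, matching the explicit 0-threshold rule) each
  error contributes 4 to the squared error, so the fitness is discrete and
  saturates once a mask classifies the split perfectly. `use_scores = TRUE`
  uses the raw discriminant outputs instead: a continuous criterion that
  still resolves the marginal value of a coordinate when error counts tie.
* **Single split vs cross-validation.** `n_folds = k` replaces the single
  validation split by pooled squared errors over $k$ seeded stratified
  folds, so each mask is judged on every training trial. This costs $k$
  classifier fits per evaluation but substantially reduces the chance that
  a noise coordinate looks useful on one small split.

The multilevel loop repeats the optimizer: level 1 searches the full
space; level $k+1$ searches only the coordinates level $k$ selected, with
a fresh swarm seeded by `seed + level` (independent initial swarms, but
fully reproducible), on the re-indexed smaller space — so the
swarm-to-dimension ratio improves as the search narrows. The loop stops at
`max_level` or as soon as two consecutive levels select the same *number*
of coordinates (count equality; set equality trivially also stops it).
Restarting is also the escape from stagnation: once a swarm's particles
collapse onto the global best with near-zero velocities, further
iterations of that swarm change little, whereas a fresh swarm on the
reduced space explores again. In the combined scheme, channel selection
runs to termination first, the feature matrix is restricted to the
surviving channels, and feature selection refines within them; the two
phases are reported separately and the final mask is mapped back to the
original column space.

## The synthetic generator

Real competition recordings cannot ship with the package, so every claim
is exercised on synthetic trials with planted ground truth
(`simulate_trials()`, `make_fixture()`). The generator emulates the
phenomenology that band-power features rely on:

* every channel carries $1/f^{\gamma}$ colored noise ($\gamma = 1$ by
  default; the average periodogram slope is recovered within $\pm 0.3$ in
  the tests);
* informative channels add band-limited oscillations (white noise through
  a zero-phase order-4 Butterworth band-pass; mu 8–12 Hz and beta
  18–26 Hz by default) whose expected power is scaled by
  $(1 \pm \mathrm{effect})$ per class, with opposite sign in alternating
  bands;
* the realised oscillatory power of each (trial, channel, band)
  additionally fluctuates with a unit-mean exponential draw
  (`burst_power`, on by default). Single-trial sensorimotor band power is
  notoriously bursty; without this term a single informative channel
  classifies almost perfectly and channel pooling — the phenomenon channel
  selection exists for — never matters.

The default oscillation amplitude (0.05 relative to the unit noise floor)
was chosen once so that an all-feature classifier of the 32-channel study
preset sits in the high-80s/low-90s accuracy range — the operating point
of an unoptimized motor-imagery pipeline — leaving measurable headroom for
selection. The generator writes the same plain-text container the readers
consume, closing the I/O loop in tests.

What the generator does *not* model: electrode-grid spatial correlation,
artifacts, non-stationarity across a session, or real ECoG waveform
morphology. Tests passing on this generator show the pipeline recovers
planted band-power structure; they do not certify performance on real
recordings.

## Problem sizes used in the checks

The packaged checks run three tiers, chosen as the smallest sizes at which
each claim is meaningful: a `"tiny"` fixture (40 trials x 8 channels x
1 s) for unit-level behaviour; the `"selection"` study preset (200 trials
x 32 channels x 3 s, 8 informative channels, effect size 0.8) for
selection-recovery studies, run with reduced swarms (about 30 particles,
25 iterations) that pilot runs showed adequate for spaces of 32–1120
bits; and the `"competition-shape"` preset (278 + 100 trials x 64 channels x
3 s) for geometry-level identities (2240 features per trial).
Optimizer-correctness checks (OneMax, planted-mask recovery) use the full
default swarm. The channel-recovery study uses the cross-validated score
fitness (`use_scores = TRUE`, `n_folds = 4`), the variant with the best
support-recovery behaviour; the improvement-with-shrinkage study runs
under `fitness_on_holdout = TRUE`, the protocol in which the wrapper
fitness is computed on the evaluation set — the improvement it
demonstrates is exactly the quantity that protocol optimizes, selection
bias included, which is why the leak-free split is the package default
for real use.

## Known limitations

* Wrapper selection with a few hundred trials cannot certify that every
  relevant channel is individually necessary: coordinates whose marginal
  contribution is below the resolution of the evaluation criterion may be
  dropped, and noise coordinates that correlate with the labels on the
  evaluation trials may be kept. The cross-validated score fitness
  mitigates but does not eliminate this; it is a property of the
  wrapper paradigm at this sample size, not of the optimizer.
* The discrete label fitness saturates on easy problems; on such problems
  the popcount tie-break, not accuracy, drives the selection toward
  minimal subsets.
* BLDA is linear; no kernel or multiclass extension is provided.
* The S-transform's periodic convention means trial edges wrap; for the
  band of interest (1–35 Hz at 100 Hz sampling) the Gaussian window's
  frequency-domain aliasing is far below the tested tolerances, but very
  low frequencies on very short trials are resolution-limited
  (`extract_features()` rejects trials shorter than one period of
  `f_min`).

## A worked example

```{r example, eval = FALSE}
library(mipso)

fx <- make_fixture("selection", seed = 1)
features <- extract_features(fx$train)
holdout <- extract_features(fx$test)

baseline <- blda(features)
mean(predict(baseline, holdout)$label == holdout$labels)

ml <- channel_selection(
  features, pso_config(n_particles = 30, n_iter = 25, seed = 1),
  max_level = 6, holdout = holdout, use_scores = TRUE, n_folds = 4
)
tidy(ml)
channel_report(ml)
autoplot(ml)
```
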