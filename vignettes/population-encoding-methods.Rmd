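---
title: "Methods: coupled population encoding models and the bump-attractor benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled population encoding models and the bump-attractor benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popglm)
```

## The model

`popglm` characterizes ensembles of simultaneously recorded spike trains
during delayed-response (memory-guided saccade) tasks with a fully coupled
Poisson generalized linear model. Spike trains are discretized into 1 ms
bins. The conditional intensity of neuron $i$ at bin $t$ is

$$\lambda_t = \exp\!\big(k * x_t + h * r_{t-1} + c * s_t + b\big)\big/\Delta,$$

where $x_t$ are task-event covariates (delta functions at target onset and at
a fixed lead before saccade onset), $r_{t-1}$ is the neuron's own spike train
up to but excluding the current bin, $s_t$ are the simultaneously recorded
partner spike trains at lags of at least one bin, and $b$ is a constant
baseline in log spikes per bin. Every temporal filter is parameterized on a
bank of nonlinearly time-scaled raised cosines (`make_raised_cosine_basis()`):
peaks are evenly spaced in $\log(t + \psi)$, so early lags are finely and
late lags coarsely resolved. Task kernels use 8 basis functions over 800 ms;
spike-history and coupling kernels use 10 over 250 ms. Columns are normalized
to a peak of 1, so weights read directly as log-gain amplitudes, and history
and coupling bases are strictly causal: a kernel from neuron $j$ to neuron
$i$ is a directed statement about how $j$'s past spikes multiply $i$'s
current rate.

Weights are estimated by maximum a posteriori inference with a Gaussian
prior on all kernel weights — equivalently, ridge-penalized maximum
likelihood with the penalty
$\lambda_r(\lVert k\rVert^2 + \lVert h\rVert^2 + \lVert c\rVert^2)$ and an
unpenalized baseline. The log-likelihood
$\sum_t r_t \log(\Delta\lambda_t) - \Delta\lambda_t$ is concave in the
weights, so the Newton solver (`fit_neuron()`, implemented in C++) converges
to the unique optimum; convergence is declared when the gradient
infinity-norm drops below $10^{-6}$ of the session's total spike count.
Cross-validation (`crossval_fit()`) partitions *trials*, never time bins, so
within-trial dependence is preserved; the conventional setting is 5 folds
(train on 80%, test on 20%). The ridge strength defaults to 1 — negligible
against the likelihood of a session with $10^5$ or more bins, but enough to
keep rarely observed covariate directions from blowing up. For model
*comparisons* the penalty can instead be selected per unit and per fold by
nested cross-validation on a log-spaced grid
(`crossval_fit(select_ridge = TRUE)`), which is the fair procedure when
models with very different column counts compete.

Model accuracy is reported two ways. Single-trial accuracy is the held-out
log-likelihood relative to a homogeneous mean-rate model, normalized by the
spike count and converted to bits per spike (`bits_per_spike()`; the
mean-rate model scores exactly 0). Trial-averaged accuracy is the variance
explained ($R^2$) of the observed PSTH by the PSTH of spike trains generated
from the fitted model (`simulate_population()` then
`variance_explained_psth()`).

## Coupling statistics

The overall strength of a directed interaction is the sum of the
reconstructed time-domain coupling kernel over its 250 ms support
(`coupling_weight()`); positive sums are excitatory, negative inhibitory. We
sum the time-domain kernel rather than the raw basis weights so the statistic
is invariant to the basis parameterization. The peak multiplicative gain is
`exp(max kernel)` (`coupling_gain()`), exactly 1 for a flat kernel. Pairs are
classed by the directed area pair (LIP-LIP, FEF-FEF, LIP-FEF, FEF-LIP).

Chance levels come from a permutation null (`permutation_null()`): for each
fitted neuron, every predictor neuron's trial order is independently
permuted and the model refit. This destroys trial-by-trial noise
correlations while leaving each spike train's own within-trial structure and
the fitted neuron's task alignment untouched. The reported exceedance
statistic is the fraction of real coupling weights above the null mean plus
two null SDs, one-sided per interaction class (`significant_fraction()`; a
two-sided variant is available). One property of this null is worth knowing:
it is exactly calibrated only when trials are exchangeable. When task-event
times are jittered across trials, the real fit's coupling columns are
partially collinear with task-locked partner activity while the permuted
refits are not, which inflates the real weights' sampling variance relative
to the null and makes the test mildly anticonservative (we measure one-sided
exceedance of roughly 0.05–0.08 instead of the nominal 0.023 on independent
data with jittered timing, and 0.01–0.03 with fixed timing). The package's
calibration studies therefore use `make_trials(fixed_timing = TRUE)`;
jittered-timing exceedances should be read against a simulated, not a
Gaussian, reference.

Kernel summaries follow standard practice: PCA of the mean-centered kernels
per interaction class (`pca_kernels()`, component signs fixed to a positive
integral); double-exponential time constants
$a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$ by Levenberg–Marquardt least squares
with a small multi-start grid (`fit_time_constant()`), reporting the $\tau$
of the larger positive-amplitude component. Kernels dominated by a
refractory trough (most negative value in the first 5 ms exceeding the
positive peak) or poorly fit by exponential decay ($R^2 < 0.5$, a
calibratable threshold) are excluded with a reason rather than given a
meaningless $\tau$. Predictive indices (`compute_predictive_indices()`)
compare held-out deviance explained between the full model and reduced
models without coupling or without history:
$(d_{full} - d_{reduced})/d_{full}$, clipped to $[0,1]$. Epoch-restricted
fits (`fit_epoch_models()`) refit the model with the likelihood confined to
matched-length windows (e.g. fixation vs delay, early vs late delay) and
compare weights pair by pair. Spatial-tuning relationships use 1D circular
Gaussian tuning fits (`fit_tuning_curve()`) and bin pairs by the distance
between preferred angles (`coupling_vs_tuning()`).

## The synthetic-data generators

Two generators provide ground truth. They are first-class, tested code — all
package benchmarks are built from them at run time.

**Ground-truth GLM sessions** (`make_ground_truth_population()`,
`simulate_population()`, wrapped by `simulate_glm_session()`). Trials emulate
the memory-guided saccade task: in the `"task"` style the target is flashed
for 200 ms after a 1–1.5 s fixation, the delay is uniform on 0.5–2 s, and
the saccade follows the go signal by 0.15–0.3 s; the `"compact"` style
compresses this into 1 s trials (all event times still jittered, which keeps
the target and saccade kernels mutually identifiable) for studies where
total bin count dominates runtime. Target eccentricity is Gaussian (mean
10°, SD 5°, truncated at 1°) with x/y jitter in the visual field, and
IN\_RF/OUT\_RF is assigned by hemifield sign. Kernels are drawn from a
parameterized library (`kernel_library()`) — transient-plus-sustained visual
responses, peri-saccadic bumps, refractory-plus-slow history, exponentially
decaying coupling — and projected onto the model bases so the truth lies
exactly in the model class. Baselines get a stationarity correction
(expected recurrent log drive at nominal rates is subtracted) so realized
rates land near nominal despite the recurrent terms.

Two generator safeguards matter with an exponential link. First, each unit's
total incoming excitatory coupling gain, $\sum_i r_i \Delta \sum_t
[c_{ij}]_+$ at nominal rates, is capped (default 0.5) by scaling; recurrent
excitation is explosive once this loop gain approaches 1, and the cap makes
every random draw simulable. Second, the sequential simulator aborts with a
diagnostic if any per-bin mean exceeds a cap (default 20 per 1 ms bin),
which also guards against simulating from unstable *fitted* models. Default
coupling amplitudes (peak log-gain 0.12–0.3 within area, 0.06–0.15 between,
25% inhibitory) encode the stronger-local-than-long-range motif at
magnitudes that keep 5–20 unit ensembles stable.

What these sessions do *not* emulate: non-Poisson dispersion, electrode
artifacts, unit drift or sorting errors, slow latent network states beyond
what history+coupling induce, and omitted common input. Passing recovery
tests on them shows the estimator is correct and well-calibrated *within the
model class*, not that real recordings satisfy the model.

**The ring bump-attractor network** (`attractor_params()`,
`build_network()`, `simulate_attractor_session()`, `sweep_jpos()`). A
classic conductance-based spiking model of spatial working memory:
excitatory LIF neurons on a ring (full size 1024, inhibitory pool 256) with
recurrent excitation through NMDA-type synapses (decay 65 ms, rise gated by
a 2 ms x-variable, voltage-dependent magnesium block), uniform GABA-type
inhibition, and 1000 external Poisson sources per neuron at 1.3 Hz through
AMPA-type synapses. The E→E profile is
$w(\Delta\theta) = J^- + (J^+ - J^-)\exp(-\Delta\theta^2/2\sigma^2)$ with
$\sigma = 20°$ and $J^-$ fixed by the normalization that the mean connection
weight is 1 (infeasible $(J^+,\sigma)$ combinations raise an error). Each
trial lasts 1 s; a 0.2 s, 0.06 nA current is injected into a 30° arc at a
uniformly random center with onset jittered 0.2–0.5 s. Voltages are
integrated at 0.1 ms with an exponential-Euler update (synaptic conductances
and the magnesium gate frozen across each step); forward Euler is unstable
here because the synaptic conductances transiently drive the effective
membrane time constant far below the step.

The published description of this model fixes the population sizes, drive,
ring profile, stimulus protocol and the NMDA time constant but not every
synaptic conductance; the defaults here (`ext2e` 2.2, `ext2i` 0.6, `e2e`
0.381, `e2i` 0.6, `i2e` 0.4, `i2i` 0.2 nS, the recurrent four multiplied by
`weight_scaling`) were calibrated once, on the desk-scale network, to the
model's documented operating regime: a stable spontaneous state near 2 Hz, a
stimulus-triggered *soft* bump (tens of Hz, not refractory-saturated), no
persistence at $J^+ \le 1.3$, graded persistence onset near 1.9 and full
persistence at 2.2. A high-gain inhibitory population (weak I→I, strong E→I)
turned out to be essential: with sluggish interneurons the bump is bistable
between silent and refractory-saturated, and a saturated bump is so regular
that measured coupling *falls* at high recurrent strength. All conductances
remain config-exposed.

The desk-scale variant (`scaled = TRUE`: 256 E / 64 I) multiplies
`weight_scaling` by the size ratio, preserving mean recurrent input, and
additionally scales the per-neuron stimulus current by 3: finite-size
fluctuations in the bump mode are about twice as large as at full size, and
without the stronger stimulus the bump's location is no longer reliably
selected by the stimulus. Sessions export a fixed random ensemble (default
20 units) drawn from a 40° arc of the ring — like a real recording, the
sampled units share a receptive-field constellation, which is what makes the
IN\_RF/OUT\_RF condition split meaningful and lets the task kernels absorb
the per-trial stimulus-location variance. Persistence is read out by a
population vector over the excitatory population: a trial counts as
sustained when the resultant amplitude exceeds 0.2 over the final 200 ms
*and* the readout angle lies within the stimulus arc width of the stimulus —
an operationalization; both numbers are arguments.

`sweep_jpos()` ties the two halves together: one session per recurrent
strength, the population GLM fit to each exported ensemble exactly as for
recorded data, and the mean estimated coupling weight tracked against
$J^+$ together with the sustained-bump fraction. On the desk-scale defaults
the mean coupling rises monotonically across $J^+ \in \{1.0, 1.3, 1.6, 1.9,
2.2\}$ (Spearman $\rho \ge 0.9$ across master seeds) while the sustained
fraction switches from ~0 to ~1, so estimated coupling acts as a proxy for
recurrent connection strength. One caveat: because coupling kernels act on
the log-rate per partner *spike*, a regime where bump firing rates grow
steeply with $J^+$ compresses per-spike gains and can flatten or bend the
top of this curve; the calibrated defaults keep bump rates moderate for
exactly this reason.

## Numerical and design choices

* Bins are half-open $[t, t+\Delta)$, 0-based, times relative to trial
  start; trials keep ragged lengths (no padding bins enter likelihoods).
* Gaussian PSTH smoothing (default SD 30 ms) uses reflection padding, so
  edge rates are not suppressed; smoothing preserves the mean up to edge
  effects, and SD 0 is the exact trial-averaged rate.
* The saccade kernel's event delta is shifted 400 ms before saccade onset
  (configurable), so the 800 ms kernel covers −400..+400 ms around the
  movement; task kernels are split by IN\_RF/OUT\_RF and fitted jointly in
  one model (configurable off).
* Convolutions are FFT-based per trial and never cross trial boundaries;
  history/coupling columns are zero over each trial's first lags.
* The design matrix is dense; the Newton step solves against
  $X^\top \mathrm{diag}(\mu) X + 2\lambda_r I$ by Cholesky with step
  halving, warm starts chain across folds, permutations and ridge grids.
* Sequential simulation draws per-bin Poisson counts and pushes each spike's
  history/coupling kernels into the future drive; spikes are placed
  deterministically inside their bin (strictly sorted, stable under
  microsecond rounding in the text container).
* The on-disk session container is a directory with `session.json` and
  `spikes.csv` (microsecond-precision times); write→read is lossless to
  1e-6 s and re-binned counts are identical.
* Seeds: every exported stochastic operation takes a seed, restores the
  caller's RNG state, and derives stage seeds deterministically; identical
  seeds give identical sessions, fits and artifact files.

## Problem sizes used by the shipped studies

The test-suite and acceptance studies run, per design, at desk scale:
recovery on 10 units × 300 one-second trials; coupling detection on 8 units
× 160 trials with 20 permutations; calibration on 20 independent 4-unit,
50-trial sessions (fixed timing) with 20 permutations each; model comparison
on 12 units across two 120-trial sessions under 5-fold CV; PSTH
self-consistency on 6 units × 200 variable-delay trials; and the attractor
sweep on the 256-neuron network, 100 trials and 10 sampled units per
recurrent strength. These sizes were chosen so each study's sampling error
is small relative to the effect it measures.

## Known limitations

* With the exponential link, generative (free-running) simulation of fitted
  models inflates rates convexly in parameter error; at very small sample
  sizes predicted PSTH levels can drift above observed ones.
* The permutation null's mild anticonservativeness under event-time jitter
  (above) is a property of trial permutation itself, not of this
  implementation.
* The attractor network is a single-module ring; no two-area variants, no
  parameter fitting of the network to data, and the full-size (1024-neuron)
  network is markedly slower than the desk-scale default because the ring
  weight matrix is applied densely every 0.1 ms.
* Time-constant fits summarize kernels, not biophysics: a history kernel's
  $\tau$ is an extracellular, model-conditional statement.
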