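# popglm

Coupled Poisson population encoding models for simultaneously recorded
spike trains.

During delayed oculomotor response tasks, neurons in the frontoparietal
network (areas LIP and FEF) keep firing through the memory delay. Whether
that persistent activity is maintained by recurrent network interactions or
by single-neuron dynamics is a circuit-level question, and answering it from
data requires separating, on single trials, the influence of (i) task events,
(ii) a neuron's own spike history and (iii) the spiking of the other
simultaneously recorded neurons. `popglm` implements the standard tool for
this: a fully coupled Poisson GLM over 1 ms bins,

```
lambda_t = exp( k * x_t  +  h * r_{t-1}  +  c * s_t  +  b ) / dt
```

with task kernels `k` (raised-cosine basis, 8 functions / 800 ms), a
spike-history kernel `h` and one directed coupling kernel per partner neuron
`c` (10 functions / 250 ms, strictly causal), fit by ridge-penalized MAP with
trial-wise 5-fold cross-validation. On top of the fits it provides the
associated population analyses:

- coupling weights (summed time-domain kernels) and peak gains, by directed
  area interaction (LIP-LIP, FEF-FEF, LIP-FEF, FEF-LIP);
- permutation nulls (trial-order shuffles of the predictor neurons, refit) and
  one-sided 2-SD exceedance fractions;
- PCA of kernel shapes, double-exponential time constants with a
  refractory-dominance exclusion rule, coupling/history predictive indices,
  epoch-restricted fits (fixation vs delay, early vs late), and
  coupling-vs-spatial-tuning relationships;
- synthetic ground-truth generators (task-emulating trials, configurable
  kernel libraries) for recovery and calibration studies;
- a ring bump-attractor spiking network (conductance-based LIF, NMDA
  recurrence, desk-scale 256-neuron variant) whose sampled spike trains feed
  the same pipeline, relating estimated coupling to the network's recurrent
  connection strength `J+`.

For whom: systems/computational neuroscientists analysing multi-electrode
recordings from behaving animals, and modellers who want a calibrated bridge
between spiking network models and functional-connectivity estimates.

## Worked example

```r
library(popglm)

# a coupled synthetic session with known ground truth: 6 units, 200 trials
sim <- simulate_glm_session(6, 200, seed = 42)
sim$session
#> spike_session: 6 units (FEF/LIP), 200 trials, 29208 spikes

binned <- bin_spikes(sim$session)            # 1 ms bins, ragged trials
fit <- crossval_fit(binned, sim$truth$spec, k_folds = 5, seed = 1)
mean(fit$cv$bits_per_spike)
#> [1] 0.2881691

head(coupling_table(fit), 3)
#>   from  to interaction     weight     gain
#> 1  u02 u01     LIP-LIP -3.8080451 1.116543
#> 2  u03 u01     LIP-LIP  1.7270120 1.115291
#> 3  u04 u01     FEF-LIP -0.9430957 1.118730

# chance levels by trial-permutation refits
cache <- design_cache(binned, sim$truth$spec)
null <- permutation_null(cache, n_perm = 20, seed = 2, init = fit$fits)
significant_fraction(coupling_table(fit), null)
#>   interaction n_pairs  null_mean   null_sd  fraction
#> 1     LIP-LIP       6 -0.1884875 1.9313449 0.0000000
#> 2     FEF-LIP       9 -0.2143182 1.1573944 0.3333333
#> 3     LIP-FEF       9  0.5109680 1.5903575 0.2222222
#> 4     FEF-FEF       6  0.1154879 0.9874004 0.8333333
```

`mean(fit$cv$bits_per_spike)` is the cross-validated single-trial prediction
accuracy relative to a mean-rate model (0.29 bits per spike here). In the
coupling table, `weight` is the summed log-gain of the directed kernel
(positive = excitatory: u03's spikes make u01 more likely to spike over the
next ~250 ms; negative = suppressive) and `gain` its peak rate multiplier.
The one-sided 2-SD exceedance fractions vary by interaction class with the
truly coupled pairs this particular session happens to contain (0 of the 6
LIP-LIP pairs, 5 of the 6 FEF-FEF pairs), all to be read against the ~0.023
expected by chance alone.

The attractor benchmark runs the same pipeline on network-model data:

```r
sw <- sweep_jpos(c(1.0, 1.3, 1.6, 1.9, 2.2),
                 params = attractor_params(scaled = TRUE),
                 n_trials = 100, n_sampled = 10, seed = 1)
sw$summary
#>   j_pos mean_coupling sustained_fraction
#> 1   1.0     -9.305502               0.00
#> 2   1.3     -2.271780               0.01
#> 3   1.6      2.194936               0.04
#> 4   1.9      4.731697               0.45
#> 5   2.2      3.984045               1.00
```

Estimated coupling rises with the network's recurrent strength while the
sustained-bump fraction switches from ~0 to ~1 — GLM coupling acts as a proxy
for recurrent connectivity. (All numbers above were produced by exactly these
calls at the given seeds.)

An end-to-end run (data, fits, nulls, summaries, report) is one call:

```r
run_pipeline(list(
  data = list(source = "synth-glm", n_units = 6, n_trials = 200),
  analysis = list(n_perm = 20, k_folds = 5),
  out_dir = "artifacts/run1", seed = 42))
```

or from a shell via the thin CLI wrapper
(`Rscript inst/cli/popglm-cli.R run --config cfg.yaml`). The methods vignette
(`vignettes/population-encoding-methods.Rmd`) documents the model,
estimation, null calibration, generators and their limitations.

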