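# cfareact

Analysis pipeline for chronic central-amygdala (CEA) population recordings
during conditioned flavour aversion (CFA) learning — the setting in which a
novel flavour consumed during a meal is followed, after a ~30-min delay in
a different context, by visceral malaise (optogenetic CGRP-neuron
stimulation in 3-s bouts, or LiCl injection). The scientific question the
pipeline addresses: are the CEA neurons that encoded the flavour during
consumption *reactivated* by the delayed malaise signal, and does the
amount of reactivation a neuron receives predict how much its flavour
response is stabilized at memory retrieval the next day?

The package is aimed at systems neuroscientists who want the full analysis
chain as tested, reusable functions, plus a synthetic-session generator
with ground truth so every stage can be validated as a parameter-recovery
exercise without any recorded data.

## What it computes

* **Selectivity** — per-neuron classification as flavour-preferring,
  water-preferring or nonselective from 10-s post-reward responses, using a
  Wilcoxon rank-sum test (midranks, tie-corrected normal approximation with
  continuity correction) under a 5% FDR across all neurons with the
  two-stage Benjamini–Krieger–Yekutieli step-up procedure.
* **PETHs** — reward-delivery PETHs (−5 to +10 s), stimulation-bout PETHs
  (−1 to +4 s, pre-bout baseline subtracted), whole-experiment and
  event-locked minute-resolution traces normalized by final-20-min delay
  statistics, and the scalar CGRP/LiCl responses derived from them.
* **Decoding** — a three-class (flavour / water / baseline) multinomial
  logistic decoder trained on 1-s consumption-period spike counts with
  Lasso regularization, minimizing
  `total NLL + λ Σ|W|` (λ = 1 default; intercepts unpenalized) by monotone
  accelerated proximal gradient descent, then evaluated in a 1-s window
  sliding by 150 ms across the delay and malaise periods. Reactivation
  events are strict local maxima of a class posterior above 0.5, counted
  in 1-min windows stepped by 30 s.
* **Trajectories** — PCA on baseline-subtracted, peak-normalized
  trial-averaged PETHs of reward-selective neurons (neurons × 1,000 time
  bins; per-time-bin centring, loadings in neuron space), projection of
  consumption and stimulation activity into PC1–PC2, and cross-day
  projection through frozen day-1 loadings.
* **Plasticity** — cross-day change in per-trial baseline-subtracted
  flavour responses regressed on each neuron's stimulation-period response
  (OLS + Pearson r with 95% CIs), per-day selectivity proportions, and a
  4-component diagonal-covariance Gaussian-mixture typing of stimulation
  responses (EM, 1e-5 variance floor, 100 restarts).
* **Photometry** — GCaMP debleaching via a linear isosbestic fit and
  AKAR2 ratiometric PKA signals, with injection-locked and reward-locked
  PETH quantification.
* **Simulation** — `sim_config()` / `simulate_session()` /
  `simulate_multiday()` / `simulate_photometry()` generate the full task
  (60 rewards in 5/5-balanced blocks of ten, 30-min delay, 45-min bout
  stimulation or LiCl), inhomogeneous-Poisson populations with
  flavour/water/nonselective classes, bout-locked reactivation gains,
  reactivation-proportional cross-day plasticity, and familiarization
  decay — all with per-neuron ground truth and named seed substreams.

See `vignettes/methods.Rmd` for the model, conventions, numerical choices
and known limitations.

## Worked example

```r
library(cfareact)

cfg  <- sim_config(n_neurons = 120)        # default task, 120 neurons
sess <- simulate_session(cfg, seed = 7)
sess$events
#> <event_log> 60 cues, 60 rewards (30 flavour / 30 water), 471 bouts
#> <epoch> acclimation: [0.0, 300.0) s (5.0 min)
#> <epoch> consumption: [300.0, 1282.3) s (16.4 min)
#> <epoch> delay: [1282.3, 3082.3) s (30.0 min)
#> <epoch> stim: [3082.3, 5782.3) s (45.0 min)

# classify neurons from consumption-period responses (5% FDR)
lab <- classify_session(sess$spikes, sess$events)
table(truth = sess$truth$label, classified = lab$label)
#>               classified
#> truth          flavour nonselective water
#>   flavour           36            0     0
#>   nonselective       1           69     2
#>   water              0            0    12

# train the population decoder on consumption, evaluate during stimulation
tr    <- build_training_set(sess$spikes, sess$events)
model <- fit_multinomial_l1(tr$features, tr$labels, lambda = 1)
model
#> <cfa_decoder> 3 classes x 120 neurons, lambda = 1, 45 non-zero weights,
#>   converged in 625 iterations

dstats <- delay_window_stats(sess$spikes, sess$events)
stim   <- sess$events$epochs$stim
post   <- sliding_posteriors(model, sess$spikes, dstats,
                             c(stim$start, stim$end))
fl <- detect_reactivations(post, "flavour")
wa <- detect_reactivations(post, "water")
c(flavour = length(fl$indices) / 45, water = length(wa$indices) / 45)
#>  flavour    water
#> 11.13333  3.24444

# stimulation-period ("CGRP") scalar response by ground-truth class
cr <- scalar_response(delay_event_trace(sess$spikes, sess$events),
                      "cgrp_45min")
round(tapply(cr, sess$truth$label, mean), 3)
#>      flavour nonselective        water
#>        0.460        0.000       -0.001
```

The classification table shows near-perfect recovery of the planted
classes at the default gains. Flavour reactivation events during the
stimulation period outnumber water events several-fold because the
generator plants bout-locked gains only in the flavour class, and the
minute-scale stimulation response isolates the same class (~0.5 z here)
while water-preferring and nonselective neurons stay at their delay
baseline.

`run_pipeline(config, out_dir, seed)` chains
simulate → classify → PETHs → decode → trajectories → plasticity →
response typing, writing every stage's CSV/JSON artifacts plus a manifest
with seeds, a configuration hash and per-file checksums; re-running with
the same config and seed reproduces the artifacts byte for byte.

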