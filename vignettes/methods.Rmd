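---
title: "Methods: simulating and analysing flavour-representation reactivation in the CEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing flavour-representation reactivation in the CEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Conditioned flavour aversion (CFA) requires an animal to associate a flavour
with gastrointestinal malaise that arrives tens of minutes after the meal.
`cfareact` implements the population-electrophysiology analysis chain used to
study how this temporal credit assignment works in the central amygdala
(CEA): flavour-coding neurons identified during consumption are selectively
*reactivated* when delayed malaise signals arrive (either optogenetic
stimulation of CGRP neurons in 3-s bouts, or LiCl injection), and the
strength of that reactivation predicts how much each neuron's flavour
response is stabilized when the memory is retrieved a day later.

Every stage of the chain is driven by a synthetic-session generator with
known ground truth, so each analysis can be validated as a
parameter-recovery problem rather than by eye.

# The task model

A simulated session reproduces the two-reward paradigm:

* 5-min acclimation, then a cued consumption period: on each trial one port
  is cued, the animal enters after a 0.5-3 s latency and receives a 20-ul
  reward; inter-trial intervals are drawn uniformly from the integers
  10-20 s. Every consecutive block of ten rewards is split 5/5 between the
  flavour and water ports, and the period ends at exactly 60 rewards
  (1.2 ml).
* a 30-min delay in a second context,
* then either a 45-min stimulation period of 3-s bouts whose gaps are
  `1 + Exp(mean 2)` seconds resampled above 7.8 s (minimum 1 s, untruncated
  mean 3 s; the resampling pulls the realized mean slightly below 3 s), or a
  LiCl injection at the period onset.

All trials are successful, matching well-trained animals.

# The population model

Spiking is inhomogeneous Poisson, generated by thinning against a
per-neuron rate ceiling. Neuron $i$ of class $c_i$ fires at

$$r_i(t) = b_i \; s(t)\,\bigl(1 + g_i K_{c_i}(t) + \rho_i \,\mathrm{bout}(t)\bigr)$$

* $b_i$: baseline rate, lognormal with median 2 sp/s (`baseline_log_mean`,
  `baseline_log_sd`), the scale typical of extracellular CEA units.
* $K_c(t)$: a sum of unit-peak alpha kernels $(t/\tau)e^{1-t/\tau}$
  ($\tau$ = 2 s) over that class's own reward deliveries; `reward_gain`
  (default 2) scales it. Flavour-preferring neurons respond to flavour
  rewards, water-preferring to water rewards, nonselective to neither
  (default split 30%/10%/60%, qualitatively mirroring the observed
  proportions of flavour- and water-activated CEA neurons without targeting
  them).
* $s(t)$: a multiplicative suppression (default 0.6) applied from the end
  of consumption onward. The magnitude is a free parameter — the biological
  observation is only that CEA activity drops after the meal ends. It is
  held flat through the stimulation period rather than lifted at
  stimulation onset: stimulation responses are measured in units of the
  delay baseline, so a step back to 1.0 at stimulation onset would give
  *every* neuron a spurious positive stimulation response and destroy the
  class specificity the analysis is meant to detect.
* $\rho_i$: the bout-locked reactivation gain, non-zero only for
  flavour-preferring neurons, drawn from a normal truncated at zero
  (`react_gain_mean` = 8, `react_gain_sd` = 3). Under Poisson variability a
  bout gain $\rho$ produces a minute-resolution reactivation of roughly
  $\rho \cdot \mathrm{duty} \cdot \sqrt{0.01\, r_{\mathrm{delay}}}$
  z-units; the default therefore yields ~0.5 z for the flavour class, the
  scale at which stimulation responses are actually observed. Much larger
  defaults would require implausible (>15x) rate gains.

Cross-day plasticity is generative: on the retrieval day each
flavour-preferring neuron's reward gain becomes
$g_i + \beta\,\rho_i + \varepsilon_i$, $\varepsilon_i \sim N(0,
\sigma_\beta)$ — plasticity proportional to the malaise-period input the
neuron received. The familiarization variant instead multiplies flavour
gains by `familiarization_decay`, leaving water responses unchanged.

One master seed feeds named substreams (`events`, `ground_truth`, `spikes`,
`plasticity`, `gmm`, `cv_folds`, `photometry`), so any stage can be
regenerated independently and identical seeds give byte-identical sessions.

## What the generator does and does not emulate

It reproduces the event statistics of the task, class-structured Poisson
spiking, bout-locked reactivation, reactivation-proportional plasticity and
familiarization decay. It does **not** model correlated (non-Poisson)
variability, bursting or refractoriness, slow drift, behavioural
microstructure (licking), cue responses, or learning within a session.
Tests passing on this generator therefore establish that the analysis chain
recovers the structure it is designed for — not that recorded data contain
that structure.

# Analysis conventions

**Binning and normalization.** Spikes are counted in 10-ms, left-closed
right-open bins; a spike exactly at a range end is dropped so counts are
conserved. All standard deviations are population (divide-by-N) statistics,
recorded in `norm_stats` provenance together with the source epoch and
granularity. Z-scoring a zero-variance neuron returns a zero row with a
warning rather than NaN.

**Selectivity.** Per-trial responses are the mean z-scored activity in the
10 s after each delivery (fixed 10 s regardless of overlap with the next
trial; windows reaching past the recorded data are truncated to the covered
bins with a warning — without that rule the final trial of a session
acquires a systematic negative bias shared by every neuron). A Wilcoxon
rank-sum test (midranks, tie-corrected variance, 0.5 continuity correction)
compares flavour and water trials per neuron; the two-stage
Benjamini-Krieger-Yekutieli step-up controls a 5% FDR across all neurons in
the call (pool per animal by calling per animal). Rejected neurons are
labelled by the sign of (mean flavour − mean water); exact ties fall to
water. The normal approximation is intrinsically coarse for samples of
size ≤ 2 (worst-case deviation from exact enumeration ≈ 0.13); with the
task's 30 trials per port this regime never arises in practice.

**PETHs.** Reward PETHs cover (−5, +10) s; day-2 PETHs reuse day-1
consumption statistics so units are comparable across days.
Stimulation-bout PETHs cover (−1, +4) s (chronic) or (−1, +2) s (acute
typing) and subtract each neuron's own (−1, 0) s baseline. Display variants
are smoothed with a causal half-Gaussian (100-ms sd, truncated at 4 sd,
renormalized to unit mass; the first samples are renormalized by the kernel
mass inside the data so constants are preserved everywhere). Minute-scale
traces z-score by the statistics of the final 20 min of the delay by
default (`"delay_full"` is available) and downsample by non-overlapping
minute means; events whose windows exceed the data are dropped from
averages, with counts recorded.

**Decoder.** Training uses one feature vector per event: 1-s post-delivery
counts (flavour/water classes) and 1-s pre-cue counts (baseline class),
each minus the neuron's mean pre-cue count and divided by the sd of 1-s
counts tiling the consumption period (the granularity of "the s.d. during
the consumption period" is not uniquely determined; non-overlapping tiling
windows are the stated convention here). The decoder minimizes the *total*
(unaveraged) multinomial negative log-likelihood plus
$\lambda \sum |W|$ with unpenalized intercepts — the convention fixed for
this package since only the name $\lambda$ is standard; the default
operating point is $\lambda = 1$ and ten-fold stratified cross-validation
over the nine log-spaced values $10^{-4} \dots 10^4$ makes conclusions
robust to the scaling. Optimization is monotone accelerated proximal
gradient descent (MFISTA) from zero: deterministic, objective
non-increasing by construction, converged when the parameter step falls
below 1e-6 (capped at 20,000 iterations, flagged if unconverged). The
analytic gradient is exposed (`multinomial_nll_grad`) and verified against
central differences; posteriors agree with an established coordinate-descent
solver at matched penalty to ~1e-6.

**Reactivation events.** Evaluation bins spikes in a 1-s window sliding by
150 ms, z-scored with delay-period 1-s-count statistics. Events are strict
local maxima of a class posterior above 0.5; a plateau contributes its
first index and endpoints are eligible against their single neighbour
(fixed for determinism). Rates are counted in 1-min windows stepped by
30 s.

**PCA trajectories.** Reward-selective neurons' smoothed PETHs are
baseline-subtracted over (−5, −4) s (averaged across reward types),
peak-normalized by the maximum absolute value across both reward types, and
the 0-5 s segments concatenated into a neurons × 1,000-bin matrix. Every
column (time bin) is centred across neurons and principal directions are
computed in neuron space — time bins as observations, neurons as variables
— so loadings are per-neuron weights and population vectors project after
per-bin centring. The alternative orientation (neurons as observations)
yields the same loading directions up to scaling but different
variance-explained values; the chosen orientation is the one under which
"project the population at each time bin" is well defined. Signs are fixed
by requiring the flavour trajectory's peak projection to be non-negative.
Day-2 data are normalized with day-1 constants and projected through frozen
day-1 loadings. Stimulation PETHs are normalized by their own peak before
projection.

**Cross-day plasticity.** Responses use per-trial baseline subtraction
(−10 to −5 s) so baseline-rate drift between days cancels; classification
comes from day 1 only. The association between the stimulation-period
scalar response and the cross-day change is summarized by ordinary least
squares with Pearson r (the figure-level statistic is not named in the
source conventions; the t-based p is cross-checked against a permutation
oracle in the tests), with 95% confidence intervals.

**Response typing.** A 4-component diagonal-covariance Gaussian mixture is
fitted to the 0-1 s stimulation bins by EM with a 1e-5 variance floor and
100 random-responsibility restarts (named substream; bit-reproducible),
keeping the best log-likelihood. Components are labelled deterministically
from their mean response: most negative → inhibited, nearest zero among the
rest → unmodulated, remaining two → strongly/weakly activated by magnitude;
a structure-mismatch warning fires if the fitted means do not show the
two-activated/one-inhibited/one-unmodulated pattern.

**Photometry.** Both channels are zero-phase low-pass filtered
(second-order Butterworth — the corner frequencies 2 Hz for GCaMP and 1 Hz
for AKAR2 are the stated facts, the family and order are this package's
recorded convention) and downsampled to 100 Hz. Signals are mirror-padded
before filtering: the filter starts from zero state and unpadded edge
transients would otherwise leak non-linear artifacts into the
channel-comparison steps. GCaMP debleaching subtracts the least-squares
linear map of the isosbestic channel fitted over the whole recording;
AKAR2 is the 488/405 ratio, so common multiplicative bleach cancels
exactly. The AKAR2 per-event PETHs are centred on their own (−5, −1) s
baseline and scaled by the sd of the concatenated baseline epochs pooled
across both ports within a recording.

# Numerical and edge-case choices

* Half-Gaussian kernel truncated at 4 sd, unit-sum, head renormalized by
  in-data kernel mass.
* Thinning ceiling: $b_i(1 + 1.15\,g_i + \rho_i)$; the 1.15 margin covers
  worst-case alpha-kernel overlap at ≥ 10-s inter-trial intervals, and
  exceeding the configured `rate_max` is an error, never silent clipping.
* Degenerate inputs: zero-sd neurons produce zero features/rows with
  warnings; a constant isosbestic channel, a zero-variance regression
  predictor and an all-identical rank-sum input each fail loudly (p = 1 for
  the last).
* Quality filtering: exclude below 20 uV median template-scaling amplitude,
  above 100% estimated false-positive rate, or below 0.05 sp/s; single
  units additionally need a `good` curation label and < 10% false-positive
  rate. The false-positive reference computation solves the standard
  refractory-violation estimator
  $V = 2(t_{ref}-t_{cens})N^2 f(1-f)/T$ for the smaller root (2-ms
  refractory period), returning 1 when no root exists.

# Problem sizes used in the test studies

The packaged studies run at sizes chosen to make each statistical property
measurable while keeping a full check of the suite comfortable on a
laptop: 100 event-structure seeds; one 300-neuron default session for
classifier recovery and trajectory geometry; 100 null seeds of 1,000
neurons for FDR control; 10 seeds each of planted and null 300-neuron
sessions for reactivation specificity; 100 seeds per β for slope-CI
coverage at ~200 flavour neurons; 340 neurons for mixture recovery; 100
photometry seeds. Unit tests use a shared 60-neuron session where class
structure suffices.

# Known limitations

* **Null reactivation-rate asymmetry.** With no planted reactivation, the
  flavour posterior produces *fewer* noise peaks than the water posterior
  (~3x at the default 30%/10% class split). The smaller water class is
  less separable from baseline during training, so its decision boundary
  sits closer to the evaluation noise cloud and crosses the 0.5 peak
  threshold more often; with equal class fractions the two null rates agree
  within ~1.5x. The asymmetry is anti-conservative *against* the
  reactivation claim (flavour is never spuriously elevated), but
  symmetric null rates should not be expected from this method when class
  sizes are unequal.
* The decoder's held-out misclassification at the default generator is
  ~3-4%, not near zero: the 1-s training window captures only the rising
  edge of a τ = 2 s response kernel. Real CEA responses are faster at
  onset, which is why near-perfect cross-validated decoding is attainable
  on recorded data but not under this kernel.
* Poisson spiking puts a hard ceiling on per-neuron z-scored effect sizes;
  analyses whose thresholds assume super-Poisson effect magnitudes (e.g.
  per-neuron minute-trace reactivation ≫ 1 z) need either larger gains than
  are biologically sensible or population averaging, which is what the
  pipeline uses.
* Unit identity across days is taken as given (as with concatenated
  spike-sorting); no matching algorithm is provided.
* The rank-sum normal approximation should not be trusted for samples of
  size ≤ 2; the task design never produces them.
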