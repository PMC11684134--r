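---
title: "Temporal classification with a single LIF neuron and time-varying synaptic efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal classification with a single LIF neuron and time-varying synaptic efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sefron)
```

## The model

`sefron` classifies two-class tabular data — typically clinical voice
features for Parkinson's disease detection, where class-1 is the patient
group — with a spiking neural network reduced to its minimum: P presynaptic
neurons connected to **one** leaky integrate-and-fire (LIF) output neuron.
The class label is read off the output neuron's firing time.

**Encoding.** Each feature is first max-normalized, x' = x / max(column),
then presented to Q Gaussian receptive fields with centers
mu_l = (2l − 3) / (2(Q − 2)), l = 1..Q, and shared width
sigma = 1 / (beta (Q − 2)). A field responding with strength
psi = exp(−(x' − mu_l)² / (2 sigma²)) emits one spike at t = T (1 − psi):
strong activation fires early, weak activation fires near the end of the
encoding window T. Max-normalization can push negative-valued features (such
as the `spread1` voice measure) far outside [0, 1]; those inputs simply get
vanishing psi and a spike at T, so the pipeline is total. A min-max mode is
available when a strict [0, 1] mapping is preferred.

**Dynamics.** Each input spike at st_j contributes
omega_j(st_j) · phi(t − st_j) to the membrane potential, with the causal
kernel phi(t) = (t/tau) e^(1 − t/tau) (peak 1 at t = tau, zero for t ≤ 0).
The synaptic weight omega_j(t) is not a constant but a *function of time*,
stored on a simulation grid and sampled at the presynaptic spike time. The
neuron fires at the first grid point where the potential reaches the
threshold theta = 1; a single output spike is modelled, so simulation stops
there. If the threshold is never reached within the observation window
[0, T + deltaT], the firing time is defined as T + deltaT.

**Decoding.** Firing before the temporal boundary t_b decodes as class-1, at
or after it (including the no-fire case) as class-2.

**Learning.** For a postsynaptic firing at t_f, each input spike receives a
normalized STDP credit chi_j(t_f) proportional to e^(−(t_f − st_j)/tau_plus)
(zero for spikes after t_f; the depression branch is disabled because only
one output spike exists). The reference potential
V_PSP(t_f) = sum chi_j phi(t_f − st_j) turns the credit into a scale: the
*overall strength* lambda(t_f) = theta / V_PSP(t_f) is the weight level that
would make the credited spikes reach threshold exactly at t_f. The training
error for a sample is epsilon = lambda(t_fd) − lambda(t_fa), the strength
mismatch between the desired and the actual firing time. Each synapse's
scalar update, mu (lambda_d chi_j(t_fd) − lambda_a chi_j(t_fa)), is spread
along the time axis as a Gaussian bump of SD `sigma_update` centered on its
spike time and added to omega_j(t) — this accumulation of signed bumps is
what makes the efficacy functions time-varying, and lets one synapse act
excitatory at some times and inhibitory at others.

**Initialization.** The threshold is defined only implicitly (it is the
potential at the firing time), so theta is fixed at 1 and the initial
weights are constructed from the first training sample: each synapse gets a
bump of height lambda_d chi_j(t_fd), which makes that sample's potential
equal exactly theta at its desired firing time. Initializing twice is an
error; the construction assumes all-zero efficacies.

## Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| Q | 6 | — | receptive fields per feature |
| beta | 0.7 | — | receptive-field overlap constant |
| mu | 0.075 | — | learning rate |
| sigma_update | 0.08 | ms | SD of the efficacy update bump |
| tau_plus | 0.45 | ms | STDP potentiation window |
| tau | 0.63 | ms | LIF membrane time constant |
| T | 3 | ms | presynaptic encoding window |
| deltaT | 1 | ms | observation extension for late output spikes |
| t_b | 2 | ms | class boundary |
| dt | 0.01 | ms | simulation step |
| theta | 1 | — | firing threshold (fixed) |

The first block is the operating point of the method for voice-feature
Parkinson's data; `sweep_parameter()` reproduces the one-at-a-time
sensitivity curves (e.g. beta over 0.2–1.2 in steps of 0.025) around it.
dt = 0.01 ms is an implementation choice: it is two orders of magnitude
below tau, keeps the 0–4 ms grid at 401 points, and halving it moves firing
times of the deterministic construction by at most one coarse grid step
(asserted in the test suite). The amplitude V_plus of the STDP curve cancels
in the credit normalization and is fixed at 1.

## Design choices in the open parts

Several ingredients are not pinned down by the method's published
description; this package's choices, and why:

**Desired firing times.** Only the boundary t_b = 2 ms and the 0–4 ms window
are given by the method; the desired times are free. We use t_d1 = 0.5 ms
and t_d2 = 3 ms rather than a symmetric placement about t_b. The asymmetry
is deliberate: the potential of a well-driven sample rises steeply early in
the window, so a desired crossing at 0.5 ms sits on the rising flank and
every spike arriving afterwards adds margin — an unseen sample with slightly
weaker drive still crosses the threshold, merely a little later (and is still
left of t_b). A late desired time instead trains samples so the potential
*peak* barely touches theta, and unseen samples with ~10% less drive never
fire at all; on synthetic data this costs 3–4 accuracy points. Both times
are configurable in `neuron_config()`.

**Update trigger.** The classification mismatch e(n) between decoded and
desired output is the driving error signal; accordingly the default policy
(`update_policy = "mismatch"`) adapts the efficacies only for misclassified
samples, and training reaches a fixed point once every training sample is on
the correct side of the boundary. The alternative `"always"` policy applies
the timing update to every sample whose firing time misses its desired time;
it is useful for studying timing convergence, but pulling already-early
class-1 samples back toward the exact desired time erodes the potential
margin and measurably hurts held-out sensitivity.

**Update form.** Two algebraic variants of the efficacy update are exposed.
`"respective_times"` (default) pairs each overall strength with the credit
at its own firing time, mu (lambda_d chi(t_fd) − lambda_a chi(t_fa)):
it strengthens synapses active just before the desired time while weakening
those that caused the actual (wrong-time) firing. The `"as_printed"` variant
uses chi(t_fd) in both terms, which collapses to mu · epsilon · chi(t_fd);
since epsilon < 0 whenever the neuron fires late or not at all, this variant
weakens exactly the synapses that should drive the desired firing and does
not converge in practice — it is retained because both forms circulate in
descriptions of the method, and the identity with mu · epsilon · chi is
verified in the tests.

**Guards.** lambda = theta / V_PSP is capped (default 100) because V_PSP at
the no-fire time T + deltaT can be tiny; epochs cap at 100 with early
stopping at the policy's fixed point; a non-finite efficacy aborts training
with a diagnostic. Degenerate situations — a firing time earlier than every
input spike, an all-zero feature column under max-normalization, a training
fold containing one class — raise errors naming the offending quantity.

**Normalization scope.** The global formulation of max-normalization divides
by the column maximum of the whole table. For honest evaluation the default
refits the normalizer on each training fold (`norm_scope = "fold"`);
`"global"` reproduces the whole-table convention.

**Percentage splits.** The training side takes floor(train_fraction × M)
samples — applied per class when stratified — and the remainder tests; for a
195-sample table at 90% this gives 175/20. Stratification is the default
for both split kinds (each fold's class count is within one sample of even).

## The synthetic-data generator

`generate_synthetic()` emulates the *structure* of the clinical voice
tables the method targets: bounded continuous features (per-feature ranges,
including strictly negative ones), a binary label with controllable
imbalance (e.g. 147:48 at `class_fraction = 0.754`, n = 195), optional
equicorrelated feature blocks (voice perturbation measures are strongly
inter-correlated), and optional replicated recordings per subject sharing a
subject-level random effect (70% of the within-class variance). Classes are
multivariate Gaussians whose per-feature means differ by `separation`
within-class SDs; the within-class SD is fixed at 10% of the feature range,
so `separation = 3` gives well-separated but overlapping classes, and values
are clipped into the range.

What it does *not* emulate: heavy tails and skew of real perturbation
measures, feature-dependent noise, label noise, and the subject-level
confounding of repeated clinical recordings. Passing tests on this generator
therefore demonstrate that the implementation learns and generalizes under
controlled conditions — not that the method attains any particular accuracy
on real clinical data.

Problem sizes used by the test suite and the acceptance script — 10-fold
cross-validation on 200 balanced and 195 imbalanced samples with 10
features, plus small fixtures of 24–100 samples — were chosen so the whole
evaluation is a routine desk run while keeping at least ~90 samples per
class for the coverage-hungry efficacy functions (see limitations).

## Numerical conventions

* Spike times are snapped to the simulation grid by nearest-point rounding,
  ties rounding down; the learning rule samples omega_j at these snapped
  times, so everything lives on the grid.
* Threshold crossing is the first grid point with v ≥ theta; equal values at
  several points resolve to the earliest.
* In the figures of merit, any 0/0 ratio is defined as 0 and flagged in the
  report's `"zero_division"` attribute; MCC with a zero denominator is 0.
* Cross-validation averages each metric arithmetically across folds.
* All randomness (synthetic draws, fold assignment, epoch shuffling) is
  seeded, and seeded runs are reproducible byte-for-byte, which the test
  suite asserts on the CLI artifacts.

## Known limitations

* **Coverage-limited generalization.** An efficacy function is a sum of
  narrow Gaussian bumps (SD 0.08 ms) at *training* spike times. A held-out
  sample samples these functions at slightly different times, so small
  training sets leave gaps: on synthetic data, mean CV accuracy grows from
  roughly 0.90 at 40 training samples to about 0.98 at 180. The method wants
  either data volume or a wider `sigma_update`.
* **Single output spike, two classes.** Multi-class extensions, refractory
  dynamics, and alternative neuron models are out of scope.
* **Online order dependence.** Training is online; results depend on the
  (seeded) sample order, and the always-update policy can jitter by a few
  grid steps around its fixed point rather than settling exactly.
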