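---
title: "Methods: from membrane potential to odor codes in the mosquito antennal lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from membrane potential to odor codes in the mosquito antennal lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mozal)
```

This vignette documents the models, conventions, and numerical choices
behind `mozal`. The package analyzes in vivo whole-cell recordings from
projection neurons (PNs) and local neurons (LNs) of the mosquito antennal
lobe (AL), together with neuron reconstructions and two-choice behavioral
assays. Because such recordings are scarce, every stage is paired with a
seeded synthetic generator that reproduces the statistical structure the
stage assumes, so all claims made by the test suite are claims about the
pipeline's correctness on data of that structure — not about any particular
animal.

## Trial structure and windows

All trial-based analyses assume 10 s trials sampled at 20 kHz with the odor
valve opening at 2 s for 1 s. Three conventions are fixed throughout:

* **Background window** `[0, 2)` s; **response window** `[2.1, 4.1)` s. The
  100 ms gap absorbs odor transit from valve to antenna; the 2 s response
  window captures responses that outlast the 1 s stimulus. Windows are
  half-open, so every spike belongs to exactly one of background / gap /
  response / post.
* **Isolation**: a spike is isolated when no other spike lies within 200 ms
  on either side. A neighbor at exactly 200 ms makes the spike a burst
  spike — the boundary is part of the window. This convention is arbitrary
  but fixed and tested.
* Longer trials (recorded when responses are prolonged) keep the same
  window anchors; nothing shifts with trial duration.

## Spike detection and the four features

Detection is deliberately parameter-light: the trace is zero-phase
low-pass filtered at 2 kHz (4th-order Butterworth via forward-backward
filtering), slow drift is removed with a zero-phase 100 Hz high-pass, and
local maxima above `k × MAD` of the band-passed signal (default `k = 6`,
absolute floor 0.5 mV so a noiseless trace has a finite threshold) are
kept, with a 2 ms refractory window resolved toward the larger peak.
Candidates must also be depolarized above the trace median on the
low-passed trace, which rejects rebound artifacts that band-passing deep
after-hyperpolarizations can create. The reported spike time is the
low-passed waveform peak. Flat or all-NA traces yield an empty spike train
with a warning rather than an error, so batch processing survives dead
recordings.

The four per-cell features are measured on the low-passed trace:

1. **Spike amplitude (mV)** — peak minus the deeper of the two troughs
   within ±10 ms. Averaged over isolated spikes when any exist; otherwise
   each burst contributes the mean of its first and last spike.
2. **Half-width (ms)** — full width at half the height, height measured
   from the deeper trough; crossings are linearly interpolated between
   samples.
3. **AHP amplitude (mV, ≤ 0)** — on a 5–500 Hz zero-phase band-passed
   trace, `min(0–10 ms post-spike) − mean(20–70 ms post-spike)` per
   isolated spike; positive values (membrane-potential flukes) are dropped
   before averaging.
4. **Isolated fraction** — isolated spikes over all spikes.

Missing features propagate as `NA`, never silently as 0. The ±10 ms trough
bound and the deeper-trough baseline for the half-width are package
choices where the feature sketches leave the convention open; both are
pinned by tests.

## Cell typing

Features are z-scored per column with the sample SD (n − 1); this
convention matters for exact test values and is fixed. Missing entries are
imputed from the reference set of complete cells: similarity = Pearson
correlation over the incomplete cell's available features, negative
similarities clipped to zero before weighting (an unclipped weighted mean
could be pulled the wrong way by anti-correlated reference cells); if no
weight is positive, or fewer than two features are available so a
correlation is undefined, the unweighted reference mean is used and the
fallback is logged. Clustering is Ward linkage (`ward.D2`) on Euclidean
distances, cut at k = 2; linkage and distance are not dictated by the
feature definitions, and Ward is the standard variance-minimizing choice.
Clusters are named by majority true label with ties broken toward PN (the
larger class), making the reported recovery accuracy deterministic.

## The responder criterion

A cell-odor pair "responds" when either 1-s half of the response window
differs from background across trials: per trial, the bin firing rate is
paired with the same trial's background rate, and a two-sided Wilcoxon
signed-rank test is run per bin; the pair responds if either p < 0.05. No
multiple-testing correction is applied across cell-odor pairs — this
mirrors the descriptive use of the criterion; the package instead reports
the criterion's null calibration (the two-bin OR rule rejects at most
about twice the per-bin exact level, ~0.094 at 7 trials; empirically ≈
0.07–0.08 because rate ties reduce achievable levels).

The signed-rank test is implemented exactly: zero differences are dropped,
absolute differences receive average ranks, and for n ≤ 25 the null
distribution of the positive-rank sum is enumerated by dynamic programming
over the doubled ranks, which handles ties exactly instead of falling back
to a normal approximation (above n = 25 a tie-corrected normal
approximation with continuity correction is used). Differences below
`1e-8 ×` the data scale are treated as zeros so that floating-point noise
in rate arithmetic cannot masquerade as a consistent sign. With 7 trials
the smallest two-sided p is 2/2⁷ = 0.015625, which is why at least 6
trials are required for the criterion to be able to fire at α = 0.05;
pairs with fewer trials are reported non-responding with a warning.

## Population decoding

The decoder follows a nearest-centroid, leave-one-trial-out design. Each
trial's population response is the background-subtracted firing rate in
eight 250 ms bins of the response window, for every cell; columns are
bin-major (first all cells' bin 1, then all cells' bin 2, …), so truncating
to the first `k × n_cells` columns uses the first `k` bins — the
"cumulative response duration" axis. The first trial is dropped by default
(odor delivery differed slightly on first trials in the recordings this
design mirrors) and the next six are used. Templates are training-trial
centroids per odor; a test trial scores a hit when Euclidean distance to
its own odor's template is smallest. Exact distance ties — which occur for
all-zero features — are resolved toward the lowest odor index,
deterministically, and accuracy is averaged over test odors within a fold
and then over folds. Population-size curves subsample cells with a seeded
RNG, ten repeats per size by default, on the first three bins (750 ms).

PCA trajectories use the 60 × 100 ms-bin PSTH matrix (odors concatenated
row-wise, cells as columns), column-centered and unscaled — the entries
are already in common units (Hz). No whitening is applied.

## Morphological similarity

Skeletons are standard SWC (µm, one root, parent links forming a tree;
violations are reported with line numbers). Before scoring, each neuron is
resampled so no edge exceeds 0.5 µm — implemented by inserting collinear
nodes, which preserves every original node and the exact cable length.
Axon isolation for lateral-horn comparisons keeps the subtree distal to
the most lateral branch point (the medial→lateral axis defaults to +x and
is configurable, since deposited reconstructions' axis conventions vary)
and then removes the maximal-Strahler cable within it — the co-fasciculating
central tract — leaving the terminal branches. The pruned object is a
forest and is used as a point cloud.

Similarity is NBLAST-style: tangents are the dominant direction of each
point's 5 nearest neighbors; the raw score sums
`exp(−d²/2σ²) · |t_q · t_t|^γ` over query points (defaults σ = 3 µm,
γ = 1), and the normalized score divides by the query's self-match, so
self-similarity is exactly 1 and scores are asymmetric (the headline
statistic averages the two directions). The original analyses used an
externally trained scoring matrix; this package uses the parametric kernel
to stay self-contained and accepts a user-supplied `scoring_fn(dist,
absdot)` for parity experiments. Consequently the *contrast* between
homotypic and heterotypic pairs is the tested claim — it holds for any
monotone kernel — while absolute score levels depend on the kernel and are
not comparable to published values; the deposited reconstructions are also
not bundled here, so the packaged similarity numbers come from synthetic
jittered clones and are labeled as such.

## Behavior

The preference index is `(N_o − N_c)/(N_o + N_c)` over the two side arms;
mosquitoes elsewhere count as non-responding. Validity requires ≥ 5
responders and covariates within 25–30 °C and 45–80 % RH; the bounds are
applied inclusively at both ends (the ranges are stated without
strictness; a fixed convention is testable). Per-odor significance is the
exact signed-rank test of per-experiment PIs against zero. The
behavior–neural link correlates |ΔPI| across odor pairs with the PN
population distance `1 − R` over the PNs common to the pair (absolute
differences keep the quantity a distance); pairs with fewer than 3 common
PNs are skipped and logged, and population-size curves subsample each
pair's common PNs with 20 seeded repeats per size, ignoring pairs with
fewer than `n` common PNs.

## What the generators emulate — and what they do not

* **Voltage traces**: an analytic biphasic template (Gaussian
  depolarization; delayed alpha-shaped AHP lobe whose onset is 1.5 ms
  after the peak so it cannot distort the half-width) parameterized
  directly by the four features, placed on events from a two-state renewal
  process — isolated single spikes separated by ≥ 250 ms, or bursts of 2–5
  spikes at 10–30 ms intervals — whose mixing probability is solved from
  the target isolated fraction, plus white Gaussian noise. Defaults follow
  the recorded group statistics where published (PN spontaneous rate
  9.5 Hz, LN 2.6 Hz, PN isolated fraction 0.04) and the printed PN/LN
  directionality otherwise (PN spikes smaller, wider, shallower-AHP:
  15 mV/1.4 ms/−2 mV vs 30 mV/0.7 ms/−6 mV — magnitudes chosen as
  physiologically typical, since no numeric means are published for these).
  Not emulated: bursty subthreshold dynamics, electrode drift, synaptic
  potentials, spike-shape adaptation within bursts.
* **Population responses**: piecewise-constant rates (per-cell baseline
  plus a step of tuned rate inside the response window, optional onset
  delays), Poisson counts per 100 ms bin. Not emulated: temporal patterning
  within responses, cross-trial adaptation, correlated noise across cells —
  so decoding results on synthetic data validate the decoder's mechanics
  and its chance-level calibration, not biological accuracy values.
* **Skeletons**: random trunk-plus-tuft trees; homotypic clones share
  topology and differ by isotropic coordinate jitter. Real homotypic PNs
  differ more richly (branch counts, topology).
* **Behavior**: responders binomial in the released count (18–20 per
  experiment), arm choice binomial in the responders. Independence across
  experiments is assumed.

## Problem sizes and runtime choices

The test suite and the acceptance script use desk-scale sizes chosen so the
full run completes in a few minutes on one CPU while keeping every check
statistically meaningful: 100 seeded runs for the chance-decoding mean
(64 cells × 6 odors × 6 trials each), ~10⁴ cell-odor pairs for the
responder null, 20 seeded cohorts of 45 cells for clustering recovery,
4 × 3 jittered skeletons at 0.5 µm resampling for the similarity contrast,
and 100 seeded runs for the behavior-correlation coverage check. A single
global seed fans out to per-generator substreams (a hash of seed and stream
label), so stages are reproducible independently of execution order.

## Known limitations

* Response onset delays are described qualitatively in the literature this
  design follows, without an estimation procedure; the package carries
  delays in the generator but does not estimate them from data.
* The decoder pools cells recorded in different animals by trial index
  (pseudo-trials); cross-animal correlation structure is therefore
  invisible.
* Absolute NBLAST score levels depend on the scoring kernel (see above).
* The feature-level cohort generator draws features independently within a
  class; real feature covariances (e.g. amplitude–AHP coupling) are not
  reproduced, which makes clustering recovery on synthetic cohorts an
  upper bound on real-data performance at equal separation.
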