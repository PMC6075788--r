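---
title: "Spatiotemporal representational similarity encoding for EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal representational similarity encoding for EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strsa)
```

## The analysis

`strsa` implements a time-resolved representational similarity encoding
analysis: it asks when, and where on the scalp, the category geometry of
event-related potentials (ERPs) comes to resemble the category geometry of a
layered feature model (for example the successive layers of a deep
convolutional network evaluated on the same stimuli).

Both systems are summarised by representational dissimilarity matrices
(RDMs). For a feature layer, the RDM entry for categories $i, j$ is
$1 - \rho_{ij}$, where $\rho_{ij}$ is the Spearman correlation between the
category-mean feature vectors. For the brain, an RDM is computed per
electrode in a 40 ms sliding window: each category's feature vector is its
mean ERP voltage over the window samples at that electrode, and the same
$1 - \rho$ metric is applied. The diagonal is undefined and only the lower
triangle (in a fixed row-major order, $j < i$) enters any analysis.

The encoding step rank-transforms the lower-triangle vectors and fits, per
electrode and window, either

* the **joint model**: OLS of the neural ranks on all layer ranks plus an
  intercept, summarised by $R^2$ ("variance explained by all layers"), or
* the **single-layer model**: the Spearman correlation $\rho$ with one
  layer, summarised by $\rho^2$ with the sign carried separately.

The joint $R^2$ is defined on the rank scale for consistency with the
Spearman dissimilarities; residuals are rescaled back to dissimilarity
units by the ratio of dissimilarity-scale to rank-scale standard deviation
so that their sign reads as under-/over-prediction of dissimilarity.
Because an OLS fit with an intercept nests every single predictor, the
joint $R^2$ is never smaller than the best single-layer $\rho^2$ on the
same data — a property the test suite asserts.

## Preprocessing

Raw epochs (electrodes × samples × trials, µV, 100 ms baseline + 750 ms
stimulus) pass through:

1. **Band-pass filtering** (default 0.1–45 Hz). Epochs are short relative
   to a 0.1 Hz time constant, so each series is demeaned exactly and then
   filtered with a 2nd-order Butterworth high-pass and a 4th-order low-pass,
   each applied forward and backward (zero phase). This design meets the
   contract the package tests: DC to below 0.5 µV, in-band tones within
   ±1 dB, 60 Hz attenuated by at least 20 dB (verified against the designed
   transfer function). A recursive band-pass of lower order misses both the
   DC and the 60 Hz bounds on short epochs, which is why the cascade is used.
2. **Artifact rejection**: a trial is invalidated if any sample at any
   electrode strictly exceeds ±100 µV. A participant with more than half
   of trials rejected raises an error (participant-level exclusion).
   Rejection is idempotent.
3. **Baseline correction** to the mean of the last 100 ms before onset.
4. **Sub-average bootstrapping**: every valid trial is replaced by the mean
   of `ceil(0.2 · n_c)` distinct same-category trials, the anchor trial
   always included, sampled without replacement. Anchoring keeps one real
   trial per surrogate and makes `fraction = 1/n_c` degenerate to the
   identity; `fraction = 1` yields the category mean for every trial.
   Sampling seeds are derived per (participant, category, trial identity),
   so the output is invariant to trial storage order. Surrogates are drawn
   once per participant per master seed, not re-drawn per analysis.

## Statistics

**Permutation null.** For each of `n_permutations` draws, every
participant's neural RDMs are independently relabelled by a random category
permutation, the encoder is recomputed at every time point, and the group
mean statistic is stored; permutation 0 is the identity and reproduces the
observed statistic exactly. Relabelling the neural vector by a permutation
equals relabelling the predictors by its inverse, which lets the package
compute whole null arrays with a handful of matrix products.

**Cluster-extent correction.** The observed trace is thresholded at the
pointwise $1-\alpha$ null quantile (one-sided; explained variance can only
meaningfully exceed chance). Contiguous suprathreshold runs form temporal
clusters, and a cluster survives only if its length strictly exceeds the
$1-\alpha/n$ quantile of the null's maximum-run-length distribution, where
$n$ is the number of traces tested simultaneously (Bonferroni at the
cluster level; 8 for the per-layer traces, 1 for the single joint trace).
Placing the multiplicity correction at the cluster stage rather than the
pointwise stage keeps the extent test informative: with a pointwise
threshold near the null maximum, almost any two-point run would survive,
and short false runs would corrupt onset estimates.

**Onsets.** The onset of significant encoding is the first significant
time point at or after stimulus onset; pre-stimulus windows cannot carry
stimulus-driven signal and are excluded from onset reporting (they still
participate in the null and the masks). An empty mask yields an absent
(`NA`) onset, never 0. Bin summaries (maximum explained variance and its
latency) use the 0–100 / 101–200 / 200–300 ms partition by default.

**Noise ceiling.** Upper bound: mean Spearman correlation of each
participant's dissimilarity vector with the group mean (overfit, hence an
overestimate). Lower bound: mean correlation with the leave-one-out mean of
the remaining participants. The suite checks `lower <= upper` everywhere
and that both approach 1 as inter-participant noise vanishes.

**Scalp clustering.** Grand-average voltages are z-transformed against the
pre-stimulus baseline per electrode. At each time point, electrodes with
$|z|$ beyond the two-sided $p < .001$ normal quantile are grouped into
connected components of the sensor adjacency graph. A closed-form random
field test is ill-defined on an irregular sensor graph, so component sizes
are tested against a Monte-Carlo null: Gaussian maps smoothed on the graph
to match the baseline's neighbour correlation (the smoothing weight solved
in closed form from the smoother's covariance), 95th percentile of the
maximum component size. Components are tracked over time by Jaccard
overlap > 0.5 between consecutive time points; tracks persisting no more
than 20 ms are discarded. A cluster's reported electrode set is the stable
(majority-presence) membership of its track — the union is kept in a
separate column — restricted to its largest connected component.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be verified
against planted ground truth without any recordings. It emulates the
study design: 30 scene categories × 75 exemplars, 8 feature layers of
increasing category separability, 256 electrodes at 1000 Hz, 850 ms epochs,
13 participants (`study_preset()`); the reduced `desk_preset()` (10
exemplars, 32 electrodes, 250 Hz, 5 participants) is used throughout the
tests so the whole suite runs in minutes on one CPU.

**Feature banks.** Each category receives a latent embedding
($k = 5$ dimensions); layer-wise embeddings follow an autoregressive chain
with neighbour correlation 0.5, so neighbouring layers' RDMs correlate —
as real network layers do — while remaining distinguishable. A pure
layer-specific rotation of a shared embedding would leave every layer's
category geometry identical and make layer-resolved recovery impossible,
which is why the chain is used instead. Exemplar activations are the
category embedding projected into the layer's feature space, scaled by the
layer's separability, plus unit-variance exemplar noise. The preset
separability ramp is 1.6–2.8: increasing across layers (later layers are
more decodable), with a floor high enough that a 10-exemplar desk-scale
bank still carries its layer's geometry into the RDM estimate.

**Epochs.** The voltage of a trial of category $c$ is
$\sum_l \text{loading}_l(e)\, \text{env}_l(t)\,
\big(A_{\text{evoked}} + A_{\text{signal}} \sum_m w_{lm}(t)\, E_l[c, m]/\sqrt{k}\big)$
plus Gaussian noise. `env` is a Gaussian bump; its "width" (default 60 ms)
is the full width at half maximum, centers are spaced 25 ms starting 70 ms
post-stimulus so that recovered onsets land in a regime comparable to
published scene-ERP onsets; envelopes are identically zero before stimulus
onset. The component waveforms $w_{lm}$ are sinusoids drawn from 8–25 Hz:
below ~8 Hz a component barely varies within a 40 ms window and
contributes only rank-degenerate (sign-of-amplitude) structure, so the
band is chosen to give every window non-degenerate temporal geometry while
staying inside the 0.1–45 Hz analysis band. The evoked amplitude
(10 µV) is category-independent: category signals are zero-mean across
categories and would cancel in the grand average, so without an evoked
deflection the z-topography stage would have nothing to cluster — real
ERPs ride on exactly such evoked components. The trial noise default is
3 µV against a 5 µV category-signal scale; the emulated study reports no
per-trial SNR, so these values are chosen once to make parameter-recovery
tests informative rather than to match an empirical anchor.

**Planted regions.** Layer loadings are indicator weights over 4 scalp
regions grown as connected, pairwise non-adjacent electrode blobs around
equally spaced anchor points; the 8 layers map to regions cyclically, so
temporally adjacent layers occupy spatially separated regions. On a
32-electrode desk layout (mean adjacency degree ≈ 4.5) four regions of
5–6 electrodes are the most that can be kept mutually non-adjacent; the
region count is a generator parameter and the planted regions are recorded
in the ground truth for Jaccard comparison against recovered clusters.

**What the generator does not emulate:** volume conduction and realistic
head geometry, ocular/muscle artifact waveforms (artifacts are injected
spikes, by design exactly detectable), 1/f background spectra by default
(a pink-noise option exists for demonstrations), inter-participant
latency or topography variability, and correlated exemplar noise across
layers. Passing recovery tests therefore shows the pipeline recovers
planted structure under clean assumptions; it does not certify performance
on real recordings.

## Numerical and design choices

* Window convention: a window labelled $t$ covers $[t, t+w)$ in ms
  relative to stimulus onset; windows are truncated at the epoch end and
  skipped below 3 samples. The default step is one sample; desk-scale runs
  use 4–8 ms steps.
* Spearman ties use average ranks. Zero-variance vectors raise errors in
  direct calls and are flagged (NA, excluded from summaries) inside
  sliding series, so degenerate windows cannot silently corrupt nulls.
* Collinear layer sets are fit through a pivoted QR (pseudoinverse
  behaviour) with a warning.
* Sub-seeds for participants, permutations, folds and waveforms are
  derived from the master seed by integer hashing, keeping every stage
  deterministic and independent of evaluation order; all seeds stay below
  $2^{31}$.
* The multi-class SVM is libsvm's (the standard linear multi-class SVM
  implementation, as used for the original decoding analyses), with
  one-vs-one voting, cost 1, and per-dimension standardization computed
  from training folds only. Fold assignments are stratified by category
  and shared across layers so per-layer accuracies are comparable.
* Problem sizes in the shipped tests: desk preset, 100–200 permutations,
  200 Monte-Carlo runs for type-I calibration, 10 recovery seeds. These
  were chosen so the full suite completes in well under half an hour on a
  single CPU while leaving the assertions statistically meaningful.

## On-disk formats

Epoch bundles are directories of plain text: `meta.json` (participant,
sampling rate, categories, dimensions, injected-artifact log),
`times.csv`, `trials.csv` (trial id, label, validity), and `voltages.csv`
(electrodes × samples rows by trials columns). Numeric arrays are written
with 17 significant digits, which round-trips IEEE doubles exactly — the
determinism guarantee of `run_pipeline()` is byte-level for every
scientific output (stage timings live in `log.json`, the one file excluded
from the guarantee). RDMs export as square CSVs with a category header,
clusters as JSON.

## Known limitations

* The residual sign convention (observed − fitted dissimilarity) is fixed
  and documented; published figures in this genre are ambiguous between
  similarity and dissimilarity space, so `residual_analysis()` exposes a
  `sign_flip` argument rather than guessing.
* Whether window RDMs should be computed on category means of sub-averaged
  trials (as here) or averaged across single-trial RDMs is ambiguous in
  the source description; the alternative is not implemented.
* The Monte-Carlo cluster-size threshold matches first-order neighbour
  correlation only, not the full spatial covariance.
* Noise ceilings are computed per time point from the same windows as the
  encoding traces; no cross-validation over time is attempted.
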