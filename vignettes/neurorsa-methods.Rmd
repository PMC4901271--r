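---
title: "Methods: spatio-temporal RSA in neurorsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal RSA in neurorsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurorsa)
```

## The model

Representational similarity analysis treats each measurement space —
MEG sensors, fMRI voxels, model units — as a geometry over experimental
conditions and compares the geometries rather than the raw signals.  The
common currency is the representational dissimilarity matrix (RDM): for
*n* conditions, the *n(n−1)/2* pairwise dissimilarities between
condition-evoked patterns, stored condensed in lexicographic pair order
(the `stats::dist()` convention) with the diagonal undefined.

Two metrics are implemented.

* **Correlation distance** (fMRI voxel patterns, model layers):
  `1 − Spearman's R` between the two pattern vectors (average ranks for
  ties), bounded in [0, 2].  Rank correlation makes the RDM invariant to
  any strictly monotone transform of each pattern — deliberate, since
  voxel t-values and unit activations have arbitrary monotone scales.
* **Decoding accuracy** (MEG): the cross-validated accuracy (percent) of
  a pairwise linear SVM, used as dissimilarity — conditions whose sensor
  patterns are more discriminable are further apart.  Trials are first
  sub-averaged: the *M* raw trials per condition are randomly assigned to
  groups of *k* = 5 and averaged into *L = M/k* pseudo-trials, trading
  trial count for signal-to-noise.  A libsvm linear SVM (cost 1, no
  rescaling) is trained on *L* − 1 pseudo-trials per condition and tested
  on the held-out pair, the fold rotating over all *L* pseudo-trials; the
  whole assignment is redrawn `n_reps` times (default 100) and accuracies
  averaged.

Brain and model RDMs are compared by Spearman's correlation between their
condensed vectors (missing entries excluded pairwise), yielding similarity
time courses (per timepoint), searchlight maps (per vertex), or ROI layer
profiles.  Peak latency is the earliest argmax of a course inside a
post-stimulus window; the hierarchy statistic is the per-subject Spearman
correlation between layer number and peak latency, averaged over subjects
and tested by sign permutation.

### Whole-model summary RDMs

Layers differ enormously in unit count, so concatenating raw activations
would let the widest layer dominate.  Each layer is therefore reduced by
PCA (features centred across conditions, no whitening, deterministic sign
convention) to *n* − 1 score dimensions — 117 for 118 conditions — and the
per-condition score blocks are concatenated across layers (117 × 8 = 936
dimensions for 8 layers) before the correlation RDM is computed.  Each
block is rescaled by a single scalar to unit root-mean-square first:
activation units are arbitrary and per-layer, and without the scalar the
rank correlation over the concatenated vector would not be invariant to
rescaling one layer.  A layer with fewer units than *n* − 1 contributes
what it has and is zero-padded to fixed width.

### Decoding engines

`e1071` (libsvm) is the classifier.  For *L* = 2 — one training vector
per class — the soft-margin linear SVM's decision boundary is exactly the
perpendicular bisector of the two training vectors, so predicted labels
have a closed form that vectorises over all condition pairs via Gram
matrices.  `decoding_rdm()` selects this engine automatically at *L* = 2
(the test suite asserts label-for-label equality with libsvm); it is an
exact shortcut, not an approximation, and makes whole-epoch,
multi-subject decoding runs cheap.

## Group inference

All group statistics are nonparametric over subjects.

* **Sign permutation**: under the null of zero mean effect, each
  subject's values may flip sign; signs are drawn per subject and applied
  jointly across all points, preserving within-subject temporal/spatial
  correlation.  The identity permutation is always included, so
  *p* ≥ 1/(n_perm + 1); an exhaustive mode enumerates all 2^n patterns.
* **Cluster-extent correction**: per-point permutation *p*-values are
  thresholded at the cluster definition threshold (*P* < 0.05, strict);
  contiguous supra-threshold points (consecutive timepoints, or connected
  mesh vertices) form clusters scored by extent with every point weighted
  equally.  The null is the maximal cluster extent per permutation, each
  permutation thresholded exactly like the observed data; a cluster is
  significant when its corrected *p* falls below the cluster threshold
  divided by a Bonferroni factor for families of maps (e.g. 16 = 8
  layers × 2 hemispheres).
* **FDR** (Benjamini–Hochberg) where no neighbourhood structure exists.
* **Subject-pool bootstrap** (default 1,000 resamples with replacement)
  for standard errors and percentile confidence intervals, including the
  divergence-time statistic of model-contrast curves.

A property worth knowing: on *temporally independent* null data the
max-extent distribution degenerates (nearly all mass at extent 1) and
cluster inference becomes very conservative.  Realistic similarity time
courses are smooth; the familywise-error calibration in the test suite
therefore uses null courses carrying the generator's 20 ms smoothing,
where the empirical false-positive rate sits at the nominal 5%.

### Onset and divergence definitions

Onset latency is defined as the first timepoint of the earliest
significant cluster at or after stimulus onset; the divergence time of a
model contrast is the first significant post-onset timepoint of the
two-sided cluster-corrected difference curve.  Both are assumptions the
package documents rather than settles — threshold-crossing definitions
exist and would differ on slowly rising curves.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated
against known ground truth without any recordings.  It emulates the
design of a 118-condition, 15-subject, 306-sensor MEG + fMRI experiment
(−100…+1000 ms epochs at 1 ms, 30 trials per condition, 100-voxel ROIs,
8 model layers), while tests and examples run scaled-down instances.

* Each layer *l* has a **target similarity matrix** drawn from a
  3-dimensional latent condition embedding (low dimensionality spreads
  the pairwise correlations widely, which keeps rank-correlation
  comparisons well conditioned) and a **latency**; defaults follow
  100 + 10·*l* ms, reversed for a descending hierarchy.
* Condition-by-feature patterns realise a target **exactly**: a zero-mean
  orthonormal basis is mixed through the target's matrix square root, so
  realized Pearson correlations equal the target entry-for-entry
  (requires features ≥ conditions + 1; below that, an approximate
  Gaussian draw).  Pattern substreams are keyed on the target's content,
  so identical targets yield identical draws.
* The **MEG signal** at time *t* mixes the layer patterns with Gaussian
  temporal kernels (SD 20 ms, matching the scale of standard 20 ms
  smoothing windows) centred on each layer's latency; i.i.d. Gaussian
  sensor noise is added per trial, and each trial is then smoothed with a
  centred 20 ms sliding window, as preprocessed evoked data would be.
  The smoothing is symmetric, so latencies are unbiased; its purpose is
  to give the noise the temporal correlation of real recordings (without
  it, peak-latency estimates are dominated by independent per-sample
  noise).
* **fMRI patterns** per region are weighted sums of layer patterns
  (weights in [0, 1], row sums ≤ 1) plus voxel noise; a region weighting
  low layers emulates early visual cortex, high layers an
  inferior-temporal-like area, all-zero weights a pure-noise control.
* **Noise images**: uniform [0, 1] per pixel and channel, convolved with
  a 10 × 10 Gaussian kernel of SD 80 px (nearly flat, reflective
  padding), giving mildly correlated noise with positive lag-1 spatial
  autocorrelation.
* All randomness flows from one master seed through named substreams
  (stage, layer, subject, repetition), so every fixture is bit-identical
  under a fixed seed.

### Calibration and scaled-down study sizes

The magnitude of condition-related signal relative to noise is a free
parameter; the default trial noise (`noise_sd = 10` against unit-variance
signal patterns) was chosen so that peak pairwise decoding accuracy lands
in the 70–85% range typical of visual MEG decoding, with pre-stimulus
accuracy at chance.  Voxel patterns are single-shot estimates, not
trial-level samples, so the spatial experiment scales the noise down
(`fmri_noise_scale = 0.1`, i.e. voxel noise SD equal to the signal SD —
per-voxel SNR 1, in line with condition-wise t-value patterns in strongly
responsive cortex).  The default end-to-end experiment
(`default_config()`) uses desk-scale sizes chosen once: 15 subjects, 16
conditions, 8 layers, 32 sensors, a −50…300 ms epoch at 5 ms steps,
*M* = 10 trials with *k* = 5 (so *L* = 2 and the closed-form engine
applies), 50 decoding repetitions, and 1,000-sample permutation
inference.  These sizes keep a full 15-subject hierarchy-recovery
experiment under a minute while leaving the recovery comfortably clean:
the injected 10 ms/layer gradient is recovered with group *R* > 0.9 and
the reversed generator flips the sign.

What the generator does *not* emulate: volume conduction and sensor
covariance, hemodynamics, eye movements, inter-subject anatomical
variability (all subjects share one mesh; the real-data subject-to-
template resampling step is out of scope), and any nonlinearity between
model features and measured signals.  Passing recovery tests shows the
pipeline's statistics behave as designed under these idealised
conditions — not that real recordings satisfy them.

## Searchlight geometry

Searchlight disks collect, for every mesh vertex, all vertices strictly
less than 9 mm away in geodesic space, mapped to voxels with each voxel
kept at most once per disk (deduplication happens after distance
selection).  Geodesic distance is the Dijkstra shortest path on the mesh
edge graph with Euclidean edge weights — with one refinement: for every
interior edge the two opposite vertices of the adjacent triangle pair are
also joined, at the length of the straight segment across the unfolded
pair (added only when that segment actually crosses the shared edge).
Pure edge-graph distances are markedly anisotropic — on a grid mesh a
diagonal neighbour against the triangulation direction costs 2·spacing
instead of √2·spacing — and this one-step unfolding, the first-order
member of the exact polyhedral geodesic family, removes most of that
bias; on a flat 3 mm grid it makes 9 mm disk membership coincide exactly
with the Euclidean disk.  `unfold = FALSE` restores the raw edge-graph
approximation.

## Numerical choices

* Pair order is lexicographic (*i* < *j*), fixed globally; serialization
  is plain text (condensed CSV at 17 significant digits for bit-exact
  round trips; square CSV with empty diagonal; OFF meshes; JSON
  manifests).
* Spearman ties use average ranks everywhere; constant pattern vectors
  make the correlation undefined and propagate as flagged missing
  entries, excluded pairwise downstream — never silently zeroed.
* Peak-latency ties resolve to the earliest timepoint (conservative for
  hierarchy-direction claims); the peak window defaults to post-stimulus.
* PCA components are ordered by variance with the largest-magnitude
  loading forced positive, so summary vectors are deterministic.
* Trials not divisible by *k* drop the surplus uniformly at random per
  repetition, keeping pseudo-trials equally weighted.
* The hierarchy group statistic is the mean of per-subject correlations
  (matching a per-subject sign-permutation test); the alternative —
  correlating subject-mean latencies — is easy to compute from the
  returned per-subject matrix but is not the default.
* Decoding accuracies are stored in percent (0–100); similarity values
  are Spearman R in [−1, 1].

## Limitations

* Only Spearman-based RDM comparison and the two dissimilarity metrics
  above are provided (no Pearson/Euclidean/crossnobis variants, no
  partial-correlation layer-unique analysis, no volumetric searchlight).
* The SVM uses a fixed regularization constant of 1 and no feature
  scaling; hyperparameter search is out of scope.
* Cluster inference assumes exchangeable subjects and, for its nominal
  error rate, temporally (or spatially) correlated signals; on unsmoothed
  independent points it is valid but conservative.
* The generator's idealisations above mean real-data channel handling
  (e.g. gradiometer/magnetometer unit harmonization) must be documented
  by the user; the reader functions accept any numeric trial tensor.
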