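---
title: "From ECG signals to binary images: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ECG signals to binary images: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgimage)
```

## The problem and the approach

Ventricular tachyarrhythmias — ventricular tachycardia (VT), fibrillation
(VFIB) and flutter (VFL) — are fast, life-threatening rhythms that an
electrocardiogram (ECG) records as characteristic deviations from normal
sinus rhythm (NSR). `ecgimage` implements a detection pipeline that avoids
QRS detection and signal pre-processing entirely: the raw one-dimensional
signal is reshaped into small binary images, image-level features are
extracted through fixed (pretrained-style) network backends, fused,
reduced by an entropy criterion, and classified with conventional
supervised learners.

The stages are:

1. **Truncate** each record to the largest whole number of 1,024-sample
   segments (`truncate_to_multiple()`). A 127,356-sample record loses its
   trailing 380 samples, leaving 126,976.
2. **Segment** into consecutive non-overlapping windows
   (`segment_signal()`): 124 segments for the record above.
3. **Inverse-vectorize** each 1,024-vector into a 32×32 matrix
   (`devectorize()`). The reshape is the inverse of column-stacking
   vectorization, `vec(A) = [a11, …, am1, a12, …]ᵀ`: entry *(i, j)* of the
   image is segment element *j·32 + i* (0-based), and re-vectorizing
   recovers the segment exactly.
4. **Binarize** (`binarize()`) into strictly {0, 1} pixels.
5. **Expand** to CNN input geometry when a backend needs it
   (`to_model_input()`): grayscale = 255 × pixel, nearest-neighbour
   upscaling to 224 or 299, three identical channels.
6. **Extract and fuse features** (`extract_features()`,
   `fuse_features()`): per-image feature vectors from each configured
   backend, concatenated column-wise. With the three published backend
   widths — 4,096 (AlexNet FC7 geometry), 4,096 (VGG19 FC7) and 2,048
   (Inception-v3 avg-pool) — the fused vector has 10,240 entries.
7. **Select by entropy** (`feature_entropy()`, `select_by_entropy()`):
   per-feature histogram entropy, ascending sort, keep a configured
   fraction (0.5 keeps exactly 5,120 of 10,240).
8. **Evaluate** (`run_experiment()`): stratified 50:50 holdout or
   stratified 10-fold cross-validation over a roster of SVM, discriminant
   and KNN classifiers, reporting sensitivity, specificity, FNR, accuracy
   (percent) and F-score.

## The binarization rule

How continuous signal values become binary pixels is genuinely open: the
digitization step admits several readings. The package's default —
per-image min–max scaling to [0, 1] followed by a strict threshold at 0.5
— was chosen because per-image scaling makes the images invariant to
positive affine rescaling of the signal (gain and offset), which matches
the pipeline's claim of needing no amplitude calibration or
pre-processing. A constant matrix maps to all-zero pixels, and a scaled
value exactly at the threshold maps to 0 (strict `>`). A mean-threshold
variant is available via `binarize(method = "mean")`, and the reshape
order can be flipped to row-major for sensitivity analysis. These are
documented package assumptions, not a prescribed rule.

## Feature backends

The three CNN backend names carry their published output geometry and are
intended to run inference-only with frozen ImageNet weights. This package
does not ship network weights or a deep-learning runtime, so invoking them
raises an explicit environment error pointing at the **stub backend**. The
stub is a first-class, fully deterministic backend: a seeded random linear
projection of the flattened image followed by a clamp-at-zero (ReLU)
nonlinearity,

\[ f = \max(0,\; xW + b), \qquad W_{ij} \sim N(0, 1/d_{in}),\ \text{fixed by `stub_seed`.} \]

Random projections approximately preserve pairwise geometry
(Johnson–Lindenstrauss), so class structure visible in the binary images
survives into feature space; the clamp makes the features sparse and
non-negative like late CNN activations. The stub is what every test and
the end-to-end evaluation use. It is a backend in its own right, with any
`output_dim`; its default input side is 32, i.e. it consumes the binary
images directly without the 224/299 expansion.

## Entropy-based selection

Each fused feature column *j* is scored by the Shannon entropy of its
empirical histogram over `n_bins = 256` equal-width bins spanning that
column's own range:

\[ H_j = -\sum_i p_i \log_2 p_i, \qquad p_i = \text{count}_i / n, \quad 0\log 0 := 0 . \]

A constant column scores 0; the maximum is \(\log_2 n_{bins}\) bits = 8.
Selection sorts the entropy vector — **ascending by default**, ties broken
by ascending column index — and keeps the first
\(\max(1, \mathrm{round}(f \cdot D))\) features (half-away-from-zero
rounding, so \(f = 0.5\) of 10,240 keeps exactly 5,120). Keeping the
low-entropy end follows the letter of the procedure this pipeline
reconstructs; because retaining near-constant features is
counter-intuitive, the conventional direction is exposed as
`order = "descending"` and both are tested. No label information enters
the criterion.

## Classifier roster

The roster names correspond to MATLAB Classification Learner presets,
which are named without parameters; the configurations here are documented
reconstructions, all overridable through `classifier_spec()`:

| name | configuration |
|---|---|
| linear/quadratic/cubic SVM | polynomial kernel degree 1/2/3, `coef0 = 1`, cost 1, one-vs-one |
| linear discriminant | LDA on z-scored features |
| fine / medium KNN | Euclidean, k = 1 / k = 10 |
| cubic KNN | Minkowski p = 3, k = 10 |
| weighted KNN | k = 10, inverse-squared-distance weights |
| subspace discriminant / KNN | random subspace, 30 learners, dimension ⌈D/2⌉, LDA or 1-NN base |

SVMs and discriminants see features z-scored with training-half statistics
only; KNN variants operate on raw features. KNN vote ties and ensemble
vote ties break toward the earliest class level, which makes every
prediction deterministic given the seed. Metrics are macro-averaged
one-vs-rest because the task is multi-class while the metric suite is
reported as single numbers; `FNR = 100 − sensitivity` holds exactly by
construction. The 50:50 holdout and 10-fold CV are two separate protocols
chosen per run — they answer the same question at different variance, and
combining them in a single run would conflate their test sets.

## The synthetic generator

`generate_record()` emulates single-rhythm two-lead records at 360 Hz
(MIT-BIH convention), default length 127,356 samples (two stated
per-patient lengths circulate for this kind of record — approximately
127,232, and 127,356; the generator uses 127,356 because only it yields
126,976 = 124 × 1,024 after the 380-sample tail drop). The class models
are:

* **NSR** — sum-of-Gaussian P-QRS-T template repeated with RR ~
  Normal(0.8 s, 0.05 s);
* **VT** — wide monomorphic complexes without a P wave, RR ~
  Normal(0.35 s, 0.01 s);
* **VFIB** — eight random-phase sinusoids with frequencies ~ Uniform(4,
  10) Hz and amplitudes resampled every second;
* **VFL** — a single 5 Hz sinusoid under slow (0.1 Hz) amplitude
  modulation;

all plus Gaussian noise (`noise_sd = 0.05`, in the same arbitrary mV-like
units as the unit-amplitude R wave) and a 0.3 Hz baseline-wander sinusoid
of amplitude 0.1. Lead II is an attenuated copy of lead I with independent
noise. These waveforms are stand-ins chosen for class separability, not
physiological fidelity: no ectopy, no mixed rhythms, no realistic P/T
morphology variation, no electrode artefacts. Consequently, passing the
end-to-end checks demonstrates that the pipeline's machinery is correct
and discriminates class-distinct morphology; it does not establish
clinical performance on real recordings, which additionally depends on the
real databases and on genuine pretrained CNN features.

## Problem sizes and numerical choices

The transformation arithmetic is checked on a full 127,356-sample record
(it runs in well under a second). The end-to-end evaluation uses a cohort
of 4 classes × 30 records of 8,192 samples each — 8 images per record, 960
images, 10,240 stub features reduced to 5,120 — which a 10-fold cubic-SVM
cross-validation completes in a few minutes on one CPU; at these settings
the pooled CV accuracy sits at or near 100%, far above the 25% chance
level. Record length is the one place the evaluation deviates from the
127,356-sample default: it multiplies runtime roughly 15-fold without
changing what the check demonstrates.

Other numerical choices: the tail drop is computed as `n mod L`, never
hard-coded 380; all dimensional constants (1,024; 32; 224; 299) are
configuration values with the published numbers as defaults; histogram
entropy uses left-closed bins with the column maximum folded into the last
bin; `sd = 0` columns standardize by 1; a record shorter than one segment
yields an empty, warned-about result rather than padding.

## Persistence

Binary images persist as lossless 8-bit grayscale PNGs (pixel 255 ↔ 1 —
written through the `png` package, which does not emit 1-bit depth;
round-trips are still bit-exact) next to a CSV manifest. Records persist
in a minimal WFDB dialect (text header plus 16-bit little-endian samples;
formats 16 and 212 are read). Selections persist as JSON with indices,
entropies and configuration, so experiments replay exactly.

## Known limitations

* The pretrained backends are declared but not runnable without an
  external deep-learning runtime and weights; results with the stub do not
  transfer to claims about CNN features.
* The annotation reader accepts a plain-text event table, not the binary
  `.atr` format.
* No resampling between sampling rates and no multi-lead fusion: the
  transform consumes one configured lead.
* The generator produces rhythm-homogeneous records only.
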