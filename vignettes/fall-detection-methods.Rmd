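---
title: "Class-based ensemble fall detection from waist-worn inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-based ensemble fall detection from waist-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Falls among elderly people are brief — the descent itself lasts on the order
of 0.8 s — and a monitoring system that only reacts after ground impact can
do nothing to soften it. The pipeline in this package therefore treats fall
monitoring as a **three-class, per-window classification problem** over
waist-worn accelerometer and gyroscope streams:

* **Non-Fall** — ordinary activities of daily living (ADLs);
* **Pre-Fall** — the interval in which the person transitions from a
  controlled to a dangerous state that may end in a fall (the window in which
  a protective device could still be triggered);
* **Fall** — the fall itself, through impact.

`fallnet` implements the full method: SisFall-dialect ingestion, filtering
and normalization, overlapping block segmentation with majority-vote labels,
label-preserving online augmentation, a class-based ensemble network trained
with weighted binary cross-entropy under a subject-wise protocol, and
per-event evaluation. A synthetic multi-subject generator makes every stage
testable without any data download.

## Preprocessing

Raw trials are rows of integer ADC counts at 200 Hz; per-sensor linear
factors (defaulting to the published SisFall device constants) convert them
to g and deg/s. The default input keeps the first accelerometer plus the
gyroscope: six channels.

Each channel is low-pass filtered with a Butterworth filter. The order and
cutoff are free parameters; the defaults are 4th order and 5 Hz, the usual
choice for human-movement accelerometry, applied forward–backward so the
filter is zero-phase and sample labels stay aligned with samples.

Normalization is per-channel z-scoring followed by hard clipping into
[-1, +1]. Z-scores are unbounded, so z-scoring alone cannot produce a
bounded range; clipping preserves both stated properties (standardized
location/scale and boundedness). `minmax` and `zscore_tanh` are selectable
alternatives. Statistics are **fitted on training subjects only** and frozen
for validation and test — under a subject-wise protocol anything else leaks
test information into training.

Segmentation uses fixed-width windows of 256 samples (1.28 s at 200 Hz) with
50% overlap; windows start at multiples of
`stride = round(W * (1 - overlap))`, 0-based and half-open, and a trailing
partial window is discarded. A block inherits the most frequent per-sample
label it covers. Ties are broken by severity (`Fall > Pre-Fall > Non-Fall`):
a missed fall is costlier than a false alarm. This tie-break priority is
shared with score fusion and is configurable.

## The network

The architecture separates *what a movement looks like* from *which event it
is*:

* **Head model** — a shared convolutional feature extractor. Each of the
  (default three) "skipped" blocks is
  `conv -> activation -> conv -> additive shortcut -> pooling (stride 2)`,
  with a 1x1 projection on the shortcut when widths change. With three
  blocks a `(256, 6)` input becomes a `(32, 16)` temporal feature map. The
  default convolutions are separable (depthwise then pointwise), activation
  is swish, pooling is max — max pooling preserves the high peaks that
  characterize impacts.
* **Ensemble model** — one recurrent sub-model *per class*, each a stack of
  (default two) width-16 LSTM layers reading the head's feature map as a
  32-step sequence, then dropout (default 0.5) and a single sigmoid unit.
  Each sub-model is a one-vs-rest detector for its class; sub-model
  parameters are pairwise disjoint outside the shared head.
* **Fusion** — the predicted class is the argmax over the per-class sigmoid
  scores, with the severity priority deciding exact ties. Stacked and
  weighted-average combiners are provided as reference variants for
  comparison experiments; the weighted combiner's weights have no principled
  default and default to 1.

Where the block internals were open design choices we fixed: two
convolutions per residual block, kernel size 5, pooling width 2/stride 2,
and dropout placed after the recurrent stack (immediately before the output
unit). All are configurable through `ensemble_spec()`.

The layers themselves — separable and standard 1-D convolution, residual
blocks, max/average pooling, LSTM/GRU/BiLSTM, dropout, Adam — are
implemented in the package (vectorized R over BLAS, with the convolution
kernels in C++). Every backward pass is verified against central finite
differences in the test suite, and recurrent parameter counts against the
closed forms `4(H(H+I)+H)` (LSTM) and `3(H(H+I)+H)` (GRU).

## Augmentation

Three label-preserving transforms diversify training data *online* (during
batch assembly; nothing is written to disk):

* **Rotation** — one random 3-D rotation per block (axis uniform on the
  sphere, angle uniform in (-pi, pi)) applied to every xyz triplet of every
  timestep. Accelerometer and gyroscope rotate with the same matrix, since a
  physical re-orientation of the device rotates both sensors identically.
  This simulates unknown sensor mounting orientation.
* **Scaling** — one scalar per block from N(1, 0.1); small enough to
  preserve labels while varying motion intensity.
* **Jitter** — element-wise Gaussian noise with sd 0.01, simulating sensor
  noise.

For each training batch, exactly half the blocks (uniformly without
replacement) are replaced by transformed copies; each selected block
receives exactly one transform, drawn from configurable probabilities
(default uniform — the selection probabilities are free parameters with no
stated values). Whether scaling should draw per block or per channel is
ambiguous; per block is the default, per channel an option.

## Training protocol

Adam with initial learning rate 0.0005, batch size 128, up to 200 epochs
(optional early stopping). The loss is weighted binary cross-entropy: each
sub-model is supervised one-vs-rest, and per-class weights counteract the
heavy Non-Fall majority. The weighting scheme itself was an open choice; the
default is inverse frequency `w_c = N / (n_classes * N_c)` normalized to a
unit minimum, with explicit overrides allowed.

The split is subject-wise: complete subjects form the test partition
(defaulting to four young plus two elderly, drawn deterministically from a
seed when not named explicitly — the published protocol names the group
sizes but not the individuals). Remaining blocks are split 80/20 into
train/validation, stratified per class by largest-remainder rounding so the
total is exact and every class deviates by less than one block. The 80–20
unit was ambiguous between blocks and trials; per-block stratified is the
default. Replicate mode trains the same configuration under three seeds and
reports mean ± sd.

## Evaluation

Because Non-Fall dominates, pooled accuracy is uninformative; the report
computes accuracy, sensitivity, and specificity **per event** from
one-vs-rest confusion counts, plus the 3x3 confusion matrix and per-class
ROC curves (threshold sweep over all unique scores). A 0/0 metric cell is
reported as missing, never as 0 or 1, so degenerate test sets cannot inflate
results. ROC aggregation across classes is not well defined, so curves are
emitted per class.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes — it is a phenomenological signal model (gravity projection +
band-limited gait oscillation + event templates + Gaussian noise), not a
biomechanical simulation, and it makes no attempt to match any real
dataset's per-activity statistics:

* **ADL** trials: gravity-dominated quasi-periodic movement; the
  acceleration norm stays within `adl_amplitude_g` (default 0.3 g) of 1 g.
* **Near-fall** trials: a hazard interval in which the body tips out of its
  controlled posture — a sustained drift of the gravity direction plus a
  slow large sway (2–3 Hz, deliberately inside the low-pass band so the
  signature survives the pipeline's own filtering) and sustained large
  angular rates — then recovery. Labeled Pre-Fall.
* **Fall** trials: a brief 0.3 s pre-impact transition, then a 0.8 s Fall
  segment containing a free-fall dip, an impact peak (default 5 g, >2x the
  ADL envelope), and post-impact rest in a lying orientation.

Two event durations are deliberately distinct. The pre-impact transition of
a fall is brief (0.3 s); the hazard interval of a *near*-fall — a dangerous
situation the person recovers from — is sustained (default 1.5 s). With
256-sample majority-labeled windows, a sub-0.65 s event can never be the
plurality label of any window, so extended hazard intervals are also what
makes the Pre-Fall class representable at the block level, consistent with
annotation practice for alert events.

Subjects get individual gait frequency (young ~1.9 Hz, elderly ~1.4 Hz),
amplitude, phase, and mounting-tilt offsets, which is what makes
subject-wise splits meaningful. Trial kinds mix at 12% ADL / 33% near-fall /
55% fall by default, chosen together with 60 six-second trials per subject
so that after segmentation the minority classes have a few hundred blocks
each while Non-Fall dominates (roughly 2300 / 230 / 350 blocks at the
default seed) — large enough to train and evaluate on a desk, small enough
for minutes-scale runs. The `hard` preset narrows the separations
(2 g impacts, wider gait amplitude, more noise, weaker hazard rates) to
exercise imbalance handling rather than to be solvable to the same standard.

What passing the synthetic study shows — and what it does not: it
demonstrates that the implementation (preprocessing, augmentation,
optimization, fusion, evaluation) is correct and that the architecture can
learn all three classes under subject-wise transfer at realistic imbalance.
It does not certify performance on real falls: real inter-subject
variability, sensor artifacts, and the diversity of genuine ADLs are far
richer than the generator's three templates.

## The desk-scale experiment

`run_synthetic_experiment()` is the package's end-to-end study: 6 subjects
(4 young, 2 elderly), one young and one elderly held out — with only six
subjects, larger test rosters would leave too few training subjects —
normalization statistics fitted on the training subjects, three replicate
training runs of 30 epochs each (the loss plateaus there at this data
scale), and per-event metrics on the held-out subjects. The same experiment
backs `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Sigmoid outputs are clipped at 1e-7 inside the loss to guard `log(0)`.
* A zero-variance channel gets sd 1 (with a warning) instead of dividing by
  zero; a zero configured scale factor is rejected outright.
* Max-pooling ties route the gradient to the earlier timestep.
* Weight initialization is Glorot-uniform; the LSTM forget-gate bias starts
  at 1.
* Trials shorter than one window segment to zero blocks (with a notice),
  not an error; trials shorter than `3 * filter_order` cannot be filtered
  and are rejected.
* All indices are 0-based with half-open windows at the API surface, matching
  the windowing arithmetic.

## Known limitations

* The generator's realism limits what the synthetic study can certify (see
  above); real-data runs use the same reader but are out of scope here.
* Training is CPU-bound, single-threaded R + BLAS; at the default desk
  scale a replicate takes a couple of minutes, but the code is not meant for
  full-dataset deep-learning workloads.
* Only the Adam optimizer is provided, and convolution stride/pool width
  are fixed at 2.
* Filtering precedes normalization; the reverse order is not offered.
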