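---
title: "From paper ECG printouts to VPC screening: methods and design notes"
author: "vpcECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paper ECG printouts to VPC screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcECG)
```

## The problem

Ventricular premature complexes (VPC) are intermittent: a patient's
resting 12-lead ECG is usually in normal sinus rhythm (NSR) even when the
patient has frequent VPC episodes, so a single printout read by eye is a
poor screening test. The structural myocardial changes that accompany VPC
are, however, thought to leave subtle signatures in the NSR waveform
itself. `vpcECG` implements a complete pipeline for exploiting that idea
when the primary data are *paper printouts* rather than digital signals:

1. **Digitization** — turn a scanned red-grid 12-lead printout into a
   clean 1250 x 12 numeric tensor (2.5 s per lead at 500 Hz);
2. **Classification** — three convolutional network families (a 2-D model
   over the 256 x 512 x 3 resized image, a single-input 1-D model over the
   1250 x 12 tensor, and a 12-branch multi-input 1-D model over one lead
   per branch);
3. **Protocol** — patient-disjoint train/validation/test splitting and
   threshold-based diagnostic evaluation with bootstrap confidence
   intervals;
4. **Synthetic ground truth** — a printout renderer with exact per-pixel
   labels, so every stage of 1–3 can be validated end to end without
   access to hospital data.

## Digitization

A standard printout lays the 12 leads out as four vertical sub-images,
each holding 2.5 s of three leads plus the long lead II rhythm strip —
four traces per pixel column, 250 columns per sub-image. The chain is:

* **Grid removal** (`removeGrid`): a pixel is grid if its red dominance
  `R - max(G, B)` exceeds 30 (configurable). This is robust to
  anti-aliased grid edges, unlike exact colour matching; dark trace ink
  always fails the predicate. Non-grid pixels are converted to grayscale
  with the conventional luma weights (0.299, 0.587, 0.114). The operation
  is idempotent.
* **Crop** (`cropToSignal`): tight bounding box of non-background content
  plus a small margin; the offset is recorded so later stages can map
  printout coordinates into the cropped frame.
* **Binarize/invert** (`binarizeInvert`): intensity below 128 becomes
  foreground 255, the rest 0. After grid removal the ink is near-black,
  so the threshold is uncritical.
* **Sub-image split** (`splitSubimages`): boundaries come from the layout
  when it is known (always, for rendered records), otherwise from blank
  column valleys. Slices are padded to exactly 250 columns so column
  index remains a time axis.
* **Column scan and grouping** (`scanColumns`, `groupTraces`): each
  column's foreground rows are clustered into runs — a gap of more than
  3 px starts a new run, since a continuous pen stroke cannot skip that
  far within a column. A run's value is its centroid (mean row), which is
  symmetric with respect to line thickness; the topmost pixel would bias
  thick strokes upward. Runs are assigned to the nearest of the four
  traces, ties to the upper trace. "Nearest" is measured against the
  trace's previously assigned row when available (tracking), falling back
  to the static baseline: this follows large excursions (an R wave
  crossing a neighbouring band) that a static assignment would misfile.
  Extra runs landing on one trace merge by pixel-weighted centroid; a
  trace absent from a column yields a missing marker.
* **Assembly** (`assembleLeads`): rows become amplitudes via
  `baseline - row` (image rows grow downward, so up is positive), in
  pixel units — absolute mV calibration is deliberately out of scope
  because the final normalization removes it anyway. Interior gaps are
  filled by linear interpolation, edge gaps by holding the nearest known
  value; a lead missing in more than half its columns is an error, not a
  guess. The rhythm strip is extracted the same way but kept out of the
  12-lead tensor (the model input is defined as the 12 leads); it is
  returned as an attribute.

### Conditioning

The 250-point series are up-sampled to 1250 points by linear
interpolation (endpoints exact; linear interpolation cannot overshoot, so
the amplitude range is preserved), low-pass filtered, and normalized.

The filter is a **Butterworth low-pass, cut-off 15 Hz, order 3** —
Butterworth because a maximally-flat passband is the natural default when
the only stated requirements are the cut-off and order. It is applied
zero-phase by default (forward + backward): classification consumes
morphology, not timing, and zero-phase filtering avoids shifting the QRS
relative to the image-derived ground truth; the squared magnitude
response that results is documented in `FilterConfig` and tested. Both
passes reflect-pad by one signal length so start-up transients decay
outside the reported window — equivalently, the filter starts at its
steady state, and the DC gain inside the window is 1 to within 1e-6.
Filtering happens after up-sampling and before normalization, matching
the processing order of the pipeline stages above.

Normalization is per-lead min–max to [0, 1]. Min–max (rather than
z-scoring) maps every lead onto the same bounded "unified scale"
regardless of its amplitude; a constant lead maps to 0.5, the midpoint,
so degenerate inputs remain finite and centred. The operation is
idempotent and invariant to per-lead positive affine transforms.

`digitizeEcg` composes the whole chain deterministically and prefixes any
stage failure with the stage name.

## Synthetic records

`generateWaveform` builds each beat from Gaussian deflections (P, Q, R,
S, T) at the requested heart rate and projects the common template onto
the 12 leads through a fixed scaling table with conventional polarities
(aVR and the right precordials predominantly negative). Fixing the table
makes every record reproducible from its seed alone. Additive white noise
and a slow sinusoidal baseline wander are optional knobs.

The VPC class is *not* given an actual ectopic beat — the classified
records are NSR by construction, as in the screening setting. Instead a
smooth morphology perturbation scaled by `classEffectSize` is applied: a
low-frequency hump on the terminal portion of the QRS (centre R+0.16 s,
FWHM 0.14 s, amplitude `0.4 * effect * qrsAmp`) together with a
proportional T-amplitude increase (factor `1 + 0.4 * effect`). Both terms
vanish at effect 0, so the two class generators are then identically
distributed — a property the tests verify with a permutation test. The
hump survives the 15 Hz low-pass (its energy sits well below 10 Hz) and
the T-ratio change survives min–max normalization, so both input
representations carry the signal.

`renderEcgImage` draws a 250-pixel-high, 1000-pixel-wide printout: a
periodic grid (minor lines every 5 px, major every 25 px, light red —
separable from ink by the red-dominance predicate), and each trace as
per-column vertical spans. A column's span runs between the rounded
midpoints toward its neighbouring samples, which keeps adjacent columns
4-connected (a continuous pen stroke) while leaving the span centred on
the sample's own row — so the extractor's centroid is an unbiased
estimate of the drawn value. Amplitudes map to rows at 20 px per unit
around baselines at rows 35/95/155/215. The record stores a per-pixel
{background, grid, trace} classification and the exact drawn row of every
(sub-image, trace, column) cell; these are the oracles for the
preprocessing and extraction tests. Pixel quantization is the dominant
round-trip error: at 20 px per unit the smallest-amplitude lead (aVL,
scale 0.35) retains r ≈ 0.99 against the drawn trace and ≈ 0.989 against
the continuous truth before filtering.

`generateCohort` draws each patient's waveform parameters once (heart
rate 55–95 bpm, QRS amplitude 0.8–1.2, small noise and wander) and an
independent realization per record, so records of one patient are similar
but not identical — the property that makes patient-disjoint splitting
matter. Class labels are allocated deterministically
(`round(balance * nPatients)` VPC patients, shuffled); every record
inherits its patient's label. With `materialize = FALSE` only the
manifest and per-record seeds are kept and `cohortRecord` regenerates any
record bit-identically on demand, which keeps memory constant for
cohorts of hundreds of patients.

**What the generator does not emulate:** photographed or skewed scans,
calibration pulses, lead-label text, printer artefacts, pathological
morphologies beyond the smooth class perturbation, or genuinely
heterogeneous per-lead morphology (leads differ only by scaling). Passing
tests therefore demonstrate that the pipeline and models are correct and
learnable on clean axis-aligned printouts with a known layout — not that
the classifier transfers to hospital scans.

## Models

All three families are built on the package's own batched conv-net
engine (index-gather im2col plus BLAS products; exact gradients are
verified against finite differences in the engine's development tests).

* **2-D image model** (`buildImageModel`): backbone → global average
  pooling → dense(512, ReLU) → dropout(0.5) → dense(2) with softmax. The
  backbone registry offers `TINY` (an average-pool stem followed by three
  conv/BN/ReLU + max-pool stages, 24k parameters — the CPU-scale default)
  and compact from-scratch variants of the five classic families (VGG-style
  plain stack, pre-activation residual bottlenecks, multi-branch
  inception concatenation, residual-inception hybrid, depthwise-separable
  stack). The variants preserve each family's topology at reduced width;
  they are not weight-compatible with the originals, and pretrained
  transfer weights are out of scope.
* **1-D models** (`buildTsModel`): blocks of conv(kernel k, stride 3) →
  batch norm → ReLU → max-pool(size 5, stride 3), then GAP. The
  single-input model runs one stack over the (1250, 12) tensor with
  dropout 0.5 before the 2-way output; the multi-input model runs 12
  weight-independent branches over (1250, 1) — implemented as grouped
  (block-diagonal) convolutions, which is algebraically identical to 12
  parallel branches with concatenated GAP features — and connects the
  1536 concatenated features directly to the 2-way output, without
  dropout. Kernel sizes 3/5/7/9/11 are the studied sweep
  (`kernelSizeGrid`, `sweepKernels`); defaults are 7 (single) and 11
  (multi), the best-performing sizes of the sweep.

Block depth is adaptive: with filters (32, 64, 128, 256) and the stated
strides, length 1250 supports three conv blocks (416 → 137 → 44 → 14 → 3
for kernel 7) — a fourth conv cannot fit, and pooling is skipped whenever
the length falls below the pool size. The builder therefore drops blocks
that no longer fit rather than failing, and `modelSummary` shows the
realized shapes; the shape arithmetic `floor((L - k)/3) + 1` and
`floor((L - 5)/3) + 1` under valid (no) padding is tested against the
closed form for every kernel size.

Weight initialization is He-style and fully seeded; dropout is disabled
and batch normalization uses running statistics at inference, so
prediction is deterministic. Batch-norm running statistics use momentum
0.8, which converges within the few hundred optimizer steps of a
desk-scale run while remaining stable.

## Training and evaluation protocol

`trainConfig` defaults follow the study protocol: Adam at learning rate
0.0011, categorical cross-entropy, batch size 32, up to 400 epochs,
early stopping with patience 250. The monitored quantity is the
validation loss (with best-weights restoration); monitoring loss rather
than accuracy is the conventional choice when the protocol does not say.

`splitByPatient` draws whole patients into the validation set until it
holds exactly 50 records, then the test set until exactly 100, the rest
training — records of one patient never cross partitions. Exactness is
achieved by skipping patients that would overshoot and reshuffling if a
pass fails; the retry budget makes the draw deterministic under its seed.

`evaluateScores` builds the ROC over all distinct score thresholds
(positive if score ≥ threshold), computes the AUC by the trapezoidal
rule — identical to the normalized Mann–Whitney count, which the tests
verify by brute-force pair counting — and selects the cut-point
maximizing Youden's J = sensitivity + specificity − 1. Youden's J is used
because the protocol names "optimal cut-points" without a criterion and J
is the standard choice; ties are broken toward higher specificity (a
screening test should not over-call). Accuracy, sensitivity, specificity,
PPV and NPV are reported at that cut-point. The 95% confidence intervals
are class-stratified bootstrap percentile intervals (2000 resamples,
seeded), with the threshold held at the point estimate and the AUC
recomputed per resample; the bootstrap is used because the reference
implementation's CI method is not stated and its printed intervals are
not reproducible as standard binomial intervals. Percentile intervals are
clamped to contain the point estimate.

## Problem sizes used by the tests and the acceptance script

The suite exercises the full pipeline at sizes a single CPU handles
comfortably, chosen once and stated here as the package's own study
conditions:

* digitization round trip: 50 noise-free records;
* split safety: 10,000 random rosters with exact 50/100 targets;
* end-to-end learnability: a 700-patient cohort with 1–2 records per
  patient (≈1050 records — about the per-patient record density of a
  typical retrospective NSR archive), class effect size 1, `TINY` image
  backbone, default single-input widths, and per-branch widths
  (8, 16, 32, 64) for the multi-input model; training runs 12–15 epochs
  with patience 5–6. All three families are required to reach test AUC
  ≥ 0.90 on the patient-disjoint 100-record test set.
* `scripts/acceptance.R` reruns the same stages at a reduced 200-patient
  scale plus the structural and filter checks, and writes every number it
  computes as JSON.

## Known limitations

* The renderer's grid geometry and 20 px-per-unit calibration are an
  emulation of red-grid printouts, not a reconstruction of any specific
  device's output; real scans additionally need deskewing and
  perspective correction, which are out of scope.
* Lead identity is positional: the extractor trusts the layout rather
  than reading printed lead labels.
* The engine is CPU-bound R; it is sized for desk-scale experiments, not
  for training full-width ImageNet-class backbones.
* Synthetic separability says nothing about clinical accuracy; the
  clinical numbers of the original setting require the original hospital
  records, which are not distributable.
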