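# vpcECG

Screening for ventricular premature complexes (VPC) from **paper ECG
printouts** recorded during normal sinus rhythm (NSR). The package is for
researchers whose 12-lead ECGs exist as scanned red-grid printouts rather
than digital signals: it digitizes the printouts into clean numeric
tensors, trains convolutional classifiers on either the image or the
recovered time series, and evaluates them under a patient-disjoint
protocol.

## What it does

**Digitization.** A standard printout shows four vertical sub-images,
each with 2.5 s of three leads plus a long lead II rhythm strip (four
traces per pixel column, 250 columns per sub-image). `digitizeEcg` runs
the full chain

> grid removal → crop → binarize/invert → sub-image split → pixel-column
> scan → nearest-trace grouping → lead assembly → linear up-sampling →
> IIR low-pass → per-lead normalization

producing a 1250 × 12 tensor (2.5 s at 500 Hz, leads I, II, III, aVR,
aVL, aVF, V1–V6). Grid pixels are identified by red dominance
(R − max(G, B) > 30); each column's ink runs are clustered (row gap > 3 px
starts a new run) and assigned to the nearest of the four traces with
tracking across columns; amplitudes are `baseline − row` in pixel units;
the low-pass is a zero-phase order-3 Butterworth with 15 Hz cut-off,

    |H(f)| = 1 / sqrt(1 + (f / f_c)^(2n)),   f_c = 15 Hz, n = 3

applied forward and backward; normalization is per-lead min–max to
[0, 1].

**Models.** Three CNN families, built on the package's own seeded,
CPU-oriented conv-net engine:

* a 2-D image model over the 256 × 512 × 3 resized printout
  (backbone → GAP → dense(512) → dropout 0.5 → softmax(2); backbone
  registry: `TINY`, `VGG16`, `ResNet50V2`, `InceptionV3`,
  `InceptionResNetV2`, `Xception` — the named ones are compact
  from-scratch family variants),
* a single-input 1-D model over the 1250 × 12 tensor, and
* a multi-input 1-D model with 12 weight-independent branches, one per
  lead (1250 × 1 each), with concatenated GAP features.

1-D blocks are conv(kernel k, stride 3) → batch norm → ReLU →
max-pool(5, stride 3); kernel sizes {3, 5, 7, 9, 11} form the supported
sweep (`sweepKernels`), with defaults k = 7 (single) and k = 11 (multi).
Training is Adam (learning rate 0.0011), categorical cross-entropy,
batch 32, early stopping on validation loss.

**Protocol.** `splitByPatient` draws whole patients until the validation
set holds exactly 50 records and the test set exactly 100 — no patient
ever crosses partitions. `evaluateScores` reports the ROC AUC
(trapezoidal = Mann–Whitney), the Youden-optimal threshold, accuracy,
sensitivity, specificity, PPV and NPV, each with stratified-bootstrap
95% confidence intervals.

**Synthetic ground truth.** `generateCohort`/`renderEcgImage` create
labeled printout images with exact per-pixel {background, grid, trace}
truth and per-column drawn trace rows, so every pipeline stage is
validated against known answers. The VPC class receives a smooth,
seedable morphology perturbation (no actual ectopic beats — records stay
NSR, as in the screening setting).

## Worked example

```r
library(vpcECG)

## one synthetic VPC-class printout, digitized
params <- waveformParams(classLabel = "VPC", classEffectSize = 1)
sig    <- generateWaveform(params, seed = 7)
rec    <- renderEcgImage(sig, recordId = "R0001", patientId = "P0001",
                         label = "VPC")
rec
#> SyntheticRecord R0001 (patient P0001, label VPC)
#> EcgImage 'R0001': 250 x 1000 RGB, 4 sub-images of 250 columns

tensor <- digitizeEcg(rec@image)
tensor
#> SignalTensor: 1250 x 12 (2.5 s @ 500 Hz), range [0.000, 1.000]

## a small labeled cohort, patient-disjoint split, one classifier
co  <- generateCohort(40, recordsPerPatient = c(1, 2),
                      classEffectSize = 1, seed = 11, materialize = FALSE)
man <- cohortManifest(co)
sp  <- splitByPatient(man, targetValN = 10, targetTestN = 15, seed = 3)
tens <- lapply(seq_len(nRecords(co)), function(i)
  tensorValues(digitizeEcg(cohortRecord(co, i)@image)))
mk <- function(s) {
  i <- which(sp$split == s)
  list(x = tens[i], labels = man$label[i], patients = man$patient_id[i])
}
fit <- trainModel(buildTsModel(tsModelSpec("single"), seed = 1),
                  mk("train"), mk("validation"),
                  trainConfig(epochs = 10, patience = 4, seed = 2))
p <- predictProba(fit$model, mk("test")$x)[, "VPC"]
evaluateScores(p, mk("test")$labels, seed = 4)
#> EvalReport @ threshold 0.8996 (Youden), 2000 bootstrap reps
#>   auc          1.000  (95% CI 1.000-1.000)
#>   accuracy     1.000  (95% CI 1.000-1.000)
#>   sensitivity  1.000  (95% CI 1.000-1.000)
#>   specificity  1.000  (95% CI 1.000-1.000)
#>   ppv          1.000  (95% CI 1.000-1.000)
#>   npv          1.000  (95% CI 1.000-1.000)
#>   counts: TP 8  FP 0  TN 7  FN 0
```

The probability of the VPC class comes from a softmax pair; the
threshold is the Youden-optimal cut on the test scores; perfect metrics
here reflect the deliberately strong class effect (`classEffectSize = 1`)
of the synthetic cohort, not clinical performance.

A thin command-line front end over the same functions is installed at
`inst/scripts/vpcecg` (subcommands `render`, `digitize`, `split`,
`evaluate`, `sweep`).

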