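# eegresp

Classification of rTMS treatment response in depression from 19-channel
resting-state EEG, with a 1D CNN-LSTM classifier and a fully synthetic,
testable stand-in for the clinical cohort.

Patients with major depressive disorder count as *responders* to a course
of repetitive transcranial magnetic stimulation (rTMS) when their BDI-II
score drops by at least 50%. `eegresp` implements the complete pipeline
for predicting that label (and pre/post-session contrasts) from
resting-state EEG recorded on the 10-20 montage at 500 Hz:

* **preprocessing** — ICA artifact rejection (negentropy-maximising,
  blink-proxy and kurtosis criteria), a 50 Hz notch (Q = 30), an order-4
  elliptic 0.1-60 Hz band-pass (Chebyshev type-II alternative), all
  zero-phase; segmentation into 1 s, 500 x 19 time-major epochs;
* **augmentation** — training-set growth by about 2% per fold across the
  10 CV folds (`ceiling(n * 1.2)` total), each artificial segment the
  mean of two same-class training segments with 2% of time instances
  re-injected from one parent;
* **the network** — five valid stride-1 1D convolutions with max-pooling
  (128/64/32/16/8 filters, kernels 4/4/4/4/2, pools 4/4/4/2), a
  50/25/25-unit LSTM stack and a two-unit sigmoid head: 77,792 trainable
  parameters, trained with Adam and per-unit binary cross-entropy.
  Forward, backward and Adam are implemented in RcppArmadillo and
  gradient-checked in the tests;
* **evaluation** — stratified 10-fold cross-validation with a fixed
  70/20/10 train/validation/test rotation, optional strict
  subject-level folds (no patient spans partitions), and per-fold
  sensitivity, specificity, accuracy, precision, F-measure, Cohen's
  kappa and ROC-AUC;
* **synthetic cohorts** — correlated 1/f background, posterior alpha
  with tunable class-conditional amplitude and lateralisation effects,
  blink/muscle/line/drift artifacts, BDI-II scores drawn per sex and
  response stratum, EDF export/import.

The convolution step for filter $r$ is
`C[l, r] = f(sum over window and channels of x * w_r + b_r)` for
`l = 1..L-s+1` (valid, stride 1), followed by non-overlapping max-pooling
of window `d`; the LSTM uses the standard single-bias gate
parameterisation (`4 (U (F + U) + U)` parameters).

## Worked example

Generate a small separable cohort, preprocess, and cross-validate:

```r
library(eegresp)

coh <- generate_cohort(10, 10, c(female = 0.5, male = 0.5),
                       recording_spec(duration = 60), seed = 11,
                       sessions = "pre", class_effect = 1)
recs <- lapply(coh$recordings, preprocess_recording)
tensor <- assemble_dataset(recs, coh$subjects, model_id = 5)
print(tensor)
#> <segment_tensor> 2400 x 500 x 19  [ nonresponder: 1200, responder: 1200 ]

plan <- make_fold_plan(tensor, 10, "segment_level", seed = 11)
report <- run_cross_validation(tensor, plan,
  train_cfg = train_config(epochs = 6, patience = 2, seed = 11),
  augment_cfg = augment_config(seed = 11), folds = 1:2)
print(report)
#> <metrics_report> 2 folds (segment_level policy)
#>   sensitivity       0.975 (+/- 0.000)
#>   specificity       1.000 (+/- 0.000)
#>   overall_accuracy  0.988 (+/- 0.000)
#>   precision         1.000 (+/- 0.000)
#>   recall            0.975 (+/- 0.000)
#>   f_measure         0.987 (+/- 0.000)
#>   cohen_kappa       0.975 (+/- 0.000)
#>   auc               0.998 (+/- 0.003)
```

The cohort injects a strong alpha-band effect (responders: doubled,
left-lateralised alpha power), and the network recovers it almost
perfectly on held-out segments; with `class_effect = 0` the same pipeline
sits at chance (the test suite asserts both). Run `folds = 1:10` for the
full protocol. The architecture itself is inspectable without training:

```r
default_architecture()$shapes
#>         kind length features params
#> 1     conv1d    497      128   9856
#> 3     conv1d    121       64  32832
#> ...                  (13 rows; total 77,792 parameters)

dataset_sizing(27683)
#> $reshaped 27683  $augmented 33220  $train_validation 29898  $test 3322
```

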