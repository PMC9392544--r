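---
title: "Methods: EEG-based classification of rTMS treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG-based classification of rTMS treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Repetitive transcranial magnetic stimulation (rTMS) helps some patients
with major depressive disorder and not others. A patient counts as a
*responder* when their BDI-II depression score falls by at least 50% over
the treatment course:

$$\text{responder} \iff \frac{\mathrm{BDI}_\text{pre} -
\mathrm{BDI}_\text{post}}{\mathrm{BDI}_\text{pre}} \ge 0.5 .$$

`eegresp` implements a pipeline that predicts this label (and related
pre/post-session contrasts) from 19-channel resting-state EEG recorded on
the 10-20 montage at 500 Hz: preprocessing, fixed-length segmentation,
training-set augmentation, a 1D CNN-LSTM classifier, and stratified
10-fold cross-validated evaluation. Because clinical EEG of this kind is
not publicly available, the package also ships a synthetic-cohort
generator so every stage is testable end to end.

## Preprocessing

Each recording passes through:

1. **ICA artifact rejection** (optional). A symmetric fixed-point,
   negentropy-maximising ICA (logcosh contrast) is fitted after centering
   and PCA whitening. Components are flagged when their source correlates
   with the frontal blink proxy (mean of Fp1 and Fp2, threshold 0.8) or
   when their kurtosis (plain fourth-moment form; 3 for a Gaussian)
   exceeds 5. Flagged components are removed before reconstruction. The
   default component count equals the channel count: the synthetic data
   are full rank, and full-rank ICA keeps reconstruction with an empty
   rejection set an exact identity. For average- or linked-ears-referenced
   clinical data whose covariance loses one rank, pass
   `n_components = 18`.
2. **50 Hz notch**, an RBJ band-stop biquad with quality factor 30. Its
   zeros lie exactly on the unit circle at 50 Hz, so a pure line tone is
   annihilated rather than merely attenuated.
3. **0.1-60 Hz band-pass**, an order-4 elliptic design (1 dB passband
   ripple, 40 dB stopband) applied as one 8th-order transfer function. A
   Chebyshev type-II band-pass of the same band is available as a config
   alternative (`default_filters("chebyshev2_bandpass")`). We verified the
   direct band-pass design numerically before adopting it: the largest
   pole modulus is 0.99987 (stable), and a cascade of separate elliptic
   high- and low-pass stages was rejected because zero-phase application
   stacks passband ripple to about 4 dB at 10 Hz.

All filters run forward-backward (`signal::filtfilt`), giving zero phase
shift and the squared design magnitude; the effective passband ripple is
therefore twice the design ripple. ICA runs before filtering so the blink
detector still sees the slow ocular transients the band-pass would thin
out.

Recordings are then cut into non-overlapping, time-major segments of 500
samples (1 s at 500 Hz); a trailing remainder is discarded, so a set of
recordings with $m_i$ samples yields $\sum_i \lfloor m_i / 500 \rfloor$
segments of shape $500 \times 19$. The segment length is the one implied
by the published data-matrix shapes.

## Classification tasks

Five binary tasks are defined over the cohort: (1) female pre vs post
session, (2) male pre vs post, (3) female pre-treatment responder vs
nonresponder, (4) male pre-treatment responder vs nonresponder, (5) both
sexes pre-treatment responder vs nonresponder. Eyes-open and eyes-closed
segments are pooled under the same class label.

## The network

The classifier is a 1D CNN-LSTM. A valid, stride-1 convolution over the
time axis with kernel length $s$ and $r$ filters maps an $L \times C$
input to $(L - s + 1) \times r$:

$$C^r_l = f\!\left(\sum_{i=1}^{s}\sum_{c=1}^{C} x_{l+i-1,c}\, w^r_{i,c}
+ b^r\right), \qquad l = 1, \dots, L - s + 1,$$

with ReLU activations. Non-overlapping max-pooling of window $d$ keeps
$\lfloor L / d\rfloor$ maxima per filter. The reference architecture on
$500 \times 19$ input is

| layer | spec | output | parameters |
|---|---|---|---|
| conv | 128 filters, $s=4$ | 497 x 128 | 9,856 |
| pool | $d=4$ | 124 x 128 | 0 |
| conv | 64, $s=4$ | 121 x 64 | 32,832 |
| pool | $d=4$ | 30 x 64 | 0 |
| conv | 32, $s=4$ | 27 x 32 | 8,224 |
| pool | $d=4$ | 6 x 32 | 0 |
| conv | 16, $s=4$ | 3 x 16 | 2,064 |
| conv | 8, $s=2$ | 2 x 8 | 264 |
| pool | $d=2$ | 1 x 8 | 0 |
| LSTM | 50, sequences | 1 x 50 | 11,800 |
| LSTM | 25, sequences | 1 x 25 | 7,600 |
| LSTM | 25, final state | 25 | 5,100 |
| dense | 2, sigmoid | 2 | 52 |

Kernel and pool lengths are not free choices: they are uniquely recovered
from the published per-layer output lengths and parameter counts under
valid stride-1 convolution (e.g. $497 = 500 - s + 1$ forces $s = 4$;
$9{,}856 = 128\,(19 s + 1)$ confirms it). LSTM parameter counts follow
the standard single-bias gate form $4\,(U(F + U) + U)$, which matches all
three printed LSTM rows exactly. The pooled $1 \times 8$ sequence enters
the LSTM stack directly; the flattening step sometimes drawn between the
stages is a no-op at that shape.

Training uses Adam (learning rate $10^{-3}$, batch size 128) with
per-unit binary cross-entropy on the two sigmoid outputs, which are
renormalised to probabilities at prediction time. Weights are
Glorot-uniform with forget-gate biases initialised to 1; batch order and
initialisation derive from one integer seed, so runs are reproducible.
Two deviations from a bare reading of the published setup were necessary
to make training work and are deliberate: per-channel standardisation of
inputs using training-partition statistics (raw microvolt scales stall
optimisation), and early stopping on validation loss (patience 10 by
default, epoch budget 50). The forward and backward passes are
implemented in compiled code (RcppArmadillo) and are verified in the test
suite against an all-R reference network and finite-difference gradients.

## Augmentation

The training partition grows by about 2% per fold across the 10 folds,
i.e. to $\lceil n\,(1 + 0.02 \times 10)\rceil$ segments. Each artificial
segment is the element-wise mean of two randomly drawn *same-class*
training segments, after which 2% of time instances per channel are
replaced by the corresponding raw values of one parent; labels are
inherited and parent indices are recorded in the provenance table.
Same-class averaging is not stated in the source description but is
forced by label consistency. Class proportions are preserved by
largest-remainder allocation of the artificial budget.

Two quirks of the published sizing table are worth recording. First, the
ceiling (not round-half-away) reproduces its self-consistent columns:
$27{,}683 \to 33{,}220$, $28{,}050 \to 33{,}660$, $14{,}358 \to 17{,}230$
and $27{,}616 \to 33{,}140$ (where $27{,}616 \times 1.2 = 33{,}139.2$
rounds down under half-away). Second, the third task's printed
post-augmentation count (16,620) is inconsistent with any uniform 20%
rule ($12{,}465 \times 1.2 = 14{,}958$); the growth fraction is therefore
exposed as configuration rather than hard-coded per task.

## Cross-validation and metrics

Segments are dealt into 10 stratified folds (class balance within one
segment per class). For fold $f$, fold $f$ is the test partition, the
next two folds cyclically are validation, and the remaining seven train —
a fixed 70/20/10 global split that reconciles the "90%/10% per fold" and
"70/20/10" descriptions of the protocol. Augmentation happens strictly
inside the training partition of each fold; the test partition contains
only real segments.

Two assignment policies exist. `segment_level` mirrors the published
protocol: segments of one subject can appear on both sides of the
train/test boundary, which leaks subject identity and flatters accuracy
whenever subjects carry stable idiosyncrasies. `subject_level` assigns
whole subjects to folds and is the policy we recommend for any claim
about unseen patients; every report records which policy produced it, and
the no-leakage property is asserted at run time from provenance.

Per-fold test metrics are sensitivity, specificity, overall accuracy,
precision, recall, F-measure, Cohen's kappa
($\kappa = (p_o - p_e)/(1 - p_e)$ with product-of-marginals $p_e$) and
ROC-AUC computed as the normalised Mann-Whitney statistic with half
weight for ties. Reports carry the per-fold values, their mean and SD
over exactly the folds run, and the summed confusion matrix. Zero
denominators yield `NA` with a warning, never a silent zero.

## The synthetic cohort

`generate_cohort()` draws subjects (sex-balanced by construction when
sizes are even) with integer BDI-II scores from per-stratum normal
distributions whose means and SDs default to the published cohort table
(e.g. male nonresponders 35.42 (9.12) pre, 27.14 (7.98) post), truncated
so that exactly the intended subjects satisfy the 50% rule. Responder
counts per sex are `round(fraction * n)`, with published defaults 11/25
female and 18/25 male.

Each recording is the sum of:

* **spatially correlated 1/f background** — per-channel pink noise mixed
  through a fixed neighbour-decay matrix (RMS 15 uV), so ICA has
  cross-channel structure to work with;
* **a posterior-dominant alpha rhythm** — an amplitude-modulated carrier
  near 10 Hz with slow +/- 0.5 Hz frequency jitter (a fixed-frequency
  sinusoid would be phase-locked to the 1 s segment grid and act as an
  unrealistic per-recording fingerprint). Base amplitude is 10 uV
  (occipital weight 1.0) eyes-closed and 4 uV eyes-open, mimicking the
  Berger effect;
* **artifacts** per `artifact_spec()`: frontal-dominant 350 ms blink
  transients (default 12/min), broadband temporal muscle bursts (3/min),
  50 Hz line interference (2 uV) and sub-0.1 Hz drift (10 uV).

Class and session effects enter through the alpha rhythm. A subject with
effect size $e$ has alpha amplitude scaled by $1 + e$ *and* a lateralised
alpha topography (left-hemisphere weights multiplied by $1 + e/2$, right
divided by it); the post session scales amplitude by a configurable
session effect (default 0.2). The amplitude component alone is a weak
per-segment feature — the shared burst envelope makes single seconds of
low-alpha responder EEG look like nonresponder EEG, capping band-power
separability near 0.9 regardless of effect size — whereas the asymmetry
component survives at the single-segment level because the left/right
power ratio cancels the common envelope. With $e = 1$ a plain band-power
classifier separates the classes essentially perfectly, which is what
"strongly separable" means in the acceptance tests; $e = 0$ is an exact
null.

What the generator does *not* emulate: volume-conducted source geometry,
per-subject idiosyncratic spectra, nonstationary artifact statistics,
cardiac artifacts (beyond what muscle bursts resemble), or any claim
about which EEG features distinguish real responders — those are unknown.
Passing the recovery test therefore shows the architecture can learn
class-conditional spectral/topographic structure through the full
pipeline; it says nothing about accuracy on clinical data.

## Problem sizes used by the test suite

The stochastic end-to-end tests run the full pipeline at desk scale: 10
subjects per class, 60 s per condition (two conditions, pre session), so
2,400 segments per cohort. The null-calibration test uses three cohort
seeds and two folds of the 10-fold plan per seed with a 2-epoch budget
(chance level needs no convergence); the recovery test uses one seed, two
folds, and up to 6 epochs with patience 2. Folds are exchangeable, so a
two-fold subset gives an unbiased (if noisier) estimate of the 10-fold
average; the pooled test sets still cover 1,440 (null) and 480
(recovery) segments. These sizes are the package's choice of a
sufficient, fast experiment, and they are stated here so anyone can scale
them up: pass `folds = 1:10` and the full epoch budget to
`run_cross_validation()` for the complete protocol.

## Known limitations

* The published experiment augments *before* the 90/10 partition (its
  test-set counts are 10% of augmented totals); we reproduce that
  arithmetic in `dataset_sizing()` but never test on artificial segments.
* `segment_level` folding reproduces the protocol but inflates accuracy
  whenever subjects are internally coherent; use `subject_level` for
  patient-level claims.
* The elliptic band-pass at 0.1 Hz has poles within 1.3e-4 of the unit
  circle; transients decay over roughly 15 s, so very short recordings
  see edge effects (the test fixtures discard filter edges when measuring
  attenuation).
* Training is CPU-bound single-node code; it is meant for desk-scale
  experiments, not large clinical corpora.
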