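---
title: "Evaluating predictive uncertainty for clinical outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predictive uncertainty for clinical outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqeval)
```

## The problem

Outcome prediction models in radiotherapy — normal tissue complication
probability (NTCP) models for side effects such as dysphagia and xerostomia,
and tumour control probability (TCP) models for survival or locoregional
control — output a single event probability per patient. A clinician acting
on that number has no way to tell a confident prediction from a guess.
Uncertainty quantification (UQ) addresses this by replacing the point
prediction with a *distribution* of predictions, whose spread is a
patient-level reliability signal.

`uqeval` implements a complete, reproducible evaluation bench for the three
most established UQ methods and three uncertainty measures in this setting,
on synthetic cohorts whose ground truth is known exactly.

## Uncertainty methods

All three methods produce, for each patient, a set of $T$ sampled
probabilities $p_1,\dots,p_T$; the final prediction is always the mean
$\bar p = \tfrac1T\sum_t p_t$.

* **MC dropout** keeps dropout layers active at inference and draws $T = 50$
  stochastic forward passes. The dropout rate is selected from
  $\{0.1, 0.2, 0.3, 0.4, 0.5\}$ by validation AUC of the MC-mean prediction,
  retraining one model per candidate rate; ties go to the smaller rate.
  Training and inference use the same rate.
* **Deep ensembles** train $M = 10$ models on identical training/validation
  splits, differing only in their member seed. The seed sets both the weight
  initialisation and the induced minibatch order — one knob per member.
  Member disagreement is the uncertainty signal; $T = M$.
* **Test-time augmentation (TTA)** applies the training-time input
  augmentations to each validation patient $T = 50$ times and runs a
  deterministic forward pass on each copy. TTA probes input — not
  parameter — randomness, so it uses the baseline model with inference-time
  dropout off.

## Uncertainty measures

For a sample set with mean $\bar p$:

* **Binary entropy** $H(\bar p) = -\bar p \log_2 \bar p -
  (1-\bar p)\log_2(1-\bar p)$, the total predictive uncertainty in bits,
  already bounded in $[0,1]$.
* **Variance** $\tfrac1T \sum_t (p_t - \bar p)^2$, the population variance
  of the samples ($T$ is fixed by design, not an estimate of a larger
  sample), bounded by $\bar p(1-\bar p) \le 0.25$.
* **Mutual information** (BALD) $H(\bar p) - \tfrac1T\sum_t H(p_t)$, the
  epistemic component. It is non-negative by Jensen's inequality; being a
  difference of two nearly equal entropies it is numerically fragile in
  binary problems, so floating-point negatives are clamped to zero.

Variance and MI are min–max normalised before calibration analyses, with the
scaling bounds taken from the independent validation cohort itself; entropy
needs no rescaling. Normalisation bounds are recorded on the score object,
and sparsification rankings use raw values (they are invariant to monotone
rescaling).

## Evaluation

* **AUC** via midranks (ties count one half); **accuracy** at the fixed
  threshold 0.5 and, as a sensitivity analysis, at the Youden-J-optimal
  threshold (midpoints between distinct scores, lowest maximiser on ties).
* **Adaptive calibration error (ACE)**: equal-frequency bins of at least 25
  patients — $\lfloor n/25\rfloor$ bins with the remainder spread one
  patient at a time, tied values never straddling a boundary — and the
  unweighted mean over bins of |observed event fraction − mean predicted
  probability|. The bin *mean* probability (not the midpoint) is the
  confidence statistic. Note the noise floor: with 25-patient bins the
  expected absolute binomial gap is $\approx \sqrt{p(1-p)/25} \cdot
  \sqrt{2/\pi} \approx 0.08$ even for a perfectly calibrated predictor, so
  convergence studies must let the bin size grow with $n$.
* **Uncertainty–accuracy calibration**: certainty is defined as
  1 − normalised uncertainty, patients are binned by certainty, and per-bin
  accuracy is compared with mean certainty (ACE-style score plus the per-bin
  curve for plotting).
* **DeLong test** for correlated AUCs via structural components; a
  zero-variance difference (identical scores) returns p = 1 by convention.
* **Sparsification**: patients ranked by descending uncertainty (ties broken
  by patient id so runs are bit-reproducible), one patient removed per step,
  AUC and accuracy recomputed on the retained set, down to half the cohort.
  If removal exhausts a class, AUC is recorded as missing, never imputed.
* **Bootstrap CIs**: percentile intervals from label-stratified resampling.

## The synthetic cohort generator

The generator emulates the *structure* of the clinical cohorts, not their
content: mixed continuous (standard normal) and categorical (multinomial,
3 levels) covariates; a logistic-linear outcome model — the classical NTCP
form — giving each patient a known true event probability; endpoint
intercepts calibrated by root-finding so the marginal prevalence hits the
target through the optional label-noise channel
($q = \bar p(1-2\rho) + \rho$); and independent label flips modelling
irreducible assessment variability. Default targets are 22% (dysphagia) and
42% (xerostomia) for the 1,205-patient NTCP-style cohort split 80%/20%, and
24% (2-year death) and 25% (locoregional-control failure) for the
340-patient TCP-style cohort split 75%/25%. Split sizes use
round-half-to-even, reproducing the cohort arithmetic (964/241 and 255/85).

The default effect sizes (decaying log-odds 1.0 … 0.1 over eight continuous
covariates plus small categorical effects) give a latent-predictor SD of
about 1.6 and an oracle AUC near 0.85 — an informative but imperfect model,
the regime the clinical endpoints occupy. The clinical studies do not report
feature–outcome effects, so these are free parameters of the bench, chosen
once, not estimates of any real cohort.

What the generator deliberately does *not* emulate: images, dose
distributions and contours (the UQ pipeline is model-agnostic by contract);
time-to-event structure and censoring (endpoints are binarised); and
correlated or missing covariates. Passing tests therefore demonstrate
correctness of the UQ machinery and its expected qualitative behaviour on
well-specified tabular data — not clinical performance.

## The classifier

A two-hidden-layer ReLU network (16–8 units by default) with a sigmoid
output, trained by Adam (learning rate 0.01, batch size 32) on binary
cross-entropy with inverted dropout on the hidden activations and optional
per-epoch input augmentation. Early stopping monitors deterministic
validation loss with patience 20 (500 epoch cap) and restores the
best-validation weights, so the retained checkpoint is never worse than the
final epoch. Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ before any
logarithm. Every stochastic ingredient (initialisation, batch order, dropout
masks, augmentation draws) is derived from one seed via keyed child streams,
making training bit-reproducible; no class reweighting is applied.

## Worked example

```{r example, eval = FALSE}
cfg <- experiment_config(
  spec = cohort_spec(1200, prevalence = c(dysphagia = 0.22), seed = 5),
  bootstrap_B = 200, seed = 99)
res <- run_uq_comparison(cfg)
print(res)
plot(res$endpoints$dysphagia$calibration$deep_ensemble$entropy)
plot(res$endpoints$dysphagia$sparsification$mc_dropout$entropy,
     metric = "accuracy")
```

On this cohort the baseline AUC is about 0.81 against an oracle (true
probability) AUC of 0.83, none of the UQ methods changes AUC materially, and
removing the most-uncertain half of the validation cohort by MC-dropout or
ensemble entropy raises accuracy from roughly 0.82 to over 0.9 — the
qualitative signature of useful uncertainty.

## The training-set-size experiment

Models are retrained on nested subsets of the training cohort (N, 2N, 3N, …
patients sampled without replacement from a per-repeat permutation, stopping
when fewer than N unsampled patients remain; N = 100 for NTCP-style and
N = 50 for TCP-style cohorts), with the validation and independent
validation cohorts held fixed — a checksum of the independent cohort is
recorded in every cell and asserted constant. The procedure is repeated R
times (10 by default) and the mean and SD of the raw (un-normalised)
per-patient uncertainties, AUC, and calibration error are reported per cell;
raw scales are kept because entropy lives on a different (bit) scale from
variance and MI and is plotted on its own axis. The dropout rate is fixed
once per endpoint rather than re-selected at each size; re-selection is a
config option away but couples the rate to sample size, confounding the
trend of interest.

## Numerical and design choices

* **Seeds**: one master seed per experiment; child seeds are derived from
  (seed, key) via a multiplicative hash and stay below $2^{31}$.
* **Intercept calibration**: Monte Carlo expectation over 200,000 covariate
  draws plus `uniroot` on $[-30, 30]$, tolerance $10^{-8}$; targets
  unreachable under the label-noise floor are reported as errors.
* **Ties**: bins never split tied values (counts may exceed the nominal
  size, and a bin starved below the floor is merged); sparsification and
  selection grids break ties deterministically (patient id, smaller rate).
* **Degenerate inputs**: single-class labels error early (AUC undefined);
  constant uncertainty collapses to a single calibration bin; a degenerate
  min–max reference maps all scores to zero with a warning; MC dropout with
  rate 0 warns and returns the deterministic prediction.
* **Test problem sizes**: the bundled suite runs cohorts of 300–2,500
  patients, comparison experiments at 1,200 and scaling at 1,500 patients
  (train pool 960, sizes 100–900, 3 repeats), chosen so the full suite and
  the acceptance script each complete in a few minutes on one CPU while
  keeping all statistical assertions comfortably powered.

## Known limitations

* Out-of-distribution behaviour: ensemble disagreement rises under *mild*
  covariate shift (the packaged property uses +0.5 SD on every covariate),
  but strong shifts push the sigmoid into saturation where all members agree
  confidently — epistemic uncertainty from ensembles is not a reliable
  far-OOD detector, and the package makes no claim that it is.
* Mutual information inherits the instability of small entropy differences;
  with $T = 50$ samples its per-patient values are noisy, which is precisely
  the behaviour the evaluation bench is designed to expose.
* Conformal prediction, evidential networks and Gaussian-process methods are
  out of scope, as are subgroup (tumour-site) analyses and any image or dose
  handling.
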