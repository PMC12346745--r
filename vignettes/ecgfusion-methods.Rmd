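---
title: "Dual-branch ECG arrhythmia classification: models, data and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch ECG arrhythmia classification: models, data and attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A resting 12-lead electrocardiogram records the heart's electrical activity
from twelve viewpoints (limb leads I, II, III, aVR, aVL, aVF and precordial
leads V1–V6) for 10 seconds.  Large annotated corpora such as PTB-XL attach
to each record a set of SCP diagnostic statements with likelihoods, patient
age and sex, and a recommended 10-fold partition.  `ecgfusion` implements a
complete pipeline for single-label arrhythmia classification on such
corpora: corpus ingestion, scenario construction, signal augmentation, two
dual-branch convolutional classifiers that fuse the waveform with patient
demographics, micro/macro evaluation, and per-lead Shapley attribution.

## Diagnostic taxonomy and label resolution

The diagnostic axis is a two-tier taxonomy: five superclasses — NORM
(normal), MI (myocardial infarction), CD (conduction disturbance), STTC
(ST/T change), HYP (hypertrophy) — refined into 23 subclasses (e.g. IMI,
CLBBB, LAFB/LPFB).  `ptbxl_taxonomy()` carries the built-in mapping; when a
corpus ships its own `scp_statements.csv` that table is used instead.  Two
statement codes, LAFB and LPFB, pool into the single subclass `LAFB/LPFB`.

Source records are multi-label, while all classification scenarios here are
single-label.  `map_scp_to_label()` therefore retains only statements with
likelihood at or above `min_likelihood` (default 100, the most conservative
choice — only fully confident statements survive) and accepts a record only
when the retained codes agree on a single superclass.  Records with no
retained diagnostic code are `"unlabeled"`, records spanning two or more
superclasses are `"ambiguous"`; both are excluded with counts reported, so
the filtering is auditable.  The threshold and the exclusion policy are
configuration, not hard-wired behaviour.

Partitioning follows the corpus's stratification fold: folds 1–8 train,
fold 9 validation, fold 10 test.  This is a pure function of the fold
(`assign_split()`), so the three partitions are disjoint and exhaustive by
construction.

## Classification scenarios

`binary_superclass()`, `binary_subclass()` and `binary_normal_abnormal()`
produce the three binary settings (normal vs one superclass, normal vs one
subclass, normal vs any single disease).  `multiclass(5)` is the fixed
five-superclass task; `multiclass(10)` and `multiclass(15)` take NORM plus
the most frequent non-NORM subclasses by training-fold record count.  Two
design choices here were genuinely open:

* **Counts come from the training folds only.**  Using the whole corpus
  would let the test set influence which classes exist — a quiet form of
  leakage.  `subclass_counts()` defaults to the training partition.
* **Ties at the cutoff break by taxonomy order**, deterministically and
  with a message, so a materialized dataset is reproducible from its YAML
  manifest (`write_scenario()`) and the corpus alone.

Class indices are 0-based and contiguous; `NORM` is always index 0 where it
participates.

## The synthetic corpus generator

`generate_corpus()` produces PTB-XL-shaped corpora — WFDB waveforms, the
two metadata CSVs, demographics, folds — whose *structure* matches clinical
corpora while their *content* is fully controlled.  Each class has a 12-lead
amplitude signature and a dominant pulse frequency; a record's signal is

    signal[, l] = A_class[l] * pulse_train(f_class, random phase) + N(0, noise_sd)

with Gaussian bumps of 25 ms width repeating at the class frequency
(1–2.5 Hz, the heart-rate range) — a caricature of periodic QRS activity,
not a morphological P-QRS-T synthesis.  Defaults: planted amplitude 1 mV on
one lead per class, noise 0.05 mV, base age Normal(60, 12) clamped to
18–95, sex balanced.  Optional per-class age shifts and sex log-odds plant
a demographic signal.

Two canned configurations define the study conditions used throughout the
tests:

* `disjoint_leads_config()` — each class's energy lives on its own lead, so
  per-lead energy separates classes in closed form and lead attribution has
  a planted ground truth;
* `demographic_signal_config()` — both classes share one signature (the
  waveforms are exchangeable) and differ only by an age shift of ±18 years
  and sex log-odds of ±2, so only the demographic branch can separate them.

What passing tests on these corpora show: the pipeline is wired correctly
end-to-end, the optimizer can exploit lead-localized and demographic
signal, and attribution recovers planted structure.  What they do not show:
performance on clinical ECGs, whose class signal is morphological, shared
across leads, and far subtler than these planted effects.

## Augmentation

Three operators expand the training partition only: additive Gaussian noise
(mean 0, sd 0.01 mV), amplification by `1 + x` and attenuation by `1 - x`
with `x` drawn uniformly from [0.001, 0.01] per copy.  The default policy
`"triple"` adds one copy per operator — the minimal reading of
one-copy-per-listed-operator — so every class count exactly quadruples; a
`"balance"` policy that tops minority classes up to the majority count is
available for imbalance experiments.  Demographics and labels are copied
untouched, augmentation happens offline (dataset expansion, not per-batch),
and calling the expander on a validation or test partition is an error, not
a no-op: silent test-set augmentation is the failure mode worth guarding
against.

## The two architectures

Both models are dual-branch: a 1-D convolutional branch over the
`time x 12` waveform and a dense branch over `(age, sex)`, concatenated and
classified by a shared head.

* **custom_cnn** — five conv blocks with 32, 64, 128, 256, 512 filters;
  each block is conv(3x1, same padding) -> ReLU -> max-pool(2x1) ->
  batch-norm; flatten; dense 100, 32 with dropout 0.4.
* **vgg_style** — eight conv blocks with 64, 64, 128, 128, 256, 256, 512,
  512 filters, pooling after every conv layer; global average pooling;
  dense 512, 512 with dropout 0.5.
* Shared: demographic branch dense 100, 64, 32, 16 with dropout 0.4
  (9,372 weights); head dense 10, 10, K with dropout 0.2; softmax output;
  categorical cross-entropy; Adam at learning rate 0.001, batch 16, at most
  60 epochs.

Points that required a decision:

* **Padding.**  Convolutions use "same" padding so the time axis halves
  exactly at each pool; with `floor` pooling both 1000-sample (100 Hz) and
  5000-sample (500 Hz) inputs pass through either stack.  A built model
  refuses an `input_length` shorter than `2^n_pool`.
* **Pooling cadence in the VGG variant.**  One pool per conv layer (eight
  pools), configurable; pooling per pair would be equally defensible.
* **Binary heads.**  Two-way softmax with cross-entropy rather than a
  sigmoid unit, keeping one head across all K.
* **Callbacks.**  Early stopping (patience 10 on validation loss),
  learning-rate halving after 5 stale epochs with floor 1e-5, and
  checkpointing: the returned weights are those of the epoch with minimum
  validation loss, which the training history makes verifiable.
* **Demographic encoding.**  Age is z-scored with training-set statistics,
  sex is 0/1 (male/female); the scaler is fitted on the training set only
  and stored in the model, so validation and test records are encoded
  without leakage.  Missing values impute to the training median age and
  0.5.

The network engine itself (im2col convolution via compiled kernels,
max-pool, batch normalization, inverted dropout, Adam) is part of the
package; its gradients are verified against numerical differentiation in
the test suite, which is the contract that matters for trusting the
training loop.

## Evaluation conventions

`evaluate()` reports the confusion matrix (rows actual, columns predicted),
accuracy, *micro*-averaged precision and recall, *macro*-averaged F1 and
the full per-class table.  For single-label multiclass tasks, micro
precision, micro recall and accuracy are identically equal (pooled TP is
the diagonal total, pooled TP+FP and TP+FN are both the grand total) — the
suite asserts this identity on random matrices.  Reporting micro
precision/recall alongside a macro F1 mirrors the common reporting pattern
in which the precision and recall columns coincide with accuracy while F1
differs; labeling the convention explicitly avoids propagating the
ambiguity.  A 0/0 precision or recall is defined as 0 with a warning, which
keeps macro averages defined when a class is absent.

## Lead-level Shapley attribution

Attribution treats the 12 leads — not time samples — as players in a
cooperative game.  Masking a lead replaces its entire time series with a
baseline (zeros by default; a reference signal such as the training mean is
available via `masking_scheme("mean", ...)`).  The value function is the
model's predicted probability of the record's own class; demographic inputs
are never masked.

With 12 players the game has 4,096 coalitions, so `exact_lead_shapley()`
computes the exact Shapley vector by full enumeration — feasible, and the
natural oracle.  The estimator of practical interest,
`sampled_lead_shapley()`, averages marginal contributions over random lead
permutations; it is unbiased, seeded, and caches value evaluations per
coalition.  The suite checks the efficiency axiom (attributions sum to
`v(all) - v(none)` within 1e-6), the dummy and additivity axioms on
analytic models, and convergence of the estimator to the oracle.

Per-class importance follows the mean-of-absolute-values convention:

    I_l = (1/N) * sum_i |phi_il|

over the N test records of a class (the signed mean is available via
`signed = TRUE`, and both raw and sum-to-one normalizations are emitted,
since figure-level conventions vary).  On the disjoint-leads corpus the
argmax of each class's importance vector must be its planted lead; this is
the package's strongest end-to-end check, because it exercises generator,
training and attribution against a known ground truth simultaneously.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic corpora
sized for a single CPU: 400 records for the five-class generalization run
(trained up to 12 epochs), 64 records for the overfit-capacity check (up to
the full 60), 200–300 records for the demographics ablation, and reduced
filter widths (8, 16) for models that only feed the Shapley machinery.
These sizes are the package's own choices for its study conditions; the
architecture audits always use the full reference configurations.

Numerical details: batch-norm uses eps 1e-3 and momentum 0.9 on running
statistics (inference uses running statistics, so prediction is a pure
function of the input); softmax subtracts the row maximum;
cross-entropy clips probabilities at 1e-12; max-pooling on an odd-length
axis floors (drops the last sample); ReLU subgradient at exactly 0 is 0.
All randomness — corpus generation, weight initialization, shuffling,
dropout, augmentation draws, permutation sampling — flows through explicit
seeds, and `generate_corpus()` restores the caller's RNG state.

## Known limitations

* Waveforms are pulse trains; no morphological realism, no
  baseline wander, no powerline artifacts, and no signal filtering (none
  is part of the modeled pipeline).
* Only the diagnostic statement axis is handled; form/rhythm statements
  are ignored.
* Training at clinical scale (tens of thousands of 500 Hz records) is out
  of the package's intended envelope; the engine is single-threaded per
  BLAS and sized for desk-scale experiments.
* No ROC/AUC or calibration analysis; no gradient-based attribution.
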