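---
title: "Predicting chronic pain after breast cancer from coded EHR histories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chronic pain after breast cancer from coded EHR histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Roughly one in three cancer patients develops chronic pain, and female
breast-cancer survivors are especially susceptible. This package
implements an end-to-end risk analysis over longitudinal electronic
health records: given a patient's diagnosis-code history *before* her
breast-cancer diagnosis, plus static demographics and survey answers,
predict whether she will develop chronic pain within three years *after*
the diagnosis. Because the cohort data such analyses run on are
access-restricted, the package ships a synthetic OMOP-style cohort
generator with a planted, recoverable risk signal; every stage is
exercised and tested against it.

# Cohort definition and the computable phenotype

Cohort entry is the first condition whose code starts with a configured
breast-cancer prefix (defaults: ICD-9-CM `170`, ICD-10-CM `C50`); that
date is the **index date** and all events are re-expressed as day
offsets around it. Note that `170` denotes bone neoplasms in standard
ICD-9-CM (breast is 174/175); the default is kept literally but is
configurable via `cohort_config()` — it is deliberately not silently
"fixed".

The outcome is a computable phenotype over the 1095 days (3 years at a
fixed 365 days/year; calendar-month arithmetic is not reproducible)
after the index date. A patient is positive if **any** of three rules
fires; the reported branch is the first true rule in the order below:

1. **Code rule** — a post-index condition with ICD-10-CM prefix `G89`,
   ICD-9-CM prefix `338.2`, or SNOMED code exactly `82423001`.
2. **Medication rule** — pain-medication exposures (17 opioid-class
   ingredients, matched case-insensitively as substrings since real
   drug fields carry brand/strength text) forming a chain whose
   consecutive administrations have gaps of at most 90 days and whose
   *union of covered days* exceeds 90. Days are counted inclusively
   (an exposure from day 10 to day 40 covers 31 days); overlaps are not
   double-counted, and the calendar span is deliberately not used — a
   span rule would mark two isolated one-day fills four months apart as
   chronic use. Chains are maximal runs under the gap rule, and a later
   chain can qualify on its own. Only post-index exposure days count;
   exposures that began before the index date contribute nothing.
3. **Exacerbation rule** — pain-intensity scores exist both before and
   after the index, and the post-index maximum (within the horizon)
   strictly exceeds the *latest* pre-index score. The latest score is
   used as the baseline because it is the least ambiguous reading of "a
   documented increase"; when several scores share the latest pre-index
   day the largest is taken, which is the conservative choice (fewer
   false positives).

The 3-year horizon is applied uniformly to all three rules, including
exacerbation evidence. `label_by_medication()` has an independently
implemented oracle, `oracle_medication_label()`, which expands
exposures into day sets and scans runs; the two are checked against
each other on randomized schedules (overlapping, nested and zero-length
intervals included) in the test suite.

# Feature preparation

* **Codes** are made unique as `"VOCABULARY:code"` strings (no ICD-9 to
  ICD-10 mapping and no truncation-grouping, on purpose) and tokenized
  to integers assigned in sorted order from 2; PAD = 0 and UNK = 1 are
  reserved. The vocabulary is fitted on the training split only, so a
  test-only code maps to UNK — this is the leakage contract and it is
  tested.
* **Sequences** are fixed at length 128, slightly above the mean
  history length of 109 codes. Longer histories keep their 128 most
  recent events (the clinically relevant tail nearest the diagnosis);
  shorter ones are padded with PAD tokens, timestamp 0 and a mask bit.
* **Statics**: age at diagnosis is divided by 100; race, ethnicity and
  survey (question, answer) pairs become one-hot blocks over
  training-split schemas.
* **Variance thresholding** retains a binary column iff its population
  variance `m(1-m)` is at least `p(1-p)`, with `p = 0.9` for
  demographics and `p = 0.8` for survey features. The population (not
  sample) variance matches the conventional threshold definition, and
  retention is non-strict: a feature exactly at the allowable constancy
  `p` is "allowable" and kept. A small absolute tolerance (1e-10)
  protects the exact-boundary case from floating-point rounding of the
  column mean.

# The classifier

An encoder-only self-attention model over the code sequence, fused with
two static branches:

* Per position: token embedding (scaled by `sqrt(d_model)`, the
  standard transformer construction) + a sinusoidal encoding of the
  position index + a sinusoidal encoding of the days-until-diagnosis
  timestamp. The timestamp enters the sinusoid as `days / time_scale`
  with `time_scale = 30` by default — see the design notes below.
* Two post-norm encoder layers with 4 attention heads, feedforward
  width 32 and dropout 0.1 at the standard transformer sites: the
  summed input embeddings, the attention probabilities, and the two
  sub-layer outputs — all inside the encoder; the static branches are
  not dropped. Padded positions are sliced out of the encoder entirely:
  they can neither attend nor be attended to, receive exactly zero
  attention weight, and are excluded from pooling.
* Pooling is the mean over unmasked positions (no CLS token is used).
  Patients with an empty pre-index history pool to a zero vector and
  are classified from their static branches alone rather than being
  excluded.
* Each static vector (demographics: normalized age plus selected
  one-hots; survey: selected one-hots) passes through a ReLU layer of
  width 4; the three vectors are concatenated and a final linear layer
  plus sigmoid yields the probability.

The loss is the positive-weighted binary cross-entropy
`-(w·y·log p + (1-y)·log(1-p))`, averaged over the batch, with
probabilities clamped to `[1e-7, 1 - 1e-7]` inside the loss for
numerical safety (the clamp is part of the contract so tests can be
exact). Training uses Adam at a constant learning rate 0.001 for 20
epochs with batch size 64.

**Epoch selection.** The validation split exists to mitigate
overfitting, so selection is validation-based with an explicit
overfitting guard: the returned parameters are those of the epoch with
the best validation AUROC *among epochs whose train-minus-validation
AUROC gap is at most `max_overfit_gap`* (default 0.10). The guard
matters at desk scale: a transformer with a ~20k-parameter embedding
table memorizes a few-thousand-patient training split within 5–10
epochs (training AUROC approaches 1.0 while test AUROC plateaus), and a
plain best-validation rule cannot see this — with ~200 validation
patients the AUROC standard error is ~0.04, so late, heavily memorized
epochs win by noise. The guard uses only training and validation data,
never the test split; its training AUROC is estimated on a fixed,
evenly spaced subsample of up to 1024 training patients (standard error
~0.02–0.03, ample against the 0.10 threshold) to keep the per-epoch
cost small. If no epoch passes the guard (e.g. on a null cohort where
validation AUROC hovers below training AUROC from the start), selection
falls back to plain best validation AUROC.

The forward and backward passes are hand-written in C++
(RcppArmadillo) with analytic gradients; the test suite verifies them
against central finite differences.

Splitting is 70/5/25 and *stratified* by outcome: an unstratified 5%
validation split of ~1100 patients at 17.6% prevalence can easily
contain no positives, leaving validation AUROC undefined. Split sizes
are rounded by largest remainder so they respect the total exactly.

# The synthetic cohort generator

The generator emulates the statistical shape of the study data: per
patient, a Poisson(109) background code sequence over a 600-code
universe with uniform day offsets up to 10 years before the index; one
cohort-defining breast-cancer condition at the index date; age normal
(57.8, 10.4) truncated to [20, 90]; the observed race/ethnicity mix;
81 survey questions with uniformly sampled answers; and an outcome
drawn from a logistic model on planted indicators — six risk codes
(each carried with probability 0.3, log-odds 3.0/2.5/2.0/1.8/1.5/1.2),
two survey answers (log-odds 1.5/1.0) and age (0.5 per decade, centred
at 55). Risk is generated through this logistic model on indicators,
*not* through the classifier's own functional form, so signal recovery
is a fair test. The effect sizes are chosen so the Bayes-optimal AUROC
of the generative law is about 0.92: large enough that a correct
pipeline recovers the signal clearly at a few thousand patients, small
enough that labels remain substantially noisy at the 17.6% prevalence.

The intercept is not hand-tuned: it is solved at configuration time by
enumerating all 2^8 indicator patterns exactly and integrating age over
midpoint quantiles, so the marginal prevalence equals the 0.176 target
by construction.

Positive patients express the outcome through post-index evidence
matching independently sampled phenotype branches (pain codes with
probability 0.6, qualifying opioid chains with probability 0.5, rising
pain scores with probability 0.3; at least one branch is forced). The
qualifying chains are built from 4–6 exposures of 25–40 days with gaps
of 5–60 days, so the covered-day union always exceeds 90. Negative
patients receive sub-threshold opioid exposures with probability 0.3 —
either a single short exposure or two short chains separated by more
than 90 days — to stress the medication rule near its boundary, and
their post-index pain scores never exceed their baseline. Dates are
synthesized relative to a per-patient index date but emitted as
absolute ISO dates, forcing the reader to recompute day offsets.

What the generator does **not** emulate: ICD code co-occurrence
structure, visit/billing semantics, mortality or censoring, informative
missingness, or realistic survey response distributions (answers are
uniform apart from the planted items, a choice made for calibration
transparency, not inferred from any reported distribution). Passing
tests on this cohort therefore demonstrate that the pipeline's
machinery is correct and that a planted additive signal is recovered;
they say nothing about predictive performance on real clinical data.

# Design notes and numerical choices

* **Timestamp encoding resolution.** The days-until-diagnosis values
  are spread over ~3650 days, so a sinusoidal encoding of the *raw* day
  value gives every patient a nearly unique high-frequency signature.
  Empirically the encoder memorizes these signatures in preference to
  the code-identity signal (on the default n = 4000 cohort, raw-day
  encodings cost about 4 AUROC points on the test split and double the
  train–test gap). Dividing the day value by `time_scale = 30` before
  the sinusoid keeps ordering and coarse timing information at roughly
  monthly resolution without the fingerprint. `time_scale` is a
  configuration field; setting it to 1 restores raw-day encoding.
* **Embedding scale.** Token embeddings are multiplied by
  `sqrt(d_model)` before the additive encodings, following the original
  transformer; without it the encodings dominate the input geometry.
* **Embedding width** d_model = 32 matches the stated feedforward
  width and keeps the model desk-scale; it must be divisible by the
  4 heads.
* **Ties and determinism.** Same-day code events are ordered by
  vocabulary then code string; top-k attention ties break by (source,
  target) position; stratified splits, minibatch order, dropout and
  initialization all derive from explicit seeds, and the pipeline fans
  a single global seed out to fixed per-stage seeds so one stage's
  randomness never perturbs another's.
* **Degenerate inputs.** Empty exposure lists, all-padded sequences,
  single-class evaluation subsets (AUROC reported as undefined),
  zero-denominator precision/recall (reported as 0 and flagged), and
  missing birth dates (patient excluded with a warning) all have
  defined behaviour and tests.
* **Initialization** is uniform scaled by fan-in, seeded from the model
  config; the PAD embedding row is fixed at zero and receives no
  gradient.

# Problem sizes used by the tests and acceptance script

Unit tests run on hand-built micro-fixtures and a 250-patient cohort.
The end-to-end property checks train the full model on a 4000-patient
planted cohort and a 4000-patient null cohort (all effects zero), run
the positive-weight sweep on a fixed 2000-patient planted cohort, a
2000-patient importance-recovery experiment with exactly 50 static
features (code effects zeroed so the dominant planted effect is the
static one), and a deterministic double run of the whole pipeline at
600 patients. The acceptance script reproduces the planted and null
analyses from scratch at n = 4000; at the study's own size (n = 1131,
only 13 minibatches per epoch) epoch selection is fragile — the signal
is not yet learned before memorization begins — so desk-scale
demonstrations use the larger cohort. These
sizes were chosen so a full check runs on a single desktop core in well
under an hour while leaving the statistical margins (binomial
prevalence bands, AUROC null bands) meaningful.

# Known limitations

* The attention-connection report is per-patient; no cross-patient
  aggregation into narrative tables is attempted.
* The medication rule is duration-based only — no dose, route or
  morphine-equivalent logic.
* The encoder is CPU-bound, double-precision and single-threaded;
  it is sized for cohorts of thousands, not millions.
* Validation-epoch selection uses AUROC only; no calibration analysis
  is performed.
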