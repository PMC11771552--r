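# painattn

Chronic pain affects roughly a third of cancer patients, and female
breast-cancer survivors are particularly susceptible. `painattn` is an
R package plus analysis workflow for predicting, from a patient's
electronic health record *before* her breast-cancer diagnosis, whether
she will develop chronic pain within three years *after* it. It is
aimed at clinical-informatics researchers working with OMOP-style coded
data (condition occurrences, drug exposures, surveys, measurements).

The real cohorts for this kind of analysis live in access-restricted
enclaves, so the package includes a synthetic cohort generator with a
planted, recoverable risk signal; the entire pipeline is developed,
tested and demonstrated against it.

## What is inside

1. **Computable chronic-pain phenotype.** A patient is positive within
   the 1095-day horizon if any of three rules fires:
   * a chronic-pain diagnosis code (ICD-10-CM prefix `G89`, ICD-9-CM
     prefix `338.2`, SNOMED `82423001`);
   * pain-medication exposures forming a chain with inter-exposure gaps
     ≤ 90 days whose union of covered days exceeds 90 (17 opioid-class
     ingredients, substring-matched);
   * a post-index pain-intensity score strictly above the latest
     pre-index score.
   The medication rule has an independent day-expansion oracle used for
   randomized equivalence testing.
2. **Feature preparation.** `"VOCAB:code"` tokenization (PAD = 0,
   UNK = 1, fitted on the training split only), truncation/padding to
   length 128 keeping the most recent events, one-hot static encodings
   with age/100, and variance-threshold selection retaining a binary
   column iff its variance ≥ p(1 − p) (p = 0.9 demographics, 0.8
   survey).
3. **Classifier.** An encoder-only self-attention model over the code
   sequence — token embeddings scaled by √d plus sinusoidal position
   and days-until-diagnosis encodings; 2 post-norm layers, 4 heads,
   feedforward width 32, dropout 0.1; masked mean pooling — fused with
   two width-4 ReLU branches for demographic and survey vectors, then a
   linear head and sigmoid:

   p(chronic pain) = σ( w·[ mean_mask(Enc(E√d + PE(pos) + PE(days/30))),
   ReLU(W_d x_demo), ReLU(W_s x_survey) ] + b )

   trained with positive-weighted binary cross-entropy
   −(w·y·log p + (1−y)·log(1−p)), Adam, lr 0.001, 20 epochs, weight 3.0,
   stratified 70/5/25 split. Epoch selection is best validation AUROC
   subject to an overfitting guard (train−validation AUROC ≤ 0.10).
   Forward and analytic backward passes are in C++ (RcppArmadillo) and
   are verified against finite differences.
4. **Evaluation and interpretation.** Accuracy, rank-based AUROC,
   precision, recall and confusion matrices; a positive-weight sweep
   {1, 3, 5}; permutation feature importance (AUROC drop under column
   shuffling); and extraction of the strongest self-attention
   connections of the final encoder layer.
5. **Synthetic cohort generator.** OMOP-style CSV tables for n patients
   with Poisson(109)-length code histories, demographics, 81 survey
   items, opioid exposure intervals and pain scores; outcome drawn from
   a logistic model on planted code/survey/age indicators with the
   intercept solved exactly so prevalence is 0.176.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the
default synthetic cohort (1131 patients, seed 1) and write artifacts
under `results/pipeline/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_phenotype.R
Rscript analysis/03_prepare.R
Rscript analysis/04_train_evaluate.R
Rscript analysis/05_sweep.R
Rscript analysis/06_interpret.R
```

Output from a run of steps 2, 4 and 5 (your numbers will be identical —
everything is seeded):

```
Phenotype positive: 212 of 1131 (18.7%)
Branch counts:
        code exacerbation   medication         none
         150           13           49          919
Agreement with generator truth: 100.0%

 split   n  accuracy     auroc precision    recall  tn fp fn  tp
 train 792 0.8775253 0.9323905 0.6440678 0.7702703 581 63 34 114
  test 283 0.7773852 0.7817063 0.4107143 0.4339623 197 33 30  23
Train-test AUROC gap: 0.151

 pos_weight  accuracy     auroc precision    recall
          1 0.8127208 0.4105824 0.0000000 0.0000000
          3 0.7773852 0.7817063 0.4107143 0.4339623
          5 0.7561837 0.7913043 0.4024390 0.6226415
```

Reading this: the phenotype labels 18.7% of the synthetic cohort
positive (the branch mix — codes, qualifying opioid chains, score
exacerbation — reflects the configured branch rates) and agrees
perfectly with the generator's intended labels. At this small cohort
size the classifier recovers a substantial part of the planted signal
(test AUROC 0.78 against a Bayes optimum of ~0.92 for the generative
law); on a 4000-patient cohort, as exercised in the test suite, test
AUROC reaches ~0.80–0.86 with a train–test gap under 0.10. The
positive-weight sweep shows the expected imbalance trade-off: with
weight 1 the model collapses to the majority class (recall 0), and
recall rises monotonically with the weight at some cost in precision.
The attention report (step 6) shows the strongest final-layer
connections for one test patient — on this run four of the top five
point at `ICD10CM:F32.9`, one of the planted risk codes:

```
 source_position target_position     source_code     target_code     weight
             109              64 SNOMED:10000056   ICD10CM:F32.9 0.04094824
               6              64 SNOMED:10000080   ICD10CM:F32.9 0.03984524
              90              64   ICD10CM:X01.6   ICD10CM:F32.9 0.03952071
               6               2 SNOMED:10000080 SNOMED:10000048 0.03920491
              21              64    ICD9CM:714.5   ICD10CM:F32.9 0.03791550
```

The same workflow is available programmatically:

```r
library(painattn)
run_pipeline("all", config = list(seed = 1L), out_dir = "results/pipeline")
```

Every stage writes its artifacts (CSV tables, labels, metrics, sweep,
importance, attention connections) plus a manifest with per-stage seeds,
timings and MD5 hashes; re-running a stage with unchanged inputs is
byte-identical.

## Scope notes

The synthetic cohort emulates the statistical shape of the study data,
not clinical reality: passing tests demonstrate that the pipeline's
machinery is correct and that a planted additive signal is recovered,
not that the model would achieve any particular performance on real
records. See the methods vignette (`vignettes/methods.Rmd`) for the
model, the phenotype edge cases, the generator's assumptions and the
package's design decisions.
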