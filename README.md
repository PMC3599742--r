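# aiia — Adaptive Interbeat Interval Analysis

`aiia` classifies heart-rate records from the *dynamics* of their interbeat
(RR) intervals. It is aimed at researchers working with heart rate
variability (HRV) who want a symbolic-dynamics representation of RR series —
for separating atrial fibrillation, congestive heart failure, healthy and
apneic recordings, or any other record-level classification task on
PhysioBank-style RR lists.

## The method

For an RR series \(x_1, \dots, x_N\) (milliseconds), the pipeline is:

1. **Differencing.** Compute the signed successive differences
   \(d_i = x_{i+1} - x_i\). Sign and magnitude both matter: a +250 ms and a
   +100 ms lengthening are different physiological events, which a binary
   accelerate/decelerate coding cannot distinguish.
2. **Symbolization by 1-D K-Means.** Cluster the \(d_i\) with Lloyd's
   algorithm into \(k \in [2, 26]\) clusters and map each difference to a
   letter — `a` for the cluster with the smallest centroid, upward from
   there. The partition adapts to each record's own variability (per-record
   fit, the default) instead of using fixed, hand-chosen bins; a pooled fit
   (train-set centroids applied to all records) is also available.
3. **n-gram signatures.** Count all overlapping grams of orders
   \(1..n_{max}\) (order-sensitive: `ab` ≠ `ba`) and convert counts to
   per-order probabilities \(P(g) = c(g) / (L - n + 1)\). Over the full
   26-letter alphabet with \(n_{max} = 3\) the vocabulary has
   \(26 + 26^2 + 26^3 = 18{,}278\) grams; each record becomes one row of a
   probability matrix over that fixed vocabulary.
4. **Classification.** Stratified 10-fold cross-validation with a pluggable
   classifier. A fully specified Gaussian naive Bayes reference classifier
   ships with the package; adapters to established implementations
   (multinomial logistic, kernel naive Bayes, SVM, neural network, CART)
   are provided behind the same interface.

A seeded synthetic-data module generates labelled five-class
(AF / CHF / HE / HY / WNU) and four-class (APNEA / HE / HY / WNU) RR
corpora with the qualitative HRV signature of each group, so the whole
pipeline can be developed and tested without clinical recordings.

## Worked example

```r
library(aiia)

corpus <- generate_study("study2", seed = 42, length = 2000)  # 80 records
report <- run_pipeline(corpus, k = 10, n_max = 2, seed = 42)
print(report)
```

```
Cross-validated classification report (gnb)
  Total instances:       80
  Correctly classified:  75
  Incorrectly classified: 5
  Accuracy:              93.8%

Per-class accuracy:
           APNEA  HE HY WNU
Total         20  20 20  20
Correct       17  20 18  20
Incorrect      3   0  2   0
Accuracy %    85 100 90 100

Confusion matrix (rows = truth):
       predicted
truth   APNEA HE HY WNU
  APNEA    17  3  0   0
  HE        0 20  0   0
  HY        0  2 18   0
  WNU       0  0  0  20
```

80 synthetic records (20 per class, 2,000 intervals each) are differenced,
symbolized with a per-record 10-cluster K-Means alphabet, featurized with
1- and 2-gram probabilities (110 features) and classified by Gaussian naive
Bayes under stratified 10-fold cross-validation: 75 of 80 records are
assigned to the correct group, with the residual confusion between the
apneic oscillation and the healthy-elderly profile.

Real recordings enter the same way via plain-text RR lists:

```r
rec    <- read_rr_record("subject01.txt", unit = "s", label = "CHF")
report <- run_pipeline("manifest.csv", k = 20, n_max = 2)   # path,label,unit
sweep  <- sweep_pipeline(corpus, k_values = 2:26, n_max_values = 1:3)
```

A command-line wrapper with `simulate`, `run` and `sweep` subcommands is in
`inst/cli/aiia.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aiia.R",package="aiia"))')" \
    simulate --preset study1 --seed 1 --outdir sim
```

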