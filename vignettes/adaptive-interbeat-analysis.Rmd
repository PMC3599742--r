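---
title: "Adaptive symbolization and n-gram classification of interbeat intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive symbolization and n-gram classification of interbeat intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiia)
```

## The problem and the representation

Heart-rate dynamics are shaped by the push and pull of sympathetic
(accelerating) and parasympathetic (decelerating) control, and several
cardiac conditions leave characteristic fingerprints in the beat-to-beat
structure of the RR-interval series: atrial fibrillation produces
near-uncorrelated, high-variance intervals; congestive heart failure
suppresses variability while adding erratic excursions; obstructive sleep
apnea imposes a slow cyclic bradycardia–tachycardia oscillation. Symbolic
dynamics is a standard way to expose such structure: map the real-valued
series to a short-alphabet sequence, then summarize the sequence by the
occurrence statistics of its subwords.

The approach implemented here symbolizes the *differences* between
successive intervals, \(d_i = x_{i+1} - x_i\), so that both the direction
and the *degree* of each acceleration or deceleration survive the
transformation — unlike binary up/down codings, which collapse a +250 ms
and a +100 ms lengthening to the same symbol. The quantization thresholds
are not fixed by hand: a one-dimensional K-Means clustering of the
differences chooses them to minimize within-cluster variance, adapting the
alphabet to each record's own variability.

## Pipeline and parameters

`run_pipeline()` composes four stages, each independently usable:

| stage | function | tunables (defaults) |
|---|---|---|
| differencing | `compute_rrid()` | — |
| symbolization | `kmeans1d_fit()`, `assign_symbols()` | `k` = 10 (2–26), `max_iter` = 300, `tol` = 1e-6 ms, `fit_scope` = per-record |
| signatures | `build_vocabulary()`, `featurize()` | `n_max` = 2 (1–3 typical) |
| classification | `crossvalidate()` | 10 stratified folds, Gaussian naive Bayes |

**Cluster count `k`.** The alphabet size, 2–26 (one lower-case letter per
cluster). Small `k` merges distinct variation magnitudes; large `k` refines
them but inflates the gram vocabulary as \(k^{n}\) and thins the counts per
gram. `sweep_pipeline()` produces accuracy-versus-`k` tables over 2..26 for
choosing `k` empirically on a given corpus; with 2,000-interval records the
defaults (`k` = 10, `n_max` = 2) are a sensible operating point, giving 110
features against 1,999 gram windows.

**Gram order `n_max`.** Features are the per-order probabilities of all
grams of orders \(1..n_{max}\) (orders are nested, so raising `n_max` adds
columns without changing existing ones). Each order is normalized
separately — the order-\(n\) probabilities sum to one — because each order
is a self-contained analysis of the sequence at that motif length; this
also makes the order-1 block identical to a standalone 1-gram run and
keeps feature semantics independent of record length. A global
normalization across orders was rejected as it would entangle the blocks
for no analytical benefit.

**Fit scope.** Per-record fitting (the default) is what makes the method
adaptive: each record's differences are clustered on their own scale, so
symbols encode *relative* variation and records of very different absolute
variability remain comparable. The alternative — a pooled model fitted on
training records and applied to all — preserves absolute comparability
instead, at the price of coupling records through the centroids; it is
exposed via `fit_scope = "pooled"`, and `crossvalidate()` then refits the
pooled model inside every fold on the training records only, so validation
records never influence the centroids. Neither reading is privileged;
both are implemented and tested.

## Numerical choices

*K-Means initialization* is deterministic: the starting centroids are the
data quantiles at positions \((i + 0.5)/k\). On one-dimensional data this
spreads the seeds across the empirical distribution and removes any
dependence on random restarts, making every downstream number reproducible
from the data alone. *Assignment ties* (a value exactly midway between two
centroids — a measure-zero event on real data, but tests exercise it) go
to the smaller centroid. *Empty clusters* are re-seeded at the point
farthest from its assigned centroid. *Letter mapping* is
ascending-centroid → alphabetical; any fixed bijection yields the same
gram statistics up to relabelling (a tested invariance), and sorting makes
sequences human-readable and run-stable. Iterations stop when the largest
centroid movement drops below `tol` = 1e-6 ms; the within-cluster sum of
squares is non-increasing across iterations (asserted per iteration in the
test suite). Records shorter than two intervals, non-positive intervals,
`k` exceeding the distinct-value count, and sequence letters outside the
vocabulary all raise immediate, named errors rather than propagating.

The *reference classifier* is a Gaussian naive Bayes chosen to be fully
specified, deterministic and dependency-free: class priors are training
frequencies, class-conditional feature distributions are Gaussians with
maximum-likelihood moments, and variances are floored at \(10^{-9}\) times
the largest pooled feature variance so that grams constant within a class
(ubiquitous in sparse gram features) keep a finite log-density.
Prediction ties break toward the first class in sorted order. The six
classifiers familiar from data-mining toolkits are represented by adapters
(`classifier_logistic()`, `classifier_naive_bayes()`, `classifier_svm()`,
`classifier_nnet()`, `classifier_tree()`) behind the same two-function
interface, so any of them — or a user-supplied `new_classifier()` — can be
swapped into `crossvalidate()`.

*Cross-validation* is stratified by default. With a 9-member class in a
142-record corpus, plain random 10-fold partitions can produce training
folds missing a class entirely; stratified dealing keeps every fold's
class counts within one record of exact proportionality (a property
checked across 100 seeds in the tests). Accuracy is reported from the
confusion matrix pooled over folds — "instances correctly classified" —
not as the mean of fold accuracies, so the accounting identities
(trace = correct, total = sum) hold exactly; per-fold accuracies are
retained in the report. Printed accuracies round half-up to one decimal
place, the convention of the classification tables this layout mirrors
(126/142 → 88.7%).

## What the synthetic corpus emulates — and what it does not

The generators produce minimal statistical surrogates of five HRV
phenotypes, not physiological models:

* **WNU** — i.i.d. uniform intervals on [600, 1400] ms. Only the
  distribution family is meaningful; the range is configurable and
  arbitrary.
* **AF** — i.i.d. truncated-normal intervals (mean 700 ms, sd 180 ms):
  serially uncorrelated with high-entropy differences.
* **CHF** — a low-variability AR(1) baseline (innovation sd 8 ms,
  coefficient 0.9) with rare ±150 ms jumps (probability 0.02/beat):
  suppressed SDNN with erratic excursions.
* **HY / HE** — mean level plus a respiratory-sinus-arrhythmia sinusoid
  plus AR(1) noise. The young preset oscillates strongly (amplitude 60 ms,
  period 5 beats, noise sd 8 ms); the elderly preset is attenuated and
  slower (amplitude 25 ms, period 7 beats, noise sd 5 ms), reflecting the
  reduced and slower respiratory modulation of older subjects.
* **APNEA** — the classic cyclic-variation surrogate: a slow
  bradycardia–tachycardia sinusoid (amplitude 150 ms, period 40 beats)
  over AR(1) noise.

Records default to 2,000 intervals — an order of magnitude below the
hours-long recordings the class structure is modelled on — which keeps a
full five-class, 142-record pipeline run in seconds; full-length corpora
are one `length` argument away. Preset parameters were fixed once, chosen
so that the five classes are genuinely separable by the pipeline (that is
their entire purpose) while respecting the qualitative orderings that
define the phenotypes (CHF SDNN below HY SDNN; HE amplitude below HY). The
structured, strongly oscillatory character of the HY/HE/APNEA surrogates
matters for the higher-order gram analysis: it gives each class a
consistent trigram signature across records, which is what real periodic
physiology provides in long recordings and what a Gaussian model over
sparse gram frequencies needs at this record length.

What passing tests on this corpus show is that the pipeline *recovers
class structure that is present in the symbolic dynamics* — synthetic
separability at 2,000 intervals says nothing quantitative about accuracy
on clinical recordings, which carry ectopy, artifacts, nonstationarity and
within-class heterogeneity that these surrogates deliberately omit. No
artifact filtering is applied at read time (a documented no-op hook exists
in `rr_record()` for future filters).

## Scale of the shipped analyses

The bundled test suite and the reproduction script run the five-class
corpus at 142 records × 2,000 intervals with `k` = 10 and gram orders up
to 3, and average the 2-gram/3-gram comparison over five corpus seeds —
sizes chosen so a complete run takes well under a minute on a single core
while every class keeps at least nine records, mirroring the smallest
group of the reference design. Under these conditions the pipeline
reaches ~0.95–0.98 overall accuracy (seed-dependent), and mean 3-gram
accuracy matches mean 2-gram accuracy to within one standard error —
consistent with higher-order grams adding signature detail once the
alphabet is rich enough, though at these record lengths trigram counts
are thin, so the gain saturates rather than grows.

## Known limitations

* Difference-based symbolization attenuates *slow* modulations: a 40-beat
  apnea cycle moves each individual difference by only a few milliseconds,
  so apneic structure is visible mainly through medium-order grams, and
  very slow trends are nearly invisible. This is intrinsic to analyzing
  \(d_i\) rather than \(x_i\).
* Gram features grow as \(k^{n}\); at `k` = 26 and order 3 most of the
  17,576 trigrams are unobserved in records of a few thousand beats, and
  Gaussian class-conditional models over such sparse frequencies become
  unstable for small classes. Discretization-based classifiers are more
  forgiving there; the adapter interface exists for exactly that reason.
* Records are assumed clean RR lists; no beat-annotation parsing, R-peak
  detection or ectopic-beat handling is provided.
* The 1-D K-Means objective guarantees a local optimum only; the
  deterministic quantile seeding makes results reproducible, not globally
  optimal (on one-dimensional data the two rarely differ in practice).
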