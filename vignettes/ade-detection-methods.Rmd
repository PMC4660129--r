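---
title: "Methods: detecting adverse drug events from structured EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting adverse drug events from structured EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrade)
```

## The problem

An adverse drug event (ADE) is harm caused by drug exposure. In an EHR,
an ADE is operationally visible as an ADE-specific ICD-10 diagnosis code
(e.g. G44.4, drug-induced headache); `ade_target_codes()` packages 27
such codes. The detection task this package formalizes is
discrimination at the point of care: given everything recorded about a
patient *before* a diagnosis from a particular disease neighborhood, does
the patient receive the drug-induced variant or a conventional one? This
is deliberately a hard contrast — cases and controls share a disease
neighborhood by construction — and it is what makes the resulting models
plausible ADE alerting tools rather than general disease classifiers.

## Cohort model

For target code $c$, the case/control rule uses the ICD-10 concept
hierarchy. Two codes are *similar* when they share the first three
hierarchy levels. Patients with $c$ anywhere in their record are
positives; patients with a similar-but-different code and never $c$ are
negatives; everyone else is excluded. Choices made where the design was
genuinely open:

- **Index anchoring**: each patient is anchored at the *first* occurrence
  of their qualifying code. Later occurrences would leak earlier disease
  history into the features.
- **Strictly-before filtering**: `prior_events()` drops events at
  timestamps $\ge$ the index, including ties. EHR timestamps at identical
  instants are unreliable as orderings, so the conservative choice is to
  treat simultaneity as potential leakage.
- **Both-codes patients are positives**: the control definition excludes
  any bearer of the target code, so a patient with both the target and a
  similar code is a case, anchored at the target.
- **Negatives are filtered symmetrically** at their own (similar-code)
  index event, so both classes contribute comparable pre-diagnosis
  windows.
- **Empty prior histories are kept** as all-zero feature rows (a config
  switch can drop them): a patient first seen at diagnosis is a real
  deployment input.

## Feature representations

Two structured data types are used. **Clinical codes** (ICD-10
diagnoses, ATC drugs) become one column per hierarchy-level prefix
present in the data, levels 1–4, valued by default as occurrence counts
— repeated prescriptions are informative — with binary existence as an
option. Prefix lengths are 1/2/3/4 characters for ICD-10 (so level 3 of
G44.4 is G44) and 1/3/4/full for ATC, collapsing ATC's two most specific
official levels into one so both systems expose exactly four levels.
Both mappings are configurable; official block-range tables (e.g.
F20–F29) are out of scope.

**Clinical measurements** are repeated $(t, v)$ series, summarized per
measurement by mean, sample SD ($n-1$ denominator, 0 when $n<2$), slope,
existence, and count. Slope is a rate, $(v_{last} - v_{first}) /
(t_{last} - t_{first})$, reading "over the time span" literally; a pure
difference variant is available. Zero-span or single observations give
slope 0. Missing summaries impute 0: for existence and count zero is
exact; for mean/SD/slope it is a convention that tree ensembles — the
main learners here — tolerate, and the alternative (per-column NA
handling) would exclude most classifiers. Units are never rescaled;
nothing in the pipeline assumes standardized measurements.

Fusion of the two data types is plain column concatenation with an
alignment check (`fuse()`): a single feature set given to one learner,
rather than an ensemble over per-type models.

## Feature selection

Features are ranked by information gain against the class label,
$I(f,Y) = H(Y) - H(Y|f)$ with $H$ in bits and $0 \log 0 = 0$. Continuous
columns are first discretized by equal-frequency binning (default 10
bins, quantile type 1 for determinism; columns with few distinct values
are left as their own categories). Ties in gain are broken
lexicographically by feature name so rankings are reproducible.
Selection takes the top $\lceil \theta m \rceil$ features on the grid
$\theta = 0.1, 0.2, \dots, 1.0$; the ceiling keeps a 10% selection of a
small feature set non-empty. Inside cross-validation, the ranking is
recomputed on each training fold by default (leakage-safe); a `global`
mode ranks once on the full matrix for the cheaper, more optimistic
protocol.

## Evaluation and comparison

The protocol is 10-fold cross-validation repeated 10 times, reporting
accuracy (%) and AUC, both averaged with equal weight over all 100 fold
results. Folds are stratified: at the prevalences this task includes
(down to 2.5%), unstratified folds can lose the minority class entirely.
AUC uses the Mann–Whitney midrank formulation (ties count ½);
`auc()` is checked in the tests against an independent exhaustive
pair-enumeration oracle.

Nine classifier configurations are supported (`classifier_config()`),
with fixed defaults: CART (min 1 per leaf, grown with cp = 0), SVM with
polynomial kernel of degree 3, SVM-RBF with $\gamma = 1/m$ (the
automatic convention; a literal $\gamma = 0$ is degenerate), L2 logistic
regression (ridge, $\lambda = 1/n$, mirroring the common unit-cost
default of regularized implementations), kNN with $k = 5$, AdaBoost with
50 stump estimators, bagging with 10 unpruned trees, Gaussian naive
Bayes, and random forest with 500 trees inspecting
$\lceil\sqrt{m}\rceil$ features per node ("all features per node" is
read as a typographic loss of the $\sqrt{\cdot}$, since it would negate
the algorithm's defining randomization). Standard fitting delegates to
rpart, e1071, glmnet, class and ranger; AdaBoost and bagging are small
in-package loops over rpart trees because no suitable ensemble
implementation is among the declared dependencies. Classifier
randomness is driven entirely by the R RNG (ranger is re-seeded from it,
single-threaded), so a `run_cv()` call is bit-reproducible from its
seed.

Configurations are compared across $N$ datasets by within-dataset ranks
(rank 1 = best, midranks on ties), the Friedman statistic
$\chi^2_F = \frac{12}{Nk(k+1)}\sum_j R_j^2 - 3N(k+1)$ on $k-1$ degrees
of freedom, and pairwise post-hoc tests: raw p-values from the
standardized rank difference
$z = (\bar R_i - \bar R_j)\big/\sqrt{k(k+1)/(6N)}$ against the normal
distribution, adjusted by the Bergmann–Hommel procedure. The adjustment
enumerates *exhaustive* hypothesis sets — pair sets realizable as the
within-group pairs of some partition of the $k$ configurations — via set
partitions; the tests cross-check this against an independent
graph-theoretic characterization (every connected component a clique).
Enumeration cost grows with the Bell number, so $k > 9$ falls back to
Holm with a warning. Bergmann–Hommel is never less powerful than Holm,
and the tests assert that dominance on random p-vectors.

## Synthetic data: what it emulates, and what it does not

`generate_cohort()` produces datasets with the statistical structure the
pipeline assumes: 4-level code hierarchies for both systems; background
code events drawn from a Zipf-like long tail (exponent 1.2), reproducing
the extreme sparsity of real code features; per-measurement Gaussian
baselines with Poisson observation counts and uniform timestamps over
each patient's pre-index window; binomial labels at a configurable
prevalence bounded to the realistic 2.5%–87.5% range; exact duplicate
rows injected at probability 0.02 to exercise multiplicity-sensitive
representations; and planted effects that act on positives only through
a chosen channel (code count or presence, measurement mean or slope).

The canonical study conditions (`planted_signal_spec()`) are 500
patients at 20% prevalence with one drug-code count effect (mean 3 extra
occurrences) and one measurement mean shift (1.5 SD) — one signal per
data type, effect sizes chosen once as a strong but not deterministic
clinical signal. The default vocabulary yields roughly 600 feature
columns, matching the smaller end of realistic per-ADE datasets while
keeping the full simulation suite inside a few CPU-minutes; the test
suite runs the 10×10 CV protocol at exactly this scale, and the fusion
comparisons use single-repeat 10-fold CV over 10 generation seeds.

What the generator does **not** emulate — and therefore what passing
simulations cannot establish about clinical data: correlated
comorbidity structure between codes, visit/calendar clumping of events,
measurement units and reference ranges, label noise from miscoding
(real diagnosis codes are wrong at material rates), and informative
missingness (which measurement is taken is itself diagnostic in real
records). Results here validate the machinery — leakage-free cohorting,
correct statistics, recoverable planted signal — not clinical
performance.

## Numerical and degenerate-input choices

- Entropy and gain use $\log_2$ throughout; gains are clamped only by
  arithmetic (non-negativity holds up to ~1e-15 rounding, asserted at
  1e-12 in tests).
- Cohorts with zero positives or zero negatives raise a
  degenerate-cohort error rather than producing a one-class dataset.
- When the minority class is smaller than the fold count, folds are
  reduced with a warning; below 2 members per class, CV refuses to run.
- Constant training columns are dropped per fold; if every column is
  constant the fold predicts the training prevalence.
- Test folds with a single class record accuracy but NA AUC; means are
  over non-NA folds (stratification makes this rare).
- Event-log writing is canonical (sorted rows, 17-significant-digit
  numeric formatting), so write→read→write is byte-identical and
  repeated runs diff cleanly.

## Limitations

Only structured events are modeled — no clinical notes or lab-test
panels. The similarity rule assumes the 3-level prefix is a clinically
sensible control neighborhood, which varies in quality across ICD
chapters. The information-gain filter is univariate: interactions
invisible to single-feature gain will be selected only by accident. And
the classifier comparison treats hyperparameters as fixed defaults;
nothing here tunes them.
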