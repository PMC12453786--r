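---
title: "Benchmarking and fuzzy-ranking diagnostic classifiers for rheumatic and autoimmune disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking and fuzzy-ranking diagnostic classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdosmbench)
```

## The problem

Differential diagnosis across six rheumatic/autoimmune conditions
(rheumatoid arthritis RA, reactive arthritis ReA, ankylosing spondylitis
AS, Sjögren's syndrome SS, systemic lupus erythematosus SLE, psoriatic
arthritis PA) plus a normal class N can be framed as seven-class tabular
classification over fourteen routine clinical features: age, gender, the
inflammation markers ESR (mm/hr) and CRP, the serological titres RF and
anti-CCP, six binary antibody/genetic markers (HLA-B27, ANA, anti-Ro,
anti-La, anti-dsDNA, anti-Sm), and the complement levels C3 and C4
(mg/dL). Once a dozen candidate classifiers have been trained and
scored on seven partially redundant metrics, *picking one model* is
itself a multi-criteria decision problem; this package pairs a
reproducible benchmark harness with the fuzzy decision by opinion score
method (FDOSM), which turns expert linguistic comparisons against
per-criterion ideal solutions into a group ranking.

The package covers five stages, each usable on its own:

1. **Synthetic cohort generation** (`generate_cohort`,
   `inject_missingness`) so the full pipeline is testable without any
   patient-level data;
2. **Preprocessing**: mean/mode imputation, binary/one-hot encoding, the
   ADASYN oversampler, and a per-class stratified 70/30 split;
3. **Benchmarking** twelve classifier configurations (`run_bench`);
4. **Evaluation**: macro precision/recall/F-score, multiclass Cohen's
   kappa, Hamming loss, the Gorodkin multiclass Matthews correlation,
   accuracy, a cross-validation overfitting gap, and
   balanced-vs-unbalanced difference statistics;
5. **FDOSM ranking** (`run_fdosm`) and **local/global explanations**
   (`explain_local`, `explain_global`).

## The synthetic cohort generator

The generator emulates the published cohort's *population marginals*:
12,085 patients in seven classes (RA 2,848, AS 2,127, SS 1,852, PA
1,783, N 1,604, SLE 1,355, ReA 516), each numeric feature's reported
min/max, mean and standard deviation, each binary feature's positivity
rate, and each feature's missing-data fraction (0% for age and gender up
to 43% for anti-Sm). Numeric features are drawn from a truncated normal
on the reported `[lo, hi]`; because some reported marginals are strongly
skewed (age has mean 29.9 and standard deviation 17.6 against a minimum
of 20), naive truncation would inflate the mean by almost 30%, so the
pre-truncation location is calibrated by root-finding so the
*post-truncation* mean equals the target. Sampling is by rejection in
the central regime and switches to the exact inverse-CDF in the dominant
tail when the truncation window carries negligible normal mass (a
strongly shifted class mean can push the location more than eight
standard deviations outside the range, where rejection would effectively
never accept). Missingness is masked per column, completely at random
(MCAR), at the reported rates.

**What is invented.** The source reports marginals only, never per-class
feature distributions. The default class profiles are therefore an
invented, documented choice informed by the clinical meaning of each
marker: RF/anti-CCP elevated in RA; HLA-B27 positivity high in AS and
ReA; anti-Ro/anti-La positive in SS; anti-dsDNA/anti-Sm positive and
C3/C4 depressed in SLE; ESR/CRP elevated in every disease class and low
in normals; ReA skewed younger and male. Shift magnitudes were chosen
once, roughly balanced by class weight so the population marginals stay
within a few percent of their targets, and are fully overridable through
`generator_config()` or the shipped `generator_config.yaml`.

**What the generator does not emulate.** Within a class, features are
conditionally independent: there are no real-data correlations between,
say, ESR and CRP beyond those induced by the shared class label, no
measurement artefacts, and no informative (MAR/MNAR) missingness. Two
consequences matter when reading test results. First, passing tests
demonstrate that the *pipeline machinery* is correct, not that any
specific published accuracy is recovered — absolute metric levels depend
on the real data and are out of scope by design. Second, conditional
independence is exactly the assumption of Gaussian naive Bayes, so NB is
relatively stronger on synthetic cohorts than on real data; the
qualitative ensemble-dominance check therefore carries a small
tolerance.

## Preprocessing

*Imputation* fills numeric columns with the mean of the observed values
and categorical/binary columns with the observed mode (first-listed
category on frequency ties). It preserves observed column means exactly
and is idempotent. Following the study's order of operations, imputation
is fitted on the full table before splitting; this leaks a small amount
of distributional information from test to train, which is noted here
and accepted for comparability (fit the imputer on the training part
yourself if you need the leak-free variant — the functions compose
either way).

*Encoding* maps two-level categoricals to a single 0/1 column with the
fixed conventions female = 0 / male = 1 and negative = 0 / positive = 1,
expands anything with more than two levels one-hot, and passes numeric
columns through. A fitted encoder can be reapplied to new data and
raises an error naming the column on unseen categories.

*ADASYN* implements the adaptive synthetic oversampler from its four
defining steps: budget `G = (n_maj − n_min) · β`; per minority point the
fraction `η_i` of its `k = 5` nearest neighbours (over the whole
dataset) belonging to other classes; normalised weights
`r_i = η_i / Σ η`; allocations `g_i = r_i · G`. Points whose
neighbourhoods are dominated by other classes thus receive more
synthetic mass. Each synthetic sample interpolates
`x_new = x_i + δ (x_zi − x_i)`, `δ ~ U(0,1)`, toward one of the point's
`k` nearest *minority* neighbours, so every synthetic point lies on a
segment between two genuine minority points — a property the tests check
exactly, alongside an independent brute-force re-derivation of the
`g_i`. Unstated details resolved here: neighbour search uses Euclidean
distance on min-max scaled features (scaling is for the search only);
`n_maj` is the size of the largest class; fractional `g_i` are rounded
half-up and the residual is redistributed over the largest-`r_i` points
so `Σ g_i = G` exactly. With the published class sizes and `β = 1`, ReA
grows 516 → 2,848 (the size of the largest class); the published
balanced count of 2,946 is not reachable from the stated budget formula
with `β ≤ 1` and is deliberately not emulated.

*Splitting* is stratified per class with `round(0.7 · n)` (half-up)
training rows. The published per-class split counts deviate slightly
from exact 70% (e.g. RA 1,997 train where 0.7 × 2,848 = 1,993.6); the
arithmetic rule is implemented rather than hard-coding those counts.

## The benchmark and its learners

`model_specs()` encodes the twelve configurations with the published
hyperparameters (e.g. XGBoost: 100 estimators, depth 6, learning rate
0.3; KNN: 5 neighbours; AdaBoost: 50 estimators). Training delegates to
the established R learners: xgboost, class::knn, rpart, randomForest,
e1071 (SVM, Gaussian NB), nnet, glmnet, and ranger with the
extremely-randomised split rule. Three mappings deserve note: the
gradient-boosting and LightGBM-style configurations are realised as
xgboost parameterisations (depth-wise, η = 0.1, depth 3, λ = 0;
histogram + loss-guide growth with 31 leaves, respectively — the
leaf-wise `min_child_samples = 20` has no exact analogue and stays at
the xgboost default); the SGD-style linear classifier is ridge-penalised
multinomial logistic regression (glmnet, pathwise to λ = 1e-4); and
AdaBoost is an in-package SAMME over depth-1 rpart stumps because no
installed package provides one. The neural network uses nnet's
BFGS optimisation (size 100, decay 1e-4, 200 iterations); a per-epoch
learning rate has no counterpart there. Features are *not* standardised
for any learner, matching the published settings' silence; expect the
RBF-kernel SVM and the network to underperform on raw feature scales. A
`regularized = TRUE` spec set (λ = 0.2, depth 4, 50% feature
subsampling, decay 0.2) mirrors the described overfitting mitigation and
is off by default.

`cross_validate()` uses stratified K = 5 folds and feeds `overfit()`,
whose gap is `(train − validation)/train × 100` with statuses Yes
(≥ 10%), Mild (5–10%), No (< 5%). `diff_report()` computes the absolute
and percentage differences between a balanced and an unbalanced run per
metric.

## The metric suite

All metrics are reported as percentages from one-vs-rest confusion
counts. Precision, recall and F-score are macro-averaged (per-class
ratios averaged over classes; a class with an empty denominator
contributes 0 and is flagged) — macro is the only averaging consistent
with the published tables, where balanced-set precision differs from
accuracy. Kappa is multiclass Cohen's `(p_o − p_e)/(1 − p_e)`; MCC is
the Gorodkin multiclass generalisation; Hamming loss for single-label
multiclass prediction equals the error rate, so `HL = 100 − accuracy`
holds identically — a relation the published tables satisfy and the test
suite asserts on every bench run. One-vs-rest ROC AUC uses the
Mann-Whitney rank statistic with midranks for ties. Values are stored at
full precision and rounded only for display.

## FDOSM

Given an `m × n` decision matrix (here 12 models × 7 metrics, all
benefit-directed except Hamming loss), the ideal solution per criterion
is the column maximum (benefit), minimum (cost), or the value nearest a
stated target (critical — named in the method but never exercised in the
source; nearest-to-target is this package's interpretation, with the
first-listed alternative taking ties). Experts then express each cell's
distance from its criterion's ideal on the five-term ordinal scale ND <
SD < D < BD < HD (no/slight/-/big/huge difference), giving one opinion
matrix per expert. Opinions are *inputs*: the value-to-term mapping is
expert judgement, and the only in-package generator of terms
(`suggest_opinions()`) is explicitly a demo helper.

Terms map to triangular fuzzy numbers — ND (0, 0.10, 0.30), SD (0.10,
0.30, 0.50), D (0.30, 0.50, 0.75), BD (0.50, 0.75, 0.90), HD (0.75,
0.90, 1.00) — defuzzified by the mean `(V1 + V2 + V3)/3`. Ranks count
strictly smaller scores (`R_i = 1 + #{S_j < S_i}`, ties share the rank),
and the *lowest* score is best, since a low score means small distance
from the ideal.

**Aggregation and rounding.** The source exhibits two conventions. Its
three-model worked example *sums* per-criterion fuzzy means after
rounding each to 4 decimals (two D terms give 0.5167 + 0.5167 = 1.0334,
and two ND terms give 0.1333 + 0.1333 = 0.2666 — both require the
per-criterion rounding). Its main ranking table instead *averages*:
per-expert scores are the mean over criteria of the unrounded
per-criterion fuzzy means, rounded to 4 decimals (six ND and one SD give
1.1/7 = 0.1571; five BD and two D give 4.61667/7 = 0.6595, which
per-criterion rounding would misreport as 0.6596), and the group score
averages the *rounded* per-expert scores (0.2048 + 0.2048 + 0.1810
yields 0.1969, unreachable from the unrounded values). `fuzzy_scores()`
therefore rounds per-criterion in `sum` mode and per-alternative in
`mean` mode, and `group_decision()` averages rounded per-expert scores —
the one pair of conventions reproducing every published score
simultaneously. `mean` is the default, matching the headline table.

```{r fdosm-demo}
ext <- function(f) system.file("extdata", f, package = "fdosmbench")
dm <- read_decision_matrix(ext("dm_balanced.csv"), ext("dm_directions.json"))
res <- run_fdosm(dm, list(ext("expert1.csv"), ext("expert2.csv"),
                          ext("expert3.csv")))
res
```

Mean-mode scores are bounded in [0.1333, 0.8833] (all-ND and all-HD
rows), escalating any single term never lowers a score, and permuting
the alternative rows permutes the output identically; the test suite
checks these properties over randomised opinion matrices.

## Explanations

`explain_local()` is a perturbation-based local linear surrogate in the
LIME tradition: numeric features receive Gaussian noise scaled by the
background standard deviation, binary features flip with probability
0.3, perturbations are weighted by an exponential proximity kernel
(width `0.75 √p` on standardised distance), and a weighted ridge
regression of the target-class probability yields one signed weight per
feature (all 14 by default). On a linear oracle the recovered weights
correlate with the true coefficients above 0.9 across seeds.
`explain_global()` offers two documented interpretations — mean absolute
local weight over a stratified instance sample, or permutation
importance clamped at zero — because the source does not state how its
global scores were produced. The published case-study weights are
real-data artefacts and serve only as a format reference, never as
numeric targets.

## Numerical conventions and problem sizes

Reported scores use round-half-up (base R rounds halves to even, which
cannot reproduce several published 4-decimal values). Degenerate inputs
are defined rather than left to chance: empty per-class metric
denominators contribute 0 and are flagged; a single observed value
reports a standard deviation of 0; a constant training label yields a
constant classifier for every spec; `beta = 0` makes ADASYN a warning
no-op. Determinism is explicit — every stochastic step takes a seed and
the suite asserts byte-identical reruns.

The test suite exercises the full 12,085-patient default cohort for
generation, marginal recovery, missingness rates, imputation and the
ADASYN budget, and for the held-out learnability check (boosted trees
must beat three times the 1/7 chance rate; observed around 58%
accuracy). Multi-model bench properties run on cohorts scaled to 3–15%
of the default sizes, which keeps the qualitative behaviour (tree
ensembles lead; memorising learners hit training accuracy 1) while the
whole suite stays interactive.

## Known limitations

Class-conditional profiles are invented (see above), so synthetic
cohorts cannot validate absolute diagnostic performance. The Hamming
loss implementation is the single-label specialisation; multi-label
prediction is out of scope. The critical-value ideal direction follows a
documented interpretation. The SGD/GBoost/LGBM configurations are
faithful-in-spirit mappings onto available learners, not bit-compatible
reimplementations of other libraries' estimators.
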