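---
title: "Predicting activity cliff compounds from bioactivity profiles"
author: "acprofiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting activity cliff compounds from bioactivity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An activity cliff (AC) is a pair of structural analogues with opposite
activity outcomes against the same target. When activity data come from
binary screening readouts rather than potency values, the natural AC
definition is assay-wise: two members of the same matching molecular
series (MMS) of which one is active and the other inactive in a given
assay. Such pairs are the worst case for structure-based machine learning,
because the representation says "almost identical" while the labels say
"opposite". This package studies an alternative compound representation —
the *bioactivity profile*, a compound's row of 0/1 outcomes across the
assays of a complete profiling matrix — and, crucially, *why* it works
when it works: the answer is nearest-neighbor similarity between the
held-out test assay and individual profile assays.

## Matching molecular series and activity cliffs

Compounds with at most 60 heavy atoms are fragmented by severing acyclic
single bonds. For a single cut, the smaller fragment is the substituent
and the larger the core; a fragmentation is retained when

$$(N_{sub} - N_{att}) / N_{mol} \le 0.2,$$

where $N_{sub}$ counts substituent heavy atoms, $N_{att}$ attachment
points and $N_{mol}$ parent heavy atoms. The threshold is inclusive:
a 7-atom substituent on a 30-atom parent (ratio exactly 0.2) passes.
Cores and substituents are serialized as canonical SMILES with `*`
attachment placeholders (OpenBabel canonicalization), so cores reached
from different parents compare byte-for-byte; all compounds sharing a core
form one MMS. An MMS with $n_a$ actives and $n_i$ inactives in an assay
yields exactly $n_a \times n_i$ ACs.

Design choices in this layer, made where several readings were possible:

* **Cut multiplicity.** Single-cut fragmentation is the default — the
  established MMS convention with one substitution site. `cuts = 2`
  additionally enumerates two-cut fragmentations whose inner linker is the
  (two-attachment) substituent; this changes MMS composition and is off by
  default.
* **Size ties.** If both fragments have equal size, every orientation
  passing the ratio filter is emitted.
* **Attachment labels.** Attachment points are unnumbered `*` atoms;
  symmetric cores therefore canonicalize identically without extra
  bookkeeping. Heavy-atom counts never include `*` or hydrogens.
* **Charges.** Formal charges are not carried through the fragment
  molblock round-trip; the chemistry layer targets neutral molecules.

## The profiling matrix and assay similarity

The profiling matrix is complete (no missing cells) and binary; rows are
compound bioactivity profiles, columns assay activity vectors. Compounds
inactive in every assay are removed before analysis
(`drop_all_inactive_compounds()`, idempotent). Assay similarity is the set
Tanimoto

$$T(a, b) = \frac{|A \cap B|}{|A \cup B|}$$

over the assays' active compound sets. Two conventions: an empty union is
defined as similarity 0 (no shared evidence — keeps rankings total), and
ranking ties are broken by ascending assay identifier, so rankings are
reproducible. Whenever a similarity feeds model construction it is
computed over *training compounds only*; the package's matrix accessor can
be instrumented (`instrumented_matrix()`) and the test suite asserts that
no post-split operation ever reads a test compound's cell in the test
assay.

## Leakage-controlled partitioning

Two schemes, both over AC-forming series only (series with one label are
excluded and counted):

* **Intra-series split**: within each series all actives go to one
  partition and all inactives to the other; the orientation is drawn with
  probability 0.5 per series. Training never sees analogues with opposite
  labels, but the test set contains the *opposite-label analogues of
  training compounds* — the adversarial scenario for structural
  representations. Compounds belonging to several series keep their first
  assignment (series processed in seeded shuffled order); a later series
  that cannot satisfy label purity because of a pinned compound is dropped
  and counted. Train/test ratios are whatever the orientations produce.
* **Series-unit split**: whole series are assigned to one partition,
  targeting a "80:20" ratio *in compounds* (the natural reading of a
  train-to-test data ratio). Series sharing compounds are first merged
  into clusters (union-find), which removes assignment conflicts
  altogether — a deliberate departure from pin-and-drop, since here the
  invariant (no boundary-crossing series) can be met without discarding
  data. Clusters are shuffled under the seed, assigned greedily, locally
  repaired (moves, then pairwise swaps), and — in the rare cases where
  local repair stalls in a 2-for-1 exchange minimum — finished by an exact
  subset-sum reconstruction, so the training size is always the closest
  achievable to the target.

Class imbalance is handled with inverse-frequency weights
$w(\ell) = n/(2 n_\ell)$ during training, never by resampling.

## Representations

For each test assay the remaining assays form the profile (121 in the
full-scale setting; the test assay is never a feature — attempting it is a
hard error). Reduced profiles keep the top half or top 10 most similar
assays per the training-compound ranking; equally sized random reductions
serve as controls. The structural representation is a 2048-bit ECFP4:
radius-2 circular environments built from (element, heavy degree,
bond-order sum, ring membership) seeds, iteratively rehashed over
bond-ordered neighbors and folded modulo 2048. Bit collisions are accepted
as usual. The combined representation concatenates profile-then-fingerprint.

In this package the random controls are *replicated*: each random
reduction is drawn `random_draws = 3` times per assay and metrics are
averaged. A single 10-of-121 draw contains the one informative assay with
probability 0.083, which at desk scale (a dozen test assays) makes a
single-draw control estimate noisy; averaging three draws is an unbiased
variance reduction of the same quantity.

## Models and the 1-NN baseline

RF, XGB and RBF-SVM are calibrated by grid search with stratified 5-fold
cross-validation (selection metric: balanced accuracy of thresholded
predictions) and refit on the full training partition. The grids are
deliberately small and conventional — RF: trees {100, 500} × depth
{unlimited, 10} (depth is mapped to `maxnodes = 2^depth`, capped at the
sample count, since randomForest exposes no depth parameter); XGB:
rounds {100, 500} × depth {6, 10} × learning rate {0.1, 0.3}; SVM:
cost {0.1, 1, 10} × gamma {1/p, 0.01}. Scores are probability-of-active
for the tree ensembles (for RF, the fraction of trees voting active) and
signed decision values oriented towards the active class for the SVM;
classification thresholds are 0.5 and 0 respectively.

The 1-NN baseline asks how far a single similar assay carries: the profile
assay $j_{NN} = \arg\max_j T(t, j)$ (training compounds only) is found and
every test compound simply receives its label from column $j_{NN}$.

MDI feature importance for forests is computed by routing the training
data through every tree and summing $p(t)\,\Delta i(s_t, t)$ with
$p(t) = N_t/N$, $\Delta i = i(t) - p_L i(t_L) - p_R i(t_R)$, averaging
over trees and normalizing to sum 1. The test suite checks this traversal
against the forest library's own Gini importance on full-sample trees to
within $10^{-9}$.

## Evaluation

Balanced accuracy, MCC (zero-denominator convention: 0) and ROC-AUC
(probability a random positive outranks a random negative, ties half).
Per experiment cell, test assays are grouped by their MCC distribution:
strictly above the third quartile "positive", strictly below the first
"negative", the closed interval between "interquartile". Quartiles use
linear interpolation (R type 7); group sizes near quartile boundaries can
shift by one under other quantile conventions. Representations are
compared per scheme/algorithm with two-sided Wilcoxon signed-rank tests
(exact for ≤ 25 untied non-zero differences, normal approximation
otherwise; all-zero difference pairs are flagged, not tested) and
Holm–Bonferroni adjustment at α = 0.05.

## The synthetic benchmark

`synthetic_config()` describes the study conditions; the defaults are the
desk-scale analogue of a large profiling-matrix campaign:

| parameter | default | meaning |
|---|---|---|
| `n_series` | 60 | analog series (one unique scaffold each) |
| `analogs_per_series` | 4–8 | single-site substituent variants |
| `n_assays` / `n_test_assays` | 133 / 12 | 121 profile assays, as full scale |
| `base_active_rate` | 0.01 | background Bernoulli sparsity (~1 % actives) |
| `ac_fraction` | 0.6 | series given mixed labels per test assay |
| `n_planted` / `flip_rate` | 6 / 0.1 | test assays with a planted neighbor |

Mixed labels draw the active count uniformly from 1 to size − 1, which
guarantees cliffs. Planted neighbors are generated by flipping every label
of the test column independently with probability ε, so the induced
similarity is high but noisy (it is measured, never asserted) and 1-NN
transfer accuracy concentrates at 1 − ε. Substituent choice is
scaffold-size aware: only substituents passing the fragment-to-size filter
on their scaffold are used, so the ground-truth series are recoverable by
the fragmentation layer — that recoverability is the generator's contract.

What the generator does *not* emulate: assay biology and target families,
realistic chemistry beyond valid analog series, correlated background
assays, and realistic (sparse) test-assay columns — test assays are
AC-enriched by construction so that every test assay supports a split.
Consequently, green benchmarks show that the machinery is correct and that
planted similarity structure is found and exploited; they do not show that
real screening matrices contain such structure.

## Problem sizes and numerical choices

The test suite and the acceptance script run the benchmark at the default
scale above (~360 compounds × 133 assays, 12 test assays, single RF
setting with 200 trees), the split-invariant checks on 1,000 random
fixtures, and the fragmentation round-trip on 200 series; the full
hyperparameter grids are exercised on small separable sets where grid
search itself is under test. Seeds fan out from one master seed via a
stable string hash (`fan_out_seed`), so every cell of an experiment is
independently reproducible; reruns of `run_experiment()` with the same
configuration are identical table-for-table. Degenerate cells (an assay
whose split leaves one class in training, fewer than two AC series, etc.)
are logged and reported as NA rows rather than aborting a sweep.

## Known limitations

* Neutral molecules only through fragmentation; no stereochemistry-aware
  series handling; no ring-cut (core-hopping) fragmentation.
* Binary labels only — no potency-difference cliffs, no regression.
* ECFP4 bits are internally consistent but not interchangeable with other
  toolkits' bit positions.
* The 1-NN baseline and assay similarity assume a *complete* matrix;
  missing-value handling is out of scope.
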