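# acprofiles

Activity cliffs (ACs) are pairs of structural analogues — members of the
same matching molecular series (MMS) — with opposite activity outcomes in
the same assay. They are the hardest cases for activity prediction from
chemical structure: by construction, nearly identical molecules carry
different labels. `acprofiles` implements an alternative: predicting the
activity state of AC compounds from their **bioactivity profiles** — their
rows in a complete binary compound-profiling matrix — and quantifying *why*
such predictions succeed or fail, namely through nearest-neighbor
relationships between the held-out test assay and the profile assays.

The package is aimed at cheminformaticians working with screening
profile matrices (e.g. PubChem-derived compound × assay tables) who want
leakage-controlled benchmarks of profile-based versus structure-based
activity prediction.

## What it computes

- **Matching molecular series / activity cliffs.** Compounds (≤ 60 heavy
  atoms) are fragmented at acyclic single bonds (single-cut, with a
  double-cut option); a fragmentation is kept when the substituent passes
  the fragment-to-size filter (N<sub>sub</sub> − N<sub>att</sub>)/N<sub>mol</sub> ≤ 0.2.
  Compounds sharing a canonical core form an MMS; every active/inactive
  pair within an MMS in a given assay is an AC, so a series with
  *n<sub>a</sub>* actives and *n<sub>i</sub>* inactives contributes
  *n<sub>a</sub> · n<sub>i</sub>* cliffs.
- **Assay similarity.** For assays *a*, *b* with active compound sets *A*,
  *B* (restricted to training compounds to prevent leakage),
  *T(a,b) = |A ∩ B| / |A ∪ B|*.
- **Leakage-controlled splits.** *Intra-series*: per series, all actives to
  one partition, all inactives to the other (orientation randomized);
  *series-unit*: whole series assigned to one side, targeting an 80:20
  compound ratio.
- **Representations.** The 0/1 bioactivity profile over the profile assays;
  similarity-reduced profiles (top 50 %, top 10) with random-reduction
  controls; a 2048-bit ECFP4 fingerprint; and the profile ⊕ ECFP4
  concatenation.
- **Models.** Random forest, XGBoost and RBF-SVM with grid-search 5-fold CV
  and inverse-frequency class weights, plus a 1-nearest-neighbor baseline
  that simply copies each test compound's label from the single most
  similar profile assay. For forests, mean decrease in impurity (MDI)
  importance Imp(X<sub>m</sub>) = (1/N<sub>T</sub>) Σ<sub>T</sub> Σ<sub>t : v(s_t)=X_m</sub> p(t) Δi(s<sub>t</sub>, t),
  normalized to sum 1.
- **Evaluation.** BA = (TP/(TP+FN) + TN/(TN+FP))/2, MCC, ROC-AUC
  (midrank convention), MCC-quartile performance groups
  (positive / interquartile / negative), and paired two-sided Wilcoxon
  signed-rank tests with Holm–Bonferroni adjustment.
- **Synthetic benchmark.** A generator for analog-series libraries (valid
  SMILES, one scaffold per series) and complete binary matrices with ~1 %
  background activity, AC-rich test assays, and *planted* nearest-neighbor
  profile assays: copies of a test assay's activity vector with each label
  flipped at rate ε, so 1-NN transfer accuracy concentrates at 1 − ε.

## Worked example

```r
library(acprofiles)

fragment_molecule("Cc1ccc(F)cc1", "p-fluorotoluene")
#>         parent_id     core_key substituent n_sub n_att
#> 1 p-fluorotoluene *c1ccc(cc1)F          *C     1     1
#> 2 p-fluorotoluene *c1ccc(cc1)C          *F     1     1

scfg <- synthetic_config(n_series = 40, analogs_per_series = c(4, 6),
                         n_assays = 60, n_test_assays = 6, n_planted = 3,
                         seed = 7)
lib <- generate_library(scfg)
gm  <- generate_matrix(scfg, lib)
cfg <- experiment_config(synthetic = scfg,
                         test_assays = gm$truth$test_assays,
                         schemes = "intra_series",
                         representations = "profile_all", algos = "RF",
                         grids = list(RF = data.frame(ntree = 200,
                                                      max_depth = 0)),
                         seed = 11)
res <- run_experiment(cfg)
res$results[, c("test_assay", "algo", "ba", "mcc", "group")]
#>    test_assay algo   ba    mcc         group
#> 1   assay_012  1NN 0.96  0.915      positive
#> 2   assay_012   RF 0.96  0.915      positive
#> 3   assay_015  1NN 0.84  0.699 interquartile
#> 4   assay_015   RF 0.84  0.699 interquartile
#> 5   assay_032  1NN 0.87  0.742      positive
#> 6   assay_032   RF 0.87  0.742      positive
#> 7   assay_034  1NN 0.47 -0.059      negative
#> 8   assay_034   RF 0.59  0.182 interquartile
#> ...
```

The three test assays with a planted nearest neighbor (`assay_012`,
`assay_015`, `assay_032` — see `gm$truth$planted`) are predicted far above
random by both the random forest and plain 1-NN label transfer, while the
assays without a similar profile assay hover around BA ≈ 0.5. The MDI
importances of the forest for `assay_012` are dominated by exactly its
planted neighbor:

```r
imp <- subset(res$importances, test_assay == "assay_012")
head(imp[order(-imp$mdi), c("feature_id", "mdi")], 3)
#>    feature_id  mdi
#> 10  assay_010 0.65   # the planted neighbor of assay_012
#> 5   assay_005 0.17
#> 1   assay_001 0.02
```

A command-line front end with `simulate` / `series` / `run` / `report`
subcommands is installed under `inst/cli/acprofiles.R`.

## Limitations

- The fragmentation layer targets neutral organic molecules; formal
  charges are not carried through core/substituent canonicalization.
- ECFP4 bit positions follow the package's own hashing (radius-2 circular
  environments folded to 2048 bits) and are not exchangeable with other
  toolkits' bit assignments; all downstream analyses depend only on
  fingerprint geometry, not on specific bit positions.
- The synthetic generator emulates the statistical structure of profiling
  matrices (sparsity, AC enrichment, planted similarity), not assay
  biology. See the methods vignette for what passing benchmarks do and do
  not establish about real screening data.
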