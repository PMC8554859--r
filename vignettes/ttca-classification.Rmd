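---
title: "Classifying tumor T cell antigens from peptide sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor T cell antigens from peptide sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumor T cell antigens (TTCAs) are peptides presented by MHC class I
molecules that CD8+ T cells can recognize on tumor cells; identifying them
from sequence alone supports cancer-vaccine candidate screening.
`pepTTCA` frames this as binary classification of short peptides
(typically 8–25 residues) into TTCA (label 1) and non-TTCA (label 0), and
implements the complete workflow: fixed-length feature encoding, feature
ranking and selection, class rebalancing, random-forest modeling, and
threshold plus ranking metrics. Because curated TTCA benchmark sets are
external downloads of uncertain availability, the package also ships a
synthetic peptide generator with a controllable compositional class
signal, so every stage can be exercised and tested offline.

## Feature encoders

All encoders are pure functions of the sequence over the standard
20-letter alphabet; a validated `peptide_dataset` rejects anything else
(non-standard residues such as B, J, O, U, X, Z are rejected by default,
or dropped per record with `residue_policy = "drop"`).

**GPSD (188 features).** The global protein sequence descriptor is the
amino acid composition (20 residue frequencies) followed by CTD blocks
for eight physicochemical properties (hydrophobicity, normalized van der
Waals volume, polarity, polarizability, charge, surface tension,
secondary-structure preference, solvent accessibility). Each property
splits the 20 residues into three groups (the partitions ship as a
versioned TSV in `inst/extdata`, load with `ctd_property_table()`).
Per property: **C** is the frequency of each group (3 values); **T** is
the count of adjacent residue pairs whose groups differ, tallied as
unordered group pairs and divided by $L-1$ (3 values); **D** records, for
each group, the positions of its first, 25%, 50%, 75% and last occurrence
as fractions of $L$ (15 values). We chose fractional positions in
$(0, 1]$ rather than percentages so all CTD features live on a common
scale, and a group absent from the sequence contributes five zeros. The
$q$-quantile occurrence is the $\max(1, \lceil q\,n_g\rceil)$-th of the
$n_g$ occurrences, which agrees with direct enumeration on small cases
and needs no interpolation. $8 \times (3+3+15) = 168$, plus 20 for the
composition.

**GAAPC (155 features).** Residues collapse into five groups — aliphatic
`c1` = GAVLMI, aromatic `c2` = FYW, positively charged `c3` = KRH,
negatively charged `c4` = DE, uncharged `c5` = STCPNQ — and the grouped
amino acid (5), grouped dipeptide ($f(x,y) = N_{xy}/(L-1)$, 25) and
grouped tripeptide ($f(x,y,z) = N_{xyz}/(L-2)$, 125) compositions are
concatenated. GDPC needs $L \ge 2$ and GTPC $L \ge 3$; these are hard
errors, reported per record at dataset encoding time.

**ASDC (400 features).** The adaptive skip dipeptide composition counts,
for every ordered residue pair $(a, b)$, the index pairs $i < j$ with
$s_i = a$ and $s_j = b$ — i.e. dipeptides with any number of intervening
residues, the full skip window up to $L-2$ — normalized by the total
number of index pairs $L(L-1)/2$, so the 400 components sum to 1.

**PAAC (20 + λ features).** Type-1 pseudo amino acid composition.
Hydrophobicity, hydrophilicity and side-chain mass are standardized to
mean 0 and population SD 1 across the 20 residues; the correlation
function $\Theta(a,b)$ is the mean squared difference of the three
standardized values, and the $j$-th sequence-order factor is
$\theta_j = \frac{1}{L-j}\sum_{i=1}^{L-j}\Theta(R_i, R_{i+j})$. With
residue frequencies $f_u$, component $u$ is
$f_u / (\sum_v f_v + w\sum_j \theta_j)$ for $u \le 20$ and
$w\,\theta_j / (\cdot)$ beyond, so all components sum to 1. Defaults
$\lambda = 2$, $w = 0.05$ (the customary defaults of the descriptor
family) give the 22-dimensional vector; $L > \lambda$ is enforced.

The default hybrid set `gpsd + gaapc + paac` has $188 + 155 + 22 = 365$
uniquely named columns; `encode_dataset()` and `concat_features()` refuse
duplicate names or misaligned sample ids.

## MRMD ranking and incremental feature selection

MRMD scores each feature as *relevance + redundancy distance*. Relevance
is the absolute Pearson correlation with the label (constant features
score 0 by convention). Redundancy distance is the feature's mean
distance to all other feature columns: large mean distance means low
redundancy. Three distances are supported — Euclidean, cosine
($1 - \cos$ similarity) and Tanimoto
($1 - a\cdot b / (\lVert a\rVert^2 + \lVert b\rVert^2 - a\cdot b)$) —
plus the default `mean3`, which min-max normalizes each pairwise distance
matrix to $[0,1]$ before averaging, because raw Euclidean distances would
otherwise dominate the bounded similarity-based ones. Feature columns are
min-max scaled before distance computation (relevance uses raw values;
Pearson is scale-invariant) since the encoder blocks have heterogeneous
scales. A zero-variance (hence zero after scaling) column has undefined
cosine/Tanimoto similarity; its distance is defined as 1 with a warning.
Ties in the combined score break by original column index, making the
ranking fully deterministic; it is also invariant to row order.

Incremental feature selection evaluates nested top-$k$ prefixes of the
ranking by stratified cross-validated balanced accuracy and keeps the
smallest $k$ attaining the maximum. The prefix step is configurable
(`step = 1` evaluates every prefix; coarser steps trade curve resolution
for time — the package's tests and the acceptance workflow use steps of
30–120 so an IFS run fits in minutes on one CPU). The ranking is
computed once on the full training matrix, mirroring the common two-step
practice; note this means the selection itself sees all training labels,
so the IFS curve is a model-selection instrument, not an unbiased
generalization estimate — the held-out evaluation of the final model is.

## SMOTE-Tomek rebalancing

TTCA benchmark sets are imbalanced (e.g. 592 positives vs 393 negatives),
and the training partition inherits the skew. `smote()` over-samples the
minority class to a 1:1 ratio: each synthetic point is
$x + u\,(x' - x)$ with $x$ a minority sample, $x'$ one of its
$k$ = 5 minority-class nearest neighbors (Euclidean) and
$u \sim U[0,1]$, so synthetic coordinates never leave the segment between
the parents. `tomek_links()` then finds opposite-class mutual nearest
neighbors in the augmented data, and `smote_tomek()` removes **both**
members of each link (the classical cleaning rule; majority-only removal
is available via `remove = "majority"`). Distances use the features as
given, which after encoding are mostly already in $[0,1]$. Nearest
neighbors break ties by smallest index, so the whole procedure is
deterministic given the seed.

## Model fitting and evaluation

The classifier is a random forest (`randomForest`, 500 trees by default,
`mtry = sqrt(D)`, node size 1); a documented default grid
(trees {100, 200, 500} × mtry {sqrt, log2} × node size {1, 3}) is
exposed through `grid_search()`, which scores every combination by CV
BACC and breaks ties toward the earlier grid row. Logistic-regression
and SVM trainers sit behind the same `fit`/`predict_prob` interface for
comparison runs.

`cross_validate()` stratifies folds by class and, by default
(`resample = TRUE` paths), fits SMOTE-Tomek **inside each training
fold**: test folds are never resampled, no synthetic sample is ever
scored, and the union of test folds is exactly the original sample set.
The alternative `resample_before_cv = TRUE` rebalances once before
splitting — some published workflows do this, but synthetic points then
carry minority information across folds and scores inflate, so it is off
by default and exists for protocol comparison only. Headline metrics
pool the out-of-fold confusion counts and scores (micro aggregation);
per-fold reports and their means are kept alongside.

Metrics: sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, balanced
accuracy $(Sn+Sp)/2$ (the model-selection metric, robust to imbalance),
MCC with the 0-by-convention rule when a denominator factor vanishes, and
ROC AUC computed as the Wilcoxon–Mann–Whitney rank statistic (ties count
one half), which equals the probability that a random positive outscores
a random negative. The decision threshold on the positive-class
probability is 0.5.

## The synthetic generator, and what it does and does not show

`generate_peptides()` draws negative sequences residue-i.i.d. from a
background distribution (uniform over the 20 residues by default, which
keeps the null analytically clean; a custom background vector can be
supplied) and positive sequences from the background with the weights of
the aromatic (`c2`) and positively charged (`c3`) residues multiplied by
$e^{\text{signal\_strength}}$ and renormalized. Lengths are uniform on
8–25 by default — the typical MHC-I peptide range. `signal_strength = 0`
makes the classes identically distributed (the null);
larger values strengthen a purely compositional, group-level signal that
GAAC/GDPC-type features capture directly, which is what makes
MRMD/IFS recovery predictable and testable. `generate_imbalanced()`
reproduces benchmark-style skew (positives as the majority class).

The generator emulates compositional class differences only. Real TTCA
data carry positional anchor motifs, MHC-allele structure, length–class
interactions and residue autocorrelation, none of which are modeled.
Passing tests therefore demonstrate that the pipeline machinery —
encoding, ranking, selection, resampling placement, evaluation — is
correct and well calibrated, not that any particular accuracy will be
attained on curated tumor-antigen datasets.

## Numerical and protocol choices

- Train/test splitting is stratified, taking `floor(class size ×
  test_fraction)` test samples per class; deterministic given a seed.
- IFS tie-break: smallest $k$; grid-search tie-break: first row; MRMD
  tie-break: column index; nearest-neighbor tie-break: smallest index.
- Sums-to-one contracts on composition blocks are asserted to 1e-9; the
  encoder oracles agree to 1e-12.
- All stochastic steps (generator, splits, folds, SMOTE, forests) are
  reproducible from integer seeds; cross-validation derives per-fold
  seeds as `seed + fold`.
- Problem sizes used by the test suite and the acceptance workflow:
  oracle equivalence on ≤30-residue peptides and ≤12-feature matrices;
  end-to-end runs on 300 + 300 peptides (strong signal) and 20 × (100 +
  100) peptides (null calibration); the acceptance workflow trains on
  470/318 and tests on 122/75 synthetic peptides with IFS step 30 and
  150-tree forests. These sizes are the package's choice of a
  desk-scale experiment that still exercises every code path.

## Known limitations

- The eight CTD property partitions and the PAAC property values are the
  canonical published tables, but descriptor toolkits differ in small
  details (quantile conventions, standardization constants); exact
  numeric agreement with any specific external toolkit is not claimed.
- MRMD's `mean3` distance combination is one defensible reading of
  "Euclidean, cosine and Tanimoto" — single-metric modes are retained
  for ablation.
- Pre-CV resampling, pooled-vs-macro aggregation and the 0.5 threshold
  are protocol choices surfaced as flags/fields rather than hidden
  defaults.
- The random forest is the only tuned classifier; the peer trainers are
  deliberately minimal.
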