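---
title: "Two-stage SVM classification of nitrogen-fixation proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SVM classification of nitrogen-fixation proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifclass)
```

# The classification problem

Diazotrophs fix atmospheric nitrogen through the nitrogenase complex,
whose molybdenum form requires six gene products: the structural proteins
nifH, nifD and nifK, and the FeMo cofactor biosynthesis proteins nifB,
nifE and nifN. `nifclass` predicts, from sequence alone, (i) whether a
protein belongs to this nif machinery and (ii) which of the six
categories it is. The intended use is proteome screening, where the
nif/non-nif problem is extremely imbalanced: a bacterial proteome holds
thousands of proteins and at most a handful of nif genes.

The classifier is hierarchical because the two decisions have very
different structure. Stage 1 (nif vs non-nif) is a binary problem against
an essentially unbounded, heterogeneous negative class; stage 2
(six categories) is a small, closed multi-class problem among related
families. Training stage 2 only on nif sequences keeps it from being
swamped by the negative class, and running it only on stage-1 positives
keeps the screen's false-category calls down.

# Feature encoders

All six encoders operate on the 20-letter standard alphabet in the fixed
order `r paste(AA_ALPHABET, collapse = " ")`; this order defines every
descriptor position, so feature matrices are bit-reproducible.

**AAC** (20 values) is the residue composition, count/N. **DPC**
(400) is the adjacent ordered-pair composition with denominator N−1.
**GPC** (400) generalizes DPC to pairs with G intervening residues
(denominator N−G−1); `gap = 1` and `gap = 2` give the GPC-1/GPC-2 sets.

**CTD** (310) concatenates three blocks over the residue alphabet
itself: composition (20, identical to AAC); transition (190) — for every
unordered residue pair the frequency with which the two abut in either
order, denominator N−1; and distribution (100) — for each residue, the
scaled positions (100·pos/N) of its 1st occurrence and of its
ceiling(q·nᵢ)-th occurrence for q ∈ {0.25, 0.5, 0.75, 1}. Five anchors
per residue are used: 20 + 190 + 5·20 is the only decomposition
consistent with the 310 total, and the first anchor (first occurrence)
plus four quantiles is the convention adopted here. Absent residues
contribute five zeros; a present residue's five anchors are by
construction non-decreasing. CTD with the radial kernel is the default
model configuration: in practice it carries composition and local-order
signal at a third fewer dimensions than DPC.

**PseAAC** (20+λ) is the type-1 pseudo amino acid composition. The
tier-k correlation factor τₖ averages, over residue pairs k apart, the
squared differences of three standardized residue properties
(hydrophobicity, hydrophilicity, side-chain mass; each standardized to
mean 0 and population-sd 1 across the 20 residues). With normalized
composition frequencies f (Σf = 1) the components are
fᵢ/(1 + wΣτ) and wτₖ/(1 + wΣτ), so the vector sums to 1 and
converges to AAC as w → 0. The tier weight w (default 0.05, the
customary value) balances composition against sequence order; λ
(default 1) must be smaller than the sequence length.

**ACF** (531·n) computes, for each of 531 AAindex physicochemical
property scales and each lag k ≤ n, the mean lagged product
(1/(N−k))·Σ v(sₜ)v(sₜ₊ₖ) of the standardized per-residue property
profile. The property table comes from the AAindex snapshot shipped with
`seqinr`: of its 544 scales, exactly 531 have values for all 20 residues,
and those complete scales — each z-scored across the residues — back the
encoder. `load_aaindex()` accepts an AAindex1 flat file or TSV snapshot
instead and applies the same rules (drop properties with missing values
when enough complete ones remain, otherwise mean-impute; exclude
zero-variance scales, which cannot be standardized). The
standardized-product form of the autocorrelation (rather than re-centering
per sequence) was chosen so a homopolymer has the interpretable value
v² at every lag; the default order is 1, since 531 descriptors per lag
grow quickly.

# The SVM core

Both stages use `e1071::svm` — C-classification with one-vs-one
decomposition for the multi-class stage and Platt-style probability
calibration — at the library's default parameters: cost 1, γ = 1/#features,
degree 3, coef0 0. `select_kernel()` reproduces the model-selection
protocol: draw a seeded subset (100 per class by default) and pick the
kernel (radial, linear, polynomial, sigmoid) with the highest stratified
five-fold CV accuracy, breaking ties toward radial, then polynomial,
sigmoid, linear.

Feature columns are standardized with center and scale learned from the
training rows only and replayed on queries. This is a deliberate design
choice with two consequences: cross-validation never leaks test-fold
statistics into training, and the classifier is invariant to rescaling
any feature column consistently in train and test (verified by a test).
Constant columns are passed through with scale 1 rather than producing
NaNs. Probability calibration uses random internal folds, so every
training function takes an explicit seed; identical inputs and seed give
bit-identical predictions.

# Evaluation harness

Metrics are computed from the counts Np, Nn, Npn, Nnp in the miss-rate
form (Sn = 1 − Nnp/Np and so on; see `?metrics_from_counts`). These
forms are algebraically identical to the classical TP/FP/TN/FN
expressions; the test suite checks agreement to 1e-12 on 1,000 random
count configurations. A metric with a zero denominator (e.g. precision
when nothing is predicted positive) is reported as `NA` — explicitly
undefined — and excluded from averages with the exclusion count logged in
the result object, rather than silently coerced to 0.

Three validation procedures are provided. `kfold_cv()` uses stratified
folds (each fold holds approximately the same number of observations from
each class), assigned by seeded within-class round-robin after
shuffling. `jackknife_cv()` is leave-one-out, aggregating all n
predictions into a confusion matrix with one-vs-rest per-class metrics;
it refuses singleton classes, which would be untrainable when their only
member is held out. `balanced_resampling_cv()` addresses the nif/non-nif
imbalance: for each of M sample sets (default 100) it draws exactly
|pos| negatives without replacement (independently across sets, seeded
as seed+m), runs stratified k-fold CV on the balanced set, and averages;
the standard error is the sd of per-set means divided by √M. "Exactly
|pos|" pins down the looser notion of an approximately balanced set and
makes M = 1 reduce to a single k-fold run.

`roc_auc()` is the rank (midrank-for-ties) estimator, equal to
concordant-pair counting; it backs feature–kernel comparisons.

# The two-stage flow

`nif_model()` encodes the pooled nif classes and the non-nif set once,
trains stage 1 on nif-vs-non-nif and stage 2 on the nif categories only,
with a shared encoder and kernel. Prediction calls stage 1 by argmax
(equivalently, nif probability ≥ 0.5 in the binary case); no separate
stage-1 threshold is exposed because the hierarchy's tunable operating
point is at stage 2. There, the best category is assigned when its
probability reaches τ, default 0.4. That default reflects the intended
screening regime: in a proteome screen false positives from the huge
negative class dominate, and most spurious stage-2 calls arrive with
low confidence, so a sub-0.5 threshold removes a large fraction of them
while keeping confidently predicted true nif proteins. Sub-threshold
positives are reported as `unassigned` rather than dropped, keeping the
screen auditable: every input yields exactly one record, and raising τ
can only shrink the categorized set (a monotonicity the tests assert).
Sequences the encoder rejects (non-standard residues, too short for the
scheme) become per-record errors without aborting the batch.

# The synthetic data generator

The generator exists so that every stage is testable offline, with
controllable signal. `random_sequences()` draws i.i.d. residues from a
composition profile with lengths uniform on 150–250 (about the scale of
nifH, the shortest of the six proteins). `two_class_dataset()` shifts
mass δ onto a fixed five-residue subset for one class: δ = 0 is an exact
null (any CV accuracy above chance would indicate leakage), δ = 0.3 is
comfortably separable from composition at 100 sequences per class.
`multiclass_dataset()` gives each class a distinct enriched residue pair
plus a first-order Markov preference for transitions into that pair, so
di-peptide/transition descriptors carry information beyond composition —
a miniature of how real protein families differ in both composition and
local order. The RNG algorithm is pinned (Mersenne-Twister with fixed
normal/sample kinds), so fixtures are identical across platforms.

What the generator does **not** emulate: homology structure within a
family, phylogenetic correlation between sequences, domain architecture,
or the heterogeneity of a real proteome's negative class. Passing tests
on these fixtures therefore validate the machinery — encoders, CV
bookkeeping, thresholding, reproducibility — not field performance on
real proteomes, which depends on curated training data supplied by the
user.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes
chosen to exercise every code path at high statistical margin: encoder
oracles on 1,000 random sequences of lengths 10–500; metric equivalence
on 1,000 random count configurations; balanced resampling with M = 10
sets of 100+100 CTD-encoded sequences; jackknife at 12 sequences per
class (72 fits); the two-stage flow trained on 30 per nif class plus 180
background. On these fixtures the separable-case accuracies sit near 1
and the null case within a few points of 0.5.

Other numerical conventions: positions are 1-based; descriptor order is
canonical-alphabet, pairs row-major, CTD blocks in C, T, D order;
composition features are fractions (not percentages), which is
immaterial under per-column standardization; duplicate sequences are
defined by exact (case-insensitive) residue-string equality; a single
terminal `*` in FASTA input is treated as a stop marker and stripped,
while any other non-standard character disqualifies the sequence in
`filter_standard()`.

# Known limitations

- Stage-2 probabilities come from one-vs-one pairwise coupling; they are
  calibrated but not guaranteed well-calibrated for classes far from the
  training distribution.
- The jackknife refits n models and is intended for the small nif
  training sets, not for thousands of sequences.
- No identity-based redundancy reduction (CD-HIT-style clustering) is
  included; training sets should be de-redundified upstream if homology
  bias matters.
- ACF at order n multiplies 531 descriptors per lag; orders beyond 1 are
  supported by contract but rarely useful at typical training sizes.
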