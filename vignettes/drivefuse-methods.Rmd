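---
title: "Classifying cancer driver mutations by fusing sequence-context CNN scores with functional features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer driver mutations by fusing sequence-context CNN scores with functional features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivefuse)
```

## The problem

Somatic single-nucleotide variants in tumors split into a small class of
*drivers* — mutations under positive selection that contribute to cancer
initiation or progression — and a large background of functionally inert
*passengers*. Classifiers built on precomputed functional and conservation
scores (dbNSFP/dbWGFP-style columns such as the ensemble meta-predictors
RadialSVM and LR, or conservation measures like GERP and PhyloP) perform
well but are limited to the variants those databases cover. A score learned
directly from the raw nucleotide context of a variant can be computed for
*any* position with known coordinates, and — because its derivation is
unrelated to the functional annotations — can carry complementary
information. `drivefuse` implements that idea end to end:

1. extract a stacked reference/mutant sequence-context matrix around each
   variant,
2. encode it numerically and train a small convolutional network selected
   by cross-validated grid search, yielding a per-variant driver
   probability (the **DL score**),
3. fuse the DL score with tabular feature columns in classical
   classifiers (random forest, gradient boosted trees, SVM), with feature
   importance, recursive feature elimination and Spearman correlation
   analysis,
4. optionally post-process predicted driver positions on protein
   structures via residue-interaction-network betweenness.

## The mutation-pair representation

For a variant at position $p$ with reference base $r$ and alternate base
$a$, a window of radius $w$ gives a context string of length $L = 2w + 1$.
Two copies are stacked: row 0 is the reference context, row 1 is identical
except that the center symbol is replaced by $a$. The rows therefore
differ in exactly one column — the mutation — and a convolution sliding
along the two rows sees the mutation in its local context. At the radii
$w \in \{10, 50, 100, 500, 5000\}$ the context lengths are 21, 101, 201,
1001 and 10001.

Positions outside the chromosome are padded with the missing-place symbol
`n`; all sequence handling is lowercase over the alphabet
$\{a, c, g, t, n\}$; coordinates are 1-based on input (the VCF
convention). Extraction is always on the forward strand. When the stored
reference base disagrees with a variant's REF field the default policy is
to reject the variant (a genome-build mismatch is likelier than a benign
discrepancy); a `warn` policy that keeps the store's base is available.

## Encodings

Three schemes turn the $2 \times L$ symbol matrix into numbers:

* **Label encoding** — each symbol becomes its integer ID under the
  alphabetical map $a \to 0, c \to 1, g \to 2, n \to 3, t \to 4$
  ($2 \times L$). Compact, but imposes an artificial ordering.
* **One-hot encoding** — each symbol becomes a 5-bit indicator block in
  slot order $(n, g, t, c, a)$, so $a \to [0,0,0,0,1]$ and
  $c \to [0,0,0,1,0]$ ($2 \times 5L$). No ordering artifact; this is the
  scheme the pipeline defaults to.
* **Learned embedding** — a skip-gram (word2vec-style) model with negative
  sampling is trained over single-nucleotide tokens of the corpus and each
  symbol becomes its learned 2-vector ($2 \times 2L$). Two dimensions
  suffice for a 5-symbol vocabulary. The skip-gram context radius defaults
  to 5 tokens; symbols never seen in the corpus keep a zero vector and a
  warning is emitted. Training is deterministic given the seed and corpus
  order.

Label and one-hot encodings are exact bijections (`decode()` inverts
them); the embedding is not invertible.

For the network, block encodings are unpacked channels-first so the
convolution slides along the $L$ nucleotide positions: label gives 2
channels (reference row, mutant row), one-hot 10 channels (5 bits per
row), embedding 4 channels. Treating the rows as channels rather than as a
2-row image is the standard reading of a two-track sequence input.

## The CNN and its selection protocol

Each architecture has 1–3 convolutional layers (kernel length 3 along the
sequence axis, ReLU, dropout 0.25 between layers) followed by flattening,
1–3 fully connected ReLU layers, and a single sigmoid output unit giving
the driver probability. Layer widths are powers of 2 between 2 and 256.
The default grid crosses 3 convolutional depths × 3 dense depths × 8
shared widths = **72 architectures**; a "tapered" preset of 11
architectures with per-layer decreasing widths is also provided (its final
2-node entry is interpreted as the output head). Optimization is Adam
(default learning rate $10^{-3}$, batch 32) on binary cross-entropy,
implemented with vectorised im2col matrix algebra so training is exactly
reproducible under a seed.

Model selection follows a fixed protocol: 20% of the data is held out,
stratified, before anything else; the remaining 80% is split into 3
stratified folds; each architecture trains on 2 folds and is evaluated on
the third after every epoch (default 100 epochs), recording accuracy, F1
and AUC; the best epoch per fold maximizes validation F1 with the earliest
epoch winning ties (these small networks often peak almost immediately and
then overfit). The selected architecture maximizes mean best-epoch F1
across folds; ties break by mean AUC, then by the smallest parameter
count. F1 rather than accuracy drives selection because the 6,389:12,941
class imbalance makes accuracy misleading — a constant all-passenger
predictor already attains 66.95% accuracy with an F1 of 0.

**DL scores without leakage.** Scoring every variant with a model trained
on all of them would leak labels into the downstream fusion stage. The
default therefore scores the training portion *out-of-fold* (each sample
scored by the fold model that never saw it) and the holdout portion with a
model refit on the full training portion; `mode = "paper"` reproduces
single-model whole-dataset scoring for comparison. Class imbalance is
handled by stratification only; no resampling.

## Fusion with tabular features

The DL score joins the feature table as an ordinary numeric column
(`attach_dl_score()`, inner or left join on the variant key). Classifiers
share one stratified 80/20 split per seed so holdout membership is
identical across algorithms. Missing values are median-imputed with
medians fitted on the training split only. The SVM uses an RBF kernel with
probability outputs and features standardized from training statistics;
the tree ensembles consume raw columns.

Feature importance is the normalized impurity-decrease importance of the
tree ensemble (mean decrease in Gini for the forest, total gain for the
boosted trees). An information-value / weight-of-evidence report
(`woe_iv_report()`, decile bins, Laplace smoothing) is provided as a
model-free alternative ranking criterion. Recursive feature elimination
refits the model and drops the lowest-importance feature until `k` remain;
the shipped profiles `top8` (RadialSVM, LR, DL score, GerpRS, LRT,
verPhyloP, SiPhy, GerpN) and `top3` (RadialSVM, LR, DL score) name the
reduced column sets. Spearman correlations use average ranks and
pairwise-complete observations; zero-variance columns yield `NA` with a
warning.

## Evaluation formulas

With drivers as the positive class: accuracy $(TP+TN)/n$, precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$, $F1 = 2PR/(P+R)$, sensitivity
$TPR = TP/(TP+FN)$, specificity $TNR = TN/(TN+FP)$. When no positives are
predicted, precision, recall and F1 are reported as 0 — the convention
that makes the constant-predictor baseline well-defined. AUC is the rank
(Mann–Whitney) statistic — the probability that a random driver outscores
a random passenger, ties counting one half — which equals the trapezoid
area under the ROC curve swept through the unique score thresholds.

## The synthetic benchmark generator

Real driver/passenger datasets with their functional annotations cannot be
redistributed, so the package generates its own benchmark with the same
statistical skeleton:

* **Genome** — i.i.d. uniform $\{a,c,g,t\}$ chromosomes (default 4 ×
  250 kb).
* **Variants** — default 6,389 drivers / 12,941 passengers (the study
  composition; `scale` shrinks both proportionally). Sites occupy
  non-overlapping window slots. Each driver carries, with probability $q$
  (default 1), a fixed 6-mer motif (`tgacgt`) written into its reference
  context at a uniform offset fully inside the window; passengers are
  never planted, though background occurrences occur at the expected
  ~0.4% rate for a fixed 6-mer in a 21-mer. A 6-mer at radius 10 is long
  enough to be specific yet learnable by stacked kernel-3 convolutions.
* **Feature table** — "ensemble-like" columns (default RadialSVM, LR) are
  class-conditional Gaussians: passenger mean 0, driver mean equal to the
  `separation` parameter (default 1.5 SD, single-column AUC
  $\Phi(1.5/\sqrt2) \approx 0.86$ — comparable to a good individual
  functional predictor), with latent correlation 0.5 between them
  (ensemble meta-scores built from overlapping inputs are substantially
  correlated); conservation-named noise columns are class-independent
  N(0,1).

The sequence signal and the tabular signal are generated independently,
so the marginal contribution of the DL score in fusion is a designed
property that tests can assert. What the generator does **not** emulate:
trinucleotide mutational-signature biases, gene models and coding
structure, realistic linkage between conservation scores and sequence
context, and label noise. Passing recovery tests therefore demonstrates
that the machinery works — extraction, encoding, optimization, selection,
fusion — not that the planted-motif task has the difficulty of real
driver prediction, where the attainable sequence-only signal is far
weaker.

## Residue interaction networks

For structure-level post-processing, residues are nodes and an edge joins
residues $i, j$ when their interaction strength exceeds a threshold
$I_{min}$ (default 4%). The strength is computed from heavy-atom contact
counts $n_{ij}$ within 4.5 Å as
$I_{ij} = 100\, n_{ij} / \sqrt{N_i N_j}$, with $N_i$ the total number of
heavy-atom contacts residue $i$ makes; this normalization is one concrete
interpretation of contact-density weighting and is isolated behind the
function arguments. Sequence-adjacent residues are excluded by default so
backbone proximity does not create trivial edges. The betweenness of
residue $i$ is
$C_b(n_i) = \sum_{j<k} g_{jk}(i)/g_{jk}$,
the sum over residue pairs of the fraction of shortest paths through $i$,
computed exactly by Brandes path-count accumulation (no sampling) and
normalized by $(N-1)(N-2)/2$ within $i$'s connected component; components
smaller than 3 get 0. Shortest paths are unweighted by default; a weighted
mode uses edge length $1/I_{ij}$. Predicted mutation positions map onto
the profile with within-structure percentiles; unresolved positions are
listed, not fatal.

## Numerical and design choices

* **One-hot slot order** $(n,g,t,c,a)$ and label IDs in alphabetical
  order are fixed, documented constants (the slot order is configurable).
* **Optimizer settings** (Adam, $10^{-3}$, batch 32) and dropout 0.25 are
  conventional defaults for networks of this size.
* **Ties**: best-epoch ties go to the earliest epoch; architecture ties to
  higher AUC then fewer parameters; AUC ties count one half; Spearman uses
  average ranks.
* **Degenerate inputs**: windows overhanging chromosome ends pad with
  `n`; zero-variance features produce `NA` correlations with warnings;
  single-class folds, empty corpora and REF = ALT rows raise errors.
* **Problem sizes in the shipped tests**: the test-suite and acceptance
  simulations run at roughly 240–2,000 variants with 6–20 epochs and
  learning rate $3\times10^{-3}$ — sizes chosen so the whole suite
  completes in minutes on one core while leaving wide margins on the
  chance-level and signal-recovery assertions. The package defaults
  (100 epochs, learning rate $10^{-3}$) remain the full-protocol
  settings.

## Known limitations

* The CNN backend is plain R; it is intended for the small architectures
  of the shipped grid at window radius 10–100, not for GPU-scale work or
  the 10,001-long contexts at radius 5,000 (extraction and encoding handle
  those; training them is impractical here).
* Betweenness is exact but $O(NM)$ per structure; fine for single protein
  domains, slow for large complexes.
* The skip-gram embedding trains on a 5-symbol vocabulary; it does not
  support k-mer tokens.
* No probability calibration is applied to the DL score; it is consumed
  as a ranking feature.

## A minimal run

```{r example, eval = FALSE}
spec <- synth_spec(scale = 0.05, seed = 1)       # ~970 variants
sim <- simulate_dataset(spec)
pairs <- extract_pairs(sim$store, sim$variants, w = 10)
enc <- encode_dataset(pairs, "onehot")

arch <- architecture_spec(c(16, 16), 16)
cfg <- training_config(epochs = 20, lr = 3e-3, seed = 1)
dl <- compute_dl_scores(enc, arch, cfg)

tab <- attach_dl_score(sim$features, dl)
fit <- train_classifier(tab, "random_forest", seed = 1)
fit$report
feature_importance(fit)
```
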