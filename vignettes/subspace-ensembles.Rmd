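---
title: "Counter-voting SVM ensembles on feature subspaces"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counter-voting SVM ensembles on feature subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Overview

`svmFSS` classifies multiclass gene-expression profiles in the common
regime where the number of genes far exceeds the number of samples and
the class sizes are strongly imbalanced. The method combines four
ingredients:

1. **One-against-all decomposition.** A C-class problem becomes C binary
   branches; branch *i* treats class *i* as positive and all other
   samples as negative. This makes every branch imbalanced by
   construction, which is why the imbalance corrections below are
   applied per branch rather than globally.
2. **Feature-space construction.** For each branch, genes are grouped by
   average-linkage hierarchical clustering on the distance
   1 − PCC (Pearson correlation coefficient), the tree is cut into K
   clusters, and the single gene with the largest signal-to-noise ratio
   (SNR) for the branch's binary task is kept from each cluster. The
   result is a branch-specific feature space of K weakly correlated,
   discriminative genes.
3. **Random feature subspaces.** Each of L base classifiers sees a
   uniform random subset of D of the K genes and is an RBF-kernel SVM.
   Two base classifiers share an expected fraction D/K of their genes
   (the *coselection rate*); the complementary quantity (K − D)/K is a
   simple a-priori diversity measure.
4. **Imbalance correction and counter voting.** Each base classifier is
   corrected for its branch's imbalance (see below). A test sample
   collects, per branch, the fraction of the L base classifiers that
   voted positive — the branch's *counter* — and is assigned to the
   branch with the largest counter.

# Model details

## Signal-to-noise ratio

For gene *g* with positive-class mean and standard deviation
$\mu_+, \sigma_+$ and negative-class $\mu_-, \sigma_-$ (population
standard deviations, i.e. denominator *n*),

$$\mathrm{SNR}(g) = \frac{|\mu_+ - \mu_-|}{\sigma_+ + \sigma_- + \varepsilon},$$

with $\varepsilon = 10^{-12}$ guarding against zero spread. Ties within
a cluster are broken toward the smallest gene index, so feature-space
construction is deterministic. Both PCC and SNR are invariant under
per-gene affine transformations, so the per-gene z-score
standardization that the trainer applies (fitted on training samples
only, stored in the model, and re-applied at prediction time) affects
only the SVMs, not the gene selection.

## Imbalance corrections

With $m_+$ positive and $m_-$ negative training samples in a branch:

* **Threshold adjustment (`"thr"`, the default).** The decision
  threshold
  $$\theta = \frac{m_+ - m_-}{m_+ + m_- + 2}$$
  is subtracted from the raw SVM margin before taking the sign. For a
  minority positive class $\theta < 0$, which moves the boundary toward
  the majority class. The +2 acts as a Laplace-style smoothing term and
  keeps $|\theta| < 1$, the width of the SVM margin.
* **Random undersampling (`"rus"`).** Each base classifier draws a fresh
  balanced subset: all minority samples plus an equal-size uniform
  sample of the majority. Redrawing per base classifier preserves
  ensemble diversity; no threshold is applied ($\theta = 0$).
* **`"none"`** trains on the raw branch data with $\theta = 0$; it is
  the baseline the corrections are compared against.

## Base classifiers and hyperparameters

Base learners are RBF-kernel SVMs (via **e1071**/libsvm) with kernel
$\exp(-\lVert x - y\rVert^2 / 2\sigma^2)$; the package's $\sigma$
parameter is translated to libsvm's $\gamma = 1/(2\sigma^2)$.
Per-branch grid search (when `cGrid`/`sigmaGrid` contain more than one
point) uses internal stratified cross-validation scored by binary
G-mean over the default grid $C \in 2^{-2}, \dots, 2^{15}$ (18 values)
and $\sigma \in 2^{-6}, \dots, 2^{5}$ (12 values). Ties prefer the
smaller cost, then the smaller $\sigma$, which biases toward smoother
models.

Defaults are K = 100, D = 20, L = 100. D = 20 sits in the flat region
of the accuracy-versus-D curve on the synthetic problems shipped with
the package while keeping the coselection rate at 0.2;
`sweepSubspaceDimension()` reproduces that curve for any dataset.

## Metrics

Per-class accuracy is the recall of each class. The headline metrics
are

* weighted accuracy $\mathrm{Acc} = \sum_i \mathrm{Acc}_i P_i$ with
  $P_i$ the class proportions (algebraically equal to the plain
  fraction correct);
* multiclass G-mean $(\prod_i \mathrm{Acc}_i)^{1/C}$, computed in log
  space and short-circuited to 0 when any class is fully missed; and
* F-score, the unweighted mean of the one-vs-rest F-measures, with the
  convention that an undefined precision (class never predicted)
  contributes 0.

G-mean and F-score are insensitive to class prevalence, which is what
makes them informative under imbalance: a classifier that ignores a
minority class entirely can keep Acc high but drives G-mean to 0.

## Evaluation protocol

`repeatedStratifiedCV()` runs stratified 3-fold cross-validation
repeated 10 times (both configurable). Out-of-fold predictions are
pooled within a repeat before computing metrics, so per-class
accuracies are estimated on every sample once per repeat. When the
smallest class has fewer samples than the requested folds the fold
count is reduced with a warning rather than silently producing folds
that miss a class. Feature spaces, standardization constants and
hyperparameters are all derived from the training portion of each fold
only; the test suite verifies this no-leakage property directly.

# Synthetic data generator

`simulateExpressionDataset()` plants three kinds of genes on Gaussian
noise with standard deviation `noiseSd`:

* *informative* genes, mean-shifted by `effectSize * noiseSd` in one
  target class;
* *redundant* genes, jittered copies of an informative parent
  (jitter SD = 0.2 `noiseSd`), forming planted correlation clusters;
* *noise* genes with no class signal.

Ground truth (role, target class, parent) is stored in `rowData` and
retrieved with `geneTruth()`.

One property of this generator matters when designing experiments:
informative genes that share a target class are themselves correlated,
because they share the class-mean pattern. With target-class
proportion *p* and effect size *e* the induced correlation is
$p(1-p)e^2 / (1 + p(1-p)e^2)$. Under average-linkage clustering,
strongly informative genes of the same class can therefore merge into
one cluster and be represented by a single gene in the feature space —
deduplication working as designed, but worth knowing when counting how
many planted genes a feature space can recover.

# Validation-fixture design

Two package-level checks in the test suite required explicit design
choices; the reasoning is recorded here because the numbers are not
arbitrary.

**Planted-cluster recovery.** To test that feature-space construction
recovers planted structure, the fixture uses 10 classes of 6 samples,
one informative parent per class with 4 redundant copies (10 planted
clusters of 5 genes), effect size 6, 50 noise genes, and the binary
task "classes 1–5 vs 6–10". Giving every class its own parent keeps
the planted clusters mutually near-orthogonal (the cross-class
correlation from the shared binary labelling is small relative to the
within-cluster copy correlation), so a K = 10 cut isolates them; the
large effect size makes each cluster's representative out-score noise
genes on SNR. The check asserts at least 8 of 10 selected genes are
planted and no planted cluster contributes twice.

**Imbalance-correction benefit.** The study fixture has 5 classes of
sizes 135/20/19/17/9 (imbalance ratio 15), 2000 genes of which 80 per
class are *distinct* informative genes (no redundant copies — copies
would be collapsed by the clustering step, starving the feature space
of signal, per the generator property above), effect size 1, K = 100,
D = 20, and a deliberately small L = 15 to fit the evaluation budget.
A single hyperparameter point ($C = 8$, $\sigma = 8$) stands in for
the full grid search, chosen from the default grid as a
moderate-regularization, moderate-bandwidth point appropriate for
standardized inputs with D = 20 features; running the full 216-point
grid per branch is supported but not affordable inside a test suite.
On a stratified two-thirds/one-third holdout, threshold adjustment and
random undersampling are each required to beat the uncorrected
baseline on median held-out G-mean and on median minority-class
accuracy across 10 simulation seeds. The uncorrected baseline
typically scores G-mean 0 here because it never predicts the 9-sample
class — exactly the failure mode the corrections address.

# Numerical choices

* SNR uses population standard deviations and $\varepsilon = 10^{-12}$;
  constant genes are dropped before clustering with a message.
* G-mean is computed as $\exp(\frac{1}{C}\sum_i \log \mathrm{Acc}_i)$
  to avoid underflow for large C, with an exact 0 when any
  $\mathrm{Acc}_i = 0$.
* libsvm orients its decision values by the order in which it first
  encounters the labels; the package stores a per-classifier flip flag
  so that the margin is always "positive = branch class".
* Counter ties are broken by the larger mean corrected margin, then by
  the smaller class index, making prediction deterministic.
* All stochastic steps (subspace draws, undersampling, folds,
  simulation) are driven by user-supplied seeds.

# Worked example

```{r example, eval = FALSE}
library(svmFSS)

cfg <- syntheticConfig(
  nClasses = 3, classSizes = c(50, 30, 10),
  nInformativePerClass = 10, nRedundantCopies = 4,
  nNoiseGenes = 350, effectSize = 1, seed = 1
)
ds <- simulateExpressionDataset(cfg)
datasetSummary(ds)

model <- trainEnsemble(ds, K = 100, D = 20, L = 100,
                       correction = "thr", seed = 2)
cv <- repeatedStratifiedCV(ds, nFolds = 3, nRepeats = 10, seed = 3,
                           K = 100, D = 20, L = 50, correction = "thr")
cv$summary
```

# Scope and limitations

* The generator plants additive mean shifts on independent Gaussian
  noise; it does not model heavy tails, batch effects or
  technical-replicate structure.
* Exhaustive error-correcting output codes are limited to C ≤ 16
  (2^(C−1) − 1 columns); only one-against-all decomposition is wired
  into the trainer, with `makeCodeMatrix()` exposing the other schemes
  for building custom pipelines.
* Hierarchical clustering of G genes costs O(G²) memory in the
  distance matrix; tens of thousands of genes are feasible, hundreds
  of thousands are not.
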