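---
title: "Population-graph staging of Alzheimer's disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-graph staging of Alzheimer's disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgraphstager)
```

## The problem and the model

Staging Alzheimer's disease from structural MRI is usually framed as a
per-subject classification problem: given a gray-matter density map,
predict cognitively normal (CN), mild cognitive impairment (MCI) or
Alzheimer's dementia (AD). This package implements the population-graph
alternative: all subjects — labeled and unlabeled — become nodes of one
weighted graph, node features are per-subject anatomical embeddings, edge
weights encode pairwise subject similarity from imaging and/or non-imaging
phenotypes, and a graph convolutional network (GCN) classifies every node
at once. The unlabeled test subjects participate in message passing
(transductive learning); only training-node labels enter the loss.

The pipeline has four stages:

1. **Anatomical embedding.** A 3D DenseNet is trained to classify
   volumetric images and the post-ReLU activations of its first fully
   connected layer (512 units by default) become the subject embedding
   $x_i$.
2. **Edge assignment.** For subjects $i, j$ the package supports three
   edge-weight families:
   - imaging: cosine similarity
     $S_{\mathrm{img}}(i,j) = \dfrac{x_i \cdot x_j}{\lVert x_i\rVert\,\lVert x_j\rVert}$;
   - non-imaging: a Kronecker delta for categorical phenotypes
     (gender, ApoE4 allele count) and a unit step
     $\mathbf{1}\{|n_i - n_j| < \beta\}$ for quantitative ones (age,
     neuropsychological scores), summed over the $P$ chosen features;
   - combined: $S_{\mathrm{com}} = S_{\mathrm{img}} \sum_{p=1}^{P}
     S_{\mathrm{nimg}}^{(p)}$, so phenotype agreement scales the imaging
     similarity and total disagreement annihilates the edge.
3. **Propagation.** The GCN uses the symmetric renormalized operator
   $S = \hat D^{-1/2}(A + I)\hat D^{-1/2}$ with
   $\hat D = \mathrm{diag}(\mathrm{rowSums}(A + I))$; two layers
   $\mathrm{softmax}\big(S\,\mathrm{ReLU}(S X W^{(0)})\,W^{(1)}\big)$
   with 32 hidden units and dropout 0.5 on both layer inputs.
4. **Evaluation.** Confusion matrices and accuracy, precision, recall,
   F1 and the Matthews correlation coefficient (MCC), reported as
   percentages, plus a linear-SVM vector-feature baseline that sees the
   same inputs without the graph.

## Key assumptions

- Edge weights must be nonnegative for $\hat D^{-1/2}$ to be real, so
  negative cosine values are clamped to zero during graph construction.
  Because embeddings are taken post-ReLU (and the synthetic features are
  rectified), the clamp is a no-op in practice.
- The unit-step similarity is symmetric: it is implemented as
  $|n_i - n_j| < \beta$ (strict). An asymmetric reading of the step
  function would contradict the undirected-graph construction.
- The adjacency diagonal is stored as zero; the self-loop is added once,
  explicitly, by the propagation operator. Storing self-similarity would
  double-count it.
- The graph is small (hundreds of nodes), so training is full-batch and
  the operator is kept dense.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `beta` (age) | 2 years | unit-step threshold for age edges |
| `beta` (scores) | per `adni1_default_thresholds()` | per-task thresholds for the nine neuropsychological scores (e.g. CDR-SB: 2 for AD/MCI, 1.5 for MCI/CN) |
| `hidden_units` | 32 | first GCN layer width |
| `dropout` | 0.5 | dropout on the GCN's layer inputs, training only |
| `learning_rate` (GCN) | 1e-3 | Adam step size |
| `max_epochs` / `patience` (GCN) | 500 / 20 | early stopping on validation accuracy; best-validation weights restored |
| `growth_rate` | 12 | channels each dense unit appends |
| `bottleneck_channels` | 48 | 1×1×1 bottleneck width in each dense unit |
| `compression` | 0.5 | transition-layer channel compression |
| `fc_sizes` | (512, 256) | fully connected head; the first entry is the embedding width |
| `learning_rate` (CNN) | 1e-4, batch 64, ≤200 epochs, patience 30 (validation loss) | CNN training protocol |

Thresholds can also be selected by `grid_search_threshold()`, which
evaluates a user-supplied callback (build graph → train → validation
accuracy) over a candidate grid and breaks ties toward the smaller
threshold. The sparser graph is preferred because denser phenotype
neighborhoods aggravate over-smoothing, the failure mode in which
repeated neighborhood averaging makes node embeddings indistinguishable.

A calibration note on the GCN learning rate: the reference protocol on
the real cohort used 1e-4 for the MCI and three-class experiments. At
the scale of the synthetic cohorts shipped here, validation accuracy
selects 1e-3 — at 1e-4 the patience-20 early stop triggers while the
validation accuracy is still sitting at the majority class, returning
near-initial weights. The experiment runners therefore default to 1e-3
for every task; any rate can be passed explicitly through
`experiment_spec(gcn = gcn_config(...))`. Selecting the rate on the
validation split is the same procedure the reference protocol used to
pick its rates.

## The synthetic cohort generator

Real gray-matter maps for this problem come from an access-controlled
cohort, so the package ships a simulator whose defaults emulate that
cohort's published summary statistics: 229 CN / 382 MCI / 187 AD
subjects; per-class normal draws for age and the nine neuropsychological
scores (means and SDs from the published demographics table, clipped to
physiological ranges — MMSE to [0, 30], CDR-SB, FAQ and ADAS to
nonnegative values); per-class category probabilities for gender and
ApoE4 allele count; and a stratified 70/10/20 train/validation/test
split. Stratification is the package's choice (the reference protocol
says only "randomly split"); it keeps class proportions stable in small
synthetic runs without changing expectations.

Synthetic embeddings place the three class centroids on a severity line:
CN at a random positive base point, MCI and AD one and two steps of
length `class_separation` along a random unit direction, with isotropic
Gaussian noise (`noise_sd`) and rectification at zero. Correlation
between covariates and diagnosis is induced only through the per-class
parameters; no within-class covariate-feature dependence is modeled.
Toy volumes are geometric phantoms: a smooth blob with two fixed
ellipsoidal regions attenuated in proportion to
`atrophy_amplitude` × class severity, plus voxel noise.

What passing tests on this cohort do show: the edge-assigning algebra,
the propagation operator, the training loop, threshold selection and the
metric pipeline are correct, and the qualitative orderings reproduce —
graphs whose edges use a strongly class-linked covariate (CDR-SB under
the default calibration) beat the imaging-only baseline, and that
covariate ranks first among candidates. What they do not show: real-data
effect sizes. The rectified synthetic embeddings are dominated by a
shared positive component, so the imaging-only cosine graph is much
denser and more uniform than a real CNN-feature graph, over-smooths, and
scores closer to chance than the published imaging-only results. The
headline accuracies of the real cohort are therefore not reproduction
targets anywhere in this package.

## Numerical and design choices

- **Dense-unit ordering** is pre-activation (BN → ReLU → conv), the
  standard DenseNet arrangement; the transition layer is BN → ReLU →
  1×1×1 conv → average pooling, stride 2 (pooling type is the package's
  choice). The stem is a bare 3×3×3 convolution with 2×growth channels;
  `stem_bn` and `stem_pool` expose the variants the reference leaves
  unspecified.
- **Embeddings are post-ReLU** of the first fully connected layer,
  guaranteeing nonnegative features and hence nonnegative cosine
  similarities.
- **Class weights** in the CNN loss are inversely proportional to
  training-class frequency, $w_c = n/(k\,n_c)$.
- **Initialization**: Glorot-uniform for fully connected and GCN
  weights, He-normal for convolutions, all under a derived seed;
  training, dropout and batch shuffling draw from seeded streams, so
  every fit is bit-reproducible from its configuration.
- **Early stopping** monitors validation *accuracy* for the GCN and
  validation *loss* for the CNN, each with its stated patience, and both
  restore the best-validation weights (restore-vs-last is unstated in
  the reference; restoring best is the package's documented choice).
- **Ties** in arg-max prediction go to the lower class index;
  threshold-search ties go to the smaller β.
- **MCC** uses the square-rooted denominator
  $\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}$. Ratios with zero denominators
  are reported as 0 and flagged in the `undefined` column rather than
  propagating NaN.
- **Zero-norm feature vectors** get cosine similarity 0 (with a message)
  instead of an error, so a degenerate embedding cannot abort graph
  construction.
- **Backpropagation** for both networks is hand-derived and verified
  against central finite differences (tolerance 1e-7 on sampled
  coordinates) in the test suite; the adjacency and propagation algebra
  are verified against brute-force pairwise/entrywise evaluation at
  1e-10.

## Problem sizes used by the tests and acceptance script

Unit and property tests run on cohorts of 40–300 subjects with 8–64
dimensional embeddings, graphs of up to 20 nodes for brute-force oracle
comparisons, and 4³–8³ volumes for the CNN (gradient checks at 4³,
training contracts at 8³ with a reduced configuration: 2 blocks × 2
units, growth 4, bottleneck 8, 32-d embedding). The planted-signal sweep
uses a 300-subject cohort, 64-d embeddings and 10 GCN seeds per graph.
The default 64³ architecture is validated through its hand-computed
shape table (channel growth 24 → 60 → 30 → 66 → 33 → 69, spatial
64 → 32 → 16, embedding 512) rather than by training it.

## Known limitations

- The vectorized dense-array implementation of the 3D DenseNet is meant
  for reduced-scale volumes; training the full 64³ architecture is
  computationally out of scope here.
- No k-NN sparsification, learned edge weights, or attention; the graph
  families are exactly the three edge-assigning functions above.
- Multi-feature *non-imaging* graphs sum indicator similarities
  (consistent with the combined formula's sum); the reference exercises
  only single-feature non-imaging graphs.
- The simulator does not model scanner physics, registration error, or
  covariate-feature dependence within class; its phantoms are not MRI.
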