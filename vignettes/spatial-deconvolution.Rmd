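---
title: "Spatial deconvolution by adversarial domain adaptation: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial deconvolution by adversarial domain adaptation: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

## The problem

A spatially barcoded capture region -- a Visium spot or a Slide-seq bead --
covers more than one cell, so its transcriptome is a mixture of the cell
types it happens to contain. Given a single-cell RNA-seq reference with
cell-type annotation, *deconvolution* asks: what proportion of each cell
type contributed to each spot?

spotdecon treats this as a domain-adaptation problem. Mixtures with known
composition are easy to simulate from the reference: draw `k` cells, give
them random weights, and sum their expression -- a *pseudospot*. A network
trained to read composition off pseudospots works perfectly in the
simulated domain, but real spots differ from simulated ones in ways the
simulation does not capture (sequencing depth, capture efficiency, dropout,
platform chemistry). Adversarial domain adaptation closes that gap: a
domain classifier is trained to tell real spots from pseudospots in the
network's feature space, while the feature embedder is trained, among its
other duties, to defeat it. At convergence the embedding carries
composition information but little domain information, so the fraction
predictor transfers to the real data.

## Preprocessing

Both modalities pass through the same fixed sequence, enforced by a layer
tag on the `count_matrix` container:

1. **Total-count normalisation** (`normalize_total`): each cell/spot is
   scaled to a common total, 10^4 by default (counts-per-10k; the
   conventional default where only the normalisation family is prescribed).
2. **log(1 + x)** (`log1p_transform`).
3. **Marker selection** (`rank_sum_markers`): per cluster, a one-sided
   Wilcoxon rank-sum test of cluster vs rest on the log-normalised values
   (tie-corrected normal approximation with continuity correction),
   Benjamini-Hochberg adjustment within each cluster comparison, top `l`
   genes kept, pooled and deduplicated. The one-sided alternative is used
   because markers are *highly expressed* genes; a two-sided option exists.
4. **Panel intersection** (`intersect_genes`): the pooled signature is
   restricted to genes measured in both modalities; everything downstream
   sees exactly this panel, in panel order.
5. **Per-sample min-max scaling** (`minmax_scale`): each cell, pseudospot
   and spot is independently mapped to [0, 1] over its panel genes. Scaling
   happens *after* subsetting to the panel, since that is the input space
   the model sees; a constant sample maps to all zeros (it carries no
   signal, and this avoids a divide-by-zero).

Scaling each sample to [0, 1] is what makes the two domains comparable at
all: it removes overall depth differences, leaving the adversarial phase to
absorb the subtler distortions.

## Pseudospots

`generate_pseudospots(sc, annot, k, n, seed)` draws, for each of `n`
pseudospots, `k` cells uniformly **without** replacement (mimicking `k`
distinct physical cells under a spot; cells are reused freely across
pseudospots) and weights `w_i = u_i / sum(u_j)` with `u_i ~ Uniform(0,1)`.
The composite profile is the weighted sum of the cells' log-normalised
expression, and the label row is the weight mass summed per cell type --
so the ground truth is known exactly, by construction. The normalised
uniform law is the package's reading of "random weights"; a Dirichlet
alternative is available via `weight_law = "dirichlet"`. Every batch logs
its (cell, weight) provenance so any row can be recomposed independently,
and is bitwise reproducible from its seed.

Defaults for `k` follow the platform: 8 for Visium-scale spots (several
cells per spot), 2 for Slide-seq beads, 10 for tissues with small packed
cells such as lung. For `n`, 5-10 times the number of real spots saturates
performance; the Visium-scale default is 20 000.

## The model

Three parts share one feature embedder `f`:

* **f**: panel genes -> 1024 -> 64, each stage an affine map followed by
  batch normalisation and ELU activation.
* **S** (source classifier): affine 64 -> K with softmax; predicts the
  fraction vector.
* **D** (domain classifier): affine 64 -> 32, batch normalisation, ELU,
  dropout (rate 0.5), then affine 32 -> 1 with sigmoid; outputs the
  probability that its input is a real spot.

With `Y` the true fractions, the losses are

* `L_s = KLD(Y || S(f(X_p)))`, the Kullback-Leibler divergence of predicted
  from true composition, averaged over the batch (natural log, `0 log 0 = 0`,
  probabilities clipped at 1e-8 inside logs);
* `L_adv1 = -log D(f(X_p)) - log(1 - D(f(X_r)))`, the inverted-label
  adversarial term;
* `L_total = L_s + alpha * L_adv1`, the embedder-side objective;
* `L_adv2 = -log D(f(X_r)) - log(1 - D(f(X_p)))`, the domain classifier's
  binary cross-entropy.

`D` emits a single sigmoid probability rather than a two-unit softmax; the
scalar form matches the loss algebra above exactly. `alpha` defaults to 0.6
(the brain-tissue 1:0.6 weighting); 1.0 is the lung-style alternative.

## Training

1. **Pretraining** (`pretrain_source`): minibatch Adam on `L_s` alone over
   the pseudospot set (10 epochs by default). On its own this is the
   `NN_wo_da` ablation baseline (`train_nn_wo_da`): same architecture,
   pseudospots only, no adaptation, domain classifier untouched.
2. **Adversarial optimisation** (`adversarial_train`), repeated for
   `iterations` (default 3000, minibatch 512):
   * *Phase A*: sample equal-size minibatches of pseudospots and real
     spots; update `f` and `S` to minimise `L_s + alpha * L_adv1` with `D`
     frozen. Gradients flow *through* the frozen `D` into `f`.
   * *Phase B*: update `D` to minimise `L_adv2` at its own learning rate
     (0.005) with `f` and `S` frozen.

"Frozen" is a contract, not a convention: a frozen component's parameters
*and* batch-norm buffers are bitwise unchanged by the step, which
`adversarial_train(check_freeze = TRUE)` asserts via parameter hashes at
every iteration, and the test suite exercises routinely.

Choices the loss formulae do not pin down, made once and documented here:

* **Optimiser**: Adam for both sides; only the domain-classifier rate
  (0.005) is prescribed, the main rate defaults to 0.001.
* **Pretraining minimises `L_s` alone**, not the total loss -- the stated
  purpose of pretraining is to initialise the fraction predictor.
* **Batch composition**: for the adversarial forward, the pseudospot and
  real minibatches are concatenated so the embedder's batch normalisation
  sees both domains in one batch; the same minibatch pair serves phases A
  and B of an iteration. Real spots are resampled with replacement when
  fewer than `batch_size` exist.
* **Initialisation**: Glorot-uniform affine weights, zero biases,
  batch-norm gamma = 1, beta = 0.
* **Batch normalisation**: eps 1e-3; running statistics updated with decay
  0.9, so they converge well within even short training runs; inference
  always uses running statistics, making predictions independent of batch
  composition (a property the tests check spot-by-spot).
* **Numerical guards**: sigmoid/softmax outputs are clipped at 1e-8 inside
  logs; a non-finite loss aborts with a diagnostic rather than training on.

Prediction (`predict_fractions`) runs in inference mode and returns a
`fraction_map` whose rows are probability vectors.

## Evaluation

With per-spot region annotation (cortical layers, tissue compartments), a
cell type known to live in one region yields a label-free accuracy measure:
`roc_auc` scores the type's predicted fraction as a classifier of region
membership (Mann-Whitney form: concordant pairs plus half the ties over
all pos x neg pairs). `auc_significance` tests AUC > 0.5 with a one-sided
rank-sum test -- exact enumeration for tie-free groups up to 25, the
tie-corrected normal approximation otherwise -- and callers Bonferroni-
correct across (type x slide) comparisons. Spots labelled `"unknown"` are
excluded from both sides.

`domain_fraction_ranking` reproduces the tissue-compartment summary used
for mapping cell types to histological domains: min-max scale each type's
fraction across all spots, average within each domain, rank types by the
ratio of in-domain to out-of-domain mean (infinite ratios -- types absent
outside -- sort first, ties by adjusted p), exclude types with in-domain
scaled mean below 0.2, flag Benjamini-Hochberg-adjusted rank-sum
enrichment at p < 0.05, and report the top 7 per domain. Whether the
scaling should pool slides or not is not prescribed; spotdecon scales per
dataset (per call).

## The synthetic generator: what it does and does not emulate

`make_reference` builds a clustered reference: negative-binomial counts
(dispersion theta = 2) around log-normal gene base means, log-normal
library sizes (sdlog 0.3), and per-type disjoint marker blocks whose means
are multiplied by `fold_change` -- the over-dispersion and depth-variation
structure of droplet data at a caricatured effect size. `make_spatial`
builds spots exactly like pseudospots and then applies what a pseudospot
never sees: a global library-size factor, entrywise log-normal
multiplicative noise, and independent dropout zeroing. With
`region_priors`, cell types can be made region-restricted, giving the AUC
evaluation a ground truth.

What it does **not** emulate: spatial autocorrelation, cell-size and
capture-efficiency differences between types, platform-specific chemistry,
segmentation noise, or batch structure in the reference. Passing tests on
this generator therefore show that the pipeline is correct and that
adaptation helps under a depth/noise/dropout shift -- not that it resolves
every distortion in real tissue.

## Study scales used by the tests and the acceptance script

The shipped checks run at desk scale, chosen to finish in minutes on one
CPU while keeping every moving part engaged: a reference of 5 types x 250
cells x 200 genes (10 planted markers per type, fold change 8), 500 spots
of k = 8 cells, l = 20 markers per cluster (panel of roughly 100 genes),
5000 pseudospots (the 10-per-spot end of the 5-10x rule), 500 adversarial
iterations at batch 256. The domain-shift benchmark uses libsize factor 5,
multiplicative noise sd 0.5 and dropout 0.3, with one cell type restricted
to one of two regions. Under these conditions the pseudospot-only baseline
recovers fractions at a mean per-type Pearson well above 0.7 when there is
no shift, and the adversarially adapted model localises the restricted
type at least as well as the baseline under shift -- the quantities
`scripts/acceptance.R` recomputes from scratch.

## Known limitations

* The number of cells per spot `k` is fixed during simulation; variable
  cell density is absorbed, if at all, by the adaptation.
* Rare cell types can be masked by dominant ones; running the pipeline on
  a subclustered reference is the practical recourse.
* Adversarial training is a minimax heuristic: it lacks a convergence
  guarantee, and the loss curves (kept in `model$history`, see
  `tidy(model)`) should be inspected on new data.
* The shared embedder presumes pseudospots and spots have comparable
  feature structure; grossly mismatched references (wrong tissue, wrong
  species) violate that silently.
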