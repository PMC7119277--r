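---
title: "Shallow CNNs for cancer-type prediction from gene expression: models and methods"
author: "cancerCNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shallow CNNs for cancer-type prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk RNA-seq profiles carry enough information to assign a tumor to its
cancer type with high accuracy, which makes them attractive both for
diagnostic support (e.g. carcinoma of unknown primary) and for marker-gene
discovery. Two methodological difficulties dominate. First, gene-expression
vectors are *unstructured*: unlike images, there is no meaningful spatial
neighborhood between alphabetically adjacent genes, so convolutional
architectures must be designed around global rather than local features.
Second, every tumor also carries the expression program of its *tissue of
origin*; a classifier trained only on tumors partly learns to recognize
tissues, and any marker genes read off such a model confound "kidney" with
"kidney cancer".

cancerCNN implements three shallow convolutional topologies addressing the
first difficulty, an explicit 34th "Normal" output class addressing the
second, a guided-saliency interpretation pipeline that scores every gene for
every class, and a class-conditional simulator of pan-cancer expression so
that the whole chain is testable end to end without any external download.

## Input representation

Expression is modelled as $x_{g} = \log_2(\mathrm{FPKM}_g + 1)$. Genes with
low information burden — mean $< 0.5$ **or** standard deviation $< 0.8$
across all samples regardless of class (sample sd, $n-1$ denominator) — are
removed; on the pan-cancer compendium this retains 7091 genes. Retained
genes are sorted alphabetically by symbol and the vector is zero-padded to
7100 with reserved `_PAD` pseudo-genes so the length factorizes (the 2D
models reshape it row-major into a $100 \times 71$ grid; row-major is fixed
as the canonical, documented convention because any fixed arrangement is
equally arbitrary and reproducibility requires picking one). Padding
pseudo-genes can never collide with real symbols and are excluded from all
marker reporting.

## The three architectures

All models share: ReLU activations, a softmax prediction layer, valid
padding, and a single convolutional stage — the shallow design is deliberate
(few samples relative to parameters; deeper stacks on expression data have
not shown gains).

**1D-CNN.** One 1D convolution whose *stride equals the kernel length*
(canonical kernel 71 on the 7100-vector, 32 filters), so each kernel
summarizes a disjoint 71-gene window and no spurious adjacency is assumed:
$h_{w,f} = \mathrm{ReLU}(\sum_{j=1}^{71} W_{j,f}\, x_{71(w-1)+j} + b_f)$ for
$w = 1..100$. Max-pooling of size 2 over windows, a 128-unit fully connected
layer, then softmax. 211,489 trainable parameters at 33 classes.

**2D-Vanilla-CNN.** A conventional strided 2D convolution on the
$100 \times 71$ grid (32 kernels of $10 \times 10$, stride $2 \times 2$ →
feature map $46 \times 31$), $2 \times 2$ max-pooling with floor semantics
($23 \times 15$), dense 128, softmax: 1,420,737 parameters at 33 classes.

**2D-Hybrid-CNN.** Two parallel 1D kernels on the grid: a row-sized kernel
($1 \times 71$) sliding vertically (100 positions) and a column-sized kernel
($100 \times 1$) sliding horizontally (71 positions), 32 filters each. Each
branch is max-pooled with size 2 using *ceiling* semantics on odd lengths
(100→50, 71→36), concatenated (2752 features), dense 128, softmax: 362,177
parameters at 33 classes.

**Subtype variant.** For 5-class breast-cancer subtyping the dense layer is
removed entirely: conv → pool → softmax, 10,309 parameters.

Pooling conventions deserve a note: the published parameter counts are only
reproduced with floor pooling in the 1D and 2D-Vanilla models and ceiling
pooling on both hybrid branches; `parameterCount()` implements the
closed-form count (weights + biases per layer) without building a network,
and every built model asserts equality with it at construction time.

Because the stride equals the kernel size, *every convolution in the package
reduces to a gather plus one matrix multiplication*; the engine represents a
branch as an index matrix into the flat input, a kernel matrix, and a
pooling map, and processes whole batches as single BLAS calls. Gradients for
all topologies are checked against central finite differences in the test
suite (relative error ~1e-7).

## Training protocol

Categorical cross-entropy, Adam at its default rate (0.001, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$), at most 50 epochs of shuffled
batches of 128, early stopping on categorical accuracy with patience 4
(training halts after 4 consecutive epochs without improvement; the weights
of the stopping epoch are kept, matching the common framework default rather
than restoring the best epoch). When a validation split is supplied the
monitor is validation accuracy — the protocol statement does not name the
split, and validation is the standard reading; the monitor is switchable.
Weights are initialized Glorot-uniform with the convolutional
receptive-field fan convention (fan_out = kernel length × filters), the
framework default the original implementation would have used; the
initialization seed is explicit everywhere.

Splitting is stratified by class (80/20 holdout; repeated stratified 5-fold
cross-validation × 6 repeats for `crossValidate()`), since 36-sample classes
make unstratified folds ill-posed. Inside cross-validation, 10% of each
fold's training portion is held out as the early-stopping monitor so fold
test data never influence training; `gridSearch()` evaluates every Cartesian
grid point with the same fold machinery and reports mean/sd train and test
cross-entropy, flagging the best row by mean test loss and recording
unbuildable points as failed rows. Class encoding order is alphabetical with
"Normal" always last (the 34th node).

## Noise robustness

Test-set corruption adds independent $\varepsilon_{ig} \sim N(0, (k
\mu_g)^2)$ per entry, where $\mu_g$ is the mean of gene $g$ *in the matrix
being corrupted* (the protocol trains on clean data and tests on noisy data,
so the test-set mean is the natural referent; this is switchable by passing
a different matrix), clipping negatives to zero. `noiseRobustnessCurve()`
evaluates micro accuracy over $k \in \{0, 0.25, 0.5, 0.75, 1, 2, 5\}$ by
default, averaging each $k > 0$ over several noise seeds; $k = 0$ is the
untouched data, so its accuracy equals the clean accuracy exactly.

## Interpretation

`guidedSaliency()` backpropagates one output class to the inputs with guided
rules: at every rectifier the gradient is zeroed where the unit was inactive
*or* the incoming gradient is negative; max-pooling routes gradient to the
winning position; negative values at the input are zeroed, keeping positive
evidence only. The differentiated quantity is the class's **softmax
probability** by default, with the pre-softmax logit behind a flag. This was
a genuinely open choice: the logit gradient is the textbook saliency target,
but it is class-insensitive under guided rules, whereas the softmax Jacobian
$\partial p_c/\partial z_k = p_c(\mathbb{1}[k{=}c] - p_k)$ subtracts
competing classes *before* the first rectifier clip and therefore retains
some class discrimination; the package defaults to the discriminative
variant.

`geneEffectMatrix()` averages the guided saliency of each class over that
class's samples and scales each column by its maximum, giving genes ×
classes scores in [0, 1] with the top gene of every class at exactly 1
(per-class scaling keeps the marker threshold comparable across classes;
global scaling is available). A gene with score > 0.5 is a marker
(`selectMarkers()`, threshold adjustable); genes may mark several classes
and the unique-gene count is the union of symbols. `markerConcordance()`
quantifies whether markers are differentially expressed: per gene the
absolute difference between the class mean and the rest-of-samples mean on
the log2 scale, compared between markers and non-markers by a one-sided
Welch t-test (the variant is unspecified in the protocol; Welch is the
safe default). `geneSetEnrichment()` reads GMT collections and applies a
one-tailed Fisher exact test per set against the post-filter universe,
matching symbols case-insensitively after whitespace stripping.

## The simulator: what it emulates and what it does not

`simulatePanCancer()` draws, for a sample of cancer class $c$ in tissue $t$:
$x_g = b_g + \tau \cdot \mathbb{1}[g \in T_t] + \delta \cdot \mathbb{1}[g \in
M_c] + \varepsilon_g$, truncated at 0, with baselines $b_g \sim U(1.5, 3.5)$
(so every gene passes the information filter by construction),
$\varepsilon_g \sim N(0, \sigma^2)$ iid, tissue signature $T_t$ shared by
tumors and normals of tissue $t$, and class markers $M_c$. Normals carry
*only* their tissue signature and are pooled under one "Normal" label — the
tissue-of-origin confound by construction. Values are emitted directly on
the log2(FPKM+1) scale.

Canonical defaults mirror the pan-cancer study conditions: 11 tissues × 3
cancers + Normal; 60 tumor samples per class and 6 normals per tissue; 7091
genes (the post-filter pan-cancer count, padded to 7100); 108 markers per
class (the observed average marker count per class); 200 tissue genes per
tissue (not externally fixed; chosen once as a broad tissue signature);
$\delta = 2.0$, $\tau = 1.5$, $\sigma = 1.0$. The subtype simulator mirrors
the published class imbalance (147/68/437/186/26) with 100 markers per
subtype — intrinsic-subtype differences span hundreds of genes; a
50-gene reporting panel is not the breadth of the underlying biology.

Deliberately **not** emulated: correlated co-expression modules, library-size
and count-level (negative binomial) sampling, heterogeneous per-gene effect
sizes and variances, any shared "normal tissue" program across tissues, and
real tissue signatures' breadth (thousands of genes). Consequences matter
for two properties:

* **Normal-node routing.** With only ~5 training normals per tissue and no
  shared normal program, the Normal class is 11 disjoint
  "tissue-minus-markers" regions. In 7091 iid-noise dimensions a per-tissue
  normal centroid estimated from 5 samples has error $\approx
  \sqrt{7091/5} \approx 38$, larger than the distance
  $\sqrt{4 \times 108} \approx 21$ to the nearest cancer cluster, so the
  region is not estimable: training normals are memorized and held-out
  normals route to Normal far below the rate seen on real data, where
  normals are ~31 per tissue and share a strong pan-tissue program. The
  tumor-only confound itself (normals assigned to cancers of the matching
  tissue) reproduces robustly.
* **Planted-marker recovery.** Guided saliency concentrates on the subset of
  markers the trained network actually uses for its margin; with 108
  redundant markers per class the network needs only a fraction of them, and
  the remaining top ranks are genes planted for other classes or tissues.
  Recovery of planted markers into the top 2× marker-count of their class
  column therefore saturates well below 1; the qualitative property — planted
  markers score systematically above unplanted genes — holds and is tested.
  Passing tests on this simulator consequently demonstrate the machinery and
  its calibration, not that guided saliency enumerates all causal genes.

## Numerical choices and degenerate inputs

* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Ceiling pooling pads a trailing odd window by repeating its first member,
  which leaves the max unchanged and keeps gradient routing unambiguous
  (first-member tie-break).
* A gene-effect column that is identically zero is left at zero rather than
  rescaled.
* A degenerate concordance test (all per-gene differences equal, e.g. all
  zero) reports p = 1 with a `degenerate` flag instead of failing.
* Gene sets with no overlap with the universe are skipped with a warning;
  zero marker overlap gives p = 1 exactly (the whole upper tail).
* Precision of a never-predicted class is reported as 0 and the class is
  flagged, so recall-collapse cases remain representable.
* One user-visible seed per entry point; internal stages derive fixed
  offsets from it (documented in each function) so stages can be re-run
  independently and all outputs are bit-reproducible.

## Problem sizes used by the shipped checks

The test suite exercises unit properties on small designs (hundreds of genes,
tens of samples per class) and the end-to-end properties on the canonical
design above (2,046 samples × 7,091 genes, 34 classes); the acceptance script
re-runs the canonical pipeline — separability, null control, confound,
interpretation, noise curve, subtype variant — from scratch in a few minutes
on one CPU. These sizes are the package's chosen study conditions, stated
here so results are interpreted at the scale that produced them.

## Known limitations

Single-threaded CPU training only (adequate for these shallow topologies);
no dropout, batch normalization, or multi-layer stacks by design; no
count-level simulation; interpretation is restricted to guided gradient
saliency — attribution methods with stronger class sensitivity
(e.g. contrastive or propagation-based schemes) are out of scope; biological
claims about specific genes require real data and external validation.
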