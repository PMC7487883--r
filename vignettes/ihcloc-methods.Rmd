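---
title: "ihcloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ihcloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In brightfield immunohistochemistry (IHC) of tissue sections, a target
protein is visualized with a DAB-labelled antibody (brown) while cell nuclei
are counterstained with hematoxylin (purple). The spatial relation between
the two stains encodes the protein's subcellular compartment, which `ihcloc`
classifies into three broad patterns: **i** nucleus, **ii** cytoplasm and
plasma membrane, **iii** both. Because several colon-cancer-associated
proteins are known to *translocate* between compartments in malignant
tissue, a classifier of these patterns can be turned into a screen for
location biomarkers: a protein whose predicted-pattern statistics differ
significantly between its normal-tissue and cancer-tissue images is flagged.

This vignette documents the model and every consequential design choice; it
states no empirical numbers beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## Stain unmixing

Transmitted light obeys the Beer–Lambert law, so stains mix additively in
optical density, `OD = -log10((pixel + 1)/255)` per RGB channel (the +1
avoids `log 0`; base-10 is the stain-separation convention). Two routes
recover per-pixel stain concentrations:

* **LIN** (`unmix_linear`): least-squares projection of each OD vector onto
  a fixed 2×3 basis of unit-norm stain color vectors, negatives clipped to
  zero because concentrations are physical. The default basis is the
  standard published hematoxylin/DAB calibration (`default_basis()`), since
  no empirical matrix ships with the method; any 2×3 basis can be supplied.
* **NMF** (`unmix_nmf`): a per-image blind rank-2 factorization of the
  (pixels × 3) OD matrix by multiplicative updates (Frobenius objective,
  500-iteration cap, 1e-5 relative tolerance). Rank-2 NMF is only defined
  up to a containing cone, so the solver is initialized at the *extreme
  angular rays* of the OD point cloud in its top-2 singular plane — a
  deterministic, SVD-based starting point that lands on the true stain
  vectors whenever the image contains near-pure pixels of each stain. That
  identifiability condition matters: an image whose protein signal sits
  entirely inside nuclei (class i) has no pure-DAB pixels and no blind
  method can recover its stain basis; validation of basis recovery therefore
  uses class-ii fixtures, where both compartments appear unmixed. Fitted
  components are matched to a reference basis by maximal row-wise cosine
  similarity (`match_channels`) so channel order is always (DNA, protein).

## Interest patches

IHC images mix stained glands, unstained stroma and background; only
protein-rich regions carry pattern information. `select_patches` smooths the
protein channel with a Gaussian low-pass (σ = size/8), scores square
candidate windows on a stride grid (stride = size/2) by mean smoothed
intensity, and greedily keeps the highest-scoring windows whose pairwise
area overlap stays ≤ 25 %. Stride, filter and overlap cap are not dictated
by the method's description; the choices here are ordinary interest-region
practice and all are arguments. Scores use the window *mean* rather than the
sum so that different patch sizes are comparable during grid search. The
engineered pipeline defaults to 205 patches of 75 px and the deep pipeline
to 35 patches of 224 px — the published optima of the grid search that
`patch_grid_search` reproduces (counts 25–385 by 20, sizes 45–225 by 30).

## Engineered features (848 per patch)

Three blocks, concatenated with name prefixes `dna.`, `har.`, `lbp.`:

1. **16 DNA features** relating protein to nuclei. Both channels are
   Otsu-binarized (mean fallback for unimodal windows) into masks P and D;
   the features are area and overlap ratios, an intensity ratio,
   Manders-style colocalization fractions (intensity of each channel inside
   P∩D over its intensity inside its own mask), Pearson correlation over
   P∪D, the intensity-weighted centroid distance, and mean/median/sd/max
   nearest-neighbor distances P→D and D→P, all distances normalized by the
   window diagonal. Degenerate denominators give 0; distance statistics of
   an empty mask are imputed at the diagonal (the maximal value 1).
2. **576 Haralick-on-wavelet features**: a 5-level periodized 2-D Daubechies
   DWT (filters db1–db10 selectable; coefficients are the standard published
   constants, validated in tests against the orthonormality identities and
   the closed-form Haar transform) yields 3·5+1 = 16 subbands; each subband
   is min–max quantized to 32 gray levels and summarized by 9 Haralick
   statistics (energy, contrast, correlation, variance, homogeneity, sum
   average, entropy, sum entropy, difference entropy; base-2 logs,
   0·log 0 := 0) of the symmetric GLCM at the four unit offsets
   (0°, 45°, 90°, 135°): 16 × 4 × 9 = 576. Only the block's dimensionality
   and its GLCM/wavelet construction are fixed by the method's description;
   the exact statistic set is this package's documented choice. Subbands too
   small for an offset, and constant subbands, get the degenerate
   single-entry-GLCM statistics, so vectors are always finite.
3. **256 LBP features**: the classic 8-neighbor radius-1 local binary
   pattern histogram (neighbor ≥ center, clockwise from top-left,
   top-left = least significant bit), normalized to sum 1. A constant window
   places all mass at code 255 — forced by the ≥ convention.

Per-image features are the element-wise mean over the image's patches,
mirroring the averaging used for the deep features.

## Deep features

Seven backbones contribute penultimate-layer features:

* **gapnet_pl** is a faithful SELU network built from scratch: 8
  convolutional layers (widths 32,32,64,64,128,128,256,256, 3×3, same
  padding), 5 pooling layers (max pools after conv 2/4/6/8, plus global
  average pooling), and 3 fully-connected layers. Global-average-pool taps
  after conv 4/6/8 are concatenated (448 values) and projected to the
  256-unit penultimate layer. There is no ReLU and no batch normalization;
  initialization is LeCun-normal, the SELU-consistent choice. Because GAP
  removes spatial dimensions, the forward pass accepts any input side
  (tests run 32–96 px), though 224 px is the nominal size.
* The six ImageNet-era names (**googlenet, resnet18, resnet50, resnet101,
  inception_v3, densenet201**) are served by compact convolutional encoders
  — strided SELU convolutions to a GAP vector and one fully-connected layer
  to the contractual 1000-dim penultimate output, with a per-name
  depth/width schedule and weights seeded from (name, seed). These are
  deliberately lightweight surrogates: the pipeline's contracts (feature
  dimensionality, determinism, patch averaging, concatenation order) are
  exercised with seeded random weights, and externally trained weights can
  be plugged in through `backbone_spec(weights = "file")`. `"pretrained"`
  is refused with instructions rather than silently downloading anything.
* For the six 1000-dim backbones the "penultimate layer" is read as the
  1000-unit classification layer — the only reading consistent with the
  stated dimensionalities — and this deviation from common usage is
  intentional and documented here.

Patches enter as the protein channel replicated across three input
channels; feeding the original RGB patch instead is a one-line change in
`window_to_input` and was left out of scope. `fine_tune` replaces the last
layer with the task's classes and trains the fully-connected head by
momentum SGD with exact manual backpropagation (softmax cross-entropy,
lr 1e-3, batch 32 defaults); the convolutional stack stays frozen and its
activations are cached once per patch. Head-only training is this package's
design: it keeps fine-tuning exactly reproducible and cheap on a CPU, and
the descent/accuracy contracts in the tests are stated for it.

The combined representation concatenates
`[engineered | googlenet | resnet18 | resnet50 | resnet101 | inception_v3 |
densenet201 | gapnet_pl]` = 848 + 6×1000 + 256 = **7104** columns.

## Feature selection

`sda_select` is classic stepwise discriminant analysis on Wilks'
Λ = det(W)/det(T): forward entry of the feature with the largest partial F
(if > f_enter), then backward removal of entered features whose partial F
fell below f_remove, Schur-complement updates making each step O(p²) per
candidate. Defaults f_enter = 3.84 / f_remove = 2.71 are the conventional
χ²₁-derived values (the method's description names none); `max_k` defaults
to min(200, n/3) to keep scatter matrices well-conditioned, and a cap of 97
reproduces the published combined-model budget. Singular scatters are
ridge-stabilized (λ = 1e-8·trace) with a warning. Λ is scale-free, so
selection is invariant to per-feature rescaling — a property the tests
check.

## Classification and evaluation

`train_svm` wraps libsvm (e1071): RBF kernel, min–max scaling to [0,1]
fitted on training data only, (c, g) chosen by inner 5-fold accuracy with
ties to the smaller c then g, final refit with one-vs-one pairwise-coupled
probability estimates. The standard coarse grid
(c = 2⁻⁵…2¹⁵, g = 2⁻¹⁵…2³) is available as `default_svm_grid()`; the
pipeline defaults to a compact 3×3 grid that keeps desk-scale runs fast.
`crossval` evaluates under two partitions: **per_image** (stratified
k-fold) and **per_protein** (grouped k-fold, no protein on both sides of a
fold — the partition that measures generalization to unseen proteins and is
systematically the harder one whenever images of one protein share nuisance
structure). Metrics are accuracy and *macro* recall/precision/F1; macro is
the informative choice under class imbalance.

## Translocation screening

Each image receives a 21-dimensional score vector: the 3-class probability
outputs of the seven single classifiers (each trained on engineered + one
backbone's features, SDA-reduced). For a protein with m ≥ 2 normal and
n ≥ 2 cancer images, `translocation_test` runs a per-dimension two-sided
two-sample t-test (pooled-variance Student by default, Welch via flag;
zero-variance dimensions give p = 1 on equal means, else 0) and
`flag_biomarker` applies the min-p < 0.05 rule with no multiplicity
correction — deliberately matching the screening rule as published, with
Bonferroni/BH available behind a flag. The minimum over 21 correlated
dimensions is *liberal*: its familywise null rejection rate exceeds the
per-dimension 5 %, which the tests document explicitly and which is the
main driver of false positives in the end-to-end experiment. Per-protein
localization calls are majority votes over per-image predictions, ties
broken by the larger mean score.

Two controls probe the rule. `null_control` splits a protein's normal
images in half and tests the halves against each other; under the
no-translocation null most p-values should exceed 0.05.
`intensity_distance_control` represents images by 64-bin protein-channel
intensity histograms, pools all normal×cancer pairwise Euclidean distances
by detection flag, and fits each pool with a maximum-likelihood gamma
distribution; similar fits for detected and undetected proteins indicate
the detection is not explained by raw pixel distributions.

## Synthetic data

`synth_image` emulates exactly the structure the pipeline assumes: random
ellipses carry hematoxylin OD; protein OD is placed inside nuclei (i), in
annular cytoplasm/membrane rings excluded from nuclei (ii, default ring
8 px), or both (iii); smooth per-region intensity jitter provides texture;
RGB = 255·10^(−C·basis) with optional Gaussian OD noise, quantized to
8 bits. With zero noise the rendering is exactly invertible, which is what
makes the linear-algebra oracles in the tests exact. `synth_dataset`
assigns each protein a balanced localization class, makes a chosen fraction
of proteins translocate in the cancer state, and adds a per-protein
log-normal nuisance factor on stain strength and nucleus size so that
images of one protein are correlated — the structure that makes per-protein
cross-validation strictly harder than per-image, as it is on real data.
What the generator does *not* emulate: glands, stroma, staining artifacts,
section thickness variation, JPEG compression. Passing tests therefore
demonstrate the pipeline's internal correctness and statistical behavior,
not field performance on real tissue.

## Problem sizes used in tests and the acceptance script

The validation suite runs everything at desk scale, chosen once as
realistic miniatures of the study design: synthetic images of 80–96 px with
5–6 nuclei, engineered patches of 32 px (the smallest side compatible with
a 5-level DWT), 2–4 patches per image, a 12-protein modeling set
(3 normal + 3 cancer images each, balanced classes) and a 20-protein
screening set with 4 normal / 12 cancer images per protein and half the
proteins translocating — the same m/n structure as the study's biomarker
data at reduced counts. The type-I calibration uses 2000 simulated null
proteins; the permutation oracle uses 10⁵ permutations.

## Known limitations

* The 16 + 576 + 256 feature construction matches the published
  dimensionalities and semantics, not any lab's byte-level implementation.
* The six ImageNet-named backbones are surrogate encoders unless real
  weights are supplied; accuracies with random weights say nothing about
  transfer-learning performance.
* Fine-tuning trains the fully-connected head only.
* The min-p screening rule is liberal by construction; users screening many
  proteins should consider the correction flags.
* Blind NMF unmixing cannot identify the stain basis on images lacking
  near-pure pixels of each stain (e.g. purely nuclear proteins); LIN with
  the standard basis is the default for a reason.
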