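---
title: "Decoding cognitive concepts from heterogeneous brain-map repositories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cognitive concepts from heterogeneous brain-map repositories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnod)
```

## The problem

Task fMRI studies publish statistical maps — per-voxel z, t or beta values
contrasting a target condition against a control — to open repositories,
with free-text annotations instead of curated labels. Pooling thousands of
such maps across studies makes *reverse inference* statistically
addressable: given a new map, which mental processes does it engage?
`nnod` implements the whole chain from uncurated maps and annotations to
multi-label concept scores, together with a synthetic-repository generator
so that every stage can be exercised against known ground truth.

Three properties of repository data drive the design:

* **Heterogeneity of baselines.** Each study's control condition differs;
  maps carry negative-going patterns of whatever their control subtracted.
* **Weak supervision.** Labels must be mined from noisy annotation text
  against a concept ontology with synonyms and is-a (hypernymy) structure.
* **Cross-study validation.** Generalization must be measured on entire
  held-out collections, never on held-out maps of a seen study, because
  within-study correlations inflate any other estimate.

## Signal representation

Maps are standardized to a common grid and mask (trilinear interpolation
for data, with out-of-range coordinates clamped to the array edge so
constant images are preserved exactly; nearest-neighbour logic for masks),
then projected onto dictionaries of K non-negative sparse spatial
components by ordinary least squares. Rank-deficient dictionaries fall
back to the minimum-norm (SVD pseudoinverse) solution. Because components
are non-negative, clipping the loadings at zero (`positive_part()`)
equals keeping only positive map activity, which suppresses
control-condition artifacts. Projections at several resolutions are
concatenated — highest resolution first, a fixed order so serialized
features are stable — into a multi-resolution representation
(1024 + 512 + 128 = 1664 features for the full-size trio). Loadings are
deliberately not rescaled or standardized before modeling, keeping the
linear model's coefficients interpretable in loading units.

## Labeling semantics

A concept labels a map when its canonical name or a registered synonym
occurs, case-insensitively at word boundaries, in any free-text annotation
field; word boundaries stop "art" from matching "startle". Enrichment
rules — token corrections ("wm" → "working memory"), per-collection
pattern rules, synonym-pair merges — are applied to *training* collections
only, so reported test metrics are never inflated by hand-tailored test
labels. Hypernym closure is applied to both splits: every positive concept
implies its ontology ancestors. Finally the vocabulary is pruned:
concepts with fewer than `min_count` (default 10) positive maps are
dropped, and within pairs whose absolute phi correlation exceeds
`max_abs_corr` (default 0.95) the rarer member is dropped (ties: the later
concept), iterated to a fixed point. Both defaults are exposed because
curation intensity is a judgment call that scales with repository size.

## The NNoD model family

The decoder is a fully connected network over the loading vector
`x ∈ R^p`, from 0 hidden layers (logistic regression, `f(x) = Wx + b`) to
3, with identity or rectifier activations. Two output formulations are
supported: independent Bernoulli per label (sigmoid + summed binary
cross-entropy) and a single categorical distribution over labels
(softmax + cross-entropy against the label-normalized target
`y / Σ y`, so a map with several labels spreads its mass uniformly and
label-vector scaling is irrelevant). Probabilities are clamped to
`[1e-7, 1 − 1e-7]` inside losses; softmax subtracts the row maximum for
stability. Regularization is an elastic-net penalty on all weight
matrices (biases exempt) plus dropout on the input and every hidden
activation — one `(l1, l2, dropout)` triple shared by all layers —
with inverted scaling so evaluation needs no correction.

Training uses mini-batch Adam (defaults: learning rate 1e-3, batch 256,
100 epochs) on hand-derived gradients; the test suite verifies them
against central finite differences for all layer counts, activations and
losses. Initialization is symmetric uniform scaled by fan-in and seeded;
with dropout included, training is bit-reproducible given the config
seed. The optimizer, epoch count and batch size are package decisions —
defaults chosen for robustness at desk scale — not facts inherited from
any particular study; all are arguments. The reference configuration is
one rectifier hidden layer of width 300, dropout 0.2, l1 = l2 = 0.001,
over stacked positive-part loadings. `grid_search_nnod()` selects
configurations by validation macro AUC with ties broken by list position.

## Evaluation

Both metrics are per-label and prevalence-agnostic. Per-label ROC AUC is
computed by midrank statistics (ties count one half); labels with a
single class in the test split are excluded with a reason rather than
scored 0.5, keeping the macro average meaningful. WR@k asks, per label,
how often a truly positive map ranks that label in its top k; boundary
ties are broken by ascending label index after the score sort, making the
metric deterministic. Splits hold out whole collections; the evaluable
vocabulary is the set of concepts positive on both sides of the split.

## Interpretation maps

Decoding (sensitivity) maps differentiate a concept's *logit* — not the
post-sigmoid probability, which saturates — with respect to the input
loadings, average over maps, and back-project through the dictionaries
(stacked blocks each through their own dictionary, summed). Averaging
over all maps is the default; a `positives_of` argument restricts to the
concept's positive maps, which is the natural choice when the question is
"what does the model use when the concept is present". Encoding maps
regress each loading on the full binary concept matrix (intercept
included; a rank-deficient design falls back to a flagged minimum-norm
fit) and back-project the concept's coefficients. Display thresholding is
rank-based — the `floor(q·n)` smallest absolute voxels are zeroed — so
exactly the top `1 − q` fraction survives, re-thresholding is a no-op and
the `q → 0` limit leaves maps untouched; the default q = 0.95 displays
the top 5%.

## The synthetic world

The generator emulates, at desk scale, the statistical structure the
analysis assumes. Defaults: 3 collections × 170 maps on an 11×13×11 grid
(~900 in-mask voxels), three independent sparse non-negative dictionaries
of 64/32/16 components, a 20-concept ontology with synonyms and hypernym
depth ≤ 3, effect size 4 against voxel noise 0.5 (a high-SNR regime in
which decoding should approach ceiling — scores far below ceiling signal
a pipeline defect, which is the point of the fixture).

Design choices that deserve justification:

* **Compositional concept names.** Generated concepts are heads
  ("perception"), modifier compounds ("auditory perception") and doubly
  modified compounds, with hypernym edges following the linguistic
  structure. A name therefore contains the names of exactly its
  ancestors, so exact matching plus closure can in principle recover
  truth exactly — and the zero-noise test asserts it does for 100% of
  maps.
* **Signatures span all dictionaries and inherit ancestors.** Each
  concept recruits 3 components drawn over the concatenated dictionaries
  (no single resolution spans the signal, which is what makes stacking
  informative) and additionally inherits its hypernym ancestors'
  components — probing "auditory reasoning" engages the reasoning
  network plus auditory areas. Inheritance makes hypernym-closed labels
  physically consistent and creates "common responses": networks shared
  through the hierarchy that encoding maps display and discriminative
  decoding down-weights, the behaviour the interpretation tests assert.
* **The baseline confound is subtracted, sparse, and map-varying.** Each
  collection has a control-condition pattern over ~20% of the finest
  dictionary's components (control tasks are localized); each map
  subtracts it with a half-normal magnitude, because contrasts cancel
  their control to varying degrees. A pattern *added identically* to all
  of a collection's maps would shift every map's scores by the same
  constant and be invisible to within-collection rank metrics; the
  per-map magnitude is what makes the artifact measurable, and its
  negative sign is what the positive part clips away. Under strong
  corruption the positive-part stacked representation wins the 8-cell
  representation-comparison grid, the direction the acceptance suite
  checks across ten seeded replicates.
* **Contaminants and annotation noise.** Mutually exclusive contaminant
  classes (thresholded: 80% of in-mask values zeroed; partial field of
  view: 70% zeroed; wrong modality: anatomical-like intensities plus a
  metadata flag) at configurable rates, and four independent Bernoulli
  corruption operators on concept mentions (synonym substitution,
  vowel-dropping abbreviation, single-character typo, whole-field
  omission). t-maps are rescaled z-maps (factor 0.8–1.25); beta-maps add
  Student-t (3 df) noise. These are caricatures: real QC failure modes
  and annotation pathologies are richer.

What the generator does **not** emulate: spatial smoothness and
anatomical structure (components are random sparse supports, not brain
parcels), inter-subject variability, any hemodynamic or time-series
level, realistic value marginals for QC threshold matching, and the
smooth nested multi-scale structure of real parcellations. The last point
has a visible consequence: in real data all dictionary resolutions decode
nearly equally well, whereas here a 16-of-112-component projection
genuinely loses class information (far above chance, well below
ceiling). A nested alternative (`generate_dictionary_pyramid()`, coarse
components aggregating fine ones plus fresh territory) recovers part of
that realism but, by making coarse spans near-subsets of the fine span,
removes most of the stacking advantage; the default world keeps
independent dictionaries because the representation-ordering property is
the scientifically load-bearing one. A green test on this world
establishes that the pipeline's machinery is correct, not that any
particular real dataset will decode well.

## Numerical and procedural choices

* QC thresholds default to coverage ≥ 0.5, zero fraction ≤ 0.5,
  |z/t| ≤ 50; beta maps are exempt from the absolute cap but rejected
  when their in-mask maximum exceeds 50× their own 99th percentile (a
  per-map spike rule, chosen over a batch-quantile rule so that QC is
  idempotent: re-filtering survivors rejects nothing).
* Duplicate detection compares full-precision formatted in-mask values —
  exact by construction.
* Stage orchestration hashes each stage's parameters and input artifacts;
  unchanged stages are skipped and downstream states invalidated on
  change. Artifacts are plain formats: NIfTI-1, JSON, CSV.
* All randomness flows from explicit integer seeds through `withr`
  seed scoping; derived seeds stay small (seed + small offsets).

## Known limitations

Pure-R training is fine at 10³–10⁴ maps × 10³ features but far from the
scale GPU frameworks reach; the multinomial mode requires every training
map to have at least one positive label; ontologies are assumed
tree-like (multi-parent diamonds would double-count inherited signature
components); and the NIfTI reader supports the common single-file subset
only (no extensions, no 4-D images).
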