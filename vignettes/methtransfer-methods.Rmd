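---
title: "Methods: transfer learning for cfDNA methylation classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer learning for cfDNA methylation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(methtransfer)
```

## The problem

Circulating cell-free DNA (cfDNA) carries the methylation signature of the
tissues that shed it, which makes plasma methylation profiling a candidate
assay for non-invasive multi-cancer detection. The statistical obstacles
are severe: cfDNA cohorts are small (tens to hundreds of samples), heavily
imbalanced across cancer types, high-dimensional (thousands to hundreds of
thousands of CpG probes), and noisy, with 10–30% of measurements missing
after quality control. `methtransfer` implements a complete analysis
framework for this setting built on four ideas:

1. **Strict, auditable preprocessing** from signal intensities to a
   harmonized feature panel.
2. **Sequence-aware features**: each probe's beta value is fused with a
   reduced embedding of its 50-bp flanking DNA sequence, so the model sees
   both the methylation level and the genomic context it occurs in.
3. **Transfer learning**: a bottleneck residual network is pretrained on a
   large bulk-tissue methylation cohort (the source domain) and fine-tuned
   on the small cfDNA cohort (the target domain) with its early stages
   frozen.
4. **Open-set recognition**: a Weibull-calibrated rescoring layer converts
   softmax outputs into scores over the known classes *plus an unknown
   class*, so samples from cancer types never seen in training can be
   flagged rather than misassigned.

Everything is testable offline: a first-class synthetic-cohort module
generates labelled methylation matrices, source/target domain pairs, toy
genomes and probe manifests in exactly the formats the real pipeline reads.

## Preprocessing model

Beta values are methylation fractions
$\beta = M / (M + U + \mathrm{offset})$, with $M$ and $U$ the methylated
and unmethylated signal intensities. The offset guards against near-zero
total intensity; we default to 100, the common array-platform convention
(the choice is configurable and only matters for low-intensity probes).

The cascade runs in a fixed order, and every stage applies a **strict**
inequality at its threshold, so boundary values survive:

| Stage | Rule | Default |
|---|---|---|
| Detection QC | mask entries with detection $P >$ threshold | 0.01 |
| Probe filter | drop probes missing in $>$ `max_frac` of *any class* | 0.30 |
| Sample filter | drop samples missing $>$ `max_frac` overall | 0.20 |
| Harmonization | keep selected probes with target missingness $\le$ cap | 0.30 |
| Zero-fill | remaining `NA` $\to 0$ | — |

The per-class view in the probe filter protects minority classes: a probe
that fails only in a rare cancer type is removed even if its overall
missingness is low. Residual missing values are zero-filled rather than
imputed — with classes of only a handful of samples, imputation borrows
values across samples whose independence the evaluation relies on, whereas
a zero reads as "no methylation signal detected". Zero-filling is
idempotent, and missingness is represented as an explicit `NA` until that
final step so every filter sees the true missingness pattern.

Feature selection ranks source-domain probes with a random forest (500
trees, impurity importance, fixed seed; ties broken lexicographically by
probe id) trained on source labels only, so no target-domain label can
leak into the panel. The forest requires complete data, so it runs on a
zero-filled view of the source cohort — consistent with what the model
will eventually see. A variance ranking is available as a lighter
fallback; the forest is the default because it scores discriminative
relevance rather than raw spread. Samples are put in a canonical order
before fitting so the ranking is invariant to row permutations of the
input.

## Sequence embedding and fusion

For each probe the 50-bp window `[pos - 25, pos + 24]` (1-based, inclusive)
is extracted from the reference genome, so the interrogated site sits at
0-based offset 25 — 25 bases upstream, the site, and 24 more downstream,
which is the only way "25 up + 25 down" totals 50. Minus-strand probes are
reverse-complemented; windows are never padded, and a window that runs off
a chromosome end is an error.

Windows are embedded by a pluggable provider declaring an output dimension
$d_0$ (640 in the full-scale preset, matching large protein-language-model
embedders). The package ships a deterministic mock — a stable hash of the
sequence seeds a normal draw — because the point of the pipeline tests is
the *plumbing around* the embedder, not the embedder itself; adapters for
real pretrained models implement the same two-generic interface. How a
nucleotide sequence should be tokenized for a protein language model is
deliberately left to the adapter. The raw probes × $d_0$ matrix is
centered and reduced by PCA (probes as observations, no scaling,
deterministic sign convention) to the probes × $d$ pretrained
probe-embedding matrix (PPE; $d$ = 128 at full scale, 8 in the test
suite).

A sample's model input fuses its beta vector with the PPE elementwise:
$X_{ij} = \beta_i \cdot \mathrm{PPE}_{ij}$. The fused tensor is presented
to the network as a single-channel 2-D array (probes × $d$); fusion is
linear in beta, a fully unmethylated probe contributes a zero row, and a
fully methylated one contributes the raw embedding row.

## Network and training

The backbone is a bottleneck residual network with four stages of
bottleneck units (1×1 reduce → 3×3 → 1×1 expand, each convolution followed
by batch normalization and ReLU). The first unit of stages 2–4 downsamples
with stride 2 and carries a 1×1 strided projection on its skip path; all
other units use identity skips. A 3×3 stride-2 stem convolution plus 3×3
stride-2 max pooling maps the single-channel input into stage 1 — a
methylation "image" has one channel, not three, so the stem is the
package's own choice. Global average pooling and a linear head of width
$C$ finish the network. The full-scale preset
(`network_config_resnet101()`) uses blocks `[3, 4, 23, 3]` with stage widths
64/128/256/512 and expansion 4 — its stage-4 first unit reduces 1024
channels to 512 and expands to 2048. Tests and laptop-scale analyses use
blocks `[1, 1, 1, 1]` with widths scaled down ~8-fold; depth and width are
configuration, not architecture.

Training minimizes multi-class cross-entropy with Adam (default learning
rate 1e-5 and batch size 16 — settings suited to full-scale cohorts; laptop-scale
runs use 1e-3, which the vignette's own experiments found necessary for
the narrow test networks to converge in tens of epochs). A stratified 10%
validation split drives early stopping: training stops after `patience`
(default 10) epochs without validation improvement and restores the best
parameters. Class weighting by inverse frequency ($N_{total}/N_c$,
normalized to mean 1) is implemented but off by default — on imbalanced
cohorts it trades overall accuracy for minority-class recall. The whole
loop is deterministic for a fixed seed under single-threaded execution:
initialization, the validation split and batch order all derive from the
config seed. The classification head is initialized with small weights
(sd 0.01) so the initial softmax is near-uniform (loss ≈ $\ln C$).

**Transfer.** Fine-tuning re-initializes the head for the target label
vocabulary and freezes the first `freeze_blocks` stages (default 2). The
stem is frozen together with stage 1, so `freeze_blocks = 4` trains only
the head and 0 trains everything. Frozen stages keep bit-identical
parameters *and* batch-norm statistics — their batch-norm layers run in
inference mode during fine-tuning — which is what the per-stage checksum
contract in the tests verifies. Optimizer and loss settings are kept
identical between pretraining and fine-tuning. Freezing is defined at the
block (stage) level, with `freeze_blocks` as the single knob — the level
at which the architecture is naturally partitioned and at which freezing
strategies are usually compared.

## Open-set layer

The activation vector of a sample is its softmax output (the
penultimate-feature alternative is an option; softmax-space distances are
the default even though the original open-set-recognition formulation
used penultimate features — a deliberate, documented choice). For
each known class $j$, calibration computes the mean activation vector
$\mathrm{MAV}_j$ over correctly-classified training samples and fits a
two-parameter Weibull (location 0, maximum likelihood, deterministic
profile-equation solver) to the `tail_size` (default 20) largest distances
to the MAV. Euclidean distance is the default, cosine optional. Rescoring
a query with softmax scores $s_j$ and distances $d_j$:

$$w_j = 1 - F_j(d_j), \qquad s_j' = s_j w_j, \qquad
s_{\mathrm{unknown}} = \sum_j s_j (1 - w_j),$$

with $F_j$ the fitted Weibull CDF. Score mass is conserved exactly in
algebra, and the decision is the argmax over
$\{s_1', \ldots, s_C', s_{\mathrm{unknown}}\}$ with ties resolved in
favour of known classes (lowest index first) — a sample is never declared
unknown on a tie. Degenerate calibrations (all tail distances ~0) fall
back to a step-like CDF with a floored scale (1e-8), so a query at the MAV
keeps $w = 1$. No top-$\alpha$ revision is applied: the rescoring
discounts every class, which is how the equations above are stated.

## Evaluation

Per-class metrics come from one-vs-rest 2×2 collapses of the confusion
matrix; "weighted MCC" and "weighted F1" are support-weighted means of the
per-class values. The weighted one-vs-rest form is the package's reading
of "weighted" — the single-coefficient multiclass MCC generalization is
computed alongside in every report for comparison, and a zero denominator
defines a per-class MCC of 0. Samples the open-set layer labels UNKNOWN
occupy their own confusion-matrix column and count as errors for every
class metric. Cross-validation is stratified (per-class fold sizes differ
by at most one, seeded assignment); each fold trains from scratch or
fine-tunes a supplied pretrained model.

The unknown-masking protocol withholds one class entirely, trains on the
rest, refits the open-set calibration within each masking run (rather
than reusing a calibration fitted with the masked class present — the
conservative choice), and reports the fraction of withheld samples
flagged UNKNOWN. Two design points matter at small cohort sizes, and both
were found empirically during the package's own development:

* **Held-out calibration.** A network trained to convergence memorizes
  its training points: their activation distances to the class MAVs are
  near zero, so a Weibull fitted to them declares *every* fresh sample —
  novel or not — extreme. The protocol therefore holds out a stratified
  `calibration_fraction` (default 25%) of the retained samples from
  network training and fits MAVs and tails on those, restoring a
  realistic distance scale. Calibrating on the training points themselves
  (`calibration_fraction = 0`) reproduces the original formulation.
* **Tail size well below the calibration sample.** The rescoring
  discounts a class once a query's distance enters the fitted tail. If
  the tail spans *all* calibration distances, its CDF reaches ~0.5 at the
  in-distribution median and half of the genuinely known samples are
  rejected. The tail must cover only the extreme distances — masking runs
  in this package use a tail of 5 against ~10 calibration samples per
  class.

## Attribution

Probe attribution backpropagates the target-class logit to the fused
input, multiplies gradient by input, takes the L2 norm over the embedding
dimension and averages over samples — by default the correctly-predicted
samples of the target class, so the saliency describes what drives
*confident, correct* predictions (averaging over all samples is available
via `attribute_probes()` directly; the restriction is the package's
resolution of an ambiguity in the source description). Plain
absolute-gradient attribution is an option flag. Gradient-times-input
makes saliency exactly zero for probes with beta 0 everywhere, and scaling
the inputs never changes the zero set. Top-ranked probes map to genes by
expanding semicolon-joined annotations, de-duplicating in first-occurrence
order.

Three properties of this operator matter for interpreting its output, all
observed directly in the package's synthetic experiments:

* **Magnitude dependence.** Because the attribution multiplies by the
  fused input, markers whose discriminative state is *low* methylation
  (beta below the 0.5 background) — or whose embedding row happens to have
  small norm — are structurally attenuated: the model may rely on them,
  but their gradient × input product is small. Hypermethylation markers
  are recovered far more reliably than hypomethylation markers.
* **Subset selection.** When markers are redundant (any 5 of 10 suffice to
  separate the classes), a trained network uses a seed-dependent subset
  and the unused markers get near-zero saliency. This is a faithful report
  of what the model does, not an attribution failure.
  [consensus_attribution()] stabilizes the ranking by averaging normalized
  saliencies over several independently seeded models, the same logic that
  makes forest importance steadier than a single tree's.
* **Spatial leakage.** Convolutions mix neighbouring probe rows, so a
  strong marker's saliency bleeds into adjacent probe indices (whose
  ordering is biologically arbitrary). Top-k lists should be read with a
  few-probe halo in mind.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws beta values from Beta distributions
parameterized by (mean, concentration): background probes at mean 0.5,
each class's informative probes shifted by ±`effect_size` (alternating
sign, so classes show hyper- and hypomethylation), missingness inserted
completely at random, labels attached, everything reproducible by seed.
`generate_domain_pair()` emulates the bulk → cfDNA setting: a larger
class-rich source cohort and a small target cohort whose classes reuse a
fraction (default 0.8) of the source's informative sites at an attenuated
effect size (default 0.18 vs 0.3) — tumour signal in cfDNA is diluted by
hematopoietic background DNA. Defaults (3 target classes × 20 samples, 200
probes, 10 informative per class, concentration 50, 10% missingness;
source 6 classes × 40) are the laptop-scale study conditions used throughout
the tests.

The generator does **not** simulate array chemistry, batch effects,
probe-probe correlation, class-dependent missingness (available as an
option but off by default), or tumour-fraction deconvolution. Passing
tests therefore demonstrate that the machinery is correct and that the
method behaves as designed under controlled signal — not that it attains
any particular accuracy on real cfDNA cohorts, whose headline numbers
require the original multi-study data and GPU-scale training.

## Numerical choices and scale

Tolerances: open-set mass conservation to 1e-9; PCA orthonormality to
1e-8; metric agreement with an independent from-the-definitions oracle to
1e-12. Weibull fitting brackets the shape in [1e-3, 1e3] and scales
distances by their maximum before profiling, so large shapes stay finite.
The problem sizes in the test suite and acceptance script — 200-probe
panels, 32→8-dim mock embeddings, blocks `[1,1,1,1]` with 16- or
8-channel stems, 60–240-sample cohorts, five CV folds, five transfer
seeds — were chosen as the smallest configurations at which each
end-to-end property is comfortably exhibited; wider stems (16 channels)
are used where near-perfect class recovery is the property under test,
narrower ones (8) where a paired comparison is. The network engine is
vectorized base R (im2col convolutions with memoized geometry); full-scale
`[3,4,23,3]` training is expressible but intended for workstation use, not
the test suite.

## Known limitations

* The real pretrained-language-model embedder is an interface, not an
  implementation; the mock embedder preserves only the shape and
  determinism of the real thing, not biological sequence similarity.
* Softmax activation vectors compress open-set geometry: two samples with
  identical softmax but different penultimate features are
  indistinguishable to the default calibration (the `penultimate` option
  exists for exactly this reason).
* A confidently-wrong prediction on a novel class lands near a known
  class's MAV and will not be flagged UNKNOWN; the unknown-masking
  protocol quantifies this failure mode rather than preventing it.
* Weighted one-vs-rest MCC can differ from the multiclass MCC
  generalization on strongly imbalanced confusion matrices; both are
  reported.
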