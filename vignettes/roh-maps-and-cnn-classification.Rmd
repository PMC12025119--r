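---
title: "ROH maps and convolutional classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH maps and convolutional classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`rohcnn`, the assumptions behind them, and the design decisions taken
where several reasonable choices existed. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The problem

A run of homozygosity (ROH) is a contiguous block of homozygous genotype
calls, arising when an individual inherits identical haplotypes from both
parents. Classical analyses summarise ROH into counts and total lengths
per length class, which ignores *where* the runs sit in the genome and how
they co-occur. `rohcnn` instead encodes each individual's full ROH
landscape as an image and lets a convolutional classifier exploit the
spatial arrangement — for between-breed discrimination or for binary trait
classification within a breed.

## 2. ROH detection

Detection follows the standard sliding-window scan of SNP-array
genotypes, per sample and chromosome:

* **Window eligibility.** A window of `window_snp = 50` consecutive SNPs
  is *homozygous* iff it contains at most `window_het = 1` heterozygous
  and at most `window_missing = 5` missing calls. Each SNP's hit ratio is
  the fraction of windows covering it that are homozygous; the SNP is
  flagged when the ratio is at least `window_threshold = 0.05`
  (inclusive). A chromosome shorter than the window is scanned with a
  single window covering all of its SNPs.
* **Segment calling.** Maximal flagged runs are split wherever
  consecutive SNPs are more than `homozyg_gap = 500` kb apart. If a
  candidate carries more than `homozyg_het = 1` heterozygous calls it is
  split at the leftmost excess heterozygous SNP (which is discarded),
  repeatedly, so each emitted piece respects the per-segment
  heterozygote budget. Pieces are kept iff they contain at least
  `homozyg_snp = 50` SNPs, span at least `homozyg_kb = 1000` kb and
  average at most `homozyg_density = 100` kb per SNP.

Notes on the less obvious choices:

* `window_missing = 5` and `window_threshold = 0.05` are the documented
  defaults of the scan this procedure mirrors; they are exposed in
  `roh_params()` like every other knob.
* Segment length is `(end_bp − start_bp)/1000` kb (no `+1`), matching the
  common convention of `.hom`-style outputs; `length_kb/n_snps` uses the
  same value, so the density bound is a bound on mean marker spacing.
* The density parameter is implemented as a **maximum kb-per-SNP** (a
  *minimum density*): a segment averaging more than 100 kb between
  markers is rejected. The parameter's historical name ("density") is
  kept even though it bounds sparsity.
* Missing calls inside a segment are allowed and never counted as
  heterozygous.
* The leftmost-excess-heterozygote split is one concrete reading of a
  per-segment heterozygote cap. It is deterministic, keeps pieces
  non-overlapping, and the exhaustive test oracle implements the same
  rule, so the suite is internally consistent; other tools may resolve
  pathological het arrangements differently.
* Only autosomes 1–18 are analysed (the pig karyotype drawn by the
  renderer); other chromosome codes are dropped with a warning at load
  time. Length classes are left-closed/right-open in Mb:
  [0,2), [2,4), [4,6), [6,8), [8,16), [16,∞).

Correctness is checked against an independent, deliberately naive oracle
(explicit window enumeration, explicit scans) on 100 random instances of
up to 200 SNPs, and every emitted segment is asserted to satisfy every
constraint. Detection is invariant to sample order and to relabelling
HOM_REF ↔ HOM_ALT, since only homozygous/heterozygous/missing status
enters the scan — which is also why the PED reader's major-allele REF
convention (ties broken alphabetically) cannot affect results.

## 3. Quality control

`qc_filter()` removes samples with a missing-call fraction strictly above
`mind = 0.1`, then variants whose missing fraction — recomputed over the
retained samples — is strictly above `geno = 0.1`. The sample-first order
and recomputation mirror common genotype-QC practice; both thresholds are
strict ("more than 10%"), so exactly-10% entities are retained. No
allele-frequency, HWE or MAF filtering is applied. A borderline caveat:
removing a variant can in principle *raise* a retained sample's missing
fraction, so sample-then-variant filtering is not mathematically
idempotent for adversarial missingness patterns; on realistic (uniform)
missingness it is, and the suite asserts idempotency on such fixtures.

## 4. ROH map rendering

Each individual becomes one RGB raster (default 512 × 512, white
background): 18 horizontal bands, chromosome 1 at the top, no labels or
axes. Within a band the segment bar occupies a configurable fraction
(default 0.6) of the band height, vertically centred. All chromosomes
share a single x-scale — `pixel = round(bp / max(chrom_lengths) × (W−1))`
— so the longest chromosome spans the full width and rectangle widths are
comparable across chromosomes; every segment is at least 1 px wide.
Colours are fixed RGB values for the six length classes (green (0,128,0),
red (255,0,0), blue (0,0,255), turquoise (64,224,208), orange-yellow
(255,165,0), gray (128,128,128)); the classifier only needs the classes
to be *distinct*, which a palette-permutation test confirms.

Training uses lossless PNG by default. JPEG (quality 95) export is
provided for compatibility with the original map format; note that the
available JPEG encoders chroma-subsample, so a small fraction of
colour-edge pixels shift noticeably even at maximum quality, while the
nearest-palette class assignment is essentially unchanged (both
properties are measured in the tests). Chromosome lengths default to the
maximum observed marker position per chromosome when no table is given.

## 5. The convolutional classifier

Architecture (input H × W × 3, pixel values rescaled by 1/255):

| stage | layers |
|---|---|
| 1–3 | conv 3×3 (8 → 16 → 32 filters, ReLU, L2 1e-4) → batch norm → max-pool 2×2 |
| head | global average pooling → dropout 0.3 → dense(2) → sigmoid |

The two-unit sigmoid head with one-hot targets and element-wise binary
cross-entropy is implemented exactly as specified for this model family
(a softmax head is available behind `model_config(head=)` for
comparison). Focal loss (`γ = 2` default) is available for imbalanced
data and reduces exactly to cross-entropy at `γ = 0`. Class weights
`w_c = N/(2 N_c)` (so Σ w_c N_c = N) are applied to the training loss.
Training uses Adam (lr 1e-3), batch size 16, up to 100 epochs, early
stopping on validation loss with patience 10 and best-weight restoration.
Optimizer, learning rate, batch size, dropout, L2 strength and patience
are not dictated by the model family; the defaults above are ordinary
values for small CNNs and all are configuration-exposed. Convolutions use
same-padding, so spatial size is controlled solely by the three pools
(input sides must be multiples of 8).

The network is implemented directly in R: convolutions as im2col + BLAS
matrix products, with the input-gradient expressed as a convolution with
spatially flipped, channel-transposed kernels, and batch normalization
(ε = 1e-3, running-stat momentum 0.9) in training and inference modes.
Every gradient path — all weights, batch-norm parameters, and the input
gradient used for saliency — is verified against central finite
differences (relative error < 1e-5 in the tests). With a fixed
`model_config(seed=)`, initialization, shuffling and dropout are
deterministic, so training is bit-reproducible on one device.

Data protocol: stratified 70:20:10 train/validation/test split with
largest-remainder rounding per class (remainder ties resolved
train → validation → test), deterministic per seed. Images are rendered
to files and loaded fully into memory; arrays can also be passed
directly. The 512 × 512 reference resolution is exercised in a one-epoch
smoke test; routine runs and `scripts/acceptance.R` use 128 × 128, which
preserves the band geometry (128/18 ≈ 7-px bands) at a fraction of the
cost. Problem sizes used by the checked-in runs — 60 samples per class,
≤ 30 epochs at 128 × 128 — were chosen as the smallest scale at which the
strong-signal and null behaviours are unambiguous.

## 6. Evaluation, cross-validation, baseline

* **Metrics** from the 2 × 2 confusion matrix (rows = predicted,
  columns = observed): accuracy, sensitivity, specificity, PPV, NPV,
  with zero-denominator metrics reported as `NA` rather than 0. The
  accuracy CI is the exact Clopper–Pearson interval from beta quantiles —
  the interval type that reproduces the published (0.6319, 0.897) for
  33/42 — cross-checked against `stats::binom.test`. The **positive
  class is the second (case/defect) class** of the class ordering;
  display rounding is 4 decimals, internal values unrounded.
* **Cross-validation**: stratified k-fold (default 10) by round-robin
  dealing within class (fold class-counts differ by ≤ 1). A fresh model
  is built per fold; a stratified 1/8 slice of each training portion
  serves as the early-stopping set. CNN and baseline receive identical
  fold assignments for a given seed, enabling paired comparison.
* **Baseline**: images flattened to vectors; column centering and PCA
  fitted on the training portion only (exact economy SVD via the n × n
  Gram matrix, appropriate for p ≫ n; `n_components = 50` default,
  capped at n_train − 1); minority class upsampled with replacement to
  balance, within the training portion only; ridge-penalized logistic
  regression (glmnet, α = 0, λ = 1e-2 default) for numerical stability
  on these wide inputs; held-out folds scored by Mann–Whitney rank
  ROC-AUC with ties counted ½. Fitting PCA per fold (rather than once
  globally) is the leakage-free choice; a corruption test — perturbing
  held-out labels and pixels must leave every fitted parameter
  bit-identical — guards both the baseline and the CNN path.

## 7. Saliency

Saliency is the absolute gradient of the target class's score with
respect to the input pixels, computed in inference mode. The gradient is
taken on the **pre-sigmoid score** by default (the standard choice; the
sigmoid's derivative only rescales the map and can saturate), with a
probability-space option. Channels are reduced by the maximum (mean
optional) and maps are min-max normalized; class-average maps are means
of per-image normalized maps. `pixel_to_genome()` inverts the renderer's
geometry, so salient pixels can be exported as merged BED intervals
(`saliency_bed()`), turning a trained classifier back into genomic
hypotheses. Pixels in inter-band margins or beyond a chromosome's scaled
end are reported as non-genomic.

Localization is assessed at the planted hotspot *rectangles* (the
hotspot chromosome's band rows restricted to the planted segments'
x-extent), not across whole chromosome bands: a band is mostly empty
background columns, which dilute any signal, whereas the rectangle is
where the class-informative pixels actually sit. On the strong-signal
preset, mean saliency inside the hotspot rectangles exceeds the
genome-wide mean for both classes (asserted in the test suite).

## 8. The synthetic-data generator

The simulator plants homozygous runs directly rather than simulating
population history: the pipeline consumes ROH *structure*, so
segment-level simulation is the simplest faithful input model. Defaults:
18 autosomes with pig-like relative lengths (~55–274 Mb), exponential
inter-marker gaps with 30 kb mean (≈ 75k markers genome-wide, the density
of a mid-size porcine array), background per-SNP heterozygosity 0.30,
residual heterozygosity 0.005 inside planted runs, 1% uniform
missingness. Class structure comes from hotspot profiles — (chromosome,
centre, occurrence probability, length-class mixture) — plus a shared
profile carried by both classes; planted lengths are drawn uniformly
within their class's kb range (short-class runs start at 1.2 Mb so they
clear the 1 Mb detection floor).

Presets define the study conditions used throughout the tests:

* `breed-like` — fully penetrant (occurrence probability 1.0) hotspot
  sets that differ between the classes in location, number *and*
  length-class mixture: one class carries three mid-length (1–4 Mb)
  runs, the other six long (4–24 Mb) runs. Real breeds differ in ROH
  abundance and length composition as well as placement, and the
  composition contrast matters here for a second reason: the classifier
  ends in global average pooling and is therefore translation-invariant,
  so a signal carried *only* by segment location is largely invisible to
  it — abundance and colour composition are what it can exploit. This
  preset's end-to-end test accuracy reaches ≥ 0.95 (the synthetic
  analogue of perfect breed separation).
* `trait-like` — shared hotspot locations with a 0.25 vs 0.85 occurrence
  gap: a partially penetrant binary-trait signal.
* `null` — identical (shared-only) profiles; labels exchangeable, so
  end-to-end accuracy must sit at chance.

What the simulator does **not** model: linkage disequilibrium, allele
frequency spectra, pedigree structure, autozygosity vs
homozygosity-by-state, genotyping batch effects. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that it
recovers planted spatial ROH signal — not that any particular real-data
accuracy will be achieved.

## 9. Degenerate inputs and numerical notes

* Empty call vectors, empty cohorts after QC, single-class label sets,
  and k > n folds raise explicit errors.
* Probabilities are clamped to [1e-12, 1−1e-12] inside losses; BN uses
  ε = 1e-3; Adam uses the standard bias correction with ε = 1e-8.
* Ties: argmax label decoding resolves exact probability ties to the
  first (sorted) class; AUC counts score ties ½; split-remainder ties go
  to the earlier subset.
* PCA components with numerically zero singular values are returned as
  zero loadings rather than noise.

## 10. Known limitations

* The ROH caller reproduces one concrete, tested reading of the
  sliding-window scan; exotic heterozygote placements may be segmented
  differently by other implementations.
* The CNN is CPU-bound R; it is sized for maps (hundreds of images,
  ≤ 512 px), not for large-scale image corpora.
* JPEG export is visually faithful but not pixel-exact (chroma
  subsampling); quantitative work should use the default PNG.
* Saliency is a first-order explanation; it highlights influential
  pixels, not causal genomic variants.
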