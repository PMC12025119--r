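# rohcnn

Runs of homozygosity (ROH) are contiguous stretches of a diploid genome
where both inherited haplotypes are identical, the footprint of inbreeding
and shared demographic history. Their number, length distribution and
genomic placement differ between livestock breeds and can associate with
complex traits, but classical ROH statistics (total length, counts per
length class) discard the *spatial arrangement* of the segments.

`rohcnn` implements an image-based alternative for SNP-array genotypes,
aimed at animal-breeding and population-genetics workflows:

1. **Detect** ROH per individual with a sliding-window homozygosity scan
   (window of 50 SNPs tolerating 1 heterozygous and 5 missing calls;
   emitted segments need ≥ 50 SNPs, ≥ 1 Mb, ≤ 100 kb/SNP density,
   inter-SNP gaps ≤ 500 kb, and ≤ 1 heterozygous call).
2. **Render** each individual's ROH landscape as an *ROH map*: an RGB
   raster with 18 chromosome rows (top = chromosome 1) and each segment a
   rectangle coloured by length class — green < 2 Mb, red 2–4, blue 4–6,
   turquoise 6–8, orange 8–16, gray > 16 Mb — on a shared genome-wide
   x-scale, 512 × 512 px by default.
3. **Classify** individuals (breed membership, binary trait status) with a
   compact convolutional network trained on the maps: three conv stages
   (8/16/32 filters, 3 × 3, ReLU, L2, batch norm, 2 × 2 max-pool), global
   average pooling, dropout, and a two-unit sigmoid head trained with
   element-wise binary cross-entropy (focal loss optional) on one-hot
   labels, class weights `w_c = N/(2 N_c)`, Adam, and early stopping. The
   network is implemented natively in R (im2col + BLAS) and is verified
   against finite-difference gradients in the test suite.
4. **Evaluate** with confusion-matrix metrics — accuracy with an exact
   Clopper–Pearson 95% CI, sensitivity, specificity, PPV, NPV — plus
   stratified 10-fold cross-validation and a PCA (exact truncated SVD) +
   ridge-logistic baseline with minority upsampling scored by
   Mann–Whitney ROC-AUC.
5. **Interpret** trained models with gradient saliency maps (per image and
   class-averaged), and map salient pixels back to chromosome/bp intervals
   (BED export).

A segment-level genotype **simulator** plants class-specific homozygous
runs on 18 pig-like autosomes (background heterozygosity 0.30, residual
within-run heterozygosity 0.005, 1% missingness, ~30 kb marker spacing) so
the entire pipeline can be exercised and tested without external data.

## Worked example

```r
library(rohcnn)

# Simulate a two-class cohort with disjoint, fully penetrant ROH hotspots
cfg <- run_config(
  out_dir = "run_demo",
  sim = sim_preset("breed-like", n_per_class = c(60L, 60L), seed = 2024L),
  model = model_config(input_shape = c(128L, 128L, 3L), epochs = 30L,
                       early_stopping_patience = 6L, seed = 2024L),
  seed = 2024L)
res <- run_pipeline(cfg)
res$metrics
```

The run prints per-stage progress and ends with the held-out test metrics
(output of the run above):

```
[..] simulate: 120 samples x 74928 variants (8.6s)
[..] qc: removed 0 sample(s)/variant(s) (9.5s)
[..] detect: 998 ROH segments (16.1s)
[..] render: 120 maps at 128x128 (16.7s)
[..] train: 24 epochs run (252.6s)
[..] evaluate: Accuracy 1.0000 (95% CI 0.7354-1.0000)  Sensitivity 1.0000
     Specificity 1.0000  PPV 1.0000  NPV 1.0000  [positive: LW]
```

The preset plants fully penetrant hotspot sets that differ between the
classes in number and length mixture, so the two classes are separable
from their maps: held-out accuracy is 1.0 on the 12-image test split —
the wide exact CI (0.7354, 1) is what 12/12 successes support.
`run_demo/` contains the segment table (`segments.tsv`, a `.hom`-style
TSV), one PNG map per animal plus a manifest, the training history, the
trained model, and `metrics.json`.

Individual stages are exposed as plain functions (`read_genotypes()`,
`qc_filter()`, `detect_roh()`, `render_roh_map()`, `train_cnn()`,
`cv_cnn()`, `logistic_baseline_cv()`, `saliency_map()`, ...), and
`inst/cli/rohcnn.R` provides shell subcommands
(`simulate | detect | render | train | evaluate | cv | baseline |
saliency | run`).

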