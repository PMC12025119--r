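Package: rohcnn
Title: Runs-of-Homozygosity Maps and Convolutional Classification for SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from PLINK text PED/MAP
    genotypes with a sliding-window scan, renders per-individual ROH maps as
    colour-coded raster images (18 chromosome rows, six length-class colours),
    trains a small convolutional neural network on those images to classify
    individuals (breed membership, binary traits), and evaluates it with
    confusion-matrix metrics, exact binomial confidence intervals, stratified
    10-fold cross-validation, a PCA plus logistic-regression baseline, and
    gradient saliency maps that localize the genomic regions driving the
    classification. Includes a synthetic genotype simulator that plants
    class-specific ROH architecture so the full pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    GenomicRanges,
    IRanges,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
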