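# Shared fixtures: tiny PED/MAP filesets, separable image sets, and a
# memoised strong-signal pipeline run reused across acceptance checks.

write_ped_fixture <- function(dir, ped_rows, map_rows) {
  ped <- file.path(dir, "fix.ped")
  map <- file.path(dir, "fix.map")
  writeLines(ped_rows, ped)
  writeLines(map_rows, map)
  list(ped = ped, map = map)
}

# Solid-colour separable image set: class "g" all-green, class "r" all-red.
solid_images <- function(n_per_class, side = 32L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- array(0, c(side, side, 3L, n))
  lab <- rep(c("g", "r"), each = n_per_class)
  for (i in seq_len(n)) {
    col <- if (lab[i] == "g") c(0, 160, 0) else c(200, 0, 0)
    for (k in 1:3) X[, , k, i] <- col[k] + rnorm(side * side, sd = 2)
  }
  X <- pmin(pmax(X, 0), 255)
  list(images = X, labels = lab)
}

tiny_model_config <- function(side = 32L, epochs = 15L, seed = 7L, ...) {
  model_config(input_shape = c(side, side, 3L), epochs = epochs,
               batch_size = 8L, early_stopping_patience = 4L,
               seed = seed, ...)
}

# Memoised acceptance-scale artifacts (strong-signal preset at 128 px),
# shared by several acceptance checks so the pipeline runs once.
.acceptance_env <- new.env(parent = emptyenv())

acceptance_strong_run <- function() {
  if (!is.null(.acceptance_env$strong)) return(.acceptance_env$strong)
  out_dir <- file.path(tempdir(), "acc_strong")
  cfg <- run_config(
    out_dir = out_dir,
    sim = sim_preset("breed-like", n_per_class = c(60L, 60L), seed = 2024L),
    model = model_config(input_shape = c(128L, 128L, 3L), epochs = 30L,
                         early_stopping_patience = 6L, seed = 2024L),
    saliency = FALSE, seed = 2024L)
  res <- run_pipeline(cfg)
  res$sim <- cfg$sim
  res$truth <- read_roh(file.path(out_dir, "truth.tsv"))
  res$out_dir <- out_dir
  .acceptance_env$strong <- res
  res
}

# Reciprocal-overlap recall of detected segments against detectable
# planted truth (those whose realized SNP content satisfies every ROH
# constraint).
truth_recall <- function(truth, segments, genotypes, snpmap,
                         p = roh_params(), min_overlap = 0.5) {
  detectable <- 0L; hit <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cols <- which(snpmap$chromosome == tr$chromosome &
                    snpmap$position_bp >= tr$start_bp &
                    snpmap$position_bp <= tr$end_bp)
    if (length(cols) < p$homozyg_snp) next
    pos <- snpmap$position_bp[cols]
    span <- (max(pos) - min(pos)) / 1000
    calls <- genotypes[tr$sample_id, cols]
    if (span < p$homozyg_kb || span / length(cols) > p$homozyg_density ||
        max(diff(pos)) / 1000 > p$homozyg_gap ||
        sum(!is.na(calls) & calls == 1L) > p$homozyg_het) next
    detectable <- detectable + 1L
    s <- segments[segments$sample_id == tr$sample_id &
                    segments$chromosome == tr$chromosome, , drop = FALSE]
    if (nrow(s)) {
      ov <- pmin(s$end_bp, tr$end_bp) - pmax(s$start_bp, tr$start_bp)
      rec <- ov / pmax(s$end_bp - s$start_bp, tr$end_bp - tr$start_bp)
      if (any(rec >= min_overlap)) hit <- hit + 1L
    }
  }
  list(detectable = detectable, hit = hit,
       recall = if (detectable) hit / detectable else NA_real_)
}
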