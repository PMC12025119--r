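# Synthetic diploid SNP-array genotypes with planted, class-specific ROH
# architecture. Segment-level simulation: homozygous runs are planted
# directly rather than arising from a coalescent model, because the
# downstream pipeline consumes ROH structure, not haplotype history.

# Approximate pig autosome lengths (Mb), chromosome 1..18. Config values,
# not biological claims; they reproduce the relative size ordering.
PIG_CHROM_MB <- c(274, 151, 132, 130, 104, 170, 121, 138, 139,
                  69, 79, 61, 208, 141, 140, 79, 63, 55)

#' Default chromosome lengths (bp) for the simulator and renderer
#'
#' @return Named numeric vector, chromosomes "1".."18", lengths in bp.
#' @export
default_chrom_lengths <- function() {
  stats::setNames(PIG_CHROM_MB * 1e6, as.character(seq_len(N_AUTOSOMES)))
}

#' Build a per-class ROH hotspot profile
#'
#' A profile is a set of hotspots; each hotspot is an ROH that a sample of
#' the class carries with probability `prob`, centred at `center_bp` on
#' `chrom`, with length drawn from a mixture over the six length classes.
#'
#' @param chrom Integer vector of hotspot chromosomes.
#' @param center_bp Numeric vector of hotspot centres (bp).
#' @param prob Numeric vector of per-sample occurrence probabilities.
#' @param class_mix Either a single numeric vector of six mixture weights
#'   over [LENGTH_CLASSES] (recycled to all hotspots) or a list of such
#'   vectors, one per hotspot.
#' @return data.frame-based profile object.
#' @export
roh_profile <- function(chrom, center_bp, prob, class_mix) {
  n <- length(chrom)
  stopifnot(length(center_bp) == n, length(prob) == n)
  if (!is.list(class_mix)) class_mix <- rep(list(class_mix), n)
  stopifnot(length(class_mix) == n,
            all(vapply(class_mix, length, 1L) == length(LENGTH_CLASSES)))
  structure(list(chrom = as.integer(chrom), center_bp = center_bp,
                 prob = prob, class_mix = class_mix), class = "roh_profile")
}

empty_profile <- function() {
  roh_profile(integer(), numeric(), numeric(), list())
}

#' Simulator configuration
#'
#' Defines the synthetic study conditions: cohort sizes, marker density,
#' background heterozygosity, within-run residual heterozygosity,
#' missingness, and the class-specific plus shared ROH hotspot profiles.
#'
#' @param n_per_class Integer pair: samples per class.
#' @param class_names Character pair of class labels.
#' @param chrom_lengths Named numeric vector of 18 chromosome lengths (bp).
#' @param snp_spacing_kb Mean inter-SNP spacing in kb (default 30, the
#'   density of a ~75k porcine genotyping array over a 2.2 Gb genome).
#' @param background_het_rate Per-SNP heterozygosity outside ROH
#'   (default 0.3).
#' @param within_roh_het_rate Residual per-SNP heterozygosity inside a
#'   planted run (default 0.005).
#' @param missing_rate Uniform missing-call rate (default 0.01).
#' @param profiles List of two [roh_profile()] objects, one per class.
#' @param shared_profile [roh_profile()] carried by both classes.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(60L, 60L),
                       class_names = c("A", "B"),
                       chrom_lengths = default_chrom_lengths(),
                       snp_spacing_kb = 30,
                       background_het_rate = 0.3,
                       within_roh_het_rate = 0.005,
                       missing_rate = 0.01,
                       profiles = list(empty_profile(), empty_profile()),
                       shared_profile = empty_profile(),
                       seed = 1L) {
  stopifnot(length(n_per_class) == 2, length(class_names) == 2,
            length(chrom_lengths) == N_AUTOSOMES,
            background_het_rate >= 0, background_het_rate <= 1,
            within_roh_het_rate >= 0, within_roh_het_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (pr in c(profiles, list(shared_profile))) {
    if (length(pr$chrom) &&
        any(pr$center_bp < 1 | pr$center_bp > chrom_lengths[pr$chrom])) {
      stop_rohcnn("hotspot centre outside chromosome bounds")
    }
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 class_names = class_names, chrom_lengths = chrom_lengths,
                 snp_spacing_kb = snp_spacing_kb,
                 background_het_rate = background_het_rate,
                 within_roh_het_rate = within_roh_het_rate,
                 missing_rate = missing_rate, profiles = profiles,
                 shared_profile = shared_profile, seed = as.integer(seed)),
            class = "sim_config")
}

# Length ranges (kb) sampled uniformly within each length class. LT2 starts
# at 1200 kb so planted short runs clear the 1000-kb minimum-length filter.
CLASS_KB_RANGES <- list(LT2 = c(1200, 2000), C2_4 = c(2000, 4000),
                        C4_6 = c(4000, 6000), C6_8 = c(6000, 8000),
                        C8_16 = c(8000, 16000), GT16 = c(16000, 24000))

#' Simulate a SNP map
#'
#' Positions per chromosome are cumulative exponential gaps with mean
#' `snp_spacing_kb`, then sorted and deduplicated.
#'
#' @param config A [sim_config()] object.
#' @return Variant map data.frame as in [read_genotypes()].
#' @export
simulate_snp_map <- function(config) {
  set.seed(derive_seeds(config$seed, "snp_map"))
  maps <- lapply(seq_len(N_AUTOSOMES), function(ch) {
    len <- config$chrom_lengths[ch]
    n_exp <- ceiling(len / (config$snp_spacing_kb * 1000)) + 50L
    pos <- cumsum(stats::rexp(n_exp, rate = 1 / (config$snp_spacing_kb * 1000)))
    pos <- unique(round(pos[pos <= len]))
    pos <- pos[pos >= 1]
    data.frame(variant_id = sprintf("snp_%d_%d", ch, seq_along(pos)),
               chromosome = ch, position_bp = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

draw_segments <- function(profile, config, retry_cap = 20L) {
  n_h <- length(profile$chrom)
  if (!n_h) {
    return(data.frame(chromosome = integer(), start_bp = numeric(),
                      end_bp = numeric()))
  }
  occurs <- stats::runif(n_h) < profile$prob
  segs <- data.frame(chromosome = integer(), start_bp = numeric(),
                     end_bp = numeric())
  for (h in which(occurs)) {
    for (attempt in seq_len(retry_cap)) {
      cls <- sample(LENGTH_CLASSES, 1L, prob = profile$class_mix[[h]])
      rng <- CLASS_KB_RANGES[[cls]]
      len_bp <- stats::runif(1, rng[1], rng[2]) * 1000
      s <- max(1, profile$center_bp[h] - len_bp / 2)
      e <- min(config$chrom_lengths[profile$chrom[h]], s + len_bp)
      same <- segs$chromosome == profile$chrom[h]
      if (!any(same & segs$start_bp <= e & segs$end_bp >= s)) {
        segs <- rbind(segs, data.frame(chromosome = profile$chrom[h],
                                       start_bp = s, end_bp = e))
        break
      }
      if (attempt == retry_cap) stop_rohcnn("hotspot overlap retry cap hit")
    }
  }
  segs
}

#' Simulate one individual's genotypes
#'
#' Planted segments are drawn from the class profile plus the shared
#' profile; calls inside them are homozygous apart from residual
#' heterozygosity at `within_roh_het_rate`; background calls are
#' heterozygous at `background_het_rate`; missingness is applied uniformly.
#' Homozygous calls are HOM_REF with probability 0.7 (a mild allele
#' frequency asymmetry keeping the major-allele coding stable on write/read).
#'
#' @param class_idx 1 or 2, the sample's class.
#' @param snpmap Variant map from [simulate_snp_map()].
#' @param config A [sim_config()] object.
#' @return List with `calls` (integer vector over variants) and `truth`
#'   (data.frame of planted segments: chromosome, start_bp, end_bp).
#' @export
simulate_individual <- function(class_idx, snpmap, config) {
  planted <- rbind(draw_segments(config$profiles[[class_idx]], config),
                   draw_segments(config$shared_profile, config))
  # shared segments may collide with class segments; drop shared on overlap
  if (nrow(planted) > 1) {
    keep <- rep(TRUE, nrow(planted))
    for (i in seq_len(nrow(planted))[-1]) {
      prior <- planted[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], ,
                                                        drop = FALSE]
      hit <- prior$chromosome == planted$chromosome[i] &
        prior$start_bp <= planted$end_bp[i] &
        prior$end_bp >= planted$start_bp[i]
      if (any(hit)) keep[i] <- FALSE
    }
    planted <- planted[keep, , drop = FALSE]
  }
  n <- nrow(snpmap)
  in_roh <- rep(FALSE, n)
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      in_roh <- in_roh | (snpmap$chromosome == planted$chromosome[i] &
                            snpmap$position_bp >= planted$start_bp[i] &
                            snpmap$position_bp <= planted$end_bp[i])
    }
  }
  het_p <- ifelse(in_roh, config$within_roh_het_rate,
                  config$background_het_rate)
  u <- stats::runif(n)
  calls <- ifelse(u < het_p, 1L,
                  ifelse(stats::runif(n) < 0.7, 0L, 2L))
  calls[stats::runif(n) < config$missing_rate] <- NA_integer_
  list(calls = as.integer(calls), truth = planted)
}

#' Simulate a labelled genotype dataset with ROH truth
#'
#' @param config A [sim_config()] object.
#' @return List with `genotypes` (samples x variants integer matrix),
#'   `snpmap`, `labels` (data.frame sample_id, label) and `truth`
#'   (data.frame of planted segments with sample_id and length_class).
#' @export
simulate_dataset <- function(config) {
  snpmap <- simulate_snp_map(config)
  set.seed(derive_seeds(config$seed, "individuals"))
  n_tot <- sum(config$n_per_class)
  class_idx <- rep(1:2, config$n_per_class)
  ids <- sprintf("%s_%03d", config$class_names[class_idx],
                 unlist(lapply(config$n_per_class, seq_len)))
  gm <- matrix(NA_integer_, n_tot, nrow(snpmap),
               dimnames = list(ids, snpmap$variant_id))
  truth <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    ind <- simulate_individual(class_idx[i], snpmap, config)
    gm[i, ] <- ind$calls
    if (nrow(ind$truth)) {
      tr <- ind$truth
      tr$sample_id <- ids[i]
      truth[[i]] <- tr
    }
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(chromosome = integer(), start_bp = numeric(),
                        end_bp = numeric(), sample_id = character())
  }
  truth$length_kb <- (truth$end_bp - truth$start_bp) / 1000
  truth$length_class <- if (nrow(truth)) classify_length(truth$length_kb) else character()
  list(genotypes = gm, snpmap = snpmap,
       labels = data.frame(sample_id = ids,
                           label = config$class_names[class_idx],
                           stringsAsFactors = FALSE),
       truth = truth[, c("sample_id", "chromosome", "start_bp", "end_bp",
                         "length_kb", "length_class")])
}

#' Preset simulator configurations
#'
#' `breed-like`: a strong, fully penetrant class signal analogous to
#' between-breed ROH divergence — the two classes carry disjoint hotspot
#' sets (occurrence probability 1) that also differ in number and in
#' length-class mixture, one breed bearing fewer, mid-length runs and the
#' other more numerous, longer runs. Breeds differ both in where their ROH
#' sit and in ROH abundance/length composition; the composition contrast
#' is what a translation-invariant classifier (global average pooling)
#' can exploit, so the preset encodes both.
#' `trait-like`: shared hotspot locations with a moderate occurrence-
#' probability gap, analogous to a within-breed binary trait.
#' `null`: identical profiles for both classes (shared hotspots only), so
#' class labels are exchangeable.
#'
#' @param preset One of "breed-like", "trait-like", "null".
#' @param n_per_class Samples per class (default 60 each).
#' @param seed Integer seed.
#' @return A [sim_config()] object.
#' @export
sim_preset <- function(preset = c("breed-like", "trait-like", "null"),
                       n_per_class = c(60L, 60L), seed = 1L) {
  preset <- match.arg(preset)
  lens <- default_chrom_lengths()
  long_mix <- c(0, 0, 0.2, 0.2, 0.4, 0.2)   # 4 Mb and up
  mid_mix <- c(0.1, 0.3, 0.3, 0.2, 0.1, 0)
  shared <- roh_profile(chrom = c(2L, 9L, 14L),
                        center_bp = 0.5 * lens[c(2, 9, 14)],
                        prob = rep(0.5, 3), class_mix = mid_mix)
  if (preset == "breed-like") {
    short_mix <- c(0.3, 0.6, 0.1, 0, 0, 0)   # few, mostly 1-4 Mb runs
    pa <- roh_profile(chrom = c(1L, 3L, 5L),
                      center_bp = 0.4 * lens[c(1, 3, 5)],
                      prob = rep(1, 3), class_mix = short_mix)
    pb <- roh_profile(chrom = c(1L, 4L, 6L, 8L, 13L, 16L),
                      center_bp = c(0.6, 0.6, 0.6, 0.6, 0.35, 0.5) *
                        lens[c(1, 4, 6, 8, 13, 16)],
                      prob = rep(1, 6), class_mix = long_mix)
    profiles <- list(pa, pb)
  } else if (preset == "trait-like") {
    pa <- roh_profile(chrom = c(1L, 6L), center_bp = 0.4 * lens[c(1, 6)],
                      prob = c(0.25, 0.25), class_mix = mid_mix)
    pb <- roh_profile(chrom = c(1L, 6L), center_bp = 0.4 * lens[c(1, 6)],
                      prob = c(0.85, 0.85), class_mix = mid_mix)
    profiles <- list(pa, pb)
  } else {
    profiles <- list(empty_profile(), empty_profile())
  }
  classes <- switch(preset, "breed-like" = c("LW", "DR"),
                    "trait-like" = c("LW1", "LW2"), "null" = c("N1", "N2"))
  sim_config(n_per_class = n_per_class, class_names = classes,
             profiles = profiles, shared_profile = shared, seed = seed)
}
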