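# Sliding-window ROH detection, length classification and summaries.

#' ROH detection parameters
#'
#' Container for the sliding-window scan parameters. Defaults follow the
#' standard genotype-analysis tool's homozygosity scan: a run must contain at
#' least `homozyg_snp` SNPs, span at least `homozyg_kb` kb, average at most
#' `homozyg_density` kb per SNP, never jump more than `homozyg_gap` kb
#' between consecutive SNPs, and contain at most `homozyg_het` heterozygous
#' calls. Window eligibility uses windows of `window_snp` SNPs tolerating
#' `window_het` heterozygous and `window_missing` missing calls; a SNP is
#' eligible when at least `window_threshold` of the windows covering it are
#' homozygous.
#'
#' @param homozyg_snp Minimum SNPs per segment (default 50).
#' @param homozyg_kb Minimum segment length in kb (default 1000).
#' @param homozyg_density Maximum kb per SNP within a segment (default 100).
#' @param homozyg_gap Maximum inter-SNP gap in kb (default 500).
#' @param window_snp Sliding-window size in SNPs (default 50).
#' @param window_het Maximum heterozygous calls per window (default 1).
#' @param homozyg_het Maximum heterozygous calls per segment (default 1).
#' @param window_missing Maximum missing calls per window (default 5).
#' @param window_threshold Minimum fraction of homozygous windows covering a
#'   SNP for it to be flagged, inclusive (default 0.05).
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(homozyg_snp = 50L, homozyg_kb = 1000,
                       homozyg_density = 100, homozyg_gap = 500,
                       window_snp = 50L, window_het = 1L,
                       homozyg_het = 1L, window_missing = 5L,
                       window_threshold = 0.05) {
  p <- list(homozyg_snp = as.integer(homozyg_snp), homozyg_kb = homozyg_kb,
            homozyg_density = homozyg_density, homozyg_gap = homozyg_gap,
            window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            homozyg_het = as.integer(homozyg_het),
            window_missing = as.integer(window_missing),
            window_threshold = window_threshold)
  if (any(vapply(p, function(x) x < 0, logical(1)))) {
    stop_rohcnn("roh_params must be nonnegative")
  }
  if (p$window_snp < 1L) stop_rohcnn("window_snp must be >= 1")
  if (p$window_threshold <= 0 || p$window_threshold > 1) {
    stop_rohcnn("window_threshold must be in (0, 1]")
  }
  structure(p, class = "roh_params")
}

#' Per-SNP window eligibility for the homozygosity scan
#'
#' Slides a window of `window_snp` consecutive SNPs along one sample's calls
#' on one chromosome. A window is homozygous iff it contains at most
#' `window_het` heterozygous and at most `window_missing` missing calls.
#' Each SNP's hit ratio is the fraction of windows covering it that are
#' homozygous; the SNP is flagged when the ratio reaches `window_threshold`
#' (inclusive). If the chromosome holds fewer SNPs than the window size, a
#' single window covering all of them is used.
#'
#' @param calls Integer call vector (one sample, one chromosome, ordered by
#'   position; see [CALL_CODES]).
#' @param params An [roh_params()] object.
#' @return Logical vector of per-SNP flags, same length as `calls`.
#' @export
compute_window_eligibility <- function(calls, params = roh_params()) {
  n <- length(calls)
  if (n == 0) stop_rohcnn("empty call vector")
  w <- min(params$window_snp, n)
  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  hom_win <- run_sum(het, w) <= params$window_het &
    run_sum(mis, w) <= params$window_missing
  # windows covering SNP i start in [max(1, i-w+1), min(i, n-w+1)]
  cs <- c(0, cumsum(hom_win))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n - w + 1L)
  n_hom <- cs[hi + 1L] - cs[lo]
  ratio <- n_hom / (hi - lo + 1L)
  ratio >= params$window_threshold
}

roh_empty <- function() {
  data.frame(sample_id = character(), chromosome = integer(),
             start_bp = integer(), end_bp = integer(), n_snps = integer(),
             length_kb = numeric(), het_count = integer(),
             length_class = character(), stringsAsFactors = FALSE)
}

#' Call ROH segments from flagged SNPs on one chromosome
#'
#' Candidate stretches are maximal runs of flagged SNPs. Each candidate is
#' split wherever the distance between consecutive SNPs exceeds
#' `homozyg_gap` kb. Within a candidate, if heterozygous calls exceed
#' `homozyg_het`, the stretch is split at the leftmost excess heterozygous
#' SNP (which is dropped), repeatedly, so every emitted piece carries at
#' most `homozyg_het` heterozygous calls. Pieces are kept when they satisfy
#' the SNP-count, length and density constraints. Missing calls inside a
#' segment are permitted and not counted as heterozygous.
#'
#' @param flags Logical per-SNP eligibility flags.
#' @param calls Integer call vector aligned with `flags`.
#' @param positions Integer bp positions aligned with `flags` (ascending).
#' @param chromosome Chromosome label for the emitted segments.
#' @param sample_id Sample label for the emitted segments.
#' @param params An [roh_params()] object.
#' @return data.frame of segments (columns `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_kb`, `het_count`,
#'   `length_class`), possibly empty.
#' @export
call_roh_segments <- function(flags, calls, positions, chromosome = 1L,
                              sample_id = "S1", params = roh_params()) {
  n <- length(flags)
  stopifnot(length(calls) == n, length(positions) == n)
  if (n == 0) return(roh_empty())

  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- cbind(starts[r$values], ends[r$values])
  if (!length(cand)) return(roh_empty())

  pieces <- list()
  for (k in seq_len(nrow(cand))) {
    s <- cand[k, 1]; e <- cand[k, 2]
    # split at gaps > homozyg_gap kb
    if (e > s) {
      gaps <- diff(positions[s:e]) / 1000
      cut_after <- which(gaps > params$homozyg_gap)
      bounds <- c(s - 1L, s - 1L + cut_after, e)
    } else {
      bounds <- c(s - 1L, e)
    }
    for (b in seq_len(length(bounds) - 1L)) {
      ps <- bounds[b] + 1L; pe <- bounds[b + 1L]
      # split at leftmost excess heterozygous SNPs
      cur <- ps
      repeat {
        if (cur > pe) break
        idx <- cur:pe
        het_pos <- idx[!is.na(calls[idx]) & calls[idx] == 1L]
        if (length(het_pos) <= params$homozyg_het) {
          pieces[[length(pieces) + 1L]] <- c(cur, pe)
          break
        }
        split_at <- het_pos[params$homozyg_het + 1L]
        if (split_at > cur) {
          pieces[[length(pieces) + 1L]] <- c(cur, split_at - 1L)
        }
        cur <- split_at + 1L
      }
    }
  }
  if (!length(pieces)) return(roh_empty())

  segs <- lapply(pieces, function(p) {
    s <- p[1]; e <- p[2]
    n_snps <- e - s + 1L
    length_kb <- (positions[e] - positions[s]) / 1000
    if (n_snps < params$homozyg_snp) return(NULL)
    if (length_kb < params$homozyg_kb) return(NULL)
    if (length_kb / n_snps > params$homozyg_density) return(NULL)
    het_count <- sum(!is.na(calls[s:e]) & calls[s:e] == 1L)
    data.frame(sample_id = sample_id, chromosome = as.integer(chromosome),
               start_bp = positions[s], end_bp = positions[e],
               n_snps = n_snps, length_kb = length_kb,
               het_count = het_count,
               length_class = classify_length(length_kb),
               stringsAsFactors = FALSE)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(roh_empty())
  do.call(rbind, segs)
}

#' Detect runs of homozygosity for all samples
#'
#' Runs the sliding-window scan ([compute_window_eligibility()]) and segment
#' calling ([call_roh_segments()]) per sample and chromosome, concatenating
#' results in deterministic (sample, chromosome, start) order.
#'
#' @param genotypes Integer call matrix (samples x variants), QC'd.
#' @param snpmap Variant map aligned with the columns.
#' @param params An [roh_params()] object.
#' @return data.frame of ROH segments (see [call_roh_segments()]).
#' @export
detect_roh <- function(genotypes, snpmap, params = roh_params()) {
  stopifnot(ncol(genotypes) == nrow(snpmap))
  ids <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  chroms <- sort(unique(snpmap$chromosome))
  chrom_cols <- lapply(chroms, function(ch) which(snpmap$chromosome == ch))
  out <- vector("list", nrow(genotypes) * length(chroms))
  k <- 0L
  for (i in seq_len(nrow(genotypes))) {
    for (ci in seq_along(chroms)) {
      cols <- chrom_cols[[ci]]
      calls <- genotypes[i, cols]
      flags <- compute_window_eligibility(calls, params)
      k <- k + 1L
      out[[k]] <- call_roh_segments(flags, calls,
                                    snpmap$position_bp[cols],
                                    chromosome = chroms[ci],
                                    sample_id = ids[i], params = params)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(roh_empty())
  res <- res[order(match(res$sample_id, ids), res$chromosome, res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify an ROH segment by length
#'
#' Bins are left-closed/right-open in Mb: \[0,2) \[2,4) \[4,6) \[6,8)
#' \[8,16) \[16,Inf), labelled `LT2`, `C2_4`, `C4_6`, `C6_8`, `C8_16`,
#' `GT16`.
#'
#' @param length_kb Numeric vector of segment lengths in kb (> 0).
#' @return Character vector of length-class labels.
#' @export
classify_length <- function(length_kb) {
  if (any(length_kb <= 0)) stop_rohcnn("length_kb must be positive")
  mb <- length_kb / 1000
  LENGTH_CLASSES[findInterval(mb, c(0, 2, 4, 6, 8, 16))]
}

#' Summarize ROH segments per length class and per sample
#'
#' @param segments ROH segment data.frame.
#' @param samples Character vector of cohort sample IDs (denominator for the
#'   per-animal mean; samples with zero segments count).
#' @return List with `class_counts` (named integer vector over the six
#'   classes), `total_segments`, `n_samples`, `mean_per_sample_int` (integer
#'   part of total/n) and `mean_per_sample` (exact fraction).
#' @export
summarize_roh <- function(segments, samples) {
  n <- length(samples)
  if (n == 0) stop_rohcnn("zero samples")
  cc <- table(factor(segments$length_class, levels = LENGTH_CLASSES))
  total <- nrow(segments)
  list(class_counts = stats::setNames(as.integer(cc), LENGTH_CLASSES),
       total_segments = total, n_samples = n,
       mean_per_sample_int = total %/% n,
       mean_per_sample = total / n)
}

#' Write ROH segments as a headered TSV
#'
#' Mirrors the layout of the standard tool's `.hom` output: one row per
#' segment with sample, chromosome, coordinates, SNP count, length and
#' length class.
#'
#' @param segments ROH segment data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_roh <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read ROH segments written by [write_roh()]
#'
#' @param path Path to the TSV.
#' @return ROH segment data.frame.
#' @export
read_roh <- function(path) {
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  seg$sample_id <- as.character(seg$sample_id)
  seg
}
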