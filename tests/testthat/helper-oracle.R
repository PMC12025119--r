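# Independent, deliberately naive re-derivation of the ROH scan used as a
# test oracle. Everything is explicit loops and direct counting -- no
# cumulative-sum tricks, no rle -- so it shares no code path with the
# package implementation.

oracle_flags <- function(calls, p) {
  n <- length(calls)
  w <- min(p$window_snp, n)
  is_hom_window <- function(j) {
    idx <- j:(j + w - 1)
    het <- 0; mis <- 0
    for (i in idx) {
      if (is.na(calls[i])) mis <- mis + 1
      else if (calls[i] == 1L) het <- het + 1
    }
    het <= p$window_het && mis <= p$window_missing
  }
  win_hom <- vapply(seq_len(n - w + 1), is_hom_window, logical(1))
  flags <- logical(n)
  for (i in seq_len(n)) {
    covering <- which(seq_len(n - w + 1) <= i & seq_len(n - w + 1) + w - 1 >= i)
    flags[i] <- mean(win_hom[covering]) >= p$window_threshold
  }
  flags
}

oracle_roh <- function(calls, positions, p, chromosome = 1L,
                       sample_id = "S1") {
  flags <- oracle_flags(calls, p)
  n <- length(calls)
  # maximal flagged runs by explicit scan
  runs <- list(); s <- NA
  for (i in seq_len(n)) {
    if (flags[i] && is.na(s)) s <- i
    if (!is.na(s) && (!flags[i] || i == n)) {
      e <- if (flags[i]) i else i - 1
      runs[[length(runs) + 1]] <- c(s, e)
      s <- NA
    }
  }
  pieces <- list()
  for (r in runs) {
    # split at oversized gaps
    sub <- list(); s <- r[1]
    for (i in r[1]:r[2]) {
      if (i > s && (positions[i] - positions[i - 1]) / 1000 > p$homozyg_gap) {
        sub[[length(sub) + 1]] <- c(s, i - 1); s <- i
      }
    }
    sub[[length(sub) + 1]] <- c(s, r[2])
    # split at the leftmost excess heterozygous SNP, repeatedly
    for (q in sub) {
      cur <- q[1]
      while (cur <= q[2]) {
        hets <- integer(0)
        for (i in cur:q[2]) {
          if (!is.na(calls[i]) && calls[i] == 1L) hets <- c(hets, i)
        }
        if (length(hets) <= p$homozyg_het) {
          pieces[[length(pieces) + 1]] <- c(cur, q[2]); break
        }
        cut <- hets[p$homozyg_het + 1]
        if (cut > cur) pieces[[length(pieces) + 1]] <- c(cur, cut - 1)
        cur <- cut + 1
      }
    }
  }
  out <- NULL
  for (q in pieces) {
    ns <- q[2] - q[1] + 1
    kb <- (positions[q[2]] - positions[q[1]]) / 1000
    het <- 0
    for (i in q[1]:q[2]) if (!is.na(calls[i]) && calls[i] == 1L) het <- het + 1
    if (ns >= p$homozyg_snp && kb >= p$homozyg_kb &&
        kb / ns <= p$homozyg_density) {
      out <- rbind(out, data.frame(
        sample_id = sample_id, chromosome = chromosome,
        start_bp = positions[q[1]], end_bp = positions[q[2]],
        n_snps = ns, length_kb = kb, het_count = het,
        length_class = classify_length(kb), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) rohcnn:::roh_empty() else out
}

# Random small one-chromosome instance with blocks of low/high
# heterozygosity, for the detector-vs-oracle sweep.
random_roh_instance <- function(n_max = 200) {
  n <- sample(20:n_max, 1)
  # mostly array-like 5-80 kb gaps, occasionally a gap-rule-triggering jump
  gaps <- ifelse(runif(n) < 0.9, sample(5:80, n, replace = TRUE),
                 sample(400:700, n, replace = TRUE))
  positions <- cumsum(gaps * 1000)
  calls <- integer(n)
  i <- 1
  while (i <= n) {
    len <- min(sample(10:80, 1), n - i + 1)
    het_rate <- sample(c(0, 0.01, 0.05, 0.3), 1)
    block <- ifelse(runif(len) < het_rate, 1L,
                    sample(c(0L, 2L), len, replace = TRUE))
    block[runif(len) < 0.02] <- NA_integer_
    calls[i:(i + len - 1)] <- block
    i <- i + len
  }
  list(calls = calls, positions = as.integer(positions))
}
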