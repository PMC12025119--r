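# PED/MAP genotype input, call coding, and missingness QC.

#' Read PLINK text PED/MAP genotypes
#'
#' Parses a PLINK text fileset into a variant map and a coded genotype
#' matrix. Genotypes are coded per variant against the major allele:
#' the more frequent allele over non-missing calls is REF (ties broken
#' alphabetically), so calls become `HOM_REF` (0), `HET` (1), `HOM_ALT` (2)
#' or `NA` for "0 0". The ROH scan downstream only uses homozygous /
#' heterozygous / missing status, so the REF/ALT labelling cannot affect
#' results. Variants are re-sorted by (chromosome, position) with the call
#' columns permuted to match. Only autosomes 1..18 are retained; variants on
#' any other chromosome code are dropped with a warning.
#'
#' @param ped_path Path to the `.ped` file (6 leading columns, then two
#'   allele columns per variant, alleles in `A,C,G,T,0`).
#' @param map_path Path to the `.map` file (chromosome, variant id, cM,
#'   bp position).
#' @return A list with elements:
#'   \describe{
#'     \item{snpmap}{data.frame with columns `variant_id`, `chromosome`,
#'       `position_bp`, `ref_allele`, `alt_allele`, sorted by
#'       (chromosome, position_bp).}
#'     \item{genotypes}{integer matrix, samples x variants, coded as above,
#'       with sample IDs as rownames and variant IDs as colnames.}
#'   }
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop_rohcnn("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop_rohcnn("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines) == 0) stop_rohcnn("empty MAP file: ", map_path)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad)) {
    stop_rohcnn("malformed MAP line ", bad[1], ": expected 4 fields, got ",
                lengths(map_tok)[bad[1]])
  }
  mm <- do.call(rbind, map_tok)
  chrom <- suppressWarnings(as.integer(mm[, 1]))
  pos <- suppressWarnings(as.integer(mm[, 4]))
  if (anyNA(pos)) {
    stop_rohcnn("malformed MAP line ", which(is.na(pos))[1],
                ": non-integer position")
  }
  snpmap <- data.frame(variant_id = mm[, 2], chromosome = chrom,
                       position_bp = pos, stringsAsFactors = FALSE)
  n_var <- nrow(snpmap)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (length(ped_lines) == 0) stop_rohcnn("empty PED file: ", ped_path)
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  expect_len <- 6L + 2L * n_var
  bad <- which(lengths(ped_tok) != expect_len)
  if (length(bad)) {
    stop_rohcnn("PED line ", bad[1], " has ", lengths(ped_tok)[bad[1]],
                " fields; expected ", expect_len,
                " for ", n_var, " MAP variants")
  }
  pm <- do.call(rbind, ped_tok)
  sample_ids <- pm[, 2]
  a1 <- pm[, 6L + 2L * seq_len(n_var) - 1L, drop = FALSE]
  a2 <- pm[, 6L + 2L * seq_len(n_var), drop = FALSE]
  ok <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% ok) || !all(a2 %in% ok)) {
    bad_row <- which(rowSums(matrix(!(a1 %in% ok) | !(a2 %in% ok),
                                    nrow = nrow(a1))) > 0)[1]
    stop_rohcnn("PED line ", bad_row, ": allele outside {A,C,G,T,0}")
  }

  n_smp <- length(sample_ids)
  calls <- matrix(NA_integer_, n_smp, n_var)
  ref <- alt <- character(n_var)
  for (j in seq_len(n_var)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    alleles <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(alleles) > 2) {
      stop_rohcnn("variant ", snpmap$variant_id[j], ": more than 2 alleles")
    }
    if (length(alleles) == 0) { ref[j] <- alt[j] <- NA_character_; next }
    cnt <- table(factor(c(x1[!miss], x2[!miss]), levels = alleles))
    # major allele = REF; alphabetical tie-break (alleles already sorted)
    ref[j] <- alleles[which.max(cnt)]
    alt[j] <- if (length(alleles) == 2) setdiff(alleles, ref[j]) else NA_character_
    g <- (x1 != ref[j]) + (x2 != ref[j])
    g[miss] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  rownames(calls) <- sample_ids
  snpmap$ref_allele <- ref
  snpmap$alt_allele <- alt

  keep <- !is.na(snpmap$chromosome) & snpmap$chromosome >= 1L &
    snpmap$chromosome <= N_AUTOSOMES
  if (any(!keep)) {
    warning(sum(!keep), " variant(s) outside autosomes 1..", N_AUTOSOMES,
            " dropped")
    snpmap <- snpmap[keep, , drop = FALSE]
    calls <- calls[, keep, drop = FALSE]
  }
  ord <- order(snpmap$chromosome, snpmap$position_bp)
  snpmap <- snpmap[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  dup <- duplicated(snpmap[, c("chromosome", "position_bp")])
  if (any(dup)) {
    stop_rohcnn("duplicate (chromosome, position) in MAP at row ",
                which(dup)[1])
  }
  rownames(snpmap) <- NULL
  colnames(calls) <- snpmap$variant_id
  list(snpmap = snpmap, genotypes = calls)
}

#' Write genotypes back to PLINK text PED/MAP
#'
#' Inverse of [read_genotypes()]: re-reading the written fileset reproduces
#' the call grid exactly (REF stays the major allele, so the coding is
#' stable). Variants lacking allele letters (e.g. all-missing columns) are
#' written with placeholder alleles A/C.
#'
#' @param genotypes Integer call matrix (samples x variants).
#' @param snpmap Variant map as returned by [read_genotypes()] (the
#'   `ref_allele`/`alt_allele` columns are used when present).
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_genotypes <- function(genotypes, snpmap, prefix) {
  stopifnot(ncol(genotypes) == nrow(snpmap))
  ref <- snpmap$ref_allele %||% rep("A", nrow(snpmap))
  alt <- snpmap$alt_allele %||% rep("C", nrow(snpmap))
  ref[is.na(ref)] <- "A"
  alt[is.na(alt)] <- "C"
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(snpmap$chromosome, snpmap$variant_id, 0L, snpmap$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  n_var <- nrow(snpmap)
  ids <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    writeLines(paste(c(ids[i], ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(x1, x2))), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a sample label file
#'
#' Two-column headered TSV with columns `sample_id` and `label`.
#'
#' @param path Path to the TSV.
#' @return data.frame with character columns `sample_id`, `label`.
#' @export
read_labels <- function(path) {
  lab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(lab))) {
    stop_rohcnn("label file must have columns sample_id, label")
  }
  lab[, c("sample_id", "label")]
}

#' Missingness quality control (mind then geno)
#'
#' Removes samples whose missing-call fraction exceeds `mind`, then removes
#' variants whose missing fraction, recomputed over the retained samples,
#' exceeds `geno`. Thresholds are strict ("more than"): a fraction exactly
#' equal to the threshold is retained. The sample-first order and the
#' recomputation mirror the behaviour of the standard genotype-QC tool;
#' either filter can be disabled by setting its threshold to 1.
#'
#' @param genotypes Integer call matrix (samples x variants).
#' @param snpmap Variant map data.frame aligned with the columns.
#' @param mind Maximum tolerated per-sample missing fraction (default 0.1).
#' @param geno Maximum tolerated per-variant missing fraction (default 0.1).
#' @return List with `genotypes`, `snpmap`, and `report` (data.frame of
#'   removed samples/variants with their missing fractions).
#' @export
qc_filter <- function(genotypes, snpmap, mind = 0.1, geno = 0.1) {
  stopifnot(mind >= 0, mind <= 1, geno >= 0, geno <= 1,
            ncol(genotypes) == nrow(snpmap))
  miss <- is.na(genotypes)
  smp_frac <- rowMeans(miss)
  drop_smp <- smp_frac > mind
  report <- data.frame(type = character(), id = character(),
                       missing_fraction = numeric(),
                       stringsAsFactors = FALSE)
  if (any(drop_smp)) {
    report <- rbind(report, data.frame(
      type = "sample",
      id = rownames(genotypes)[drop_smp] %||% as.character(which(drop_smp)),
      missing_fraction = smp_frac[drop_smp]))
  }
  gm <- genotypes[!drop_smp, , drop = FALSE]
  if (nrow(gm) == 0) stop_rohcnn("empty cohort: all samples removed by mind filter")
  var_frac <- colMeans(is.na(gm))
  drop_var <- var_frac > geno
  if (any(drop_var)) {
    report <- rbind(report, data.frame(
      type = "variant", id = snpmap$variant_id[drop_var],
      missing_fraction = var_frac[drop_var]))
  }
  list(genotypes = gm[, !drop_var, drop = FALSE],
       snpmap = {
         sm <- snpmap[!drop_var, , drop = FALSE]; rownames(sm) <- NULL; sm
       },
       report = report)
}
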