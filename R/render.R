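# Per-individual ROH map rendering: 18 chromosome rows, segments drawn as
# rectangles coloured by length class, shared genome-wide x-scale.

#' Default length-class palette
#'
#' Concrete RGB triplets for the six length classes: green (<2 Mb), red
#' (2-4), blue (4-6), turquoise (6-8), orange-yellow (8-16), gray (>16 Mb).
#'
#' @return Named list of integer RGB triplets (0..255).
#' @export
default_palette <- function() {
  list(LT2 = c(0L, 128L, 0L), C2_4 = c(255L, 0L, 0L),
       C4_6 = c(0L, 0L, 255L), C6_8 = c(64L, 224L, 208L),
       C8_16 = c(255L, 165L, 0L), GT16 = c(128L, 128L, 128L))
}

#' Rendering configuration
#'
#' @param width_px,height_px Image size in pixels (default 512 x 512).
#' @param palette Named list mapping each length class to an RGB triplet;
#'   colours must be distinct.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp);
#'   defaults to the simulator's pig-like lengths. When rendering detected
#'   segments from real data, pass the observed maxima via
#'   [chrom_lengths_from_map()].
#' @param band_fill_fraction Fraction of each chromosome row band occupied
#'   by the segment bar (default 0.6, vertically centred).
#' @param background Background RGB triplet (default white).
#' @param output_format "png" (lossless, default) or "jpeg" (quality 95).
#' @return An object of class `render_config`.
#' @export
render_config <- function(width_px = 512L, height_px = 512L,
                          palette = default_palette(),
                          chrom_lengths = default_chrom_lengths(),
                          band_fill_fraction = 0.6,
                          background = c(255L, 255L, 255L),
                          output_format = c("png", "jpeg")) {
  output_format <- match.arg(output_format)
  stopifnot(width_px >= N_AUTOSOMES, height_px >= N_AUTOSOMES,
            all(LENGTH_CLASSES %in% names(palette)),
            band_fill_fraction > 0, band_fill_fraction <= 1,
            all(chrom_lengths > 0))
  cols <- vapply(palette[LENGTH_CLASSES], paste, collapse = ",",
                 FUN.VALUE = "")
  if (anyDuplicated(cols)) stop_rohcnn("palette colours must be distinct")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), palette = palette,
                 chrom_lengths = chrom_lengths,
                 band_fill_fraction = band_fill_fraction,
                 background = as.integer(background),
                 output_format = output_format),
            class = "render_config")
}

#' Chromosome lengths inferred from a SNP map
#'
#' @param snpmap Variant map data.frame.
#' @return Named numeric vector: maximum observed position per chromosome.
#' @export
chrom_lengths_from_map <- function(snpmap) {
  tapply(snpmap$position_bp, snpmap$chromosome, max)
}

band_geometry <- function(config) {
  band_h <- config$height_px %/% N_AUTOSOMES
  bar_h <- max(1L, round(config$band_fill_fraction * band_h))
  off <- (band_h - bar_h) %/% 2L
  list(band_h = band_h, bar_h = bar_h, off = off)
}

bp_to_px <- function(bp, config) {
  # shared genome-wide x-scale: the longest chromosome spans the full width
  as.integer(round(bp / max(config$chrom_lengths) *
                     (config$width_px - 1L))) + 1L
}

#' Render one individual's ROH map
#'
#' Chromosome 1 occupies the top row band through chromosome 18 at the
#' bottom; no labels or axes are drawn. All chromosomes share one x-scale
#' (the longest chromosome spans the full width). Each segment becomes a
#' filled rectangle in its length-class colour, at least 1 px wide.
#' Rendering is a pure function of (segments, config).
#'
#' @param segments ROH segments of a single sample (data.frame as returned
#'   by [detect_roh()]); may be empty.
#' @param config A [render_config()] object.
#' @return Integer array of dim (height, width, 3), values 0..255, with the
#'   sample ID (if any) in attribute `sample_id`.
#' @export
render_roh_map <- function(segments, config = render_config()) {
  if (nrow(segments) > 0) {
    if (length(unique(segments$sample_id)) > 1) {
      stop_rohcnn("segments from more than one sample")
    }
    if (!all(as.character(segments$chromosome) %in%
             names(config$chrom_lengths))) {
      stop_rohcnn("segment on a chromosome missing from chrom_lengths")
    }
    for (ch in unique(segments$chromosome)) {
      s <- segments[segments$chromosome == ch, , drop = FALSE]
      if (nrow(s) > 1) {
        s <- s[order(s$start_bp), , drop = FALSE]
        if (any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
          stop_rohcnn("overlapping segments on chromosome ", ch)
        }
      }
    }
  }
  img <- array(0L, c(config$height_px, config$width_px, 3L))
  for (k in 1:3) img[, , k] <- config$background[k]
  geo <- band_geometry(config)
  for (i in seq_len(nrow(segments))) {
    ch <- as.integer(segments$chromosome[i])
    rows <- ((ch - 1L) * geo$band_h + geo$off + 1L):
      ((ch - 1L) * geo$band_h + geo$off + geo$bar_h)
    x1 <- bp_to_px(segments$start_bp[i], config)
    x2 <- max(bp_to_px(segments$end_bp[i], config), x1)  # min width 1 px
    col <- config$palette[[segments$length_class[i]]]
    for (k in 1:3) img[rows, x1:x2, k] <- col[k]
  }
  attr(img, "sample_id") <- if (nrow(segments)) segments$sample_id[1] else NA_character_
  img
}

#' Write an ROH map image to disk
#'
#' PNG is lossless (pixels round-trip exactly); JPEG is written at quality
#' 95 for fidelity with the original map export.
#'
#' @param img Integer array (H, W, 3) from [render_roh_map()].
#' @param path Output path.
#' @param config A [render_config()] (chooses the format).
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, config = render_config()) {
  if (config$output_format == "png") {
    png::writePNG(img / 255, path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_rohcnn("JPEG output requires the EBImage package")
    }
    eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
    EBImage::writeImage(eb, path, type = "jpeg", quality = 95)
  }
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path Path to a PNG or JPEG file.
#' @return Integer array (H, W, 3), values 0..255.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_rohcnn("JPEG input requires the EBImage package")
    }
    x <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim(x))
}

#' Per-class pixel counts by nearest palette colour
#'
#' Assigns each pixel to the nearest colour among the palette entries and
#' the background (Euclidean distance in RGB), and counts pixels per class.
#' Intended as a rendering test oracle; counts over classes plus background
#' sum to width x height.
#'
#' @param img Integer array (H, W, 3).
#' @param config A [render_config()] supplying palette and background.
#' @return Named integer vector over the six classes plus "background".
#' @export
color_histogram <- function(img, config = render_config()) {
  cols <- c(config$palette[LENGTH_CLASSES],
            list(background = config$background))
  pal <- do.call(rbind, cols)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  d2 <- outer(rowSums(px^2), rowSums(pal^2), "+") - 2 * px %*% t(pal)
  idx <- max.col(-d2, ties.method = "first")
  stats::setNames(tabulate(idx, nbins = nrow(pal)), names(cols))
}

#' Render ROH maps for a cohort and write a manifest
#'
#' One image per sample, named `<sample_id>.<ext>`, plus a manifest TSV
#' (`sample_id`, `path`, `label`) consumed by the classifier. Samples with
#' no segments get an all-background map.
#'
#' @param segments ROH segments for the whole cohort.
#' @param labels data.frame (`sample_id`, `label`); defines the sample set.
#' @param out_dir Output directory (created if needed).
#' @param config A [render_config()] object.
#' @return data.frame manifest, invisibly also written to
#'   `<out_dir>/manifest.tsv`.
#' @export
render_dataset <- function(segments, labels, out_dir,
                           config = render_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (config$output_format == "png") "png" else "jpg"
  paths <- file.path(out_dir, paste0(labels$sample_id, ".", ext))
  for (i in seq_len(nrow(labels))) {
    seg_i <- segments[segments$sample_id == labels$sample_id[i], ,
                      drop = FALSE]
    write_image(render_roh_map(seg_i, config), paths[i], config)
  }
  manifest <- data.frame(sample_id = labels$sample_id, path = paths,
                         label = labels$label, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Load manifest images into a 4D array
#'
#' @param manifest data.frame with columns `sample_id`, `path`.
#' @return Numeric array (H, W, 3, N) of pixel values 0..255, with sample
#'   IDs in `dimnames[[4]]`.
#' @export
load_images <- function(manifest) {
  imgs <- lapply(manifest$path, read_image)
  d <- dim(imgs[[1]])
  arr <- array(0, c(d, length(imgs)),
               dimnames = list(NULL, NULL, NULL, manifest$sample_id))
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d)) stop_rohcnn("image size mismatch")
    arr[, , , i] <- imgs[[i]]
  }
  arr
}
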