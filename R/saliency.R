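# Gradient saliency maps and the pixel -> genome back-mapping.

#' Gradient saliency map for one image
#'
#' Gradient of the target class's score with respect to the input pixels,
#' taken on the pre-sigmoid score of the target unit by default (the
#' probability can be used instead), in inference mode (batch-norm running
#' statistics, no dropout). The absolute gradient is reduced over colour
#' channels by the maximum (mean available) and optionally min-max
#' normalized to \[0, 1\].
#'
#' @param model A trained `roh_cnn`.
#' @param image Pixel array (H, W, 3), values 0..255.
#' @param target_class Class name or index (1 or 2).
#' @param on_logit Differentiate the pre-sigmoid score (default TRUE) or
#'   the sigmoid probability.
#' @param channel_reduce "max" (default) or "mean".
#' @param normalize Min-max normalize to \[0, 1\] (default TRUE).
#' @return H x W matrix of nonnegative saliency values, with attributes
#'   `target_class` and `normalized`.
#' @export
saliency_map <- function(model, image, target_class = 2L, on_logit = TRUE,
                         channel_reduce = c("max", "mean"),
                         normalize = TRUE) {
  channel_reduce <- match.arg(channel_reduce)
  if (!isTRUE(model$trained)) stop_rohcnn("model is not trained")
  if (is.character(target_class)) {
    target_class <- match(target_class, model$classes)
    if (is.na(target_class)) stop_rohcnn("unknown target class")
  }
  x <- image
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[1] == model$config$input_shape[1],
            dim(x)[2] == model$config$input_shape[2])
  fw <- nn_forward(model, x, training = FALSE, keep_cache = TRUE)
  dlog <- matrix(0, 1, 2)
  if (on_logit) {
    dlog[1, target_class] <- 1
  } else {
    p <- fw$probs[1, target_class]
    dlog[1, target_class] <- p * (1 - p)
  }
  bw <- nn_backward(model, fw$cache, dlog, training = FALSE,
                    need_input_grad = TRUE)
  g <- abs(bw$dinput[, , , 1])
  sal <- if (channel_reduce == "max") {
    pmax(g[, , 1], g[, , 2], g[, , 3])
  } else {
    (g[, , 1] + g[, , 2] + g[, , 3]) / 3
  }
  if (normalize) {
    rng <- range(sal)
    if (rng[2] > rng[1]) sal <- (sal - rng[1]) / (rng[2] - rng[1])
  }
  attr(sal, "target_class") <- model$classes[target_class] %||% target_class
  attr(sal, "normalized") <- normalize
  sal
}

#' Class-averaged saliency map
#'
#' Element-wise mean of the per-image normalized saliency maps.
#'
#' @param model A trained `roh_cnn`.
#' @param images Pixel array (H, W, 3, N), N >= 1.
#' @param target_class Class name or index.
#' @param ... Passed to [saliency_map()].
#' @return H x W matrix.
#' @export
average_saliency <- function(model, images, target_class = 2L, ...) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  if (n == 0) stop_rohcnn("empty image set")
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + saliency_map(model, images[, , , i], target_class, ...)
  }
  out <- acc / n
  attr(out, "target_class") <- attr(
    saliency_map(model, images[, , , 1], target_class, ...), "target_class")
  out
}

#' Map an image pixel back to genomic coordinates
#'
#' Inverts the renderer's row/column mapping: the pixel row selects the
#' chromosome band (or the inter-band margin), and the pixel column maps
#' to the bp interval whose rendered x-coordinate rounds to that column.
#'
#' @param y Pixel row (1-based, from the top).
#' @param x Pixel column (1-based).
#' @param config The [render_config()] used for rendering.
#' @return List with `genomic` (logical), and when genomic: `chromosome`,
#'   `start_bp`, `end_bp`.
#' @export
pixel_to_genome <- function(y, x, config = render_config()) {
  stopifnot(y >= 1, y <= config$height_px, x >= 1, x <= config$width_px)
  geo <- band_geometry(config)
  band <- (y - 1L) %/% geo$band_h + 1L
  if (band > N_AUTOSOMES) return(list(genomic = FALSE, reason = "below chromosome bands"))
  within <- (y - 1L) %% geo$band_h + 1L
  if (within <= geo$off || within > geo$off + geo$bar_h) {
    return(list(genomic = FALSE, reason = "inter-band margin"))
  }
  lmax <- max(config$chrom_lengths)
  half <- lmax / (config$width_px - 1L) / 2
  center <- (x - 1L) / (config$width_px - 1L) * lmax
  chrom_len <- config$chrom_lengths[[as.character(band)]] %||%
    config$chrom_lengths[[band]]
  start_bp <- max(1, ceiling(center - half))
  if (start_bp > chrom_len) {
    return(list(genomic = FALSE, reason = "beyond chromosome end"))
  }
  list(genomic = TRUE, chromosome = band, start_bp = start_bp,
       end_bp = floor(min(center + half, chrom_len)))
}

#' Export the most salient pixels as genomic BED intervals
#'
#' Maps the top `q` fraction of salient pixels back to the genome and
#' merges overlapping/adjacent intervals.
#'
#' @param sal H x W saliency matrix.
#' @param config The [render_config()] used for rendering.
#' @param q Fraction of pixels to keep (default 0.01).
#' @param path Optional BED output path (0-based half-open intervals).
#' @return data.frame with `chromosome`, `start_bp`, `end_bp` (1-based
#'   inclusive), sorted.
#' @export
saliency_bed <- function(sal, config = render_config(), q = 0.01,
                         path = NULL) {
  stopifnot(q > 0, q <= 1)
  thr <- stats::quantile(sal, 1 - q)
  hits <- which(sal >= thr, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    g <- pixel_to_genome(hits[i, 1], hits[i, 2], config)
    if (isTRUE(g$genomic)) {
      data.frame(chromosome = g$chromosome, start_bp = g$start_bp,
                 end_bp = g$end_bp)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(chromosome = integer(), start_bp = numeric(),
                      end_bp = numeric())
  } else {
    df <- unique(do.call(rbind, rows))
    if (requireNamespace("GenomicRanges", quietly = TRUE)) {
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        as.character(df$chromosome),
        IRanges::IRanges(df$start_bp, df$end_bp)))
      out <- data.frame(
        chromosome = as.integer(as.character(GenomicRanges::seqnames(gr))),
        start_bp = GenomicRanges::start(gr), end_bp = GenomicRanges::end(gr))
    } else {
      df <- df[order(df$chromosome, df$start_bp), , drop = FALSE]
      merged <- list()
      for (i in seq_len(nrow(df))) {
        m <- length(merged)
        if (m > 0 && merged[[m]]$chromosome == df$chromosome[i] &&
            df$start_bp[i] <= merged[[m]]$end_bp + 1) {
          merged[[m]]$end_bp <- max(merged[[m]]$end_bp, df$end_bp[i])
        } else {
          merged[[m + 1]] <- df[i, ]
        }
      }
      out <- do.call(rbind, merged)
    }
    out <- out[order(out$chromosome, out$start_bp), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(
      data.frame(out$chromosome, out$start_bp - 1L, out$end_bp),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Write a saliency map as a grayscale or overlay PNG
#'
#' @param sal H x W saliency matrix (min-max scaled for display).
#' @param path Output path.
#' @param overlay_on Optional background image (H, W, 3) to blend with.
#' @param alpha Overlay opacity (default 0.6).
#' @return Invisibly, `path`.
#' @export
write_saliency_png <- function(sal, path, overlay_on = NULL, alpha = 0.6) {
  rng <- range(sal)
  s <- if (rng[2] > rng[1]) (sal - rng[1]) / (rng[2] - rng[1]) else sal * 0
  if (is.null(overlay_on)) {
    png::writePNG(s, path)
  } else {
    base <- overlay_on / 255
    heat <- array(0, dim(base))
    heat[, , 1] <- s
    png::writePNG((1 - alpha) * base + alpha * heat, path)
  }
  invisible(path)
}
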