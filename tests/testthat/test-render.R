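seg_row <- function(sample_id, chrom, start, end, class = NULL) {
  kb <- (end - start) / 1000
  data.frame(sample_id = sample_id, chromosome = chrom, start_bp = start,
             end_bp = end, n_snps = 50L, length_kb = kb, het_count = 0L,
             length_class = class %||% classify_length(kb),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("an empty segment list renders pure background", {
  rc <- render_config(width_px = 64L, height_px = 64L)
  img <- render_roh_map(rohcnn:::roh_empty(), rc)
  expect_equal(dim(img), c(64L, 64L, 3L))
  expect_true(all(img[, , 1] == 255 & img[, , 2] == 255 & img[, , 3] == 255))
  h <- color_histogram(img, rc)
  expect_equal(sum(h), 64L * 64L)
  expect_true(all(h[LENGTH_CLASSES] == 0))
})

test_that("a whole-chromosome GT16 segment paints row 1 gray only", {
  lens <- default_chrom_lengths()
  rc <- render_config(width_px = 128L, height_px = 128L,
                      chrom_lengths = lens)
  seg <- seg_row("s", 1L, 1, lens[[1]])  # chromosome 1 is the longest
  img <- render_roh_map(seg, rc)
  geo <- rohcnn:::band_geometry(rc)
  bar_rows <- geo$off + seq_len(geo$bar_h)
  gray <- default_palette()$GT16
  for (k in 1:3) {
    expect_true(all(img[bar_rows, , k] == gray[k]))
  }
  # all rows below band 1 untouched
  expect_true(all(img[(geo$band_h + 1):128, , 1] == 255))
})

test_that("rendering is deterministic and monotone in added segments", {
  rc <- render_config(width_px = 64L, height_px = 64L)
  s1 <- seg_row("s", 3L, 10e6, 40e6)
  s2 <- seg_row("s", 9L, 5e6, 8e6)
  expect_identical(render_roh_map(s1, rc), render_roh_map(s1, rc))
  h1 <- color_histogram(render_roh_map(s1, rc), rc)
  h12 <- color_histogram(render_roh_map(rbind(s1, s2), rc), rc)
  expect_gte(h12[[s2$length_class]], h1[[s2$length_class]])
  expect_gte(h12[[s1$length_class]], 1)
})

test_that("overlapping or unknown-chromosome segments are rejected", {
  rc <- render_config(width_px = 64L, height_px = 64L)
  bad <- rbind(seg_row("s", 2L, 10e6, 40e6), seg_row("s", 2L, 30e6, 60e6))
  expect_error(render_roh_map(bad, rc), "overlapping")
  rc2 <- render_config(width_px = 64L, height_px = 64L,
                       chrom_lengths = default_chrom_lengths()[1:18])
  mixed <- rbind(seg_row("a", 1L, 1e6, 5e6), seg_row("b", 1L, 1e6, 5e6))
  expect_error(render_roh_map(mixed, rc2), "one sample")
})

test_that("PNG round-trips exactly; JPEG stays within a small deviation", {
  d <- withr::local_tempdir()
  rc <- render_config(width_px = 128L, height_px = 128L)
  seg <- rbind(seg_row("s", 1L, 20e6, 60e6), seg_row("s", 7L, 5e6, 10e6))
  img <- render_roh_map(seg, rc)
  png_path <- file.path(d, "m.png")
  write_image(img, png_path, rc)
  expect_identical(read_image(png_path), unclass(img)[, , ],
                   ignore_attr = TRUE)

  rcj <- render_config(width_px = 128L, height_px = 128L,
                       output_format = "jpeg")
  jpg_path <- file.path(d, "m.jpg")
  write_image(img, jpg_path, rcj)
  back <- read_image(jpg_path)
  expect_equal(dim(back), dim(img))
  dev <- abs(back - img)
  # chroma subsampling shifts a handful of colour-edge pixels strongly;
  # the bulk of the image must stay within a small deviation and the
  # nearest-palette class assignment must be essentially unchanged
  expect_lte(stats::quantile(dev, 0.995), 16)
  h0 <- color_histogram(img, rcj)
  h1 <- color_histogram(back, rcj)
  expect_lte(max(abs(h1 - h0)), 0.005 * length(img[, , 1]))
})

test_that("the default 512x512 export decodes at 512x512", {
  d <- withr::local_tempdir()
  rc <- render_config()
  img <- render_roh_map(seg_row("s", 5L, 10e6, 30e6), rc)
  p <- file.path(d, "full.png")
  write_image(img, p, rc)
  expect_equal(dim(read_image(p)), c(512L, 512L, 3L))
})

test_that("class pixel counts are proportional to class segment length", {
  set.seed(404)
  lens <- default_chrom_lengths()
  rc <- render_config(width_px = 512L, height_px = 512L,
                      chrom_lengths = lens)
  for (fix in 1:20) {
    segs <- list()
    for (ch in 1:18) {
      n_seg <- sample(0:3, 1)
      if (n_seg == 0) next
      bounds <- sort(sample(seq(1e6, lens[[ch]] - 1e6, by = 5e5),
                            2 * n_seg))
      for (j in seq_len(n_seg)) {
        s <- bounds[2 * j - 1]
        e <- min(bounds[2 * j], s + runif(1, 5e6, 40e6))
        if (e - s < 5e6) next
        segs[[length(segs) + 1]] <- seg_row("s", ch, s, e)
      }
    }
    segs <- do.call(rbind, segs)
    img <- render_roh_map(segs, rc)
    h <- color_histogram(img, rc)
    len_by_class <- tapply(segs$length_kb, segs$length_class, sum)
    px <- h[names(len_by_class)]
    ratio <- (px / sum(px)) / (len_by_class / sum(len_by_class))
    expect_true(all(abs(ratio - 1) <= 0.15),
                info = paste("fixture", fix, "ratios",
                             paste(round(ratio, 3), collapse = ",")))
  }
})

test_that("palette permutation leaves pixel-count structure intact", {
  rc <- render_config(width_px = 64L, height_px = 64L)
  pal2 <- default_palette()[c(2, 1, 4, 3, 6, 5)]
  names(pal2) <- names(default_palette())
  rc2 <- render_config(width_px = 64L, height_px = 64L, palette = pal2)
  seg <- rbind(seg_row("s", 1L, 10e6, 40e6), seg_row("s", 4L, 5e6, 10e6))
  h1 <- color_histogram(render_roh_map(seg, rc), rc)
  h2 <- color_histogram(render_roh_map(seg, rc2), rc2)
  expect_equal(h1, h2)
})

test_that("render_dataset writes one image per sample plus a manifest", {
  d <- withr::local_tempdir()
  rc <- render_config(width_px = 32L, height_px = 32L)
  segs <- seg_row("a1", 1L, 10e6, 40e6)
  labels <- data.frame(sample_id = c("a1", "b1"), label = c("A", "B"))
  man <- render_dataset(segs, labels, file.path(d, "imgs"), rc)
  expect_equal(nrow(man), 2L)
  expect_true(all(file.exists(man$path)))
  arr <- load_images(man)
  expect_equal(dim(arr), c(32L, 32L, 3L, 2L))
  # sample b1 has no segments: all background
  expect_true(all(arr[, , , 2] == 255))
})
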