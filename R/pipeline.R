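# End-to-end orchestration: detect -> render -> split -> train -> evaluate
# -> (optional) cross-validation, baseline, saliency.

#' Assemble a pipeline run configuration
#'
#' Either `genotype_prefix` (a PLINK text fileset `<prefix>.ped/.map` plus
#' `labels_path`) or `sim` (a [sim_config()], genotypes are simulated) must
#' be given. The single `seed` fans out to per-stage seeds via
#' [derive_seeds()].
#'
#' @param out_dir Run directory (created).
#' @param genotype_prefix Optional PED/MAP path prefix.
#' @param labels_path Optional label TSV (required with `genotype_prefix`).
#' @param sim Optional [sim_config()] for synthetic input.
#' @param qc List with `mind`, `geno` (see [qc_filter()]).
#' @param roh An [roh_params()] object.
#' @param render A [render_config()] object (chromosome lengths default to
#'   observed per-chromosome maxima when NULL).
#' @param model A [model_config()] object.
#' @param split_ratios Train/validation/test ratios (default .7/.2/.1).
#' @param cv_k Folds for optional cross-validation (0 disables; default 0).
#' @param baseline Run the PCA+logistic baseline (default FALSE).
#' @param saliency Emit class-average saliency outputs (default FALSE).
#' @param resume Reuse `<out_dir>/images` when already present
#'   (default FALSE).
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, genotype_prefix = NULL, labels_path = NULL,
                       sim = NULL, qc = list(mind = 0.1, geno = 0.1),
                       roh = roh_params(), render = NULL,
                       model = model_config(),
                       split_ratios = c(0.7, 0.2, 0.1), cv_k = 0L,
                       baseline = FALSE, saliency = FALSE, resume = FALSE,
                       seed = 1L) {
  if (is.null(sim) && (is.null(genotype_prefix) || is.null(labels_path))) {
    stop_rohcnn("either sim or genotype_prefix + labels_path required")
  }
  structure(list(out_dir = out_dir, genotype_prefix = genotype_prefix,
                 labels_path = labels_path, sim = sim, qc = qc, roh = roh,
                 render = render, model = model,
                 split_ratios = split_ratios, cv_k = as.integer(cv_k),
                 baseline = isTRUE(baseline), saliency = isTRUE(saliency),
                 resume = isTRUE(resume), seed = as.integer(seed)),
            class = "run_config")
}

log_stage <- function(con, stage, msg, t0) {
  line <- sprintf("[%s] %s: %s (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                  stage, msg, as.numeric(Sys.time()) - t0)
  writeLines(line, con)
  message(line)
}

#' Run the full pipeline
#'
#' Executes detect -> render -> split -> train -> evaluate, plus optional
#' cross-validation, PCA+logistic baseline and saliency stages. Every
#' artifact is written under `config$out_dir` with a manifest and the
#' resolved configuration echoed for provenance. Re-running with the same
#' configuration and seed reproduces the segment table and metrics
#' exactly; with `resume = TRUE`, existing rendered images are reused and
#' downstream results are unchanged.
#'
#' @param config A [run_config()] object.
#' @return Invisible list with the run artifacts (`segments`, `manifest`,
#'   `model`, `metrics`, and any optional stage results).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  t0 <- as.numeric(Sys.time())
  seeds <- derive_seeds(config$seed, c("split", "cv", "baseline"))

  tryCatch({
    img_dir <- file.path(config$out_dir, "images")
    manifest_path <- file.path(img_dir, "manifest.tsv")
    seg_path <- file.path(config$out_dir, "segments.tsv")

    if (config$resume && file.exists(manifest_path)) {
      manifest <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
      log_stage(logf, "render", sprintf("resumed %d cached images",
                                        nrow(manifest)), t0)
      segments <- if (file.exists(seg_path)) read_roh(seg_path) else NULL
    } else {
      if (!is.null(config$sim)) {
        ds <- simulate_dataset(config$sim)
        gm <- ds$genotypes; snpmap <- ds$snpmap; labels <- ds$labels
        write_roh(ds$truth, file.path(config$out_dir, "truth.tsv"))
        log_stage(logf, "simulate",
                  sprintf("%d samples x %d variants", nrow(gm), ncol(gm)), t0)
      } else {
        geno <- read_genotypes(paste0(config$genotype_prefix, ".ped"),
                               paste0(config$genotype_prefix, ".map"))
        gm <- geno$genotypes; snpmap <- geno$snpmap
        labels <- read_labels(config$labels_path)
        labels <- labels[labels$sample_id %in% rownames(gm), , drop = FALSE]
        log_stage(logf, "load",
                  sprintf("%d samples x %d variants", nrow(gm), ncol(gm)), t0)
      }
      qcres <- qc_filter(gm, snpmap, config$qc$mind, config$qc$geno)
      labels <- labels[labels$sample_id %in% rownames(qcres$genotypes), ,
                       drop = FALSE]
      log_stage(logf, "qc", sprintf("removed %d sample(s)/variant(s)",
                                    nrow(qcres$report)), t0)

      segments <- detect_roh(qcres$genotypes, qcres$snpmap, config$roh)
      write_roh(segments, seg_path)
      log_stage(logf, "detect", sprintf("%d ROH segments", nrow(segments)), t0)

      rcfg <- config$render %||% render_config(
        width_px = config$model$input_shape[2],
        height_px = config$model$input_shape[1],
        chrom_lengths = if (!is.null(config$sim)) config$sim$chrom_lengths
        else chrom_lengths_from_map(qcres$snpmap))
      config$render <- rcfg
      manifest <- render_dataset(segments, labels, img_dir, rcfg)
      log_stage(logf, "render", sprintf("%d maps at %dx%d", nrow(manifest),
                                        rcfg$width_px, rcfg$height_px), t0)
    }

    images <- load_images(manifest)
    y <- encode_onehot(manifest$label)
    split <- stratified_split(manifest$label, config$split_ratios,
                              seed = seeds["split"])
    model <- build_cnn(config$model)
    model <- train_cnn(model,
                       images[, , , split$train, drop = FALSE],
                       y[split$train, , drop = FALSE],
                       images[, , , split$validation, drop = FALSE],
                       y[split$validation, , drop = FALSE])
    log_stage(logf, "train", sprintf("%d epochs run", nrow(model$history)), t0)
    utils::write.csv(model$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    saveRDS(model, file.path(config$out_dir, "model.rds"))

    pred <- predict_labels(model, images[, , , split$test, drop = FALSE])
    cm <- confusion_matrix(pred, manifest$label[split$test],
                           colnames(y))
    metrics <- classification_metrics(cm)
    write_metrics(metrics, file.path(config$out_dir, "metrics.json"), cm)
    log_stage(logf, "evaluate", format(metrics), t0)

    out <- list(segments = segments, manifest = manifest, model = model,
                split = split, confusion = cm, metrics = metrics)

    if (config$cv_k > 0) {
      out$cv <- cv_cnn(images, manifest$label, config$model,
                       k = config$cv_k, seed = seeds["cv"])
      jsonlite::write_json(
        list(aggregate = as.data.frame(out$cv$aggregate)),
        file.path(config$out_dir, "cv.json"), digits = NA)
      log_stage(logf, "cv", sprintf("mean accuracy %.3f",
                                    out$cv$aggregate["mean", "accuracy"]), t0)
    }
    if (config$baseline) {
      out$baseline <- logistic_baseline_cv(images, manifest$label,
                                           k = max(config$cv_k, 10L),
                                           seed = seeds["baseline"])
      jsonlite::write_json(out$baseline[c("fold_auc", "mean_auc", "sd_auc")],
                           file.path(config$out_dir, "baseline.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage(logf, "baseline", sprintf("mean AUC %.3f",
                                          out$baseline$mean_auc), t0)
    }
    if (config$saliency) {
      rcfg <- config$render %||% render_config(
        width_px = config$model$input_shape[2],
        height_px = config$model$input_shape[1])
      for (cl in colnames(y)) {
        idx <- which(manifest$label == cl)
        sal <- average_saliency(model, images[, , , idx, drop = FALSE],
                                target_class = cl)
        write_saliency_png(sal, file.path(config$out_dir,
                                          paste0("saliency_", cl, ".png")))
        saliency_bed(sal, rcfg, q = 0.01,
                     path = file.path(config$out_dir,
                                      paste0("saliency_", cl, ".bed")))
        out$saliency[[cl]] <- sal
      }
      log_stage(logf, "saliency", "class-average maps written", t0)
    }

    cfg_echo <- config
    cfg_echo$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
    yaml::write_yaml(rapply(unclass(cfg_echo), unclass, how = "replace"),
                     file.path(config$out_dir, "config_resolved.yaml"))
    log_stage(logf, "done", "pipeline complete", t0)
    invisible(out)
  }, error = function(e) {
    writeLines(paste("ERROR:", conditionMessage(e)), logf)
    stop(e)
  })
}
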