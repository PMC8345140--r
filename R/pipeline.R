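#' Pipeline configuration
#'
#' Bundles all stage configurations of the end-to-end workflow
#' (synthesise/ingest, split, train, predict, segment, evaluate, survival)
#' with one global seed. The demo-scale defaults run the whole chain on a
#' laptop CPU in a couple of minutes.
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param data_dir optional existing patch folder (with `images/` and
#'   `masks/`); when `NULL` the synth stage generates `n_patches` patches.
#' @param n_patches number of synthetic patches for the synth stage.
#' @param patch a [synth_patch_config()] for the synth stage.
#' @param split_ratios train / train-val / test fractions.
#' @param unet a [unet_config()] (spatial size must match the patches).
#' @param train a [train_config()].
#' @param loss a [loss_spec()].
#' @param post a [postproc_params()].
#' @param iou_threshold object-match IoU criterion for evaluation.
#' @param thresholds probability grid for the object-level sweep.
#' @param mpp microns per pixel for density estimation.
#' @param cohort a [synth_cohort_config()] for the survival stage.
#' @param horizon survival horizon in years.
#' @param seed global seed; stage seeds are derived from it.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("nucquant-run-"),
                            data_dir = NULL,
                            n_patches = 60L,
                            patch = synth_patch_config(patch_size = 64L,
                                                       n_nuclei = c(3L, 8L),
                                                       radius = c(4, 9)),
                            split_ratios = c(0.6, 0.1, 0.3),
                            unet = unet_config(input_size = c(64L, 64L, 3L),
                                               depth = 3L, base_channels = 8L),
                            train = train_config(epochs = 20L),
                            loss = loss_spec("bce"),
                            post = postproc_params(h = 2),
                            iou_threshold = 0.5,
                            thresholds = seq(0.30, 0.50, by = 0.05),
                            mpp = 0.25,
                            cohort = synth_cohort_config(),
                            horizon = 5,
                            seed = 1L) {
  structure(list(out_dir = out_dir, data_dir = data_dir,
                 n_patches = as.integer(n_patches), patch = patch,
                 split_ratios = split_ratios, unet = unet, train = train,
                 loss = loss, post = post, iou_threshold = iou_threshold,
                 thresholds = thresholds, mpp = mpp, cohort = cohort,
                 horizon = horizon, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stages <- c("synth", "split", "train", "predict", "segment",
                     "eval", "survival")

#' Run the end-to-end workflow
#'
#' Executes the enabled stages in their natural order: data synthesis (or
#' ingestion of an existing patch folder), splitting, U-Net training,
#' prediction on the test partition, watershed post-processing, pixel- and
#' object-level evaluation (including the threshold sweep and density
#' concordance), and survival stratification of a synthetic cohort. All
#' outputs plus a manifest (file checksums, seed, R version) are written to
#' `config$out_dir`. A stage that requires outputs of a disabled earlier
#' stage raises a stage-named error.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run (subset of
#'   `"synth", "split", "train", "predict", "segment", "eval", "survival"`)
#'   or `"all"`.
#' @param state optionally, the returned state of a previous partial run to
#'   continue from.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the run directory and all in-memory
#'   stage results (`patches`, `split`, `model`, `probs`, `instances`,
#'   `metrics`, `sweep`, `concordance`, `strat`).
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         state = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- if (is.null(state)) list() else state
  note <- function(...) if (verbose) message(sprintf(...))
  need <- function(what, stage) {
    if (is.null(st[[what]]))
      stop(sprintf("stage `%s` requires `%s` from an earlier stage", stage, what),
           call. = FALSE)
  }

  if ("synth" %in% stages) {
    note("stage synth")
    if (is.null(config$data_dir)) {
      ddir <- file.path(config$out_dir, "data")
      write_synth_patches(config$n_patches, ddir, config$patch,
                          seed = config$seed)
    } else {
      ddir <- config$data_dir
    }
    st$patches <- load_patch_folder(ddir)
  }

  if ("split" %in% stages) {
    note("stage split")
    need("patches", "split")
    ids <- vapply(st$patches, `[[`, "", "source_id")
    st$split <- split_dataset(ids, config$split_ratios, seed = config$seed)
    write_cohort_csv <- file.path(config$out_dir, "split.csv")
    utils::write.csv(st$split, write_cohort_csv, row.names = FALSE)
  }

  part_of <- function(p) {
    st$split$partition[match(vapply(st$patches, `[[`, "", "source_id"),
                             st$split$id)]
  }
  gt_inst <- function(pt) if (!is.null(pt$gt_instances)) pt$gt_instances else
    label_components(pt$gt_binary)

  if ("train" %in% stages) {
    note("stage train")
    need("patches", "train"); need("split", "train")
    part <- part_of()
    tr <- which(part == "train"); va <- which(part == "train_val")
    st$model <- unet_train(
      x = lapply(st$patches[tr], `[[`, "image"),
      y = lapply(st$patches[tr], `[[`, "gt_binary"),
      x_val = lapply(st$patches[va], `[[`, "image"),
      y_val = lapply(st$patches[va], `[[`, "gt_binary"),
      config = config$unet, train = config$train, loss = config$loss)
    utils::write.csv(st$model$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    saveRDS(st$model, file.path(config$out_dir, "model.rds"))
  }

  if ("predict" %in% stages) {
    note("stage predict")
    need("patches", "predict"); need("split", "predict"); need("model", "predict")
    te <- which(part_of() == "test")
    st$test_idx <- te
    st$probs <- lapply(st$patches[te],
                       function(pt) predict(st$model, pt$image))
  }

  if ("segment" %in% stages) {
    note("stage segment")
    need("probs", "segment")
    st$instances <- lapply(st$probs, segment_nuclei, params = config$post)
  }

  if ("eval" %in% stages) {
    note("stage eval")
    need("probs", "eval"); need("instances", "eval")
    te <- st$test_idx
    gts_bin <- lapply(st$patches[te], `[[`, "gt_binary")
    gts_inst <- lapply(st$patches[te], gt_inst)
    preds_bin <- lapply(st$probs, binarize,
                        threshold = config$post$prob_threshold)
    cts <- list(tp = 0, fp = 0, tn = 0, fn = 0)
    for (i in seq_along(te)) {
      ci <- pixel_confusion(preds_bin[[i]], gts_bin[[i]])
      cts <- Map(`+`, cts, ci)
    }
    pm <- pixel_metrics(cts)
    dices <- mapply(dice_pixel, preds_bin, gts_bin)
    ajis <- mapply(aji, gts_inst, st$instances)
    curves <- roc_pr_curves(st$probs, gts_bin)
    st$sweep <- threshold_sweep(st$probs, gts_inst,
                                thresholds = config$thresholds,
                                h = config$post$h,
                                iou_threshold = config$iou_threshold,
                                min_area = config$post$min_area)
    dens_pred <- vapply(st$instances, function(l)
      cell_density(l, config$mpp)$density, numeric(1))
    dens_gt <- vapply(gts_inst, function(l)
      cell_density(l, config$mpp)$density, numeric(1))
    st$concordance <- tryCatch(density_concordance(dens_pred, dens_gt),
                               error = function(e) NA_real_)
    st$metrics <- list(
      pixel = as.list(pm), dice_mean = mean(dices, na.rm = TRUE),
      aji_mean = mean(ajis, na.rm = TRUE), auc_roc = curves$auc_roc,
      auc_pr = curves$auc_pr, per_patch = list(dice = dices, aji = ajis),
      density_pearson_r = st$concordance)
    jsonlite::write_json(st$metrics[c("pixel", "dice_mean", "aji_mean",
                                      "auc_roc", "auc_pr",
                                      "density_pearson_r")],
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(st$sweep, file.path(config$out_dir, "sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patch = seq_along(dices), dice = dices,
                                aji = ajis),
                     file.path(config$out_dir, "per_patch_metrics.csv"),
                     row.names = FALSE)
  }

  if ("survival" %in% stages) {
    note("stage survival")
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    st$strat <- stratify_survival(cohort, horizon = config$horizon)
    jsonlite::write_json(list(
      cutoff = st$strat$cutoff, auc = st$strat$auc,
      n_group1 = st$strat$n[1], n_group2 = st$strat$n[2],
      logrank_chisq = st$strat$logrank$chisq, logrank_p = st$strat$logrank$p),
      file.path(config$out_dir, "survival.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(
      rbind(cbind(group = 1L, st$strat$km$group1),
            cbind(group = 2L, st$strat$km$group2)),
      file.path(config$out_dir, "km_curves.csv"), row.names = FALSE)
    utils::write.csv(st$strat$roc, file.path(config$out_dir, "td_roc.csv"),
                     row.names = FALSE)
  }

  # manifest: every output file with checksum, plus run metadata
  files <- list.files(config$out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(config$out_dir, files))
  jsonlite::write_json(list(
    seed = config$seed, stages = stages,
    r_version = as.character(getRversion()),
    files = data.frame(path = files, md5 = unname(sums))),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(c(list(out_dir = config$out_dir), st))
}
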