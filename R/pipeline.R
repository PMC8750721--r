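# End-to-end orchestration: simulate (or ingest) -> calibrate -> ROI ->
# preprocess -> Kennard-Stone split -> PCA -> classifier bank -> optional
# SFS -> reports. Every stage seed derives from the master seed and the
# resolved configuration is serialized next to the outputs.

#' Build a fully explicit pipeline configuration
#'
#' Collects the per-stage settings into one resolved object; every field has
#' an explicit value so a run is reproducible from the serialized config
#' plus the master seed. `mode` selects the dataset-construction approach:
#' `auto-roi` (automatic calyx-centered circular ROI, pixel level),
#' `manual-roi` (10 x 10 rectangle at the calyx, pixel level) or
#' `mean-spectra` (one whole-fruit mean spectrum per apple).
#'
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param seed master seed.
#' @param mode dataset construction approach.
#' @param n_control,n_infested apples per class.
#' @param scene template [scene_config()].
#' @param jitter between-apple jitter, see [generate_study()].
#' @param roi list: `seg_nm`, `diameter_px`, `selem_radius`.
#' @param rect list: `height`, `width` (manual mode).
#' @param preprocess a [preprocess_config()].
#' @param split_fraction Kennard-Stone training share.
#' @param use_pca project onto principal components before classification?
#' @param pca_ncomp component count when `use_pca`.
#' @param classifiers character vector of classifier tags.
#' @param hyperparams named list of per-tag hyperparameter overrides.
#' @param cv_folds folds for training-set cross-validation.
#' @param sfs `NULL`, or a list with `max_k`, `classifier`, `hyperparams`
#'   to run wavelength selection on the training set.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = NULL, seed = 1,
                       mode = c("auto-roi", "manual-roi", "mean-spectra"),
                       n_control = 6, n_infested = 12,
                       scene = scene_config(),
                       jitter = list(center_px = 3, radius_px = 4,
                                     gain_sd = 0.05),
                       roi = list(seg_nm = 1084, diameter_px = 50,
                                  selem_radius = 2),
                       rect = list(height = 10, width = 10),
                       preprocess = preprocess_config(),
                       split_fraction = 0.7,
                       use_pca = TRUE, pca_ncomp = 3,
                       classifiers = c("lda", "knn", "rf", "gtb", "plsda"),
                       hyperparams = list(),
                       cv_folds = 5,
                       sfs = NULL) {
  mode <- match.arg(mode)
  structure(list(out_dir = out_dir, seed = seed, mode = mode,
                 n_control = n_control, n_infested = n_infested,
                 scene = scene, jitter = jitter, roi = roi, rect = rect,
                 preprocess = preprocess, split_fraction = split_fraction,
                 use_pca = use_pca, pca_ncomp = pca_ncomp,
                 classifiers = classifiers, hyperparams = hyperparams,
                 cv_folds = cv_folds, sfs = sfs),
            class = "run_config")
}

.log_line <- function(log, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  c(log, msg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cs_stop(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), "calyxscan_pipeline_error")
  })
}

#' Run the full study pipeline
#'
#' Executes simulation, calibration, dataset construction in the configured
#' mode, preprocessing, the Kennard-Stone split, optional PCA, the
#' classifier bank with training-set cross-validation, and optional
#' sequential forward wavelength selection. When `config$out_dir` is set,
#' per-classifier reports (JSON), a flat metrics CSV, the SFS curve CSV and
#' the resolved config (YAML) are written there.
#'
#' Pixel labels follow the apple-level label: every ROI pixel of an infested
#' apple is labeled `infested`, every pixel of a control apple `healthy` --
#' a deliberate, documented label-noise source of pixel-level studies.
#'
#' @param config a [run_config()].
#' @param scenes optional pre-generated list of scenes (as from
#'   [generate_study()]); when `NULL`, scenes are simulated.
#' @return invisibly, a list: `dataset`, `split`, `pca`, `reports`
#'   (per classifier: train/validation [classification_report()]s and a
#'   `cv_result`), `sfs`, `config`, `log`.
#' @export
run_pipeline <- function(config = run_config(), scenes = NULL) {
  log <- character(0)
  log <- .log_line(log, "run start: mode=%s seed=%d", config$mode, config$seed)

  if (is.null(scenes)) {
    scenes <- .stage("simulate", generate_study(
      config$n_control, config$n_infested, config$scene,
      seed = derive_seed(config$seed, 1L), jitter = config$jitter))
    log <- .log_line(log, "simulated %d scenes (stage seed %d)",
                     length(scenes), derive_seed(config$seed, 1L))
  }

  tables <- .stage("dataset", lapply(scenes, function(sc) {
    cal <- calibrate(sc$raw, sc$refs)
    lab <- if (!is.null(sc$label)) sc$label else sc$raw$meta$label
    sid <- if (!is.null(sc$apple_id)) sc$apple_id else cal$name
    if (config$mode == "auto-roi") {
      roi <- acquire_roi(cal, seg_nm = config$roi$seg_nm,
                         diameter_px = config$roi$diameter_px,
                         selem_radius = config$roi$selem_radius)
      extract_pixel_spectra(cal, roi$mask, lab, sample_id = sid,
                            orientation = "calyx")
    } else if (config$mode == "manual-roi") {
      ctr <- round(sc$truth$config$calyx_center)
      extract_pixel_spectra(
        cal, rect_roi(ctr, config$rect$height, config$rect$width, dim(cal)[1:2]),
        lab, sample_id = sid, orientation = "calyx")
    } else {
      s <- mean_spectrum(cal, sc$truth$fruit)
      pixel_spectra_table(matrix(s, 1L), cal$wavelengths, lab,
                          data.frame(sample_id = sid, cultivar = "",
                                     orientation = "calyx", row = NA_integer_,
                                     col = NA_integer_))
    }
  }))
  dataset <- assemble_dataset(tables)
  log <- .log_line(log, "dataset: %d observations x %d bands",
                   nrow(dataset$spectra), ncol(dataset$spectra))

  pre <- .stage("preprocess", preprocess(dataset, config$preprocess))
  # Kennard-Stone distances are invariant to subtracting a common mean, so
  # the split computed on the centered table equals the uncentered one.
  split <- .stage("split", kennard_stone(pre$table$spectra,
                                         config$split_fraction))
  train_tab <- .subset_rows(pre$table, split$train_idx)
  val_tab <- .subset_rows(pre$table, split$val_idx)
  # Re-center with the training mean only (leakage-free statistics).
  if (config$preprocess$center == "train-mean") {
    shift <- colMeans(train_tab$spectra)
    train_tab$spectra <- sweep(train_tab$spectra, 2L, shift)
    val_tab$spectra <- sweep(val_tab$spectra, 2L, shift)
  }
  log <- .log_line(log, "split: %d train / %d validation",
                   length(split$train_idx), length(split$val_idx))

  if (config$use_pca) {
    pca <- .stage("pca", fit_pca(train_tab$spectra, ncomp = config$pca_ncomp))
    ftrain <- transform_pca(pca, train_tab$spectra)
    fval <- transform_pca(pca, val_tab$spectra)
    log <- .log_line(log, "pca: %d components, %.2f%% variance",
                     ncol(pca$loadings),
                     100 * sum(pca$explained_variance_ratio))
  } else {
    pca <- NULL
    ftrain <- train_tab$spectra
    fval <- val_tab$spectra
  }

  reports <- list()
  for (tag in config$classifiers) {
    seed_i <- derive_seed(config$seed, 100L + match(tag, .classifier_tags))
    hp <- if (!is.null(config$hyperparams[[tag]])) {
      config$hyperparams[[tag]]
    } else list()
    m <- .stage(tag, train_classifier(tag, ftrain, train_tab$labels, hp,
                                      seed = seed_i))
    reports[[tag]] <- list(
      train = evaluate(m, ftrain, train_tab$labels, partition = "train"),
      validation = evaluate(m, fval, val_tab$labels,
                            partition = "validation"),
      cv = if (config$cv_folds >= 2) {
        cross_validate(tag, ftrain, train_tab$labels,
                       folds = config$cv_folds, seed = seed_i,
                       hyperparams = hp)
      }
    )
    log <- .log_line(log, "%s: val acc %.4f (seed %d)", tag,
                     reports[[tag]]$validation$accuracy, seed_i)
  }

  sfs_res <- NULL
  if (!is.null(config$sfs)) {
    sfs_seed <- derive_seed(config$seed, 500L)
    sfs_res <- .stage("sfs", sfs_select(
      train_tab$spectra, train_tab$labels,
      classifier = if (!is.null(config$sfs$classifier)) {
        config$sfs$classifier
      } else "gtb",
      max_k = config$sfs$max_k, folds = config$cv_folds, seed = sfs_seed,
      wavelengths = train_tab$wavelengths,
      hyperparams = config$sfs$hyperparams))
    log <- .log_line(log, "sfs: %d bands selected (seed %d)",
                     length(sfs_res$selected_band_indices), sfs_seed)
  }

  result <- list(dataset = dataset, split = split, pca = pca,
                 reports = reports, sfs = sfs_res, config = config,
                 log = log)
  if (!is.null(config$out_dir)) .write_run_outputs(result, config$out_dir)
  invisible(result)
}

.report_row <- function(rep) {
  cbind(data.frame(classifier = rep$classifier, partition = rep$partition,
                   accuracy = rep$accuracy, n = rep$n_observations),
        rep$metrics)
}

.write_run_outputs <- function(result, out_dir) {
  dir.create(file.path(out_dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  rows <- list()
  for (tag in names(result$reports)) {
    r <- result$reports[[tag]]
    jsonlite::write_json(
      list(classifier = tag,
           train = list(accuracy = r$train$accuracy,
                        metrics = r$train$metrics),
           validation = list(accuracy = r$validation$accuracy,
                             metrics = r$validation$metrics),
           cv = if (!is.null(r$cv)) {
             list(mean_accuracy = r$cv$mean_accuracy,
                  sd_accuracy = r$cv$sd_accuracy)
           }),
      file.path(out_dir, "reports", paste0(tag, ".json")),
      auto_unbox = TRUE, digits = NA)
    rows <- c(rows, list(.report_row(r$train), .report_row(r$validation)))
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "tables", "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(result$sfs)) {
    write_sfs_result(result$sfs,
                     json_path = file.path(out_dir, "reports", "sfs.json"),
                     csv_path = file.path(out_dir, "tables", "sfs_curve.csv"))
  }
  cfg <- result$config
  cfg$preprocess <- unclass(cfg$preprocess)
  cfg$scene <- unclass(cfg$scene)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
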