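#' Build a QC'd patch set for a whole cohort
#'
#' Streams scan by scan: each scan is rendered (or loaded), tiled, QC'd, and
#' only metadata plus the retained patches' pixels are kept, so arbitrarily
#' large cohorts fit in memory. Synthetic scans are regenerated
#' deterministically from the manifest, so this never stores images.
#'
#' @param cohort A `synth_cohort` (images optional - they are regenerated
#'   from the manifest when absent), or a manifest tibble with a `path`
#'   column of scan image files.
#' @param grid A [grid_spec()].
#' @param artifact_model Trained artifact filter, or `NULL` to train one on
#'   a synthetic labeled set at `grid$resize_to`.
#' @param config A [qc_config()].
#' @param keep_rejected_pixels Keep pixel data for rejected patches
#'   (default drops them to save memory; their metadata rows remain).
#' @param verbose Print per-scan progress.
#' @return List with `patches` (tibble over all scans), `qc` (per-scan QC
#'   reports), `artifact_model`.
#' @export
build_patch_set <- function(cohort, grid, artifact_model = NULL,
                            config = qc_config(),
                            keep_rejected_pixels = FALSE, verbose = FALSE) {
  is_synth <- inherits(cohort, "synth_cohort")
  manifest <- if (is_synth) cohort$manifest else cohort
  if (is.null(artifact_model)) {
    params <- if (is_synth) cohort$params else synth_params()
    labeled <- synth_qc_training_set(params, n_per_class = 80,
                                    size = grid$resize_to,
                                    seed = derive_seed(
                                      if (is_synth) params$seed else 1L, "qc"))
    artifact_model <- train_artifact_filter(labeled)
  }
  all_patches <- vector("list", nrow(manifest))
  reports <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    scan <- if (is_synth) {
      sc <- cohort$scans[[r$scan_id]]
      if (is.null(sc))
        sc <- generate_section_scan(cohort$params, r$patient_num, r$scan_num,
                                    labels = list(
                                      abnormal = r$abnormal,
                                      active_inflammation = r$active_inflammation,
                                      chronic_changes = r$chronic_changes,
                                      granuloma = r$granuloma))
      sc$image
    } else read_scan_png(r$path)
    tiled <- tile_scan(scan, r$scan_id, grid)
    qc <- qc_scan_patches(tiled, scan, artifact_model, config)
    p <- qc$patches
    if (!keep_rejected_pixels) {
      drop <- p$qc_status != "retained"
      p$pixels[drop] <- list(NULL)
      p$pad_mask[drop] <- list(NULL)
    }
    all_patches[[i]] <- p
    reports[[i]] <- dplyr::bind_cols(tibble::tibble(scan_id = r$scan_id),
                                     qc$report)
    if (verbose && i %% 20 == 0) message(sprintf("  tiled+QC'd %d/%d scans", i, nrow(manifest)))
  }
  list(patches = dplyr::bind_rows(all_patches),
       qc = dplyr::bind_rows(reports),
       artifact_model = artifact_model)
}

#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings with a single global seed that fans out to
#' derived per-stage seeds. The defaults are the desk-scale profile used
#' throughout the package's examples: synthetic 1024-2048 px scans, 128-px
#' tiles resized to 32 px, and a narrow fast classifier; slide-scale work
#' would instead pass `grid_spec()` and `cnn_config()` defaults.
#'
#' @param params [synth_params()] for cohort synthesis (ignored when
#'   `scan_manifest` points at real images).
#' @param grid A [grid_spec()].
#' @param qc A [qc_config()].
#' @param model A [cnn_config()].
#' @param aggregation An [aggregation_config()].
#' @param tasks Tasks to model.
#' @param n_folds,n_val Cross-validation shape.
#' @param max_train_patches,max_val_patches Per-fold patch caps.
#' @param seed Global seed.
#' @param scan_manifest Optional manifest tibble with `path` column for
#'   pre-existing scan images.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(params = synth_params(),
                            grid = grid_spec(patch_size = 128, overlap = 0.25,
                                             resize_to = 32),
                            qc = qc_config(),
                            model = cnn_config(input_size = 32,
                                               filters = c(8, 16, 32, 64),
                                               dense_units = 64,
                                               learning_rate = 1e-3,
                                               batch_size = 8,
                                               max_epochs = 4, patience = 3),
                            aggregation = aggregation_config(),
                            tasks = c("abnormal", "active_inflammation",
                                      "chronic_changes"),
                            n_folds = 5, n_val = 3,
                            max_train_patches = 600, max_val_patches = 160,
                            seed = 1L, scan_manifest = NULL) {
  assert_that(grid$resize_to == model$input_size,
              "grid$resize_to must equal model$input_size")
  structure(list(params = params, grid = grid, qc = qc, model = model,
                 aggregation = aggregation, tasks = tasks, n_folds = n_folds,
                 n_val = n_val, max_train_patches = max_train_patches,
                 max_val_patches = max_val_patches, seed = as.integer(seed),
                 scan_manifest = scan_manifest),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Synthesis (or ingest) -> tiling -> two-stage QC -> per-fold weak-label
#' training -> patch-to-section aggregation -> patient-level
#' cross-validated evaluation. When `out_dir` is given, the manifest, patch
#' index (metadata only), section predictions, fold metrics, summary, QC
#' reports and a config/seed snapshot are written as CSV/JSON. Re-running
#' with an identical config and seed reproduces the predictions.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return List with `report` (a `cv_report`), `patch_set`, `manifest`,
#'   `config`, and `paths` (when written).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  if (!is.null(config$scan_manifest)) {
    missing <- !file.exists(config$scan_manifest$path)
    assert_that(!any(missing),
                paste("scan files not found:",
                      paste(head(config$scan_manifest$path[missing], 3),
                            collapse = ", ")))
    cohort <- config$scan_manifest
    manifest <- cohort
  } else {
    params <- config$params
    params$seed <- derive_seed(config$seed, "synth")
    if (verbose) message("synthesizing cohort manifest...")
    cohort <- generate_cohort(params, keep_images = FALSE)
    manifest <- cohort$manifest
  }
  if (verbose) message("tiling + QC...")
  ps <- build_patch_set(cohort, config$grid, config = config$qc,
                        verbose = verbose)
  if (verbose) message("cross-validated training...")
  report <- cross_validate(ps$patches, manifest, tasks = config$tasks,
                           model_config = config$model,
                           agg_config = config$aggregation,
                           n_folds = config$n_folds, n_val = config$n_val,
                           seed = derive_seed(config$seed, "cv"),
                           max_train_patches = config$max_train_patches,
                           max_val_patches = config$max_val_patches,
                           verbose = verbose)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    idx <- ps$patches[, c("scan_id", "origin_x", "origin_y", "padded_right",
                          "padded_bottom", "qc_status", "artifact_prob",
                          "tissue_fraction")]
    paths <- list(
      manifest = file.path(out_dir, "manifest.csv"),
      patch_index = file.path(out_dir, "patch_index.csv"),
      predictions = file.path(out_dir, "section_predictions.csv"),
      folds = file.path(out_dir, "fold_metrics.csv"),
      summary = file.path(out_dir, "cv_summary.csv"),
      qc = file.path(out_dir, "qc_reports.csv"),
      config = file.path(out_dir, "run_config.json"))
    utils::write.csv(manifest[, setdiff(names(manifest),
                                        c("patient_num", "scan_num"))],
                     paths$manifest, row.names = FALSE)
    utils::write.csv(idx, paths$patch_index, row.names = FALSE)
    utils::write.csv(report$predictions, paths$predictions, row.names = FALSE)
    utils::write.csv(report$folds, paths$folds, row.names = FALSE)
    utils::write.csv(report$summary, paths$summary, row.names = FALSE)
    utils::write.csv(ps$qc, paths$qc, row.names = FALSE)
    snapshot <- list(seed = config$seed,
                     grid = unclass(config$grid), qc = unclass(config$qc),
                     model = unclass(config$model),
                     aggregation = unclass(config$aggregation),
                     tasks = config$tasks, n_folds = config$n_folds,
                     n_val = config$n_val,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(snapshot, paths$config, auto_unbox = TRUE, digits = NA)
  }
  list(report = report, patch_set = ps, manifest = manifest,
       config = config, paths = paths)
}
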