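#' Patch quality-control configuration
#'
#' QC runs in a fixed two-stage order: first the artifact/background
#' convolutional filter, then the per-scan Otsu tissue-fraction rule. A
#' patch is dropped when its artifact probability exceeds
#' `artifact_threshold`, or (if it survives) when its tissue fraction is
#' strictly below `min_tissue_fraction` (the "less than 20% tissue" rule).
#'
#' @param artifact_threshold Probability above which a patch is rejected as
#'   artifact/background.
#' @param min_tissue_fraction Minimum tissue fraction (strict `<` rejects).
#' @return A `qc_config` object.
#' @export
qc_config <- function(artifact_threshold = 0.5, min_tissue_fraction = 0.20) {
  assert_that(artifact_threshold >= 0 && artifact_threshold <= 1 &&
                min_tissue_fraction >= 0 && min_tissue_fraction <= 1,
              "QC thresholds must be in [0, 1]")
  structure(list(artifact_threshold = artifact_threshold,
                 min_tissue_fraction = min_tissue_fraction,
                 otsu_scope = "per_scan"),
            class = "qc_config")
}

#' Otsu threshold of a gray-level sample
#'
#' Standard 256-bin Otsu: the gray level maximizing between-class variance,
#' with classes `[0, t)` (tissue, darker) and `[t, 255]` (background). Values
#' are rounded into bins 0-255. A constant input returns that constant (so
#' no pixel is darker than the threshold and the tissue fraction downstream
#' is 0).
#'
#' @param values Numeric vector of gray levels in `[0, 255]`.
#' @return A single threshold `t`; "tissue" pixels are those with gray `< t`.
#' @export
otsu_threshold <- function(values) {
  assert_that(length(values) > 0, "empty gray-level sample")
  v <- pmin(pmax(round(values), 0), 255)
  if (length(unique(v)) == 1L) return(v[1])
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  lev <- 0:255
  wcum <- cumsum(h)
  mcum <- cumsum(lev * h)
  total <- wcum[256]
  mtot <- mcum[256]
  # split after bin t (classes <= t vs > t), t = 0..254
  w0 <- wcum[1:255]
  w1 <- total - w0
  m0 <- mcum[1:255] / pmax(w0, 1)
  m1 <- (mtot - mcum[1:255]) / pmax(w1, 1)
  sb <- w0 * w1 * (m0 - m1)^2
  sb[w0 == 0 | w1 == 0] <- -Inf
  t_star <- which.max(sb) - 1L # first maximizer
  t_star + 1L # dark class = gray < threshold
}

#' Per-scan Otsu threshold
#'
#' Computes the tissue/background threshold once per scan on its luminance
#' image (optionally strided down for speed), excluding any pixels marked in
#' `exclude`. Computing Otsu per scan rather than per patch avoids the
#' instability of thresholding homogeneous all-tissue or all-background
#' tiles.
#'
#' @param scan `H x W x 3` array of 0-255 intensities (or a gray matrix).
#' @param exclude Optional logical mask of pixels to ignore (e.g. padding).
#' @param max_pixels Downsampling cap: a regular pixel stride is applied so
#'   at most about this many pixels enter the histogram.
#' @return Gray-level threshold (tissue = luminance strictly below it).
#' @export
compute_scan_otsu <- function(scan, exclude = NULL, max_pixels = 5e5) {
  gray <- if (length(dim(scan)) == 3L) luminance(scan) else scan
  assert_that(length(gray) > 0, "empty image")
  if (!is.null(exclude)) gray <- gray[!exclude]
  gray <- as.vector(gray)
  assert_that(length(gray) > 0, "image is entirely excluded")
  if (length(gray) > max_pixels) {
    step <- ceiling(length(gray) / max_pixels)
    gray <- gray[seq(1, length(gray), by = step)]
  }
  thr <- otsu_threshold(gray)
  # degenerate tissue-free scan: Otsu on pure background noise splits the
  # noise itself. H&E tissue is never near-white, so when even the "dark"
  # class is near-white the scan holds no tissue at all.
  dark <- gray[gray < thr]
  if (length(dark) == 0 || mean(dark) > 235) return(0)
  thr
}

#' Tissue fraction of one patch
#'
#' Fraction of non-padded pixels whose luminance is strictly below the scan's
#' Otsu threshold (H&E tissue is darker than slide background). Zero-filled
#' padding is excluded from numerator and denominator; a fully padded patch
#' has fraction 0 by definition.
#'
#' @param pixels Square `k x k x 3` patch array (0-255).
#' @param threshold Scan-level gray threshold from [compute_scan_otsu()].
#' @param pad_mask Optional logical matrix marking padded pixels.
#' @return Proportion in `[0, 1]`.
#' @export
tissue_fraction <- function(pixels, threshold, pad_mask = NULL) {
  gray <- luminance(pixels)
  keep <- if (is.null(pad_mask)) rep(TRUE, length(gray)) else !pad_mask
  n <- sum(keep)
  if (n == 0) return(0)
  sum(gray[keep] < threshold) / n
}

#' Train the artifact/background filter
#'
#' A reduced-width instance of the patch classifier (filters 8/16/32/64 by
#' default) trained on labeled patches (1 = artifact or background,
#' 0 = usable tissue). A held-out fraction of the input is split off for
#' validation/checkpointing.
#'
#' @param labeled Tibble with list-column `pixels` and binary `label`, e.g.
#'   from [synth_qc_training_set()].
#' @param config Optional [cnn_config()]; the default derives the input size
#'   from the patches and uses a short schedule.
#' @param val_fraction Fraction held out for validation.
#' @return A trained `patch_cnn` with task `"artifact_filter"`.
#' @export
train_artifact_filter <- function(labeled, config = NULL, val_fraction = 0.25) {
  assert_that(nrow(labeled) > 0, "empty training set")
  assert_that(length(unique(labeled$label)) == 2,
              "artifact training needs both classes")
  size <- dim(labeled$pixels[[1]])[1]
  # narrow net on a small labeled set: dropout off, short Adam schedule
  config <- config %||% cnn_config(
    input_size = size, filters = c(8, 16, 32, 64), dense_units = 64,
    dropout = c(0, 0, 0, 0), dense_dropout = 0,
    learning_rate = 1e-3, max_epochs = 24, patience = 22,
    batch_size = 8, seed = 409L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "qc_split"))
  n <- nrow(labeled)
  val_ix <- sort(sample(n, max(2, round(val_fraction * n))))
  if (length(unique(labeled$label[val_ix])) < 2 ||
      length(unique(labeled$label[-val_ix])) < 2)
    val_ix <- c(which(labeled$label == 1)[1:2], which(labeled$label == 0)[1:2])
  model <- build_model(config)
  fit_patch_cnn(model,
                labeled$pixels[-val_ix], labeled$label[-val_ix],
                labeled$pixels[val_ix], labeled$label[val_ix],
                task = "artifact_filter")
}

#' Apply the artifact filter to a patch set
#'
#' Patches whose predicted artifact probability strictly exceeds
#' `config$artifact_threshold` get `qc_status = "artifact_rejected"`; row
#' order is preserved and an `artifact_prob` column is added.
#'
#' @param patches Patch tibble from [tile_scan()].
#' @param model Trained artifact filter.
#' @param config A [qc_config()].
#' @return The patch tibble with updated `qc_status` and `artifact_prob`.
#' @export
apply_artifact_filter <- function(patches, model, config = qc_config()) {
  assert_that(inherits(model, "patch_cnn") && isTRUE(model$trained),
              "artifact filter must be a trained patch_cnn")
  probs <- predict_patches(model, patches$pixels)
  patches$artifact_prob <- probs
  rej <- probs > config$artifact_threshold & patches$qc_status == "retained"
  patches$qc_status[rej] <- "artifact_rejected"
  patches
}

#' Apply the tissue-fraction filter and report QC counts
#'
#' Runs after the artifact filter (fixed order). Retained patches with
#' tissue fraction strictly below `config$min_tissue_fraction` become
#' `low_tissue_rejected`. The report partitions every patch of the scan into
#' retained / artifact_rejected / low_tissue_rejected.
#'
#' @param patches Patch tibble (after [apply_artifact_filter()]).
#' @param threshold Scan-level Otsu gray threshold.
#' @param config A [qc_config()].
#' @return List with `patches` (updated tibble, plus `tissue_fraction`
#'   column) and `report` (one-row tibble of per-status counts).
#' @export
apply_tissue_filter <- function(patches, threshold, config = qc_config()) {
  tf <- vapply(seq_len(nrow(patches)), function(i) {
    tissue_fraction(patches$pixels[[i]], threshold, patches$pad_mask[[i]])
  }, 0)
  patches$tissue_fraction <- tf
  rej <- patches$qc_status == "retained" & tf < config$min_tissue_fraction
  patches$qc_status[rej] <- "low_tissue_rejected"
  report <- tibble::tibble(
    n_patches = nrow(patches),
    retained = sum(patches$qc_status == "retained"),
    artifact_rejected = sum(patches$qc_status == "artifact_rejected"),
    low_tissue_rejected = sum(patches$qc_status == "low_tissue_rejected"),
    otsu_threshold = threshold
  )
  list(patches = patches, report = report)
}

#' Full two-stage QC for one scan's patches
#'
#' Convenience wrapper: per-scan Otsu, artifact filter, then tissue filter,
#' in the fixed order.
#'
#' @param patches Patch tibble from [tile_scan()].
#' @param scan The scan array the patches came from.
#' @param artifact_model Trained artifact filter.
#' @param config A [qc_config()].
#' @return List with `patches` and `report` as in [apply_tissue_filter()].
#' @export
qc_scan_patches <- function(patches, scan, artifact_model, config = qc_config()) {
  thr <- compute_scan_otsu(scan)
  patches <- apply_artifact_filter(patches, artifact_model, config)
  apply_tissue_filter(patches, thr, config)
}
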