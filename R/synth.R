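#' Parameters for the synthetic section-scan generator
#'
#' The generator renders H&E-like tissue-section scans with known ground
#' truth: a near-white slide background, darker pink-purple tissue blobs with
#' gentle crypt-like texture, a contiguous "witness" region of higher-frequency
#' abnormal texture in abnormal scans, and pen-mark / air-bubble artifacts.
#' Defaults reproduce a realistic study regime: 25 patients, ~41% abnormal
#' sections, phenotype prevalences of 87.3% (active inflammation) and 79.5%
#' (chronic changes) among abnormal sections, and a witness region covering
#' 60% of the tissue so that majority-style section aggregation is satisfiable
#' on truly abnormal scans.
#'
#' @param seed Integer seed; the same seed yields bit-identical cohorts.
#' @param n_patients Number of patients.
#' @param scans_per_patient Section scans per patient.
#' @param scan_width_range,scan_height_range Two-element pixel ranges the scan
#'   dimensions are drawn from.
#' @param background_level Mean slide-background gray level (0-255).
#' @param tissue_blob_count Number of elliptical tissue fragments per scan.
#' @param abnormal_scan_fraction Probability a scan is abnormal.
#' @param phenotype_probs Named probabilities of `active_inflammation` and
#'   `chronic_changes` conditional on the scan being abnormal (phenotypes are
#'   not mutually exclusive).
#' @param witness_fraction Fraction of the tissue area carrying abnormal
#'   texture in an abnormal scan.
#' @param artifact_density Target fraction of scan area covered by artifacts.
#' @param noise_sd Gaussian pixel-noise standard deviation (gray levels).
#' @return A `synth_params` object.
#' @export
synth_params <- function(seed = 1L,
                         n_patients = 25L,
                         scans_per_patient = 4L,
                         scan_width_range = c(1024L, 2048L),
                         scan_height_range = c(1024L, 2048L),
                         background_level = 247,
                         tissue_blob_count = 3L,
                         abnormal_scan_fraction = 0.412,
                         phenotype_probs = c(active_inflammation = 0.873,
                                             chronic_changes = 0.795),
                         witness_fraction = 0.6,
                         artifact_density = 0.01,
                         noise_sd = 3) {
  props <- c(abnormal_scan_fraction, phenotype_probs, witness_fraction,
             artifact_density)
  assert_that(all(props >= 0 & props <= 1), "all proportions must be in [0, 1]")
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  assert_that(scans_per_patient >= 1, "scans_per_patient must be >= 1")
  assert_that(all(scan_width_range >= 1) && all(scan_height_range >= 1) &&
                diff(scan_width_range) >= 0 && diff(scan_height_range) >= 0,
              "scan dimension ranges must be positive and non-decreasing")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(all(c("active_inflammation", "chronic_changes") %in%
                    names(phenotype_probs)),
              "phenotype_probs must name active_inflammation and chronic_changes")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 scans_per_patient = as.integer(scans_per_patient),
                 scan_width_range = as.integer(scan_width_range),
                 scan_height_range = as.integer(scan_height_range),
                 background_level = background_level,
                 tissue_blob_count = as.integer(tissue_blob_count),
                 abnormal_scan_fraction = abnormal_scan_fraction,
                 phenotype_probs = phenotype_probs,
                 witness_fraction = witness_fraction,
                 artifact_density = artifact_density,
                 noise_sd = noise_sd),
            class = "synth_params")
}

# ---- rendering primitives ----------------------------------------------

# Random rotated ellipse mask with a wobbly boundary; X/Y are coordinate
# matrices (columns = x, rows = y).
ellipse_mask <- function(X, Y, cx, cy, rx, ry, theta, wobble = 0.35) {
  h <- nrow(X); w <- ncol(X)
  # evaluate only inside the ellipse's bounding window
  rmax <- max(rx, ry) * (1 + wobble) + 2
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(h, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(w, ceiling(cx + rmax))
  out <- matrix(FALSE, h, w)
  if (r0 > r1 || c0 > c1) return(out)
  Xs <- X[r0:r1, c0:c1]; Ys <- Y[r0:r1, c0:c1]
  ct <- cos(theta); st <- sin(theta)
  Xr <- (Xs - cx) * ct + (Ys - cy) * st
  Yr <- -(Xs - cx) * st + (Ys - cy) * ct
  r2 <- (Xr / rx)^2 + (Yr / ry)^2
  wn <- value_noise(nrow(Xs), ncol(Xs), cell = max(24, round(min(rx, ry) / 2)))
  out[r0:r1, c0:c1] <- r2 < 1 + wobble * (wn - 0.5) * 2
  out
}

segment_mask <- function(X, Y, x1, y1, x2, y2, thick) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- clip01(((X - x1) * vx + (Y - y1) * vy) / max(len2, 1e-9))
  d2 <- (X - (x1 + t * vx))^2 + (Y - (y1 + t * vy))^2
  d2 < thick^2
}

# Paint tissue colouring onto an RGB array at masked pixels.
paint <- function(img, mask, r, g, b) {
  img[, , 1][mask] <- r[mask]
  img[, , 2][mask] <- g[mask]
  img[, , 3][mask] <- b[mask]
  img
}

darken <- function(img, mask, factor, blue_shift = 0) {
  for (c in 1:3) {
    f <- factor + if (c == 3) blue_shift else 0
    ch <- img[, , c]
    ch[mask] <- ch[mask] * f
    img[, , c] <- ch
  }
  img
}

# Spot texture mask (dense dark dots - an active-inflammation-like signal).
spot_mask <- function(h, w) value_noise(h, w, cell = 3) > 0.72

# Oriented ridge texture mask (a chronic-changes-like signal).
ridge_mask <- function(h, w, X, Y, theta, period = 14) {
  ph <- 4 * value_noise(h, w, cell = 32)
  sin(2 * pi * (X * cos(theta) + Y * sin(theta)) / period + ph) > 0.25
}

# Mid-frequency mottle (generic abnormality with neither phenotype).
mottle_mask <- function(h, w) value_noise(h, w, cell = 6) > 0.62

draw_labels <- function(params) {
  abnormal <- runif(1) < params$abnormal_scan_fraction
  ai <- abnormal && runif(1) < params$phenotype_probs[["active_inflammation"]]
  cc <- abnormal && runif(1) < params$phenotype_probs[["chronic_changes"]]
  gr <- abnormal && runif(1) < 0.078
  list(abnormal = abnormal, active_inflammation = ai,
       chronic_changes = cc, granuloma = gr)
}

# ---- scan generation ----------------------------------------------------

#' Generate one synthetic section scan with ground truth
#'
#' Deterministic given `(params$seed, patient_id, scan_id, labels)`: the
#' per-scan RNG stream is derived from those values, so a scan regenerated
#' standalone is bit-identical to the one produced inside [generate_cohort()].
#'
#' @param params A [synth_params()] object.
#' @param patient_id,scan_id Integer identifiers.
#' @param labels Optional list with logical `abnormal`,
#'   `active_inflammation`, `chronic_changes` (and optionally `granuloma`).
#'   Drawn from `params` when `NULL`.
#' @return A list with `image` (`H x W x 3` array, 0-255), `truth` (list of
#'   `tissue_mask`, `abnormal_mask`, `artifact_mask`, `labels`), and the ids.
#' @export
generate_section_scan <- function(params, patient_id, scan_id, labels = NULL) {
  assert_that(inherits(params, "synth_params"), "params must be synth_params")
  seed <- derive_seed(params$seed, patient_id, scan_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  if (is.null(labels)) labels <- draw_labels(params)
  labels$granuloma <- labels$granuloma %||% FALSE
  if (!labels$abnormal) labels$active_inflammation <- labels$chronic_changes <- FALSE

  w <- if (diff(params$scan_width_range) == 0) params$scan_width_range[1] else
    sample(params$scan_width_range[1]:params$scan_width_range[2], 1)
  h <- if (diff(params$scan_height_range) == 0) params$scan_height_range[1] else
    sample(params$scan_height_range[1]:params$scan_height_range[2], 1)

  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)

  img <- array(params$background_level, c(h, w, 3))

  # tissue fragments
  tissue <- matrix(FALSE, h, w)
  for (k in seq_len(params$tissue_blob_count)) {
    rx <- runif(1, 0.14, 0.30) * min(h, w)
    ry <- runif(1, 0.14, 0.30) * min(h, w)
    cx <- runif(1, 0.22, 0.78) * w
    cy <- runif(1, 0.22, 0.78) * h
    tissue <- tissue | ellipse_mask(X, Y, cx, cy, rx, ry, runif(1, 0, pi))
  }

  lum_mod <- 0.80 + 0.35 * value_noise(h, w, cell = 24)
  lum_mod[value_noise(h, w, cell = 10) > 0.82] <- 1.35 # pale crypt lumina
  tix <- which(tissue)
  fv <- lum_mod[tix]
  base <- c(208, 148, 186) # H&E pink-purple; capped below background white
  hw <- as.numeric(h) * w
  for (c in 1:3) img[tix + (c - 1) * hw] <- pmin(base[c] * fv, 238)

  # witness region of abnormal texture
  abnormal_mask <- matrix(FALSE, h, w)
  if (labels$abnormal && any(tissue)) {
    t_area <- sum(tissue)
    target <- params$witness_fraction * t_area
    centers <- which(tissue)
    ci <- centers[sample.int(length(centers), 1)]
    cy0 <- ((ci - 1) %% h) + 1
    cx0 <- ((ci - 1) %/% h) + 1
    r0 <- sqrt(target / pi)
    wm <- ellipse_mask(X, Y, cx0, cy0, r0, r0, 0, wobble = 0.25) & tissue
    tries <- 0 # grow the disc until its tissue intersection reaches the target
    while (sum(wm) < 0.94 * target && tries < 5) {
      tries <- tries + 1
      r0 <- r0 * min(sqrt(target / max(sum(wm), 1)), 1.8)
      wm <- ellipse_mask(X, Y, cx0, cy0, r0, r0, 0, wobble = 0.25) & tissue
    }
    if (!any(wm)) wm[cy0, cx0] <- TRUE
    abnormal_mask <- wm

    # texture fields only need the witness bounding box
    rows <- range(which(rowSums(abnormal_mask) > 0))
    cols <- range(which(colSums(abnormal_mask) > 0))
    bh <- rows[2] - rows[1] + 1
    bw <- cols[2] - cols[1] + 1
    texb <- matrix(FALSE, bh, bw)
    if (labels$active_inflammation) texb <- texb | spot_mask(bh, bw)
    if (labels$chronic_changes)
      texb <- texb | ridge_mask(bh, bw, X[rows[1]:rows[2], cols[1]:cols[2]],
                                Y[rows[1]:rows[2], cols[1]:cols[2]],
                                theta = runif(1, 0, pi))
    if (!labels$active_inflammation && !labels$chronic_changes)
      texb <- mottle_mask(bh, bw)
    tex <- matrix(FALSE, h, w)
    tex[rows[1]:rows[2], cols[1]:cols[2]] <- texb
    aix <- which(abnormal_mask & tex)
    for (c in 1:3) {
      f <- 0.42 + if (c == 3) 0.10 else 0
      img[aix + (c - 1) * hw] <- img[aix + (c - 1) * hw] * f
    }
  }

  # artifacts: opaque pen strokes and bright air-bubble rings, each
  # rendered inside its own bounding window
  artifact_mask <- matrix(FALSE, h, w)
  sub_flat <- function(mask_sub, r0, c0) { # flat indices into the h x w plane
    ij <- which(mask_sub, arr.ind = TRUE)
    (ij[, 2] + c0 - 2) * h + (ij[, 1] + r0 - 1)
  }
  if (params$artifact_density > 0) {
    target <- params$artifact_density * hw
    pens <- list(c(35, 130, 60), c(45, 60, 160), c(35, 35, 35))
    n_art <- 0
    tries <- 0
    while (n_art < target && tries < 40) {
      tries <- tries + 1
      if (tries %% 2 == 1) { # pen stroke
        x1 <- runif(1, 0, w); y1 <- runif(1, 0, h)
        ang <- runif(1, 0, 2 * pi); len <- runif(1, 0.25, 0.6) * min(h, w)
        x2 <- x1 + len * cos(ang); y2 <- y1 + len * sin(ang)
        th <- runif(1, 3.5, 7)
        r0 <- max(1, floor(min(y1, y2) - th)); r1 <- min(h, ceiling(max(y1, y2) + th))
        c0 <- max(1, floor(min(x1, x2) - th)); c1 <- min(w, ceiling(max(x1, x2) + th))
        if (r0 > r1 || c0 > c1) next
        nr <- r1 - r0 + 1; nc <- c1 - c0 + 1
        Xs <- matrix(rep(c0:c1, each = nr), nr, nc)
        Ys <- matrix(rep(r0:r1, times = nc), nr, nc)
        idx <- sub_flat(segment_mask(Xs, Ys, x1, y1, x2, y2, th), r0, c0)
        col <- pens[[sample.int(3, 1)]]
        for (c in 1:3) img[idx + (c - 1) * hw] <- col[c]
      } else { # bubble ring on the slide
        cx <- runif(1, 0.1, 0.9) * w; cy <- runif(1, 0.1, 0.9) * h
        r <- runif(1, 0.03, 0.08) * min(h, w)
        r0 <- max(1, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
        c0 <- max(1, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
        if (r0 > r1 || c0 > c1) next
        nr <- r1 - r0 + 1; nc <- c1 - c0 + 1
        Xs <- matrix(rep(c0:c1, each = nr), nr, nc)
        Ys <- matrix(rep(r0:r1, times = nc), nr, nc)
        d <- sqrt((Xs - cx)^2 + (Ys - cy)^2)
        idx_in <- sub_flat(d <= 0.82 * r, r0, c0)
        idx_rim <- sub_flat(d < r & d > 0.82 * r, r0, c0)
        for (c in 1:3) {
          off <- (c - 1) * hw
          img[idx_in + off] <- 0.35 * img[idx_in + off] + 0.65 * 252
          img[idx_rim + off] <- 120
        }
        idx <- c(idx_in, idx_rim)
      }
      new_idx <- idx[!artifact_mask[idx]]
      artifact_mask[new_idx] <- TRUE
      n_art <- n_art + length(new_idx)
    }
  }

  img <- clip255(img + array(rnorm(h * w * 3, 0, params$noise_sd), c(h, w, 3)))
  img <- round(img)

  truth <- list(tissue_mask = tissue, abnormal_mask = abnormal_mask,
                artifact_mask = artifact_mask,
                labels = labels[c("abnormal", "active_inflammation",
                                  "chronic_changes", "granuloma")])
  list(image = img, truth = truth,
       patient_id = patient_id, scan_id = scan_id,
       width = w, height = h)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort with manifest
#'
#' Draws section labels per scan under `params$seed`, renders each scan under
#' a derived per-scan seed, and assembles the study manifest (scan, slide,
#' patient, biopsy site, labels). Phenotype and abnormality rates follow
#' `params`; granuloma is recorded in the manifest but never modeled.
#'
#' @param params A [synth_params()] object.
#' @param keep_images Keep rendered images (and truth masks) in memory. Set
#'   `FALSE` for large cohorts; scans can be regenerated on demand from the
#'   manifest via [generate_section_scan()] because rendering is
#'   deterministic.
#' @param scan_dir Optional directory: when given, scans are written as PNG
#'   (`<scan_id>.png`) plus single-channel mask PNGs and a `manifest.csv`.
#' @return A `synth_cohort` list: `manifest` (tibble), `scans` (named list of
#'   scan objects, empty when `keep_images = FALSE`), `params`.
#' @examples
#' co <- generate_cohort(synth_params(seed = 7, n_patients = 2,
#'   scans_per_patient = 1, scan_width_range = c(256, 320),
#'   scan_height_range = c(256, 320)))
#' co$manifest
#' @export
generate_cohort <- function(params, keep_images = TRUE, scan_dir = NULL) {
  assert_that(inherits(params, "synth_params"), "params must be synth_params")
  assert_that(params$n_patients > 0, "n_patients must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  sites <- c("duodenum", "stomach", "esophagus", "ileum", "cecum", "colon", "rectum")
  rows <- list()
  scans <- list()
  idx <- 0
  for (p in seq_len(params$n_patients)) {
    for (s in seq_len(params$scans_per_patient)) {
      idx <- idx + 1
      labels <- draw_labels(params)
      site <- sites[sample.int(length(sites), 1)]
      rows[[idx]] <- tibble::tibble(
        scan_id = sprintf("P%02d_T%02d", p, s),
        patient_id = sprintf("P%02d", p),
        slide_id = sprintf("P%02d_SL%d", p, ceiling(s / 3)),
        site = site,
        patient_num = p, scan_num = s,
        abnormal = labels$abnormal,
        active_inflammation = labels$active_inflammation && labels$abnormal,
        chronic_changes = labels$chronic_changes && labels$abnormal,
        granuloma = labels$granuloma && labels$abnormal
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)

  if (keep_images || !is.null(scan_dir)) {
    for (i in seq_len(nrow(manifest))) {
      r <- manifest[i, ]
      sc <- generate_section_scan(params, r$patient_num, r$scan_num,
                                  labels = list(abnormal = r$abnormal,
                                                active_inflammation = r$active_inflammation,
                                                chronic_changes = r$chronic_changes,
                                                granuloma = r$granuloma))
      if (!is.null(scan_dir)) {
        dir.create(scan_dir, recursive = TRUE, showWarnings = FALSE)
        write_scan_png(sc$image, file.path(scan_dir, paste0(r$scan_id, ".png")))
        write_mask_png(sc$truth$tissue_mask,
                       file.path(scan_dir, paste0(r$scan_id, "_tissue.png")))
        write_mask_png(sc$truth$abnormal_mask,
                       file.path(scan_dir, paste0(r$scan_id, "_abnormal.png")))
        write_mask_png(sc$truth$artifact_mask,
                       file.path(scan_dir, paste0(r$scan_id, "_artifact.png")))
      }
      if (keep_images) scans[[r$scan_id]] <- sc
    }
  }
  if (!is.null(scan_dir))
    utils::write.csv(manifest[, c("scan_id", "patient_id", "slide_id", "site",
                                  "abnormal", "active_inflammation",
                                  "chronic_changes", "granuloma")],
                     file.path(scan_dir, "manifest.csv"), row.names = FALSE)
  structure(list(manifest = manifest, scans = scans, params = params),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synth_cohort> %d scans / %d patients; %.0f%% abnormal; images %s\n",
              nrow(m), dplyr::n_distinct(m$patient_id),
              100 * mean(m$abnormal),
              if (length(x$scans)) "in memory" else "regenerable on demand"))
  invisible(x)
}

#' Permute section labels to build a zero-signal null cohort
#'
#' Jointly permutes the label columns of a manifest across scans, breaking
#' any association between rendered texture and label while preserving the
#' marginal class balance. Used as a leakage control: cross-validating on a
#' permuted cohort must give chance-level metrics.
#'
#' @param manifest Cohort manifest tibble.
#' @param seed Integer seed for the permutation.
#' @return Manifest with permuted `abnormal`/phenotype columns.
#' @export
permute_manifest_labels <- function(manifest, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample(nrow(manifest))
  cols <- c("abnormal", "active_inflammation", "chronic_changes", "granuloma")
  cols <- intersect(cols, names(manifest))
  manifest[, cols] <- manifest[perm, cols]
  manifest
}

# ---- QC training fixtures ----------------------------------------------

render_qc_tile <- function(kind, size, params) {
  h <- w <- size
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  img <- array(params$background_level, c(h, w, 3))
  tissue_fill <- function(img) {
    lum <- 0.80 + 0.35 * value_noise(h, w, cell = max(4, size %/% 5))
    all_m <- matrix(TRUE, h, w)
    paint(img, all_m, clip255(208 * lum), clip255(148 * lum), clip255(186 * lum))
  }
  if (kind == "background") {
    # nothing to add
  } else if (kind == "tissue_edge") {
    # tissue occupies one side of the tile, as at a fragment boundary;
    # keeps the filter from rejecting partial-tissue patches as background
    f <- runif(1, 0.25, 0.6)
    lum <- 0.80 + 0.35 * value_noise(h, w, cell = max(4, size %/% 5))
    edge <- X <= f * w + (value_noise(h, w, cell = max(4, size %/% 4)) - 0.5) * 0.3 * w
    img <- paint(img, edge, clip255(208 * lum), clip255(148 * lum), clip255(186 * lum))
  } else if (kind == "bubble") {
    cx <- runif(1, 0.3, 0.7) * w; cy <- runif(1, 0.3, 0.7) * h
    r <- runif(1, 0.25, 0.45) * size
    d <- sqrt((X - cx)^2 + (Y - cy)^2)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[d < r & d > 0.82 * r] <- 120
      img[, , c] <- ch
    }
  } else if (kind == "pen_tissue") {
    img <- tissue_fill(img)
    col <- list(c(35, 130, 60), c(45, 60, 160), c(35, 35, 35))[[sample.int(3, 1)]]
    m <- segment_mask(X, Y, runif(1, 0, 0.3) * w, runif(1, 0, h),
                      runif(1, 0.7, 1) * w, runif(1, 0, h),
                      thick = runif(1, 0.2, 0.4) * size)
    for (c in 1:3) { ch <- img[, , c]; ch[m] <- col[c]; img[, , c] <- ch }
  } else if (kind == "tissue") {
    img <- tissue_fill(img)
  } else if (kind == "tissue_abnormal") {
    img <- tissue_fill(img)
    tex <- if (runif(1) < 0.5) spot_mask(h, w) else
      ridge_mask(h, w, X, Y, theta = runif(1, 0, pi), period = max(6, size %/% 9))
    img <- darken(img, tex, 0.42, blue_shift = 0.10)
  }
  round(clip255(img + array(rnorm(h * w * 3, 0, params$noise_sd), c(h, w, 3))))
}

#' Labeled patches for training the artifact/background filter
#'
#' Builds a balanced training set by rendering small synthetic scans (with
#' artifacts), tiling them exactly as the pipeline does, and labeling each
#' patch from the ground-truth masks: the reject class is patches dominated
#' by pen/bubble artifacts or bare slide background, the usable class is
#' patches with real tissue (normal or abnormal texture, including fragment
#' edges) and no meaningful artifact overlap. Ambiguous patches between the
#' class definitions are excluded. Training on pipeline-identical patches
#' keeps the filter's decision boundary aligned with what it will see.
#'
#' @param params A [synth_params()]; rendering style is reused, scan sizes
#'   are reduced internally and artifact density is raised so both classes
#'   appear quickly.
#' @param n_per_class Patches per class.
#' @param size Resized patch side length in pixels (pipeline `resize_to`).
#' @param seed Integer seed.
#' @param patch_size Native tile size used for the QC scans.
#' @return Tibble with list-column `pixels`, integer `label`
#'   (1 = artifact/background, 0 = usable tissue), and `kind`.
#' @export
synth_qc_training_set <- function(params = synth_params(), n_per_class = 60,
                                  size = 32, seed = 1L, patch_size = 128) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  qp <- params
  qp$seed <- derive_seed(seed, "qc_scans")
  qp$scan_width_range <- qp$scan_height_range <- c(640L, 832L)
  qp$artifact_density <- max(params$artifact_density, 0.03)
  grid <- grid_spec(patch_size = patch_size, overlap = 0.25, resize_to = size)
  pos <- list(); neg <- list(); pos_kind <- character(); neg_kind <- character()
  pos_tis <- numeric(); neg_tis <- numeric()
  pos_art <- numeric(); neg_art <- numeric()
  s <- 0
  while ((length(pos) < n_per_class || length(neg) < n_per_class) && s < 16) {
    s <- s + 1
    sc <- generate_section_scan(qp, 1, s,
                                labels = list(abnormal = s %% 2 == 0,
                                              active_inflammation = s %% 4 == 0,
                                              chronic_changes = s %% 4 == 2,
                                              granuloma = FALSE))
    tiled <- tile_scan(sc$image, paste0("qc", s), grid)
    for (i in seq_len(nrow(tiled))) {
      ys <- (tiled$origin_y[i] + 1):min(nrow(sc$image), tiled$origin_y[i] + patch_size)
      xs <- (tiled$origin_x[i] + 1):min(ncol(sc$image), tiled$origin_x[i] + patch_size)
      art <- mean(sc$truth$artifact_mask[ys, xs])
      tis <- mean(sc$truth$tissue_mask[ys, xs])
      if (art > 0.10 || (tis < 0.02 && art < 0.02)) {
        if (length(pos) < n_per_class) {
          pos[[length(pos) + 1]] <- tiled$pixels[[i]]
          pos_kind <- c(pos_kind, if (art > 0.10) "artifact" else "background")
          pos_tis <- c(pos_tis, tis); pos_art <- c(pos_art, art)
        }
      } else if (art < 0.02 && tis >= 0.15) {
        if (length(neg) < n_per_class) {
          neg[[length(neg) + 1]] <- tiled$pixels[[i]]
          neg_kind <- c(neg_kind, "tissue")
          neg_tis <- c(neg_tis, tis); neg_art <- c(neg_art, art)
        }
      } # else ambiguous: excluded
    }
  }
  tibble::tibble(
    kind = c(pos_kind, neg_kind),
    label = rep(c(1L, 0L), c(length(pos), length(neg))),
    tissue_frac = c(pos_tis, neg_tis),
    artifact_frac = c(pos_art, neg_art),
    pixels = c(pos, neg)
  )
}

#' Labeled texture tiles (normal vs abnormal tissue)
#'
#' Renders full-tissue tiles with and without abnormal texture (dense spots
#' or oriented ridges), a separable-by-construction fixture for exercising
#' the patch classifier and Grad-CAM.
#'
#' @param params A [synth_params()].
#' @param n_per_class Tiles per class.
#' @param size Tile side length in pixels.
#' @param seed Integer seed.
#' @return Tibble with `kind`, `label` (1 = abnormal texture), `pixels`.
#' @export
synth_texture_patches <- function(params = synth_params(), n_per_class = 60,
                                  size = 32, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  kinds <- sample(rep(c("tissue", "tissue_abnormal"), each = n_per_class))
  tibble::tibble(
    kind = kinds,
    label = as.integer(kinds == "tissue_abnormal"),
    pixels = lapply(kinds, render_qc_tile, size = size, params = params)
  )
}

# ---- image IO -----------------------------------------------------------

#' Read and write section scans as PNG
#'
#' Thin wrappers over EBImage converting between this package's `H x W x 3`
#' 0-255 arrays (rows = y) and EBImage's `[x, y, channel]` 0-1 layout.
#'
#' @param scan `H x W x 3` array of 0-255 intensities.
#' @param path File path.
#' @return `read_scan_png` returns an `H x W x 3` array of 0-255 values.
#' @export
write_scan_png <- function(scan, path) {
  img <- EBImage::Image(aperm(scan, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @rdname write_scan_png
#' @export
read_scan_png <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  round(aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255)
}

write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path)
  invisible(path)
}
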