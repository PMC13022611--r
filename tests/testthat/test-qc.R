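test_that("Otsu threshold maximizes between-class variance (exhaustive oracle)", {
  # independent oracle: try all 255 split points directly
  otsu_oracle <- function(v) {
    v <- pmin(pmax(round(v), 0), 255)
    best <- -1; best_t <- 0
    for (t in 0:254) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (!length(lo) || !length(hi)) next
      sb <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
      if (sb > best) { best <- sb; best_t <- t }
    }
    best_t + 1
  }
  set.seed(81)
  for (i in 1:20) {
    v <- c(rnorm(300, runif(1, 30, 100), 12), rnorm(300, runif(1, 150, 230), 12))
    expect_equal(otsu_threshold(v), otsu_oracle(v))
  }
  thr <- otsu_threshold(c(rep(50, 100), rep(200, 100)))
  expect_true(thr > 50 && thr <= 200)
  expect_equal(otsu_threshold(rep(77, 10)), 77)
  expect_error(otsu_threshold(numeric()), "empty")
})

test_that("tissue fraction is a padding-aware dark-pixel count", {
  white <- array(255, c(10, 10, 3))
  expect_equal(tissue_fraction(white, 128), 0)

  half <- array(250, c(10, 10, 3))
  half[1:5, , ] <- 10
  expect_equal(tissue_fraction(half, 128), 0.5)

  # permuting pixel positions does not change the fraction
  set.seed(82)
  px <- array(sample(c(10, 250), 300, replace = TRUE), c(10, 10, 3))
  perm <- sample(100)
  px_perm <- array(0, c(10, 10, 3))
  for (c in 1:3) px_perm[, , c] <- matrix(as.vector(px[, , c])[perm], 10, 10)
  expect_equal(tissue_fraction(px, 128), tissue_fraction(px_perm, 128))

  # fully padded patch has fraction 0 by definition
  pad_all <- matrix(TRUE, 10, 10)
  expect_equal(tissue_fraction(array(0, c(10, 10, 3)), 128, pad_all), 0)

  # padding excluded from numerator and denominator
  padded <- array(10, c(10, 10, 3))
  pm <- matrix(FALSE, 10, 10); pm[, 6:10] <- TRUE
  padded[, 6:10, ] <- 0
  expect_equal(tissue_fraction(padded, 128, pm), 1)
})

test_that("the 20% tissue rule is strict at the boundary", {
  mk <- function(n_dark) {
    px <- array(250, c(10, 10, 3))
    for (c in 1:3) { ch <- matrix(250, 10, 10); ch[seq_len(n_dark)] <- 20
                     px[, , c] <- ch }
    tibble::tibble(scan_id = "s", qc_status = "retained",
                   pixels = list(px), pad_mask = list(NULL))
  }
  res19 <- apply_tissue_filter(mk(19), threshold = 128)
  expect_equal(res19$patches$tissue_fraction, 0.19)
  expect_equal(res19$patches$qc_status, "low_tissue_rejected")

  res21 <- apply_tissue_filter(mk(21), threshold = 128)
  expect_equal(res21$patches$qc_status, "retained")

  res0 <- apply_tissue_filter(mk(19), threshold = 128,
                              config = qc_config(min_tissue_fraction = 0))
  expect_equal(res0$patches$qc_status, "retained")
})

test_that("artifact filter training demands two classes and separates them", {
  s <- synth_qc_training_set(fx_params(), n_per_class = 40, size = 32, seed = 44)
  expect_error(train_artifact_filter(s[s$label == 1, ]), "class")
  expect_error(train_artifact_filter(s[0, ]), "empty")

  am <- fx_artifact_filter()
  # separable-by-construction held-out set: pure slide vs solid tissue
  held <- synth_qc_training_set(fx_params(), n_per_class = 40, size = 32, seed = 45)
  held <- held[(held$kind == "background" & held$tissue_frac == 0) |
                 (held$kind == "tissue" & held$tissue_frac > 0.6), ]
  acc <- mean((predict_patches(am, held$pixels) > 0.5) == (held$label == 1))
  expect_gte(acc, 0.95)
})

test_that("artifact filter training is reproducible under its seed", {
  s <- synth_qc_training_set(fx_params(), n_per_class = 20, size = 32, seed = 46)
  cfg <- fx_quick_cnn(seed = 7L, max_epochs = 2, patience = 1)
  a <- train_artifact_filter(s, config = cfg)
  b <- train_artifact_filter(s, config = cfg)
  expect_identical(a$history$val_loss, b$history$val_loss)
})

test_that("artifact thresholds behave as strict cutoffs and preserve order", {
  am <- fx_artifact_filter()
  # constructed fixture: 10 bare-slide tiles then 10 full-tissue tiles
  set.seed(47)
  bg <- lapply(1:10, function(i)
    array(pmin(pmax(rnorm(32 * 32 * 3, 247, 3), 0), 255), c(32, 32, 3)))
  ts <- synth_texture_patches(fx_params(), n_per_class = 5, size = 32,
                              seed = 48)$pixels
  patches <- tibble::tibble(scan_id = "s", qc_status = "retained",
                            pixels = c(bg, ts),
                            pad_mask = rep(list(NULL), 20))
  none <- apply_artifact_filter(patches, am, qc_config(artifact_threshold = 1))
  expect_true(all(none$qc_status == "retained"))
  all_r <- apply_artifact_filter(patches, am, qc_config(artifact_threshold = 0))
  expect_true(all(all_r$qc_status[all_r$artifact_prob > 0] == "artifact_rejected"))

  flt <- apply_artifact_filter(patches, am)
  expect_identical(flt$pixels, patches$pixels) # order preserved
  # the known background tiles are exactly the rejected ones
  expect_equal(which(flt$qc_status == "artifact_rejected"), 1:10)
})

test_that("QC statuses partition the patch set and match the mask oracle", {
  sc <- fx_clean_scan()
  g <- fx_grid()
  tiled <- tile_scan(sc$image, "clean", g)
  qc <- qc_scan_patches(tiled, sc$image, fx_artifact_filter())
  p <- qc$patches

  expect_equal(qc$report$retained + qc$report$artifact_rejected +
                 qc$report$low_tissue_rejected, nrow(p))

  # oracle: native-resolution tissue coverage from the ground-truth mask
  truth_frac <- vapply(seq_len(nrow(p)), function(i) {
    ys <- (p$origin_y[i] + 1):min(nrow(sc$image), p$origin_y[i] + g$patch_size)
    xs <- (p$origin_x[i] + 1):min(ncol(sc$image), p$origin_x[i] + g$patch_size)
    sum(sc$truth$tissue_mask[ys, xs]) / (length(ys) * length(xs))
  }, 0)
  oracle_keep <- truth_frac >= 0.2
  got_keep <- p$qc_status == "retained"
  agreement <- mean(oracle_keep == got_keep)
  expect_gte(agreement, 0.95)
})

test_that("an all-background scan is emitted with zero retained patches", {
  p <- fx_params(tissue_blob_count = 0, artifact_density = 0,
                 abnormal_scan_fraction = 0)
  sc <- generate_section_scan(p, 1, 1)
  qc <- qc_scan_patches(tile_scan(sc$image, "bg", fx_grid()), sc$image,
                        fx_artifact_filter())
  expect_equal(qc$report$retained, 0L)
  expect_equal(qc$report$n_patches, nrow(qc$patches))
})
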