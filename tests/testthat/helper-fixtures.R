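# Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_params <- function(...) {
  synth_params(seed = 101, n_patients = 2, scans_per_patient = 2,
               scan_width_range = c(512, 700), scan_height_range = c(512, 700),
               ...)
}

# one abnormal scan (inflammation texture) with artifacts
fx_scan <- function() fx_memo("scan", function() {
  generate_section_scan(fx_params(), 1, 1,
                        labels = list(abnormal = TRUE, active_inflammation = TRUE,
                                      chronic_changes = FALSE, granuloma = FALSE))
})

# artifact-free abnormal scan for mask-oracle QC checks
fx_clean_scan <- function() fx_memo("clean_scan", function() {
  generate_section_scan(fx_params(artifact_density = 0), 1, 2,
                        labels = list(abnormal = TRUE, active_inflammation = TRUE,
                                      chronic_changes = TRUE, granuloma = FALSE))
})

fx_grid <- function() grid_spec(patch_size = 128, overlap = 0.25, resize_to = 32)

fx_artifact_filter <- function() fx_memo("artifact_filter", function() {
  train_artifact_filter(synth_qc_training_set(fx_params(), n_per_class = 80,
                                              size = 32, seed = 11))
})

# separable labeled patches: plain tissue (0) vs abnormal-textured tissue (1)
fx_sep_patches <- function() fx_memo("sep_patches", function() {
  synth_texture_patches(fx_params(), n_per_class = 130, size = 32, seed = 21)
})

fx_quick_cnn <- function(seed = 5L, max_epochs = 7, patience = 6, ...) {
  cnn_config(input_size = 32, filters = c(8, 16, 32, 64), dense_units = 64,
             learning_rate = 1e-3, max_epochs = max_epochs, patience = patience,
             batch_size = 8, seed = seed, ...)
}

# CNN trained on the separable fixture (train/test split inside)
fx_sep_model <- function() fx_memo("sep_model", function() {
  s <- fx_sep_patches()
  set.seed(31)
  n <- nrow(s)
  test_ix <- sort(sample(n, round(0.3 * n)))
  tr <- setdiff(seq_len(n), test_ix)
  val_ix <- tr[seq(1, length(tr), by = 4)]
  tr <- setdiff(tr, val_ix)
  model <- build_model(fx_quick_cnn())
  model <- fit_patch_cnn(model, s$pixels[tr], s$label[tr],
                         s$pixels[val_ix], s$label[val_ix], task = "abnormal")
  list(model = model, test_ix = test_ix, data = s)
})

# independent brute-force tiling oracle: walk origins until coverage
oracle_axis_origins <- function(extent, ps, stride) {
  o <- 0
  origins <- 0
  while (o + ps < extent) {
    o <- o + stride
    origins <- c(origins, o)
  }
  origins
}

# local vertical-gradient contrast within a mask
local_contrast <- function(gray, mask) {
  d <- abs(gray[-1, ] - gray[-nrow(gray), ])
  m <- mask[-1, ] & mask[-nrow(gray), ]
  mean(d[m])
}

# closed-form bilinear sample of the ramp value a + b*(0-based column index)
# at each output column's half-pixel-centre source coordinate
resize_bilinear_oracle_cols <- function(a, b, from, to) {
  vapply(seq_len(to), function(j) {
    src <- (j - 0.5) * (from / to) - 0.5
    src <- min(max(src, 0), from - 1)
    a + b * src
  }, 0)
}
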