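test_that("grid spec derives the stride and validates inputs", {
  g <- grid_spec()
  expect_equal(g$stride, 3072L)
  expect_equal(grid_spec(128, 0.25)$stride, 96L)
  expect_error(grid_spec(overlap = 1), "overlap")
  expect_error(grid_spec(patch_size = 0), "patch_size")
})

test_that("known grids: single tile, 3x3 with padding, and the large-scan case", {
  g <- grid_spec()
  expect_equal(nrow(compute_patch_grid(4096, 4096, g)), 1L)
  one <- compute_patch_grid(4096, 4096, g)
  expect_equal(unlist(one[1, ]), c(origin_x = 0L, origin_y = 0L,
                                   padded_right = 0L, padded_bottom = 0L))

  nine <- compute_patch_grid(8192, 8192, g)
  expect_equal(nrow(nine), 9L)
  expect_equal(sort(unique(nine$origin_x)), c(0L, 3072L, 6144L))
  expect_equal(unique(nine$padded_right[nine$origin_x == 6144]), 2048L)

  # a scan at the grid's working scale for very large slides
  expect_equal(nrow(compute_patch_grid(28416, 28928, g)), 90L)

  expect_error(compute_patch_grid(0, 100, g), "positive")
})

test_that("grid matches brute-force origin enumeration for random dimensions", {
  g <- grid_spec()
  set.seed(71)
  for (i in 1:500) {
    w <- sample(1:20000, 1)
    h <- sample(1:20000, 1)
    pg <- compute_patch_grid(w, h, g)
    ox <- oracle_axis_origins(w, g$patch_size, g$stride)
    oy <- oracle_axis_origins(h, g$patch_size, g$stride)
    expect_identical(sort(unique(pg$origin_x)), as.integer(ox))
    expect_identical(sort(unique(pg$origin_y)), as.integer(oy))
    expect_equal(nrow(pg), length(ox) * length(oy))
  }
})

test_that("grid is row-major with consecutive origins one stride apart", {
  g <- grid_spec()
  pg <- compute_patch_grid(10000, 7000, g)
  nx <- length(unique(pg$origin_x))
  expect_equal(pg$origin_x[1:nx], sort(unique(pg$origin_x))) # x fastest
  expect_true(all(diff(sort(unique(pg$origin_x))) == g$stride))
  expect_true(all(diff(sort(unique(pg$origin_y))) == g$stride))
})

test_that("every scan pixel is covered by at least one patch", {
  g <- grid_spec(patch_size = 96, overlap = 0.25, resize_to = 16)
  set.seed(72)
  for (i in 1:25) {
    w <- sample(1:2048, 1)
    h <- sample(1:2048, 1)
    pg <- compute_patch_grid(w, h, g)
    cov <- matrix(FALSE, h, w)
    for (r in seq_len(nrow(pg))) {
      ys <- (pg$origin_y[r] + 1):min(h, pg$origin_y[r] + g$patch_size)
      xs <- (pg$origin_x[r] + 1):min(w, pg$origin_x[r] + g$patch_size)
      cov[ys, xs] <- TRUE
    }
    expect_true(all(cov))
  }
})

test_that("patch count is monotone in scan dimensions", {
  g <- grid_spec()
  widths <- seq(1000, 30000, by = 2900)
  counts <- vapply(widths, function(w) nrow(compute_patch_grid(w, 5000, g)), 0)
  expect_true(all(diff(counts) >= 0))
  counts_h <- vapply(widths, function(h) nrow(compute_patch_grid(5000, h, g)), 0)
  expect_true(all(diff(counts_h) >= 0))
})

test_that("extract_patch copies in-bounds pixels and zero-fills the rest", {
  g <- grid_spec()
  set.seed(73)
  scan <- array(runif(5000 * 5000 * 3, 1, 255), c(5000, 5000, 3))

  interior <- extract_patch(scan, 0, 0, g)
  expect_identical(interior, scan[1:4096, 1:4096, ])
  expect_true(all(interior > 0)) # nothing attributable to padding

  corner <- extract_patch(scan, 3072, 3072, g)
  expect_true(all(corner[, (4096 - 2168 + 1):4096, ] == 0))
  expect_true(all(corner[(4096 - 2168 + 1):4096, , ] == 0))
  expect_identical(corner[1:1928, 1:1928, ], scan[3073:5000, 3073:5000, ])

  expect_error(extract_patch(scan, 5000, 0, g), "origin")

  const <- array(7, c(256, 256, 3))
  expect_true(all(extract_patch(const, 0, 0, grid_spec(128)) == 7))
})

test_that("bilinear resize preserves constants, identity, range, and ramps", {
  g <- grid_spec(patch_size = 128, resize_to = 32)
  const <- array(42, c(128, 128, 3))
  expect_equal(resize_patch(const, g), array(42, c(32, 32, 3)))

  ident <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(resize_patch(ident, grid_spec(32, resize_to = 32)), ident)

  rnd <- array(runif(128 * 128 * 3, 10, 90), c(128, 128, 3))
  out <- resize_patch(rnd, g)
  expect_true(min(out) >= min(rnd) - 1e-9 && max(out) <= max(rnd) + 1e-9)

  # linear ramp along columns: interior output equals the closed-form
  # bilinear evaluation at half-pixel-centre sample points
  a <- 5; b <- 1.5
  ramp <- array(rep(a + b * (0:127), each = 128), c(128, 128, 1))
  dim(ramp) <- c(128, 128, 1)
  rr <- resize_bilinear_oracle_cols(a, b, from = 128, to = 16)
  got <- wsimil:::resize_bilinear(ramp[, , 1], 16, 16)
  expect_equal(got[8, 2:15], rr[2:15], tolerance = 1e-6)
})
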