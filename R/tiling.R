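#' Patch-grid specification
#'
#' Defines how a section scan is subdivided into overlapping square patches.
#' The defaults mirror common whole-slide practice: 4096-px tiles with 25%
#' overlap (stride 3072) downsized to 128 x 128 for the classifier. The
#' stride is derived as `round(patch_size * (1 - overlap))`; tiles whose
#' extent runs past the scan edge are zero-padded so the entire scan is
#' covered.
#'
#' @param patch_size Side length of a square patch at native resolution, px.
#' @param overlap Fractional overlap between neighbouring patches, in `[0, 1)`.
#' @param resize_to Side length patches are bilinearly resized to before
#'   entering the classifier.
#' @return A `grid_spec` object (list with `patch_size`, `overlap`, `stride`,
#'   `resize_to`).
#' @examples
#' grid_spec()                      # slide-scale defaults
#' grid_spec(128, 0.25, 32)        # desk-scale profile for synthetic runs
#' @export
grid_spec <- function(patch_size = 4096, overlap = 0.25, resize_to = 128) {
  assert_that(is.numeric(patch_size) && patch_size >= 1, "patch_size must be >= 1")
  assert_that(is.numeric(overlap) && overlap >= 0 && overlap < 1,
              "overlap must be in [0, 1)")
  assert_that(is.numeric(resize_to) && resize_to >= 1, "resize_to must be >= 1")
  stride <- max(1L, as.integer(round(patch_size * (1 - overlap))))
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 stride = stride, resize_to = as.integer(resize_to)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> patch %d px, overlap %.0f%% (stride %d), resize to %d px\n",
              x$patch_size, 100 * x$overlap, x$stride, x$resize_to))
  invisible(x)
}

# Tile origins along one axis: 0, stride, 2*stride, ...; a single tile when
# the extent fits inside one patch, otherwise enough tiles that the last one
# reaches (possibly past) the far edge.
axis_origins <- function(extent, patch_size, stride) {
  if (extent <= patch_size) return(0L)
  n <- ceiling((extent - patch_size) / stride) + 1
  as.integer(stride * (seq_len(n) - 1))
}

#' Compute the overlapping patch grid for a scan
#'
#' Origins are 0-based with half-open extents `[origin, origin + patch_size)`,
#' returned in row-major order (rows of tiles, left to right). Tiles that
#' extend past the scan carry positive `padded_right` / `padded_bottom`
#' counts, the number of zero-filled pixel columns/rows at native resolution.
#'
#' @param width,height Scan dimensions in pixels.
#' @param grid A [grid_spec()].
#' @return A tibble with one row per patch: `origin_x`, `origin_y`,
#'   `padded_right`, `padded_bottom`.
#' @examples
#' nrow(compute_patch_grid(8192, 8192, grid_spec()))  # 9
#' @export
compute_patch_grid <- function(width, height, grid = grid_spec()) {
  assert_that(is.numeric(width) && width >= 1 && is.numeric(height) && height >= 1,
              "scan dimensions must be positive")
  xs <- axis_origins(width, grid$patch_size, grid$stride)
  ys <- axis_origins(height, grid$patch_size, grid$stride)
  g <- expand.grid(origin_x = xs, origin_y = ys) # x fastest = row-major
  tibble::tibble(
    origin_x = g$origin_x,
    origin_y = g$origin_y,
    padded_right = pmax(0L, as.integer(g$origin_x + grid$patch_size - width)),
    padded_bottom = pmax(0L, as.integer(g$origin_y + grid$patch_size - height))
  )
}

#' Extract one native-resolution patch from a scan
#'
#' Pixels outside the scan (trailing tiles) are zero-filled; in-bounds pixels
#' are copied verbatim.
#'
#' @param scan `H x W x 3` array of 0-255 intensities (rows = y, cols = x).
#' @param origin_x,origin_y 0-based tile origin.
#' @param grid A [grid_spec()].
#' @return `patch_size x patch_size x 3` array.
#' @export
extract_patch <- function(scan, origin_x, origin_y, grid = grid_spec()) {
  d <- dim(scan)
  assert_that(length(d) == 3L && d[3] == 3L, "scan must be H x W x 3")
  assert_that(origin_x >= 0 && origin_y >= 0 && origin_x < d[2] && origin_y < d[1],
              "patch origin outside scan extent")
  ps <- grid$patch_size
  out <- array(0, c(ps, ps, 3))
  nr <- min(ps, d[1] - origin_y)
  nc <- min(ps, d[2] - origin_x)
  out[seq_len(nr), seq_len(nc), ] <-
    scan[origin_y + seq_len(nr), origin_x + seq_len(nc), , drop = FALSE]
  out
}

#' Bilinearly resize a raw patch to the classifier input size
#'
#' Uses half-pixel-center sampling with edge clamping; constant inputs map to
#' the same constant and the output range never exceeds the input range.
#'
#' @param raw Square `n x n x 3` array (or `n x n` matrix).
#' @param grid A [grid_spec()]; target side is `grid$resize_to`.
#' @return `resize_to x resize_to x 3` array (or matrix).
#' @export
resize_patch <- function(raw, grid = grid_spec()) {
  d <- dim(raw)
  assert_that(d[1] == d[2], "raw patch must be square")
  resize_bilinear(raw, grid$resize_to, grid$resize_to)
}

# Resized padding mask for a tile: TRUE where the downsized pixel is mostly
# zero-fill (interpolated pad indicator > 0.5). NULL when the tile has no
# padding.
resized_pad_mask <- function(padded_right, padded_bottom, grid) {
  if (padded_right <= 0 && padded_bottom <= 0) return(NULL)
  ps <- grid$patch_size
  m <- matrix(0, ps, ps)
  if (padded_bottom > 0) m[(ps - padded_bottom + 1):ps, ] <- 1
  if (padded_right > 0) m[, (ps - padded_right + 1):ps] <- 1
  resize_bilinear(m, grid$resize_to, grid$resize_to) > 0.5
}

#' Tile a scan into resized patch records
#'
#' Runs the full tiling stage for one scan: grid computation, zero-padded
#' extraction, bilinear downsizing, and pad-mask bookkeeping. Every patch
#' starts with `qc_status = "retained"`; quality control downstream may
#' change that.
#'
#' @param scan `H x W x 3` array of 0-255 intensities.
#' @param scan_id Identifier copied into every record.
#' @param grid A [grid_spec()].
#' @return A tibble with columns `scan_id`, `origin_x`, `origin_y`,
#'   `padded_right`, `padded_bottom`, `qc_status`, and list-columns `pixels`
#'   (`resize_to^2 x 3` arrays) and `pad_mask` (logical matrix or `NULL`).
#' @export
tile_scan <- function(scan, scan_id, grid = grid_spec()) {
  specs <- compute_patch_grid(dim(scan)[2], dim(scan)[1], grid)
  n <- nrow(specs)
  pixels <- vector("list", n)
  pad_mask <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- extract_patch(scan, specs$origin_x[i], specs$origin_y[i], grid)
    pixels[[i]] <- resize_patch(raw, grid)
    pad_mask[[i]] <- resized_pad_mask(specs$padded_right[i], specs$padded_bottom[i], grid)
  }
  tibble::tibble(
    scan_id = scan_id,
    specs,
    qc_status = "retained",
    pixels = pixels,
    pad_mask = pad_mask
  )
}
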