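# Internal numeric helpers shared across modules.

# Rec. 601 luma; input array/matrix of 0-255 RGB, returns matrix of gray values.
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Deterministic 31-bit seed derived from a base seed and a couple of ids, so
# each scan / fold / stage gets an independent but reproducible RNG stream.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  })))
  h <- 0
  for (p in parts) h <- (h * 48271 + abs(p) + 1) %% 2147483647
  as.integer(h)
}

# Row-interpolation matrix for 1-D linear resampling with half-pixel centers
# (to x from): out = A %*% in. Used for bilinear patch resizing and for
# upsampling Grad-CAM maps.
resize_matrix <- function(from, to) {
  A <- matrix(0, to, from)
  if (from == to) {
    diag(A) <- 1
    return(A)
  }
  scale <- from / to
  for (i in seq_len(to)) {
    src <- (i - 0.5) * scale - 0.5
    lo <- floor(src)
    w <- src - lo
    if (lo < 0) { lo <- 0; w <- 0 }
    if (lo >= from - 1) { lo <- from - 2; w <- 1 }
    if (from == 1) { A[i, 1] <- 1; next }
    A[i, lo + 1] <- A[i, lo + 1] + (1 - w)
    A[i, lo + 2] <- A[i, lo + 2] + w
  }
  A
}

# Bilinear resize of a matrix or H x W x C array to th x tw.
resize_bilinear <- function(img, th, tw = th) {
  d <- dim(img)
  Ar <- resize_matrix(d[1], th)
  Ac <- t(resize_matrix(d[2], tw))
  if (length(d) == 2L) return(Ar %*% img %*% Ac)
  out <- array(0, c(th, tw, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Ar %*% img[, , c] %*% Ac
  out
}

# Smooth "value noise" field in [0,1]: coarse uniform grid upsampled
# bilinearly. cell is the approximate correlation length in pixels. Large
# fields go through EBImage's C resize for speed.
value_noise <- function(h, w, cell) {
  ch <- max(2L, ceiling(h / cell))
  cw <- max(2L, ceiling(w / cell))
  coarse <- matrix(runif(ch * cw), ch, cw)
  if (as.numeric(h) * w > 65536) {
    out <- EBImage::imageData(EBImage::resize(EBImage::Image(t(coarse)),
                                              w = w, h = h))
    t(out)
  } else {
    resize_bilinear(coarse, h, w)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
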