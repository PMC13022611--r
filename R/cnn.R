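#' Configuration of the patch classifier CNN
#'
#' A compact 2D CNN over RGB patches: four convolutional sets, each
#' `Conv(3x3) -> ELU -> BatchNorm -> MaxPool(2x2, stride 2) -> Dropout`,
#' followed by global max pooling, a dense layer, dropout, and a single
#' sigmoid output. Defaults follow the reference training schedule for
#' 128 x 128 x 3 patches: filters 16/32/64/128, per-set dropout
#' 0.1/0.15/0.2/0.25, L1 penalty 1e-4 on convolution kernels, dense width
#' 256 with dropout 0.3, Adam with learning rate 1e-4, binary cross-entropy,
#' batch size 4, early stopping at patience 50 within at most 300 epochs,
#' checkpointing the weights with the best validation accuracy. Inputs are
#' scaled to `[0, 1]` by division by 255; no normalization or augmentation
#' is applied.
#'
#' @param input_size Patch side length (must be divisible by 16 so four
#'   stride-2 poolings land on an integer grid).
#' @param filters Four increasing filter counts.
#' @param dropout Four per-set dropout rates in `[0, 1)`.
#' @param kernel_l1 L1 penalty on convolution kernels.
#' @param dense_units Width of the dense head.
#' @param dense_dropout Dropout after the dense layer.
#' @param learning_rate,batch_size,max_epochs,patience Training schedule.
#' @param seed Integer seed controlling weight init, shuffling and dropout.
#' @return A `cnn_config` object.
#' @export
cnn_config <- function(input_size = 128, filters = c(16, 32, 64, 128),
                       dropout = c(0.1, 0.15, 0.2, 0.25), kernel_l1 = 1e-4,
                       dense_units = 256, dense_dropout = 0.3,
                       learning_rate = 1e-4, batch_size = 4,
                       max_epochs = 300, patience = 50, seed = 1L) {
  assert_that(input_size %% 16 == 0, "input_size must be divisible by 16")
  assert_that(length(filters) == 4 && all(diff(filters) > 0),
              "filters must be 4 strictly increasing counts")
  assert_that(length(dropout) == 4 && all(dropout >= 0 & dropout < 1),
              "dropout rates must be in [0, 1)")
  assert_that(dense_dropout >= 0 && dense_dropout < 1, "dense_dropout in [0,1)")
  assert_that(patience < max_epochs, "patience must be < max_epochs")
  assert_that(batch_size >= 1 && learning_rate > 0, "invalid schedule")
  structure(list(input_size = as.integer(input_size),
                 filters = as.integer(filters), dropout = dropout,
                 kernel_l1 = kernel_l1, dense_units = as.integer(dense_units),
                 dense_dropout = dense_dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    "<cnn_config> input %dx%dx3; filters %s; dense %d; lr %g; batch %d; epochs <= %d (patience %d)\n",
    x$input_size, x$input_size, paste(x$filters, collapse = "/"),
    x$dense_units, x$learning_rate, x$batch_size, x$max_epochs, x$patience))
  invisible(x)
}

# elu(x) = x for x > 0, exp(x) - 1 otherwise; branch-free forms
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) exp(pmin(x, 0)) # exp(0) = 1 on the positive side
sigmoid <- function(x) 1 / (1 + exp(-x))

cnn_init_params <- function(cfg) {
  cin <- c(3L, cfg$filters[1:3])
  conv <- vector("list", 4)
  for (k in 1:4) {
    f <- cfg$filters[k]
    conv[[k]] <- list(
      W = array(rnorm(9 * cin[k] * f, 0, sqrt(2 / (9 * cin[k]))), c(3, 3, cin[k], f)),
      b = numeric(f), gamma = rep(1, f), beta = numeric(f),
      rmean = numeric(f), rvar = rep(1, f))
  }
  c4 <- cfg$filters[4]
  list(conv = conv,
       dense = list(
         W1 = matrix(rnorm(c4 * cfg$dense_units, 0, sqrt(2 / c4)), c4, cfg$dense_units),
         b1 = numeric(cfg$dense_units),
         W2 = matrix(rnorm(cfg$dense_units, 0, sqrt(2 / cfg$dense_units)),
                     cfg$dense_units, 1),
         b2 = 0))
}

#' Build an untrained patch classifier
#'
#' Initializes weights (He-scaled Gaussian) under `config$seed`; two builds
#' with the same seed have identical initial weights.
#'
#' @param config A [cnn_config()].
#' @return A `patch_cnn` object (`params`, `config`, `trained`, `history`).
#' @export
build_model <- function(config = cnn_config()) {
  assert_that(inherits(config, "cnn_config"), "config must be a cnn_config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  structure(list(params = cnn_init_params(config), config = config,
                 trained = FALSE, history = NULL, task = NULL,
                 selected_epoch = NA_integer_),
            class = "patch_cnn")
}

#' @export
print.patch_cnn <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, identity, how = "unlist"), length, 1L))
  cat(sprintf("<patch_cnn> %s, %s params%s\n",
              if (x$trained) "trained" else "untrained",
              format(np, big.mark = ","),
              if (x$trained) sprintf(", best epoch %d (val acc %.3f)",
                                     x$selected_epoch,
                                     max(x$history$val_accuracy)) else ""))
  invisible(x)
}

# Forward pass. x: [H, W, 3, B] already scaled to [0, 1]. Returns output
# probabilities plus per-layer caches for backprop / Grad-CAM. In training
# mode batch statistics drive batch norm and dropout masks are drawn from
# the current RNG stream; in inference mode running statistics are used and
# dropout is the identity (deterministic predictions).
cnn_forward <- function(params, cfg, x, train = FALSE) {
  B <- dim(x)[4]
  caches <- vector("list", 4)
  bn_batch <- vector("list", 4)
  h <- x
  for (k in 1:4) {
    pk <- params$conv[[k]]
    H <- dim(h)[1]; W <- dim(h)[2]; Ck <- dim(h)[3]; F <- cfg$filters[k]
    a <- conv3x3_fwd(h, pk$W, pk$b, H, W, Ck, B, F)
    e <- elu(a)
    m <- matrix(aperm(e, c(1, 2, 4, 3)), ncol = F)
    if (train) {
      mu <- colMeans(m)
      va <- colMeans(m * m) - mu * mu
      va[va < 0] <- 0
      bn_batch[[k]] <- list(mu = mu, va = va)
    } else {
      mu <- pk$rmean; va <- pk$rvar
    }
    sdv <- sqrt(va + 1e-5)
    zn <- sweep(sweep(m, 2, mu), 2, sdv, "/")
    bnm <- sweep(sweep(zn, 2, pk$gamma, "*"), 2, pk$beta, "+")
    bn <- aperm(array(bnm, c(H, W, B, F)), c(1, 2, 4, 3))
    pl <- maxpool2_fwd(bn, H, W, F, B)
    p <- pl$y
    if (train && cfg$dropout[k] > 0) {
      mask <- array((runif(length(p)) >= cfg$dropout[k]) / (1 - cfg$dropout[k]),
                    dim(p))
      p <- p * mask
    } else mask <- NULL
    caches[[k]] <- list(x = h, a = a, zn = zn, sdv = sdv, idx = pl$idx,
                        mask = mask, out = p, dims = c(H, W, F, B))
    h <- p
  }
  HW4 <- dim(h)[1] * dim(h)[2]; C4 <- cfg$filters[4]
  hm <- matrix(h, HW4, C4 * B)
  gidx <- max.col(t(hm), ties.method = "first")
  g <- hm[cbind(gidx, seq_along(gidx))]
  G <- t(matrix(g, C4, B)) # B x C4
  d <- params$dense
  h1a <- sweep(G %*% d$W1, 2, d$b1, "+")
  h1 <- elu(h1a)
  if (train && cfg$dense_dropout > 0) {
    maskd <- matrix((runif(length(h1)) >= cfg$dense_dropout) / (1 - cfg$dense_dropout),
                    nrow(h1), ncol(h1))
    h1d <- h1 * maskd
  } else { maskd <- NULL; h1d <- h1 }
  logit <- h1d %*% d$W2 + d$b2
  list(prob = as.vector(sigmoid(logit)), logit = as.vector(logit),
       caches = caches, bn_batch = bn_batch, G = G, gidx = gidx,
       h1a = h1a, h1d = h1d, maskd = maskd, train = train, HW4 = HW4, B = B)
}

# Backward pass from d(loss)/d(logit). Returns gradients shaped like params;
# when collect > 0 also the gradient at conv set `collect`'s pooled output
# (used by Grad-CAM, with dlogit = 1 and stop before the conv gradients of
# earlier sets).
cnn_backward <- function(params, cfg, fw, dlogit, collect = 0) {
  B <- fw$B
  d <- params$dense
  dlogit <- matrix(dlogit, B, 1)
  dW2 <- t(fw$h1d) %*% dlogit
  db2 <- sum(dlogit)
  dh1d <- dlogit %*% t(d$W2)
  dh1 <- if (is.null(fw$maskd)) dh1d else dh1d * fw$maskd
  dh1a <- dh1 * elu_grad(fw$h1a)
  dW1 <- t(fw$G) %*% dh1a
  db1 <- colSums(dh1a)
  dG <- dh1a %*% t(d$W1) # B x C4
  C4 <- cfg$filters[4]
  dg <- as.vector(t(dG)) # channel fastest, matching gidx column order
  dh <- numeric(fw$HW4 * C4 * B)
  dh[fw$gidx + fw$HW4 * (seq_along(fw$gidx) - 1)] <- dg
  dims4 <- dim(fw$caches[[4]]$out)
  dim(dh) <- dims4
  grads <- list(conv = vector("list", 4),
                dense = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
  collected <- NULL
  for (k in 4:1) {
    ca <- fw$caches[[k]]
    if (collect == k) { collected <- dh; break }
    if (!is.null(ca$mask)) dh <- dh * ca$mask
    H <- ca$dims[1]; W <- ca$dims[2]; F <- ca$dims[3]
    dbn <- maxpool2_bwd(dh, ca$idx, H * W * F * B)
    dim(dbn) <- c(H, W, F, B)
    dbnm <- matrix(aperm(dbn, c(1, 2, 4, 3)), ncol = F)
    pk <- params$conv[[k]]
    dgamma <- colSums(dbnm * ca$zn)
    dbeta <- colSums(dbnm)
    dzn <- sweep(dbnm, 2, pk$gamma, "*")
    if (fw$train) {
      mz <- colMeans(dzn)
      mzz <- colMeans(dzn * ca$zn)
      dxm <- sweep(dzn, 2, mz) - sweep(ca$zn, 2, mzz, "*")
      dxm <- sweep(dxm, 2, ca$sdv, "/")
    } else {
      dxm <- sweep(dzn, 2, ca$sdv, "/")
    }
    de <- aperm(array(dxm, c(H, W, B, F)), c(1, 2, 4, 3))
    da <- de * elu_grad(ca$a)
    Ck <- dim(ca$x)[3]
    cb <- conv3x3_bwd(ca$x, pk$W, da, H, W, Ck, B, F)
    grads$conv[[k]] <- list(W = cb$dw, b = cb$db, gamma = dgamma, beta = dbeta)
    dh <- cb$dx
  }
  list(grads = grads, collected = collected)
}

cnn_loss_forward <- function(params, cfg, x, y, train = TRUE) {
  fw <- cnn_forward(params, cfg, x, train = train)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  l1 <- cfg$kernel_l1 * sum(vapply(params$conv, function(pk) sum(abs(pk$W)), 0))
  list(fw = fw, loss = bce + l1, bce = bce)
}

adam_init <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_step <- function(params, grads, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (k in 1:4) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(params$conv[[k]][[nm]], grads$conv[[k]][[nm]],
               st$m$conv[[k]][[nm]], st$v$conv[[k]][[nm]])
      params$conv[[k]][[nm]] <- u$p
      st$m$conv[[k]][[nm]] <- u$m
      st$v$conv[[k]][[nm]] <- u$v
    }
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    u <- upd(params$dense[[nm]], grads$dense[[nm]],
             st$m$dense[[nm]], st$v$dense[[nm]])
    params$dense[[nm]] <- u$p
    st$m$dense[[nm]] <- u$m
    st$v$dense[[nm]] <- u$v
  }
  list(params = params, st = st)
}

# Stack a list of H x W x 3 pixel arrays into [H, W, 3, n], scaled to [0, 1].
stack_patches <- function(pixels) {
  d <- dim(pixels[[1]])
  array(unlist(pixels, use.names = FALSE) / 255, c(d[1], d[2], d[3], length(pixels)))
}

predict_array <- function(params, cfg, x, chunk = 64L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    xb <- x[, , , s:e, drop = FALSE]
    out[s:e] <- cnn_forward(params, cfg, xb, train = FALSE)$prob
  }
  out
}

#' Train the patch classifier under weak section labels
#'
#' Mini-batch Adam on binary cross-entropy plus an L1 kernel penalty, with
#' per-epoch validation, early stopping (training halts once
#' `patience` epochs pass without a new best validation accuracy), and
#' checkpointing of the best-validation-accuracy weights. Batch norm running
#' statistics are updated with momentum 0.9. Fully reproducible for a fixed
#' `config$seed`.
#'
#' @param model An untrained (or trained) `patch_cnn` from [build_model()].
#' @param x_train,x_val `[H, W, 3, n]` arrays of 0-255 pixels, or lists of
#'   `H x W x 3` arrays.
#' @param y_train,y_val Binary labels (0/1).
#' @param task Optional task tag stored on the model.
#' @param verbose Print per-epoch progress.
#' @return The trained `patch_cnn`, with `history` (per-epoch tibble of
#'   train/validation loss and accuracy) and `selected_epoch`.
#' @export
fit_patch_cnn <- function(model, x_train, y_train, x_val, y_val,
                          task = NULL, verbose = FALSE) {
  assert_that(inherits(model, "patch_cnn"), "model must come from build_model()")
  cfg <- model$config
  if (is.list(x_train) && !is.array(x_train)) x_train <- stack_patches(x_train) * 255
  if (is.list(x_val) && !is.array(x_val)) x_val <- stack_patches(x_val) * 255
  n <- dim(x_train)[4]
  assert_that(n >= 1 && length(y_train) == n, "x_train/y_train size mismatch")
  assert_that(length(unique(y_train)) == 2,
              "training labels must contain both classes")
  assert_that(dim(x_val)[4] == length(y_val) && length(y_val) >= 1,
              "x_val/y_val size mismatch")
  x_train <- x_train / 255
  x_val <- x_val / 255

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "train"))

  params <- model$params
  st <- list(m = adam_init(params), v = adam_init(params))
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- list()
  t_step <- 0
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_correct <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      ix <- ord[s:min(n, s + cfg$batch_size - 1)]
      xb <- x_train[, , , ix, drop = FALSE]
      yb <- y_train[ix]
      lf <- cnn_loss_forward(params, cfg, xb, yb, train = TRUE)
      p <- pmin(pmax(lf$fw$prob, 1e-12), 1 - 1e-12)
      dlogit <- (p - yb) / length(yb)
      bw <- cnn_backward(params, cfg, lf$fw, dlogit)
      for (k in 1:4) { # L1 subgradient on conv kernels
        bw$grads$conv[[k]]$W <- bw$grads$conv[[k]]$W +
          cfg$kernel_l1 * sign(params$conv[[k]]$W)
      }
      # batch-norm running stats (momentum 0.9)
      for (k in 1:4) {
        bb <- lf$fw$bn_batch[[k]]
        params$conv[[k]]$rmean <- 0.9 * params$conv[[k]]$rmean + 0.1 * bb$mu
        params$conv[[k]]$rvar <- 0.9 * params$conv[[k]]$rvar + 0.1 * bb$va
      }
      t_step <- t_step + 1
      au <- adam_step(params, bw$grads, st, cfg$learning_rate, t_step)
      params <- au$params
      st <- au$st
      ep_loss <- ep_loss + lf$bce * length(ix)
      ep_correct <- ep_correct + sum((lf$fw$prob > 0.5) == (yb == 1))
    }
    vp <- predict_array(params, cfg, x_val)
    vploss <- pmin(pmax(vp, 1e-12), 1 - 1e-12)
    val_loss <- -mean(y_val * log(vploss) + (1 - y_val) * log(1 - vploss))
    val_acc <- mean((vp > 0.5) == (y_val == 1))
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / n, accuracy = ep_correct / n,
      val_loss = val_loss, val_accuracy = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                      epoch, ep_loss / n, ep_correct / n, val_loss, val_acc))
    if (val_acc > best$acc) best <- list(acc = val_acc, params = params, epoch = epoch)
    if (epoch - best$epoch >= cfg$patience) break
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model$selected_epoch <- best$epoch
  model$task <- task %||% model$task
  model
}

#' Predict per-patch probabilities
#'
#' Inference is deterministic: dropout is disabled and batch norm uses
#' running statistics.
#'
#' @param model A trained `patch_cnn`.
#' @param patches `[H, W, 3, n]` array of 0-255 pixels, a list of `H x W x 3`
#'   arrays, or a patch tibble with a `pixels` list-column.
#' @return Numeric vector of probabilities in `[0, 1]`, one per patch, in
#'   input order.
#' @export
predict_patches <- function(model, patches) {
  assert_that(inherits(model, "patch_cnn"), "model must be a patch_cnn")
  assert_that(isTRUE(model$trained), "model has not been trained")
  if (is.data.frame(patches)) patches <- patches$pixels
  x <- if (is.list(patches) && !is.array(patches)) stack_patches(patches)
       else patches / 255
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  predict_array(model$params, model$config, x)
}

#' Grad-CAM heatmap for one patch
#'
#' Gradient-weighted class activation mapping on the (pre-sigmoid) logit:
#' channel weights are the spatial means of the logit gradient at the chosen
#' convolutional set's pooled feature map, the weighted activation sum is
#' rectified and max-normalized, then bilinearly upsampled to the patch
#' size. An all-zero map is returned when every rectified value is zero.
#'
#' @param model Trained `patch_cnn`.
#' @param patch `H x W x 3` array of 0-255 pixels.
#' @param conv_set Conv set index 1-4 (4 = deepest, the default).
#' @return Matrix of values in `[0, 1]` with the patch's spatial dimensions.
#' @export
grad_cam <- function(model, patch, conv_set = 4) {
  assert_that(inherits(model, "patch_cnn") && isTRUE(model$trained),
              "model must be a trained patch_cnn")
  assert_that(conv_set %in% 1:4, "conv_set must be in 1..4")
  cfg <- model$config
  x <- array(patch / 255, c(dim(patch)[1], dim(patch)[2], 3, 1))
  fw <- cnn_forward(model$params, cfg, x, train = FALSE)
  bw <- cnn_backward(model$params, cfg, fw, dlogit = 1, collect = conv_set)
  A <- fw$caches[[conv_set]]$out # [h, w, C, 1]
  dA <- bw$collected
  alpha <- apply(dA[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_along(alpha)) cam <- cam + alpha[c] * A[, , c, 1]
  cam[cam < 0] <- 0
  if (max(cam) > 0) cam <- cam / max(cam)
  resize_bilinear(cam, dim(patch)[1], dim(patch)[2])
}

#' Serialize a patch classifier to JSON and back
#'
#' Weights, config, history and the selected epoch round-trip through a
#' single JSON file (text-only storage).
#'
#' @param model A `patch_cnn`.
#' @param path File path.
#' @return `load_model` returns the restored `patch_cnn`.
#' @export
save_model <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    trained = model$trained,
    task = model$task,
    selected_epoch = model$selected_epoch,
    history = model$history,
    params = rapply(model$params, function(x) {
      list(dim = dim(x) %||% length(x), data = as.vector(x))
    }, how = "replace"))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- do.call(cnn_config, ser$config)
  rebuild <- function(node) {
    if (is.list(node) && all(c("dim", "data") %in% names(node))) {
      d <- unlist(node$dim)
      if (length(d) > 1) array(as.numeric(node$data), d) else as.numeric(node$data)
    } else if (is.list(node)) lapply(node, rebuild) else node
  }
  params <- rebuild(ser$params)
  hist <- if (length(ser$history))
    dplyr::bind_rows(lapply(ser$history, tibble::as_tibble)) else NULL
  structure(list(params = params, config = cfg, trained = ser$trained,
                 history = hist, task = ser$task,
                 selected_epoch = as.integer(ser$selected_epoch)),
            class = "patch_cnn")
}
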