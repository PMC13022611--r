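test_that("analytic gradients match finite differences through every layer", {
  cfg <- cnn_config(input_size = 16, filters = c(2, 3, 4, 5), dense_units = 6,
                    dropout = c(0, 0, 0, 0), dense_dropout = 0, kernel_l1 = 1e-3,
                    max_epochs = 2, patience = 1, seed = 3)
  m <- build_model(cfg)
  set.seed(42)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1, 0)
  lf <- wsimil:::cnn_loss_forward(m$params, cfg, x, y, train = TRUE)
  dlogit <- (lf$fw$prob - y) / 2
  bw <- wsimil:::cnn_backward(m$params, cfg, lf$fw, dlogit)
  for (k in 1:4)
    bw$grads$conv[[k]]$W <- bw$grads$conv[[k]]$W +
      cfg$kernel_l1 * sign(m$params$conv[[k]]$W)

  eps <- 1e-5
  num_grad <- function(path, i) {
    bump <- function(d) {
      p2 <- m$params
      if (path[1] == "conv") p2$conv[[as.integer(path[2])]][[path[3]]][i] <-
          p2$conv[[as.integer(path[2])]][[path[3]]][i] + d
      else p2$dense[[path[2]]][i] <- p2$dense[[path[2]]][i] + d
      wsimil:::cnn_loss_forward(p2, cfg, x, y, train = TRUE)$loss
    }
    (bump(eps) - bump(-eps)) / (2 * eps)
  }
  set.seed(43)
  for (k in 1:4) {
    for (nm in c("W", "gamma", "beta")) {
      ana <- bw$grads$conv[[k]][[nm]]
      for (i in sample(length(ana), min(3, length(ana)))) {
        ng <- num_grad(c("conv", k, nm), i)
        expect_lt(abs(ng - ana[i]) / max(abs(ng) + abs(ana[i]), 1e-6), 1e-4)
      }
    }
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    ana <- bw$grads$dense[[nm]]
    for (i in sample(length(ana), min(3, length(ana)))) {
      ng <- num_grad(c("dense", nm), i)
      expect_lt(abs(ng - ana[i]) / max(abs(ng) + abs(ana[i]), 1e-6), 1e-4)
    }
  }
})

test_that("feature maps halve at each pooling stage and outputs stay in (0,1)", {
  cfg <- cnn_config(input_size = 128, filters = c(1, 2, 3, 4), dense_units = 4,
                    seed = 2)
  m <- build_model(cfg)
  x <- array(0, c(128, 128, 3, 1))
  fw <- wsimil:::cnn_forward(m$params, cfg, x)
  sizes <- vapply(fw$caches, function(ca) dim(ca$out)[1], 0)
  expect_equal(sizes, c(64, 32, 16, 8)) # 128 / 2^k
  expect_true(fw$prob > 0 && fw$prob < 1 && is.finite(fw$prob))

  expect_error(cnn_config(input_size = 100), "divisible")
  expect_error(cnn_config(filters = c(16, 8, 32, 64)), "increasing")
  expect_error(cnn_config(patience = 300, max_epochs = 300), "patience")
})

test_that("weight init and training are reproducible under a fixed seed", {
  cfg <- fx_quick_cnn(seed = 12L, max_epochs = 2, patience = 1)
  expect_identical(build_model(cfg)$params, build_model(cfg)$params)

  s <- fx_sep_patches()[1:40, ]
  fit_once <- function() {
    m <- fit_patch_cnn(build_model(cfg), s$pixels[1:30], s$label[1:30],
                       s$pixels[31:40], s$label[31:40])
    m$history
  }
  expect_identical(fit_once(), fit_once())
})

test_that("a separable texture fixture is learned almost perfectly", {
  fx <- fx_sep_model()
  s <- fx$data
  probs <- predict_patches(fx$model, s$pixels[fx$test_ix])
  acc <- mean((probs > 0.5) == (s$label[fx$test_ix] == 1))
  expect_gte(acc, 0.9)
  # mean probability separates the classes
  expect_gt(mean(probs[s$label[fx$test_ix] == 1]),
            mean(probs[s$label[fx$test_ix] == 0]))
})

test_that("training on permuted labels stays at chance level", {
  s <- fx_sep_patches()
  set.seed(55)
  y_perm <- sample(s$label)
  n <- nrow(s)
  test_ix <- sort(sample(n, 60))
  tr <- setdiff(seq_len(n), test_ix)
  val_ix <- tr[seq(1, length(tr), by = 5)]
  tr <- setdiff(tr, val_ix)
  m <- fit_patch_cnn(build_model(fx_quick_cnn(seed = 66L, max_epochs = 3, patience = 2)),
                     s$pixels[tr], y_perm[tr], s$pixels[val_ix], y_perm[val_ix])
  acc <- mean((predict_patches(m, s$pixels[test_ix]) > 0.5) == (y_perm[test_ix] == 1))
  se <- sqrt(0.25 / length(test_ix))
  expect_lt(abs(acc - 0.5), 3 * se + 1e-9)
})

test_that("early stopping halts one patience past a stagnant best epoch", {
  s <- fx_sep_patches()[1:24, ]
  # vanishing learning rate: validation accuracy can never improve on epoch 1
  cfg <- fx_quick_cnn(seed = 8L, max_epochs = 40, patience = 3)
  cfg$learning_rate <- 1e-12
  m <- fit_patch_cnn(build_model(cfg), s$pixels[1:16], s$label[1:16],
                     s$pixels[17:24], s$label[17:24])
  expect_equal(nrow(m$history), 1 + 3) # best at 1, stop at 1 + patience
  expect_equal(m$selected_epoch, 1L)
})

test_that("the checkpoint corresponds to the best validation accuracy", {
  fx <- fx_sep_model()
  h <- fx$model$history
  expect_equal(fx$model$selected_epoch, which.max(h$val_accuracy))
  expect_lte(nrow(h), fx$model$config$max_epochs)
})

test_that("inference is deterministic, ordered, and shape-stable", {
  fx <- fx_sep_model()
  px <- fx$data$pixels[fx$test_ix[1:7]]
  p1 <- predict_patches(fx$model, px)
  p2 <- predict_patches(fx$model, px)
  expect_identical(p1, p2)
  expect_length(p1, 7)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(p1[3], predict_patches(fx$model, px[[3]]), tolerance = 1e-10)
  expect_error(predict_patches(build_model(fx_quick_cnn()), px), "trained")

  # training error paths
  expect_error(fit_patch_cnn(build_model(fx_quick_cnn()),
                             px[1:4], rep(1, 4), px[5:6], c(1, 0)), "classes")
})

test_that("model weights round-trip through JSON serialization", {
  fx <- fx_sep_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fx$model, path)
  back <- load_model(path)
  px <- fx$data$pixels[fx$test_ix[1:5]]
  expect_equal(predict_patches(back, px), predict_patches(fx$model, px),
               tolerance = 1e-12)
  expect_equal(back$selected_epoch, fx$model$selected_epoch)
})

test_that("Grad-CAM maps are normalized, patch-sized, and texture-localized", {
  fx <- fx_sep_model()
  patch <- fx$data$pixels[fx$data$label == 1][[1]]
  cam <- grad_cam(fx$model, patch)
  expect_identical(dim(cam), dim(patch)[1:2])
  expect_true(all(cam >= -1e-9 & cam <= 1 + 1e-9))
  expect_true(max(cam) <= 1 + 1e-9)
  expect_error(grad_cam(fx$model, patch, conv_set = 5), "conv_set")

  # half-and-half patch: abnormal texture left, plain tissue right
  set.seed(91)
  ab <- fx$data$pixels[fx$data$label == 1][[2]]
  pl <- fx$data$pixels[fx$data$label == 0][[2]]
  half <- ab
  half[, 17:32, ] <- pl[, 17:32, ]
  cam <- grad_cam(fx$model, half, conv_set = 3)
  inside <- mean(cam[, 1:16])
  outside <- mean(cam[, 17:32])
  expect_gt(inside, outside)
})
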