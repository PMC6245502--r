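# The convolutional classifier: architecture shape, gradient exactness,
# seeded determinism, persistence, and learning on separable data.

test_that("the reference architecture halves length down the stack", {
  cfg <- network_config()
  lens <- squiggleplex:::network_lengths(cfg)
  expect_equal(lens[1:3], c(1024, 512, 256))
  expect_equal(diff(log2(lens)), rep(-1, cfg$n_groups))
  expect_error(network_config(input_len = 1000), "power of two")
  expect_error(network_config(input_len = 64, n_groups = 4,
                              pools = c(4, 4, 4, 4)),
               "not divisible")
})

test_that("model outputs are 13-way probability rows", {
  model <- build_model(desk_network_config(13), seed = 1)
  withr::with_seed(2, {
    W <- matrix(rnorm(5 * 1024), 5)
    P <- predict_probs(model, W)
    expect_equal(dim(P), c(5, 13))
    expect_equal(colnames(P)[13], "no_barcode")
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
    # degenerate all-zero window still yields a finite probability row
    P0 <- predict_probs(model, rep(0, 1024))
    expect_false(anyNA(P0))
    expect_equal(sum(P0), 1, tolerance = 1e-6)
    expect_error(predict_probs(model, matrix(rnorm(10), 1)), "input")
  })
})

test_that("parameter counts respect the small-model discipline", {
  expect_lt(n_params(build_model(network_config(), seed = 1)), 5e5)
  expect_lt(n_params(build_model(desk_network_config(), seed = 1)), 5e5)
})

test_that("backpropagated gradients match finite differences", {
  # run the convolutions in double precision: central differences at
  # eps = 1e-6 are meaningless through single-precision arithmetic
  withr::local_options(squiggleplex.double_conv = TRUE)
  ns <- asNamespace("squiggleplex")
  cfg <- network_config(input_len = 32, n_classes = 3, base_filters = 6,
                        n_groups = 2, n_conv = 1, kernel = 3,
                        pools = c(2, 2), inception_after = 1,
                        dropout = 0, noise_sd = 0)
  model <- build_model(cfg, seed = 5)
  # nudge biases off zero so no pre-activation sits exactly on the ReLU
  # kink (where the subgradient and a central difference may differ)
  withr::with_seed(6, {
    for (li in seq_along(model$layers)) {
      p <- ns$layer_params(model$layers[[li]])
      bump <- function(pp) {
        if (!is.null(pp$b)) pp$b <- pp$b + rnorm(length(pp$b), sd = 0.05)
        pp
      }
      if (!is.null(p$branches)) {
        p$branches <- lapply(p$branches, function(br) lapply(br, function(s) {
          if (is.null(s)) s else bump(s)
        }))
      } else if (!is.null(p$b)) {
        p <- bump(p)
      } else next
      model$layers[[li]] <- ns$layer_set_params(model$layers[[li]], p)
    }
    X <- matrix(rnorm(4 * 32), 4)
    y <- c(1, 2, 3, 1)
  })
  loss_fn <- function(m) {
    fw <- ns$nn_forward(m$layers, ns$windows_to_cube(X), training = TRUE)
    ns$xent_loss(ns$softmax_rows(fw$out), y)
  }
  fw <- ns$nn_forward(model$layers, ns$windows_to_cube(X), training = TRUE)
  probs <- ns$softmax_rows(fw$out)
  dl <- probs
  dl[cbind(1:4, y)] <- dl[cbind(1:4, y)] - 1
  dl <- dl / 4
  grads <- ns$nn_backward(model$layers, fw$caches, dl)
  eps <- 1e-6
  types <- vapply(model$layers, function(l) l$type, character(1))
  for (li in which(types %in% c("conv", "bn", "dense"))) {
    g <- grads[[li]]
    for (nm in names(g)) {
      gv <- as.numeric(g[[nm]])
      idx <- withr::with_seed(li, sample(length(gv), min(4, length(gv))))
      for (i in idx) {
        m2 <- model
        p <- ns$layer_params(m2$layers[[li]])
        p[[nm]][i] <- p[[nm]][i] + eps
        m2$layers[[li]] <- ns$layer_set_params(m2$layers[[li]], p)
        lp <- loss_fn(m2)
        p[[nm]][i] <- p[[nm]][i] - 2 * eps
        m2$layers[[li]] <- ns$layer_set_params(m2$layers[[li]], p)
        lm <- loss_fn(m2)
        expect_equal(gv[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
  # one weight and one bias inside each inception branch
  ili <- which(types == "incept")
  g <- grads[[ili]]
  for (bi in seq_along(g$branches)) {
    for (sj in seq_along(g$branches[[bi]])) {
      gg <- g$branches[[bi]][[sj]]
      if (is.null(gg)) next
      for (nm in c("W", "b")) {
        gv <- as.numeric(gg[[nm]])
        i <- length(gv)
        m2 <- model
        p <- ns$layer_params(m2$layers[[ili]])
        p$branches[[bi]][[sj]][[nm]][i] <- p$branches[[bi]][[sj]][[nm]][i] + eps
        m2$layers[[ili]] <- ns$layer_set_params(m2$layers[[ili]], p)
        lp <- loss_fn(m2)
        p$branches[[bi]][[sj]][[nm]][i] <- p$branches[[bi]][[sj]][[nm]][i] - 2 * eps
        m2$layers[[ili]] <- ns$layer_set_params(m2$layers[[ili]], p)
        lm <- loss_fn(m2)
        expect_equal(gv[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  set <- separable_set(20, n_classes = 3, window_len = 64, seed = 7)
  cfg <- network_config(input_len = 64, n_classes = 3, base_filters = 8,
                        n_groups = 2, n_conv = 1, pools = c(4, 4),
                        inception_after = 1)
  run <- function() {
    model <- build_model(cfg, seed = 8)
    train_model(model, set, train_config(epochs = 2, seed = 9))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("a trained model survives save and load unchanged", {
  set <- separable_set(20, n_classes = 3, window_len = 64, seed = 10)
  cfg <- network_config(input_len = 64, n_classes = 3, base_filters = 8,
                        n_groups = 2, n_conv = 1, pools = c(4, 4),
                        inception_after = 1)
  fit <- train_model(build_model(cfg, seed = 11), set,
                     train_config(epochs = 2, seed = 12))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  W <- separable_set(5, n_classes = 3, window_len = 64, seed = 13)$X
  expect_identical(predict_probs(back, W), predict_probs(fit$model, W))
})

test_that("the network learns an easy separable barcode problem", {
  # 4 barcodes, minimal-noise library, hundreds of samples per class
  lib <- simulate_library(520, barcodes = barcode_set(4),
                          noise_mult_range = c(1, 1),
                          no_barcode_rate = 0, chimera_rate = 0,
                          seed = 1234)
  ext <- harvest_training_windows(lib$squiggles, end = "start",
                                  truth = lib$truth, n_classes = 5,
                                  seed = 14)
  set <- assemble_training_set(ext, no_barcode_fraction = 0.2, seed = 15)
  model <- build_model(desk_network_config(5), seed = 16)
  fit <- train_model(model, set,
                     train_config(epochs = 10, seed = 17))
  expect_gte(max(fit$history$val_acc), 0.95)
  # with augmentation and training-only noise layers, validation metrics
  # may legitimately exceed training metrics
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_error(
    train_model(model,
                training_set(matrix(rnorm(10 * 1024), 10), rep(1, 10), 5),
                train_config(epochs = 1)),
    "fewer than 2 classes")
})
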