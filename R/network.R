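# The convolutional classifier: a compact 1-D CNN mapping a 1024-sample
# z-normalised signal window to 13 class probabilities (12 barcodes +
# no-barcode).
#
# Reference stack: a training-only Gaussian noise layer, then repeated
# groups of [conv(F) x n -> max-pool -> batch-norm -> dropout] that halve
# the signal length as it progresses, one inception-style parallel module
# (1-wide path, stacked-convolution path and pooled path, each behind a
# low-dimension bottleneck, concatenated to more than F filters)
# mid-network, a constant filter count F elsewhere, and finally global
# average pooling into a softmax output. Noise and dropout are active
# only during training.

#' Network configuration
#'
#' @param input_len Window length in samples; must be a power of two so
#'   the signal can halve cleanly through the pooling layers.
#' @param n_classes Number of output classes (barcodes + 1 no-barcode).
#' @param base_filters Constant filter count used outside the inception
#'   module (48 in the reference architecture).
#' @param n_groups Number of conv/pool groups.
#' @param n_conv Convolutions per group.
#' @param kernel Convolution kernel width (odd).
#' @param pools Pool width per group (length `n_groups`); the reference
#'   stack halves (pool 2) at every group.
#' @param inception_after Index of the group after which the inception
#'   module sits (0 = none).
#' @param dropout Dropout rate (training only).
#' @param noise_sd Input Gaussian-noise sd in z-units (training only).
#' @param scale Multiplier applied to `base_filters` (and bottleneck
#'   widths) for reduced-size models.
#' @return A list of class `network_config`.
#' @export
network_config <- function(input_len = 1024, n_classes = 13,
                           base_filters = 48, n_groups = 6, n_conv = 2,
                           kernel = 9, pools = rep(2, n_groups),
                           inception_after = 3, dropout = 0.1,
                           noise_sd = 0.02, scale = 1) {
  if (bitwAnd(input_len, input_len - 1L) != 0) {
    stopf("input_len must be a power of two")
  }
  if (length(pools) != n_groups) stopf("need one pool width per group")
  if (input_len %% prod(pools) != 0) {
    stopf("input_len %d not divisible by cumulative pooling %d",
          input_len, prod(pools))
  }
  f <- max(4L, as.integer(round(base_filters * scale)))
  structure(list(input_len = input_len, n_classes = n_classes,
                 base_filters = f, n_groups = n_groups, n_conv = n_conv,
                 kernel = kernel, pools = pools,
                 inception_after = inception_after,
                 dropout = dropout, noise_sd = noise_sd),
            class = "network_config")
}

#' Desk-scale network configuration
#'
#' A reduced model (24 filters, one convolution per group, heavier early
#' pooling, light dropout; ~20k parameters) that trains to high accuracy
#' on simulated libraries in minutes on a single CPU while keeping every
#' architectural element of the reference stack.
#'
#' @param n_classes Number of output classes.
#' @return A `network_config`.
#' @export
desk_network_config <- function(n_classes = 13) {
  network_config(input_len = 1024, n_classes = n_classes,
                 base_filters = 24, n_groups = 4, n_conv = 1,
                 kernel = 9, pools = c(4, 4, 2, 2),
                 inception_after = 2, dropout = 0.05, noise_sd = 0.02)
}

# Internal signal lengths after each group, starting at the input.
network_lengths <- function(config) {
  cumprod(c(config$input_len, 1 / config$pools)) |> round()
}

#' Build a classifier model
#'
#' Instantiates the network with randomly initialised weights (He
#' initialisation, deterministic under `seed`).
#'
#' @param config A [network_config()].
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `squiggle_net`.
#' @export
build_model <- function(config = network_config(), seed = NULL) {
  with_seed(seed, {
    layers <- list(list(type = "noise", sd = config$noise_sd))
    ch <- 1L
    f <- config$base_filters
    for (g in seq_len(config$n_groups)) {
      for (j in seq_len(config$n_conv)) {
        cv <- nn_init_conv(config$kernel, ch, f)
        # the first convolution sits right above the (parameter-free)
        # input noise layer, so its input gradient is never consumed
        cv$first <- g == 1 && j == 1
        layers <- c(layers, list(cv))
        ch <- f
      }
      layers <- c(layers, list(list(type = "pool", p = config$pools[g])))
      layers <- c(layers, list(nn_init_bn(ch)))
      layers <- c(layers, list(list(type = "dropout", rate = config$dropout)))
      if (g == config$inception_after) {
        half <- max(2L, f %/% 2L)
        btl <- max(2L, f %/% 3L)
        branches <- list(
          list(nn_init_conv(1, ch, half)),                      # 1-wide path
          list(nn_init_conv(1, ch, btl),                        # bottleneck
               nn_init_conv(config$kernel, btl, half)),         # stacked conv
          list(list(type = "samepool", w = 3),                  # pooled path
               nn_init_conv(1, ch, half)))
        layers <- c(layers, list(list(type = "incept", branches = branches)))
        ch <- 3L * half
      }
    }
    layers <- c(layers, list(list(type = "gap")),
                list(nn_init_dense(ch, config$n_classes)))
    structure(list(config = config, layers = layers),
              class = "squiggle_net")
  })
}

#' @export
print.squiggle_net <- function(x, ...) {
  cat(sprintf("<squiggle_net: input %d -> %d classes, %d filters, %s parameters>\n",
              x$config$input_len, x$config$n_classes,
              x$config$base_filters, format(n_params(x), big.mark = " ")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A [build_model()] object.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  count <- 0
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else count <<- count + length(p)
    invisible(NULL)
  }
  for (l in model$layers) walk(layer_params(l))
  count
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Initial Adam learning rate; halved whenever the validation
#'   loss has not improved for `patience` consecutive epochs.
#' @param patience Plateau patience, in epochs.
#' @param val_fraction Validation fraction of the random
#'   training:validation split (default 0.05, i.e. 95:5).
#' @param augmentation_factor Total copies of each training sample per
#'   epoch (2 = one temporally distorted copy per unmodified sample;
#'   1 = no augmentation). Applied to the training partition only.
#' @param samples_per_epoch Optional cap on training samples drawn per
#'   epoch (before augmentation); NULL uses the full training partition.
#' @param seed Seed controlling the split, shuffling, augmentation and
#'   the training-only noise layers.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 64, lr = 2e-3,
                         patience = 2, val_fraction = 0.05,
                         augmentation_factor = 2,
                         samples_per_epoch = NULL, seed = NULL) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stopf("val_fraction must be in (0, 1)")
  }
  if (epochs < 1) stopf("epochs must be >= 1")
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 patience = patience, val_fraction = val_fraction,
                 augmentation_factor = augmentation_factor,
                 samples_per_epoch = samples_per_epoch, seed = seed),
            class = "train_config")
}

# matrix [n, L] of windows -> cube [L, 1, n]
windows_to_cube <- function(M) {
  array(t(M), c(ncol(M), 1L, nrow(M)))
}

#' Train the classifier
#'
#' Minimises categorical cross-entropy with Adam over a random 95:5
#' training:validation split. Data augmentation (temporal distortion,
#' [augment_signal()]) is applied to the training partition only and
#' regenerated every epoch; the Gaussian-noise and dropout layers are
#' likewise active only on the training passes, so validation metrics
#' can legitimately exceed training metrics.
#'
#' @param model A [build_model()] object.
#' @param training_set A [training_set()] (matrix of windows + labels).
#' @param config A [train_config()].
#' @param verbose Print per-epoch metrics.
#' @return List with the trained `model` and a `history` data.frame
#'   (epoch, train/validation loss and accuracy).
#' @export
train_model <- function(model, training_set, config = train_config(),
                        verbose = FALSE) {
  X <- training_set$X
  y <- training_set$labels
  if (length(unique(y)) < 2) stopf("training set has fewer than 2 classes")
  if (ncol(X) != model$config$input_len) {
    stopf("window length %d does not match model input %d",
          ncol(X), model$config$input_len)
  }
  with_seed(config$seed, {
    n <- nrow(X)
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xval <- windows_to_cube(X[val_idx, , drop = FALSE])
    yval <- y[val_idx]

    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_acc = numeric(), val_loss = numeric(),
                       val_acc = numeric())
    opt <- NULL
    t_step <- 0
    lr <- config$lr
    best_val <- Inf
    since_best <- 0
    for (ep in seq_len(config$epochs)) {
      idx <- tr_idx
      if (!is.null(config$samples_per_epoch) &&
          config$samples_per_epoch < length(idx)) {
        idx <- sample(idx, config$samples_per_epoch)
      }
      # presentation list: each sample once, plus (factor - 1) copies to
      # be temporally distorted; distortion happens per batch so the
      # full augmented epoch matrix is never materialised
      pres_row <- rep(idx, config$augmentation_factor)
      pres_aug <- rep(c(FALSE, rep(TRUE, config$augmentation_factor - 1L)),
                      each = length(idx))
      ord <- sample.int(length(pres_row))
      pres_row <- pres_row[ord]
      pres_aug <- pres_aug[ord]

      tot_loss <- 0
      tot_correct <- 0
      n_pres <- length(pres_row)
      starts <- seq(1, n_pres, by = config$batch_size)
      for (s in starts) {
        e <- min(s + config$batch_size - 1L, n_pres)
        Xb_mat <- X[pres_row[s:e], , drop = FALSE]
        for (k in which(pres_aug[s:e])) {
          Xb_mat[k, ] <- augment_signal(Xb_mat[k, ])
        }
        Xb <- windows_to_cube(Xb_mat)
        yb <- y[pres_row[s:e]]
        fw <- nn_forward(model$layers, Xb, training = TRUE)
        model$layers <- nn_update_bn_stats(model$layers, fw$caches)
        probs <- softmax_rows(fw$out)
        loss <- xent_loss(probs, yb)
        if (!is.finite(loss)) {
          stopf("non-finite loss at epoch %d (batch starting %d)", ep, s)
        }
        tot_loss <- tot_loss + loss * length(yb)
        tot_correct <- tot_correct + sum(max.col(probs) == yb)
        B <- length(yb)
        dlogits <- probs
        dlogits[cbind(seq_len(B), yb)] <- dlogits[cbind(seq_len(B), yb)] - 1
        dlogits <- dlogits / B
        grads <- nn_backward(model$layers, fw$caches, dlogits)
        if (is.null(opt)) {
          pg <- lapply(model$layers, layer_params)
          opt <- list(m = adam_init_like(pg), v = adam_init_like(pg))
        }
        t_step <- t_step + 1
        for (li in seq_along(model$layers)) {
          if (is.null(grads[[li]])) next
          p <- layer_params(model$layers[[li]])
          r <- adam_apply(p, grads[[li]], opt$m[[li]], opt$v[[li]],
                          lr, t_step)
          model$layers[[li]] <- layer_set_params(model$layers[[li]], r$p)
          opt$m[[li]] <- r$m
          opt$v[[li]] <- r$v
        }
      }
      val <- evaluate_batch(model, Xval, yval)
      if (val$loss < best_val - 1e-5) {
        best_val <- val$loss
        since_best <- 0
      } else {
        since_best <- since_best + 1
        if (since_best >= config$patience) {
          lr <- max(lr / 2, 1e-4)
          since_best <- 0
        }
      }
      hist <- rbind(hist, data.frame(
        epoch = ep,
        train_loss = tot_loss / n_pres,
        train_acc = tot_correct / n_pres,
        val_loss = val$loss, val_acc = val$acc, lr = lr))
      if (verbose) {
        message(sprintf(
          "epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          ep, hist$train_loss[ep], hist$train_acc[ep],
          hist$val_loss[ep], hist$val_acc[ep]))
      }
    }
    list(model = model, history = hist)
  })
}

evaluate_batch <- function(model, Xcube, y, batch_size = 256) {
  n <- dim(Xcube)[3]
  loss <- 0
  correct <- 0
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fw <- nn_forward(model$layers, Xcube[, , s:e, drop = FALSE],
                     training = FALSE)
    probs <- softmax_rows(fw$out)
    loss <- loss + xent_loss(probs, y[s:e]) * (e - s + 1)
    correct <- correct + sum(max.col(probs) == y[s:e])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict class probabilities for signal windows
#'
#' @param model A trained [build_model()] object.
#' @param windows Matrix with one z-normalised window per row (or a
#'   single numeric window); row length must equal the model input.
#' @param batch_size Inference batch size.
#' @return Matrix of probabilities, one row per window, columns named by
#'   class (`barcode1`..`barcodeN`, `no_barcode`); each row sums to 1.
#' @export
predict_probs <- function(model, windows, batch_size = 256) {
  if (is.numeric(windows) && is.null(dim(windows))) {
    windows <- matrix(windows, nrow = 1)
  }
  if (ncol(windows) != model$config$input_len) {
    stopf("window length %d does not match model input %d",
          ncol(windows), model$config$input_len)
  }
  n <- nrow(windows)
  out <- matrix(0, n, model$config$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fw <- nn_forward(model$layers,
                     windows_to_cube(windows[s:e, , drop = FALSE]),
                     training = FALSE)
    out[s:e, ] <- softmax_rows(fw$out)
  }
  colnames(out) <- class_labels(model$config$n_classes - 1L)
  out
}

#' Save / load a trained model
#'
#' The model is serialised with R's native serialisation; a JSON sidecar
#' (`<path>.json`) records the network configuration for inspection.
#'
#' @param model A `squiggle_net`.
#' @param path Output path (e.g. `model.rds`).
#' @return `path` (or, for `load_model`, the model).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "squiggle_net")) stopf("%s is not a saved model", path)
  model
}
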