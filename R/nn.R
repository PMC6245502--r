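# Internal neural-network machinery: layer forward/backward passes and
# the Adam optimiser. Batches are arrays [length, channels, batch]; the
# convolution and pooling kernels are compiled (see src/kernels.cpp),
# everything else is vectorised R.
#
# Layer descriptors are plain lists with a `type` field:
#   noise    — additive Gaussian noise, training only
#   conv     — same-padding 1-D convolution + ReLU (W [K*Cin, F], b [F])
#   pool     — non-overlapping max pool, width = stride = p
#   bn       — per-channel batch normalisation with running stats
#   dropout  — inverted dropout, training only
#   incept   — inception-style parallel module (branches of conv layers,
#              plus a stride-1 max-pool path), concatenated on channels
#   gap      — global average pooling [L,C,B] -> [B,C]
#   dense    — linear output layer [B,C] -> [B,n_classes]

nn_init_conv <- function(kernel, in_ch, out_ch) {
  w <- matrix(stats::rnorm(kernel * in_ch * out_ch,
                           sd = sqrt(2 / (kernel * in_ch))),
              nrow = kernel * in_ch, ncol = out_ch)
  list(type = "conv", kernel = kernel, in_ch = in_ch, out_ch = out_ch,
       W = w, b = numeric(out_ch))
}

nn_init_bn <- function(ch) {
  list(type = "bn", ch = ch, gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch),
       momentum = 0.9, eps = 1e-5)
}

nn_init_dense <- function(in_ch, out_ch) {
  list(type = "dense",
       W = matrix(stats::rnorm(in_ch * out_ch, sd = sqrt(2 / in_ch)),
                  nrow = in_ch, ncol = out_ch),
       b = numeric(out_ch))
}

# Batch-norm works on the flat [L, C*B] view of a [L,C,B] array (a dim
# change, no copy). Per-channel quantities are expanded to the column
# layout (channel fastest) with rep(v, each = L); R's recycling then
# covers all B slices since the pattern repeats every L*C elements.
chan_stat <- function(col_stat, C, B) rowMeans(matrix(col_stat, C, B))
chan_expand <- function(v, L) rep(v, each = L)

nn_forward_layer <- function(layer, X, training) {
  switch(layer$type,
    noise = {
      if (training && layer$sd > 0) {
        X <- X + array(stats::rnorm(length(X), sd = layer$sd), dim(X))
      }
      list(Y = X, cache = NULL)
    },
    conv = {
      # convolution arithmetic runs in single precision by default;
      # option squiggleplex.double_conv = TRUE switches to double (used
      # by the finite-difference gradient checks, where float rounding
      # would swamp the numeric derivatives)
      Y <- cpp_conv1d_forward(X, layer$W, layer$b,
                              single = !isTRUE(getOption("squiggleplex.double_conv")))
      list(Y = Y, cache = if (training) list(X = X, Y = Y))
    },
    pool = {
      r <- cpp_maxpool_forward(X, layer$p)
      list(Y = r$Y, cache = list(idx = r$idx, Lin = dim(X)[1]))
    },
    bn = {
      d <- dim(X)
      L <- d[1]; C <- d[2]; B <- d[3]
      dim(X) <- c(L, C * B)
      if (training) {
        mu <- chan_stat(colMeans(X), C, B)
        v <- chan_stat(colMeans(X^2), C, B) - mu^2
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- X * chan_expand(inv_sd, L) - chan_expand(mu * inv_sd, L)
      Y <- xhat * chan_expand(layer$gamma, L) + chan_expand(layer$beta, L)
      dim(Y) <- d
      list(Y = Y,
           cache = list(xhat = xhat, inv_sd = inv_sd, d = d,
                        batch_mu = if (training) mu else NULL,
                        batch_var = if (training) v else NULL))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array((stats::runif(length(X)) >= layer$rate) /
                        (1 - layer$rate), dim(X))
        list(Y = X * mask, cache = list(mask = mask))
      } else {
        list(Y = X, cache = NULL)
      }
    },
    incept = {
      outs <- vector("list", length(layer$branches))
      caches <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        br <- layer$branches[[i]]
        Xi <- X
        bc <- vector("list", length(br))
        for (j in seq_along(br)) {
          sub <- br[[j]]
          if (sub$type == "samepool") {
            r <- cpp_maxpool_same_forward(Xi, sub$w)
            bc[[j]] <- list(idx = r$idx, Lin = dim(Xi)[1])
            Xi <- r$Y
          } else {
            r <- nn_forward_layer(sub, Xi, training)
            bc[[j]] <- r$cache
            Xi <- r$Y
          }
        }
        outs[[i]] <- Xi
        caches[[i]] <- bc
      }
      chans <- vapply(outs, function(o) dim(o)[2], numeric(1))
      d <- dim(X)
      Y <- array(0, c(d[1], sum(chans), d[3]))
      at <- 0
      for (i in seq_along(outs)) {
        Y[, at + seq_len(chans[i]), ] <- outs[[i]]
        at <- at + chans[i]
      }
      list(Y = Y, cache = list(branches = caches, chans = chans))
    },
    gap = {
      d <- dim(X)
      Y <- t(matrix(colMeans(matrix(X, nrow = d[1])), nrow = d[2]))  # [B,C]
      list(Y = Y, cache = list(d = d))
    },
    dense = {
      Y <- X %*% layer$W
      Y <- sweep(Y, 2, layer$b, "+")
      list(Y = Y, cache = list(X = X))
    },
    stopf("unknown layer type '%s'", layer$type))
}

nn_backward_layer <- function(layer, cache, dY) {
  switch(layer$type,
    noise = list(dX = dY, grads = NULL),
    conv = {
      dZ <- dY * (cache$Y > 0)   # ReLU mask from the activated output
      g <- cpp_conv1d_backward(cache$X, layer$W, dZ,
                               want_dx = !isTRUE(layer$first),
                               single = !isTRUE(getOption("squiggleplex.double_conv")))
      list(dX = g$dX, grads = list(W = g$dW, b = as.numeric(g$db)))
    },
    pool = {
      list(dX = cpp_maxpool_backward(dY, cache$idx, cache$Lin), grads = NULL)
    },
    bn = {
      d <- cache$d
      L <- d[1]; C <- d[2]; B <- d[3]
      dim(dY) <- c(L, C * B)
      xhat <- cache$xhat
      dgamma <- rowSums(matrix(colSums(dY * xhat), C, B))
      dbeta <- rowSums(matrix(colSums(dY), C, B))
      # train-mode gradient through the batch statistics
      dxhat <- dY * chan_expand(layer$gamma, L)
      m1 <- chan_stat(colMeans(dxhat), C, B)
      m2 <- chan_stat(colMeans(dxhat * xhat), C, B)
      dX <- (dxhat - chan_expand(m1, L) - xhat * chan_expand(m2, L)) *
        chan_expand(cache$inv_sd, L)
      dim(dX) <- d
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    dropout = {
      if (is.null(cache)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    incept = {
      chans <- cache$chans
      at <- 0
      dX <- NULL
      grads <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        dYi <- dY[, at + seq_len(chans[i]), , drop = FALSE]
        at <- at + chans[i]
        br <- layer$branches[[i]]
        bg <- vector("list", length(br))
        for (j in rev(seq_along(br))) {
          sub <- br[[j]]
          if (sub$type == "samepool") {
            bc <- cache$branches[[i]][[j]]
            dYi <- cpp_maxpool_backward(dYi, bc$idx, bc$Lin)
            bg[j] <- list(NULL)
          } else {
            r <- nn_backward_layer(sub, cache$branches[[i]][[j]], dYi)
            dYi <- r$dX
            bg[[j]] <- r$grads
          }
        }
        grads[[i]] <- bg
        dX <- if (is.null(dX)) dYi else dX + dYi
      }
      list(dX = dX, grads = list(branches = grads))
    },
    gap = {
      d <- cache$d
      dX <- array(rep(as.vector(t(dY)) / d[1], each = d[1]), d)
      list(dX = dX, grads = NULL)
    },
    dense = {
      list(dX = dY %*% t(layer$W),
           grads = list(W = t(cache$X) %*% dY, b = colSums(dY)))
    })
}

nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_forward_layer(layers[[i]], X, training)
    X <- r$Y
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

nn_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_backward_layer(layers[[i]], caches[[i]], dOut)
    dOut <- r$dX
    grads[i] <- list(r$grads)   # [[<-]] with NULL would drop the slot
  }
  grads
}

# Update the running batch-norm statistics after a training-mode forward.
nn_update_bn_stats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !is.null(caches[[i]]$batch_mu)) {
      m <- layers[[i]]$momentum
      layers[[i]]$run_mean <- m * layers[[i]]$run_mean +
        (1 - m) * caches[[i]]$batch_mu
      layers[[i]]$run_var <- m * layers[[i]]$run_var +
        (1 - m) * caches[[i]]$batch_var
    }
  }
  layers
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Categorical cross-entropy; `labels` are 1-based class indices.
xent_loss <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p, 1e-12)))
}

# --- Adam ------------------------------------------------------------

# Walk layer parameters (and parallel structures) applying `fn(param,
# grad, m, v)`; used for both state init and updates.
adam_init_like <- function(grads) {
  rapply(grads, function(g) array(0, dim(g) %||% length(g)),
         how = "replace")
}

adam_apply <- function(params, grads, m, v, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(params)) {
    for (k in seq_along(params)) {
      if (is.null(params[[k]]) || is.null(grads[[k]])) next
      r <- adam_apply(params[[k]], grads[[k]], m[[k]], v[[k]],
                      lr, t, beta1, beta2, eps)
      params[[k]] <- r$p
      m[[k]] <- r$m
      v[[k]] <- r$v
    }
    return(list(p = params, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = params - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# Extract/replace the trainable parameter subtrees of a layer, matching
# the shape of its gradient list.
layer_params <- function(layer) {
  switch(layer$type,
    conv = list(W = layer$W, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    dense = list(W = layer$W, b = layer$b),
    incept = list(branches = lapply(layer$branches, function(br) {
      lapply(br, function(sub) {
        if (sub$type == "conv") list(W = sub$W, b = sub$b) else NULL
      })
    })),
    NULL)
}

layer_set_params <- function(layer, p) {
  switch(layer$type,
    conv = , dense = { layer$W <- p$W; layer$b <- p$b },
    bn = { layer$gamma <- p$gamma; layer$beta <- p$beta },
    incept = {
      for (i in seq_along(layer$branches)) {
        for (j in seq_along(layer$branches[[i]])) {
          if (layer$branches[[i]][[j]]$type == "conv") {
            layer$branches[[i]][[j]]$W <- p$branches[[i]][[j]]$W
            layer$branches[[i]][[j]]$b <- p$branches[[i]][[j]]$b
          }
        }
      }
    })
  layer
}
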