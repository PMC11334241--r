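# Minimal 1-D neural-network engine with explicit backpropagation.
#
# Activations flow as 3-D arrays (channels, length, batch) through the
# convolutional part and as matrices (features, batch) after global average
# pooling.  Every layer is a plain list whose learnable parameters live in an
# environment, so the two siamese branches share one parameter store and
# gradients accumulate across branches.  Forward passes return the output
# plus a per-call cache (the model can be run on both branches before any
# backward pass), and backward passes add into the gradient slots.
#
# Convolutions are evaluated as k matrix products (one per kernel tap), each
# a (out_ch x in_ch) %*% (in_ch x L_out*B) BLAS call, which is fast enough
# for desk-scale encoders without compiled code.

nn_param_env <- function(...) {
  e <- new.env(parent = emptyenv())
  vals <- list(...)
  for (nm in names(vals)) assign(nm, vals[[nm]], envir = e)
  e
}

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = FALSE) {
  W <- array(rnorm(out_ch * in_ch * k, sd = sqrt(2 / (in_ch * k))),
             dim = c(out_ch, in_ch, k))
  e <- nn_param_env(W = W, gW = array(0, dim(W)), mW = array(0, dim(W)))
  if (bias) { e$b <- numeric(out_ch); e$gb <- numeric(out_ch); e$mb <- numeric(out_ch) }
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       s = as.integer(stride), p = as.integer(pad), bias = bias, env = e)
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- nn_param_env(gamma = rep(1, ch), beta = numeric(ch),
                    ggamma = numeric(ch), gbeta = numeric(ch),
                    mgamma = numeric(ch), mbeta = numeric(ch),
                    rmean = numeric(ch), rvar = rep(1, ch))
  list(type = "bn", ch = ch, momentum = momentum, eps = eps, env = e)
}

nn_relu <- function() list(type = "relu")

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", k = as.integer(k), s = as.integer(stride),
       p = as.integer(pad))

nn_gap <- function() list(type = "gap")

nn_dense <- function(in_dim, out_dim, bias = TRUE) {
  W <- matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)), out_dim, in_dim)
  e <- nn_param_env(W = W, gW = matrix(0, out_dim, in_dim),
                    mW = matrix(0, out_dim, in_dim))
  if (bias) { e$b <- numeric(out_dim); e$gb <- numeric(out_dim); e$mb <- numeric(out_dim) }
  list(type = "dense", in_dim = in_dim, out_dim = out_dim, bias = bias, env = e)
}

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.null(layers[[1]]$type)) layers <- layers[[1]]
  list(type = "seq", layers = layers)
}

nn_res <- function(main, shortcut = NULL)
  list(type = "res", main = main, shortcut = shortcut)

pad_length <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2L * p, d[3]))
  xp[, (p + 1L):(p + d[2]), ] <- x
  xp
}

nn_forward <- function(layer, x, training = TRUE, update_stats = training) {
  switch(layer$type,
    conv = {
      e <- layer$env
      xp <- pad_length(x, layer$p)
      d <- dim(xp)
      Lo <- (d[2] - layer$k) %/% layer$s + 1L
      B <- d[3]
      pos0 <- layer$s * (0:(Lo - 1L))
      Ymat <- matrix(0, layer$out_ch, Lo * B)
      for (j in seq_len(layer$k)) {
        Xj <- matrix(xp[, j + pos0, , drop = FALSE], nrow = layer$in_ch)
        Ymat <- Ymat + matrix(e$W[, , j], nrow = layer$out_ch) %*% Xj
      }
      if (layer$bias) Ymat <- Ymat + e$b
      list(out = array(Ymat, c(layer$out_ch, Lo, B)),
           cache = list(xp = xp, Lo = Lo, B = B, pos0 = pos0, in_len = dim(x)[2]))
    },
    bn = {
      e <- layer$env
      d <- dim(x)
      xm <- if (length(d) == 3L) matrix(x, nrow = d[1]) else x
      if (training) {
        mu <- rowMeans(xm)
        xc <- xm - mu
        v <- rowMeans(xc * xc)
        if (update_stats) {
          e$rmean <- (1 - layer$momentum) * e$rmean + layer$momentum * mu
          e$rvar <- (1 - layer$momentum) * e$rvar + layer$momentum * v
        }
      } else {
        mu <- e$rmean
        v <- e$rvar
        xc <- xm - mu
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- xc * inv
      y <- e$gamma * xhat + e$beta
      list(out = if (length(d) == 3L) array(y, d) else y,
           cache = list(xhat = xhat, inv = inv, training = training, d = d))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask)
    },
    maxpool = {
      xp <- pad_length(x, layer$p, fill = -Inf)
      d <- dim(xp)
      Lo <- (d[2] - layer$k) %/% layer$s + 1L
      pos0 <- layer$s * (0:(Lo - 1L))
      Y <- array(-Inf, c(d[1], Lo, d[3]))
      idx <- array(0L, c(d[1], Lo, d[3]))
      for (j in seq_len(layer$k)) {
        v <- xp[, j + pos0, , drop = FALSE]
        better <- v > Y
        Y[better] <- v[better]
        idx[better] <- j
      }
      list(out = Y, cache = list(idx = idx, pos0 = pos0, d = d,
                                 in_len = dim(x)[2]))
    },
    gap = {
      d <- dim(x)
      h <- colSums(aperm(x, c(2, 1, 3))) / d[2]  # (C, B)
      list(out = h, cache = d)
    },
    dense = {
      e <- layer$env
      y <- e$W %*% x
      if (layer$bias) y <- y + e$b
      list(out = y, cache = x)
    },
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- nn_forward(layer$layers[[i]], x, training, update_stats)
        x <- r$out
        caches[[i]] <- r$cache
      }
      list(out = x, cache = caches)
    },
    res = {
      rm_ <- nn_forward(layer$main, x, training, update_stats)
      rs <- if (is.null(layer$shortcut)) list(out = x, cache = NULL)
            else nn_forward(layer$shortcut, x, training, update_stats)
      pre <- rm_$out + rs$out
      mask <- pre > 0
      list(out = pre * mask,
           cache = list(main = rm_$cache, shortcut = rs$cache, mask = mask))
    },
    stopf("unknown layer type %s", layer$type))
}

nn_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      e <- layer$env
      dY <- matrix(dout, nrow = layer$out_ch)
      d <- dim(cache$xp)
      dxp <- array(0, d)
      for (j in seq_len(layer$k)) {
        cols <- j + cache$pos0
        Xj <- matrix(cache$xp[, cols, , drop = FALSE], nrow = layer$in_ch)
        e$gW[, , j] <- e$gW[, , j] + dY %*% t(Xj)
        Cj <- crossprod(matrix(e$W[, , j], nrow = layer$out_ch), dY)
        dxp[, cols, ] <- dxp[, cols, , drop = FALSE] +
          array(Cj, c(layer$in_ch, cache$Lo, cache$B))
      }
      if (layer$bias) e$gb <- e$gb + rowSums(dY)
      if (layer$p > 0L)
        dxp[, (layer$p + 1L):(layer$p + cache$in_len), , drop = FALSE]
      else dxp
    },
    bn = {
      e <- layer$env
      d <- cache$d
      dym <- if (length(d) == 3L) matrix(dout, nrow = d[1]) else dout
      e$ggamma <- e$ggamma + rowSums(dym * cache$xhat)
      e$gbeta <- e$gbeta + rowSums(dym)
      if (cache$training) {
        N <- ncol(dym)
        dxhat <- dym * e$gamma
        dx <- (cache$inv / N) *
          (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
      } else {
        dx <- dym * (e$gamma * cache$inv)
      }
      if (length(d) == 3L) array(dx, d) else dx
    },
    relu = dout * cache,
    maxpool = {
      d <- cache$d
      dxp <- array(0, d)
      Lo <- dim(dout)[2]
      for (j in seq_len(layer$k)) {
        sel <- cache$idx == j
        if (!any(sel)) next
        contrib <- dout * sel
        cols <- j + cache$pos0
        dxp[, cols, ] <- dxp[, cols, , drop = FALSE] + contrib
      }
      if (layer$p > 0L)
        dxp[, (layer$p + 1L):(layer$p + cache$in_len), , drop = FALSE]
      else dxp
    },
    gap = {
      d <- cache
      aperm(array(rep(c(dout / d[2]), times = d[2]), c(d[1], d[3], d[2])),
            c(1, 3, 2))
    },
    dense = {
      e <- layer$env
      e$gW <- e$gW + dout %*% t(cache)
      if (layer$bias) e$gb <- e$gb + rowSums(dout)
      crossprod(e$W, dout)
    },
    seq = {
      for (i in rev(seq_along(layer$layers)))
        dout <- nn_backward(layer$layers[[i]], cache[[i]], dout)
      dout
    },
    res = {
      dpre <- dout * cache$mask
      dxm <- nn_backward(layer$main, cache$main, dpre)
      dxs <- if (is.null(layer$shortcut)) dpre
             else nn_backward(layer$shortcut, cache$shortcut, dpre)
      dxm + dxs
    },
    stopf("unknown layer type %s", layer$type))
}

# collect all parameter environments in a module tree
nn_param_envs <- function(layer) {
  switch(layer$type,
    conv = , bn = , dense = list(layer$env),
    seq = do.call(c, lapply(layer$layers, nn_param_envs)),
    res = c(nn_param_envs(layer$main),
            if (!is.null(layer$shortcut)) nn_param_envs(layer$shortcut)),
    list())
}

nn_zero_grads <- function(envs) {
  for (e in envs) {
    if (!is.null(e$gW)) e$gW[] <- 0
    if (!is.null(e$gb)) e$gb[] <- 0
    if (!is.null(e$ggamma)) { e$ggamma[] <- 0; e$gbeta[] <- 0 }
  }
  invisible(NULL)
}

# SGD with momentum and decoupled weight decay (decay on weights only,
# not biases or batch-norm affine parameters)
nn_sgd_step <- function(envs, lr, momentum = 0.9, weight_decay = 0) {
  for (e in envs) {
    if (!is.null(e$gW)) {
      g <- e$gW + weight_decay * e$W
      e$mW <- momentum * e$mW + g
      e$W <- e$W - lr * e$mW
    }
    if (!is.null(e$gb)) {
      e$mb <- momentum * e$mb + e$gb
      e$b <- e$b - lr * e$mb
    }
    if (!is.null(e$ggamma)) {
      e$mgamma <- momentum * e$mgamma + e$ggamma
      e$gamma <- e$gamma - lr * e$mgamma
      e$mbeta <- momentum * e$mbeta + e$gbeta
      e$beta <- e$beta - lr * e$mbeta
    }
  }
  invisible(NULL)
}

# flatten all learnable parameters (and running stats) to a named numeric
# vector; used for checkpointing and freeze-contract tests
nn_param_vector <- function(layer, prefix = "m") {
  envs <- nn_param_envs(layer)
  out <- list()
  for (i in seq_along(envs)) {
    e <- envs[[i]]
    for (nm in c("W", "b", "gamma", "beta", "rmean", "rvar")) {
      if (!is.null(e[[nm]]))
        out[[sprintf("%s.%02d.%s", prefix, i, nm)]] <- as.numeric(e[[nm]])
    }
  }
  unlist(out)
}

nn_set_param_vector <- function(layer, vec, prefix = "m") {
  envs <- nn_param_envs(layer)
  for (i in seq_along(envs)) {
    e <- envs[[i]]
    for (nm in c("W", "b", "gamma", "beta", "rmean", "rvar")) {
      if (!is.null(e[[nm]])) {
        key <- sprintf("%s.%02d.%s", prefix, i, nm)
        idx <- startsWith(names(vec), paste0(key, ""))
        vals <- vec[idx]
        if (length(vals) != length(e[[nm]]))
          stopf("checkpoint mismatch at %s: %d vs %d values",
                key, length(vals), length(e[[nm]]))
        v <- e[[nm]]
        v[] <- as.numeric(vals)
        e[[nm]] <- v
      }
    }
  }
  invisible(NULL)
}

# residual block builders ----------------------------------------------------

basic_block <- function(in_ch, out_ch, stride = 1L) {
  main <- nn_seq(nn_conv(in_ch, out_ch, 3L, stride, 1L), nn_bn(out_ch),
                 nn_relu(), nn_conv(out_ch, out_ch, 3L, 1L, 1L), nn_bn(out_ch))
  shortcut <- if (stride != 1L || in_ch != out_ch)
    nn_seq(nn_conv(in_ch, out_ch, 1L, stride, 0L), nn_bn(out_ch)) else NULL
  nn_res(main, shortcut)
}

bottleneck_block <- function(in_ch, mid_ch, out_ch, stride = 1L) {
  main <- nn_seq(nn_conv(in_ch, mid_ch, 1L), nn_bn(mid_ch), nn_relu(),
                 nn_conv(mid_ch, mid_ch, 3L, stride, 1L), nn_bn(mid_ch),
                 nn_relu(),
                 nn_conv(mid_ch, out_ch, 1L), nn_bn(out_ch))
  shortcut <- if (stride != 1L || in_ch != out_ch)
    nn_seq(nn_conv(in_ch, out_ch, 1L, stride, 0L), nn_bn(out_ch)) else NULL
  nn_res(main, shortcut)
}

build_encoder <- function(variant, feature_dim) {
  if (variant == "tiny_1d") {
    if (feature_dim %% 4 != 0) stopf("tiny_1d feature_dim must be divisible by 4")
    w <- feature_dim %/% 4
    return(nn_seq(
      nn_conv(1L, w, 7L, 2L, 3L), nn_bn(w), nn_relu(), nn_maxpool(),
      basic_block(w, w, 1L),
      basic_block(w, 2L * w, 2L),
      basic_block(2L * w, 4L * w, 2L),
      basic_block(4L * w, 4L * w, 1L),
      nn_gap()))
  }
  counts <- switch(variant,
                   resnet50_1d = c(3L, 4L, 6L, 3L),
                   resnet101_1d = c(3L, 4L, 23L, 3L),
                   resnet152_1d = c(3L, 8L, 36L, 3L),
                   stopf("unknown encoder variant %s", variant))
  mids <- c(64L, 128L, 256L, 512L)
  layers <- list(nn_conv(1L, 64L, 7L, 2L, 3L), nn_bn(64L), nn_relu(),
                 nn_maxpool())
  in_ch <- 64L
  for (stage in 1:4) {
    stride <- if (stage == 1L) 1L else 2L
    out_ch <- mids[stage] * 4L
    for (b in seq_len(counts[stage])) {
      layers <- c(layers, list(bottleneck_block(in_ch, mids[stage], out_ch,
                                                if (b == 1L) stride else 1L)))
      in_ch <- out_ch
    }
  }
  nn_seq(c(layers, list(nn_gap())))
}

encoder_feature_dim <- function(variant, feature_dim = NULL) {
  if (variant == "tiny_1d") {
    if (is.null(feature_dim)) 64L else as.integer(feature_dim)
  } else 2048L
}
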