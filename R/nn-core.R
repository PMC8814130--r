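# Minimal neural-network engine: 2D/3D convolution, max-pooling, batch
# normalisation, dense layers, dropout, LSTM, Adam, and exact backprop.
# Single-sample forward/backward with gradient accumulation over minibatches;
# all layers are pure functions of their inputs and the R RNG stream, so a
# set.seed() upstream makes training bit-reproducible (single-threaded BLAS
# assumed, as in any R session).
#
# Layer constructors draw initial weights from the *current* RNG stream.

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- layer constructors -----------------------------------------------

nn_layer_conv2 <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L,
                           trainable = TRUE) {
  fan_in <- k * k * cin
  list(type = "conv2", k = k, pad = pad, cin = cin, cout = cout,
       W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout), trainable = trainable)
}

nn_layer_conv3 <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L,
                           trainable = TRUE) {
  fan_in <- k * k * k * cin
  list(type = "conv3", k = k, pad = pad, cin = cin, cout = cout,
       W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout), trainable = trainable)
}

nn_layer_pool2 <- function() list(type = "pool2", trainable = FALSE)
nn_layer_pool3 <- function() list(type = "pool3", trainable = FALSE)
nn_layer_relu  <- function() list(type = "relu", trainable = FALSE)

nn_layer_dense <- function(din, dout, trainable = TRUE) {
  list(type = "dense", din = din, dout = dout,
       W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), dout, din),
       b = numeric(dout), trainable = trainable)
}

nn_layer_dropout <- function(rate) list(type = "dropout", rate = rate,
                                        trainable = FALSE)

# Adaptive average pooling to a gh x gw grid, flattened to a vector.
nn_layer_gapgrid <- function(gh, gw) list(type = "gapgrid", gh = gh, gw = gw,
                                          trainable = FALSE)

# Global average pooling over all spatial dims of a 3D/2D feature map.
nn_layer_gap <- function() list(type = "gap", trainable = FALSE)

# Per-channel batch normalisation over the spatial extent of one sample
# (volume-wise stats during training; running averages at inference).
nn_layer_bn <- function(c, momentum = 0.1, eps = 1e-5, trainable = TRUE) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), trainable = trainable)
}

## ---- im2col helpers ---------------------------------------------------

nn_pad2 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

nn_pad3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

# Patch-extraction index matrices depend only on the input shape and
# kernel size, so they are built once and cached; extraction itself is a
# single vectorised gather.
.nn_idx_cache <- new.env(parent = emptyenv())

nn_im2col2_idx <- function(dimxp, k, ho, wo) {
  key <- paste0("c2_", paste(dimxp, collapse = "x"), "_", k)
  idx <- .nn_idx_cache[[key]]
  if (is.null(idx)) {
    h <- dimxp[1]; w <- dimxp[2]; cc <- dimxp[3]
    idx <- matrix(0L, ho * wo, k * k * cc)
    col <- 0L
    for (ch in seq_len(cc)) for (dj in seq_len(k)) for (di in seq_len(k)) {
      col <- col + 1L
      idx[, col] <- as.integer(
        outer(di:(di + ho - 1L), (dj:(dj + wo - 1L) - 1L) * h, "+") +
          (ch - 1L) * h * w)
    }
    .nn_idx_cache[[key]] <- idx
  }
  idx
}

nn_im2col2 <- function(xp, k, ho, wo) {
  idx <- nn_im2col2_idx(dim(xp), k, ho, wo)
  matrix(xp[idx], nrow(idx), ncol(idx))
}

nn_col2im2 <- function(dpatches, dimxp, k, ho, wo) {
  dxp <- array(0, dimxp)
  col <- 0L
  for (ch in seq_len(dimxp[3])) {
    acc <- matrix(0, dimxp[1], dimxp[2])
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      col <- col + 1L
      acc[di:(di + ho - 1L), dj:(dj + wo - 1L)] <-
        acc[di:(di + ho - 1L), dj:(dj + wo - 1L)] +
        matrix(dpatches[, col], ho, wo)
    }
    dxp[, , ch] <- acc
  }
  dxp
}

nn_im2col3_idx <- function(dimxp, k, dout, ho, wo) {
  key <- paste0("c3_", paste(dimxp, collapse = "x"), "_", k)
  idx <- .nn_idx_cache[[key]]
  if (is.null(idx)) {
    d <- dimxp[1]; h <- dimxp[2]; w <- dimxp[3]; cc <- dimxp[4]
    idx <- matrix(0L, dout * ho * wo, k * k * k * cc)
    col <- 0L
    base <- array(0L, c(dout, ho, wo))
    for (ch in seq_len(cc)) for (dj in seq_len(k)) for (di in seq_len(k))
      for (dd in seq_len(k)) {
        col <- col + 1L
        for (j in seq_len(wo))
          base[, , j] <- outer(dd:(dd + dout - 1L),
                               (di:(di + ho - 1L) - 1L) * d, "+") +
            (dj + j - 2L) * d * h
        idx[, col] <- as.integer(base) + (ch - 1L) * d * h * w
      }
    .nn_idx_cache[[key]] <- idx
  }
  idx
}

nn_im2col3 <- function(xp, k, dout, ho, wo) {
  idx <- nn_im2col3_idx(dim(xp), k, dout, ho, wo)
  matrix(xp[idx], nrow(idx), ncol(idx))
}

nn_col2im3 <- function(dpatches, dimxp, k, dout, ho, wo) {
  dxp <- array(0, dimxp)
  col <- 0L
  for (ch in seq_len(dimxp[4])) {
    acc <- array(0, dimxp[1:3])
    for (dj in seq_len(k)) for (di in seq_len(k)) for (dd in seq_len(k)) {
      col <- col + 1L
      acc[dd:(dd + dout - 1L), di:(di + ho - 1L), dj:(dj + wo - 1L)] <-
        acc[dd:(dd + dout - 1L), di:(di + ho - 1L), dj:(dj + wo - 1L)] +
        array(dpatches[, col], c(dout, ho, wo))
    }
    dxp[, , , ch] <- acc
  }
  dxp
}

## ---- forward/backward per layer ---------------------------------------

nn_fwd_layer <- function(layer, x, training) {
  switch(layer$type,
    conv2 = {
      xp <- nn_pad2(x, layer$pad)
      ho <- dim(xp)[1] - layer$k + 1L
      wo <- dim(xp)[2] - layer$k + 1L
      patches <- nn_im2col2(xp, layer$k, ho, wo)
      out <- sweep(patches %*% layer$W, 2, layer$b, "+")
      dim(out) <- c(ho, wo, layer$cout)
      list(out = out, cache = list(patches = patches, dimxp = dim(xp),
                                   ho = ho, wo = wo, pad = layer$pad))
    },
    conv3 = {
      xp <- nn_pad3(x, layer$pad)
      dd <- dim(xp)[1] - layer$k + 1L
      ho <- dim(xp)[2] - layer$k + 1L
      wo <- dim(xp)[3] - layer$k + 1L
      patches <- nn_im2col3(xp, layer$k, dd, ho, wo)
      out <- sweep(patches %*% layer$W, 2, layer$b, "+")
      dim(out) <- c(dd, ho, wo, layer$cout)
      list(out = out, cache = list(patches = patches, dimxp = dim(xp),
                                   dd = dd, ho = ho, wo = wo,
                                   pad = layer$pad))
    },
    pool2 = {
      d <- dim(x)
      ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
      out <- array(0, c(ho, wo, d[3]))
      arg <- array(0L, c(ho, wo, d[3]))
      i1 <- seq.int(1L, 2L * ho, 2L); j1 <- seq.int(1L, 2L * wo, 2L)
      for (ch in seq_len(d[3])) {
        xc <- x[, , ch]
        m <- list(xc[i1, j1, drop = FALSE], xc[i1 + 1L, j1, drop = FALSE],
                  xc[i1, j1 + 1L, drop = FALSE],
                  xc[i1 + 1L, j1 + 1L, drop = FALSE])
        best <- m[[1]]; a <- matrix(1L, ho, wo)
        for (q in 2:4) {
          upd <- m[[q]] > best
          best[upd] <- m[[q]][upd]; a[upd] <- q
        }
        out[, , ch] <- best; arg[, , ch] <- a
      }
      list(out = out, cache = list(arg = arg, dimx = d, ho = ho, wo = wo))
    },
    pool3 = {
      d <- dim(x)
      dd <- d[1] %/% 2L; ho <- d[2] %/% 2L; wo <- d[3] %/% 2L
      out <- array(0, c(dd, ho, wo, d[4]))
      arg <- array(0L, c(dd, ho, wo, d[4]))
      s1 <- seq.int(1L, 2L * dd, 2L)
      i1 <- seq.int(1L, 2L * ho, 2L); j1 <- seq.int(1L, 2L * wo, 2L)
      offs <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
      for (ch in seq_len(d[4])) {
        xc <- x[, , , ch]
        best <- xc[s1, i1, j1, drop = FALSE]
        dim(best) <- c(dd, ho, wo)
        a <- array(1L, c(dd, ho, wo))
        for (q in 2:8) {
          mq <- xc[s1 + offs$a[q], i1 + offs$b[q], j1 + offs$c[q],
                   drop = FALSE]
          dim(mq) <- c(dd, ho, wo)
          upd <- mq > best
          best[upd] <- mq[upd]; a[upd] <- q
        }
        out[, , , ch] <- best; arg[, , , ch] <- a
      }
      list(out = out, cache = list(arg = arg, dimx = d, dd = dd, ho = ho,
                                   wo = wo, offs = offs))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    dense = {
      out <- drop(layer$W %*% as.numeric(x)) + layer$b
      list(out = out, cache = list(x = as.numeric(x)))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    gapgrid = {
      d <- dim(x)
      pr <- nn_bin_matrix(layer$gh, d[1])
      pc <- nn_bin_matrix(layer$gw, d[2])
      out <- array(0, c(layer$gh, layer$gw, d[3]))
      for (ch in seq_len(d[3])) out[, , ch] <- pr %*% x[, , ch] %*% t(pc)
      list(out = as.numeric(out), cache = list(pr = pr, pc = pc, dimx = d))
    },
    gap = {
      d <- dim(x)
      nd <- length(d)
      cc <- d[nd]
      xm <- matrix(x, ncol = cc)
      list(out = colMeans(xm), cache = list(dimx = d, nsp = nrow(xm)))
    },
    bn = {
      d <- dim(x)
      cc <- d[length(d)]
      xm <- matrix(x, ncol = cc)
      if (training) {
        m <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, m)^2)
      } else {
        m <- layer$run_mean; v <- layer$run_var
      }
      xhat <- sweep(sweep(xm, 2, m), 2, sqrt(v + layer$eps), "/")
      out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, m = m, v = v, dimx = d,
                                   training = training))
    },
    stop("unknown layer type: ", layer$type))
}

# Averaging matrix mapping n input positions onto g contiguous bins.
nn_bin_matrix <- function(g, n) {
  bins <- pmin(g, floor((seq_len(n) - 1) * g / n) + 1L)
  m <- matrix(0, g, n)
  for (i in seq_len(n)) m[bins[i], i] <- 1
  m / pmax(rowSums(m), 1)
}

nn_bwd_layer <- function(layer, cache, dout) {
  switch(layer$type,
    conv2 = {
      doutm <- matrix(dout, cache$ho * cache$wo, layer$cout)
      dW <- crossprod(cache$patches, doutm)
      db <- colSums(doutm)
      dpatches <- tcrossprod(doutm, layer$W)
      dxp <- nn_col2im2(dpatches, cache$dimxp, layer$k, cache$ho, cache$wo)
      p <- cache$pad
      dx <- if (p > 0)
        dxp[(p + 1):(dim(dxp)[1] - p), (p + 1):(dim(dxp)[2] - p), ,
            drop = FALSE] else dxp
      list(grads = list(W = dW, b = db), dx = dx)
    },
    conv3 = {
      doutm <- matrix(dout, cache$dd * cache$ho * cache$wo, layer$cout)
      dW <- crossprod(cache$patches, doutm)
      db <- colSums(doutm)
      dpatches <- tcrossprod(doutm, layer$W)
      dxp <- nn_col2im3(dpatches, cache$dimxp, layer$k, cache$dd, cache$ho,
                        cache$wo)
      p <- cache$pad
      dx <- if (p > 0)
        dxp[(p + 1):(dim(dxp)[1] - p), (p + 1):(dim(dxp)[2] - p),
            (p + 1):(dim(dxp)[3] - p), , drop = FALSE] else dxp
      list(grads = list(W = dW, b = db), dx = dx)
    },
    pool2 = {
      d <- cache$dimx
      dx <- array(0, d)
      i1 <- seq.int(1L, 2L * cache$ho, 2L)
      j1 <- seq.int(1L, 2L * cache$wo, 2L)
      di <- c(0L, 1L, 0L, 1L); dj <- c(0L, 0L, 1L, 1L)
      for (ch in seq_len(d[3])) {
        dc <- matrix(0, d[1], d[2])
        g <- dout[, , ch]; a <- cache$arg[, , ch]
        for (q in 1:4) {
          sel <- a == q
          if (!any(sel)) next
          gi <- i1[row(a)[sel]] + di[q]
          gj <- j1[col(a)[sel]] + dj[q]
          dc[cbind(gi, gj)] <- dc[cbind(gi, gj)] + g[sel]
        }
        dx[, , ch] <- dc
      }
      list(grads = NULL, dx = dx)
    },
    pool3 = {
      d <- cache$dimx
      dx <- array(0, d)
      s1 <- seq.int(1L, 2L * cache$dd, 2L)
      i1 <- seq.int(1L, 2L * cache$ho, 2L)
      j1 <- seq.int(1L, 2L * cache$wo, 2L)
      offs <- cache$offs
      idx <- expand.grid(a = seq_len(cache$dd), b = seq_len(cache$ho),
                         c = seq_len(cache$wo))
      for (ch in seq_len(d[4])) {
        dc <- array(0, d[1:3])
        g <- as.numeric(dout[, , , ch]); a <- as.integer(cache$arg[, , , ch])
        for (q in 1:8) {
          sel <- a == q
          if (!any(sel)) next
          coord <- cbind(s1[idx$a[sel]] + offs$a[q],
                         i1[idx$b[sel]] + offs$b[q],
                         j1[idx$c[sel]] + offs$c[q])
          dc[coord] <- dc[coord] + g[sel]
        }
        dx[, , , ch] <- dc
      }
      list(grads = NULL, dx = dx)
    },
    relu = list(grads = NULL, dx = dout * cache$mask),
    dense = {
      dout <- as.numeric(dout)
      list(grads = list(W = tcrossprod(dout, cache$x), b = dout),
           dx = drop(crossprod(layer$W, dout)))
    },
    dropout = {
      if (is.null(cache$mask)) list(grads = NULL, dx = dout)
      else list(grads = NULL, dx = dout * cache$mask)
    },
    gapgrid = {
      d <- cache$dimx
      dg <- array(dout, c(nrow(cache$pr), nrow(cache$pc), d[3]))
      dx <- array(0, d)
      for (ch in seq_len(d[3]))
        dx[, , ch] <- t(cache$pr) %*% dg[, , ch] %*% cache$pc
      list(grads = NULL, dx = dx)
    },
    gap = {
      cc <- cache$dimx[length(cache$dimx)]
      dxm <- matrix(rep(as.numeric(dout) / cache$nsp, each = cache$nsp),
                    ncol = cc)
      dx <- array(dxm, cache$dimx)
      list(grads = NULL, dx = dx)
    },
    bn = {
      d <- cache$dimx
      cc <- d[length(d)]
      dom <- matrix(dout, ncol = cc)
      n <- nrow(dom)
      dgamma <- colSums(dom * cache$xhat)
      dbeta <- colSums(dom)
      if (cache$training) {
        inv_sd <- 1 / sqrt(cache$v + layer$eps)
        dxhat <- sweep(dom, 2, layer$gamma, "*")
        # standard batch-norm backward, vectorised per channel
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
        dxm <- sweep(t1 - t2, 2, inv_sd, "*")
      } else {
        dxm <- sweep(sweep(dom, 2, layer$gamma, "*"), 2,
                     sqrt(layer$run_var + layer$eps), "/")
      }
      dx <- array(dxm, d)
      list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
    },
    stop("unknown layer type: ", layer$type))
}

## ---- whole-net forward/backward ---------------------------------------

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- nn_fwd_layer(net[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- nn_bwd_layer(net[[i]], caches[[i]], dout)
    grads[i] <- list(r$grads)
    dout <- r$dx
  }
  list(grads = grads, dx = dout)
}

# Update batch-norm running statistics from a training-mode forward pass.
nn_update_bn <- function(net, caches) {
  for (i in seq_along(net)) {
    if (net[[i]]$type == "bn") {
      mom <- net[[i]]$momentum
      net[[i]]$run_mean <- (1 - mom) * net[[i]]$run_mean + mom * caches[[i]]$m
      net[[i]]$run_var <- (1 - mom) * net[[i]]$run_var + mom * caches[[i]]$v
    }
  }
  net
}

nn_param_names <- function(layer)
  switch(layer$type, conv2 = , conv3 = , dense = c("W", "b"),
         bn = c("gamma", "beta"), character(0))

nn_count_params <- function(net, trainable_only = FALSE) {
  total <- 0
  for (layer in net) {
    if (trainable_only && !isTRUE(layer$trainable)) next
    for (p in nn_param_names(layer)) total <- total + length(layer[[p]])
  }
  total
}

# Flat digest of all weights: used by freeze-contract tests.
nn_weight_checksum <- function(net) {
  vals <- unlist(lapply(net, function(l)
    lapply(nn_param_names(l), function(p) as.numeric(l[[p]]))))
  if (is.null(vals)) return(0)
  sum(vals * seq_along(vals) %% 97)
}

## ---- Adam -------------------------------------------------------------

nn_adam_init <- function() list(t = 0, m = list(), v = list())

nn_adam_step <- function(value, grad, state, key, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m[[key]])) {
    state$m[[key]] <- grad * 0
    state$v[[key]] <- grad * 0
  }
  state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * grad
  state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * grad^2
  mhat <- state$m[[key]] / (1 - beta1^state$t)
  vhat <- state$v[[key]] / (1 - beta2^state$t)
  list(value = value - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# One Adam update of every trainable layer in `net` given accumulated grads.
nn_apply_grads <- function(net, grads, state, lr, prefix = "L") {
  state$t <- state$t + 1
  for (i in seq_along(net)) {
    if (!isTRUE(net[[i]]$trainable) || is.null(grads[[i]])) next
    for (p in names(grads[[i]])) {
      r <- nn_adam_step(net[[i]][[p]], grads[[i]][[p]], state,
                        paste0(prefix, i, ".", p), lr)
      net[[i]][[p]] <- r$value
      state <- r$state
    }
  }
  list(net = net, state = state)
}

nn_acc_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]]))
      acc[[i]][[p]] <- acc[[i]][[p]] + grads[[i]][[p]]
  }
  acc
}

nn_scale_grads <- function(grads, s) {
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) grads[[i]][[p]] <- grads[[i]][[p]] * s
  }
  grads
}

## ---- softmax cross-entropy --------------------------------------------

nn_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# returns loss, probabilities and gradient wrt logits for integer label y
nn_softmax_ce <- function(z, y) {
  p <- nn_softmax(z)
  dz <- p
  dz[y] <- dz[y] - 1
  list(loss = -log(max(p[y], 1e-12)), p = p, dz = dz)
}

## ---- LSTM -------------------------------------------------------------

nn_lstm_init <- function(d, h) {
  s <- 1 / sqrt(h)
  list(Wx = matrix(stats::runif(4 * h * d, -s, s), 4 * h, d),
       Wh = matrix(stats::runif(4 * h * h, -s, s), 4 * h, h),
       b = numeric(4 * h), h = h, d = d)
}

# X: T x d matrix of slice embeddings, in slice order. Returns final hidden
# state plus the cache needed for truncated-free full BPTT.
nn_lstm_forward <- function(p, X) {
  h <- p$h; Tn <- nrow(X)
  ht <- numeric(h); ct <- numeric(h)
  cache <- vector("list", Tn)
  ii <- 1:h; ff <- (h + 1):(2 * h); gg <- (2 * h + 1):(3 * h)
  oo <- (3 * h + 1):(4 * h)
  for (t in seq_len(Tn)) {
    xt <- X[t, ]
    z <- drop(p$Wx %*% xt + p$Wh %*% ht) + p$b
    i <- nn_sigmoid(z[ii]); f <- nn_sigmoid(z[ff])
    g <- tanh(z[gg]); o <- nn_sigmoid(z[oo])
    c_prev <- ct
    ct <- f * c_prev + i * g
    tc <- tanh(ct)
    hp <- ht
    ht <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o, c = ct,
                       c_prev = c_prev, tc = tc, h_prev = hp)
  }
  list(h = ht, cache = cache)
}

nn_lstm_backward <- function(p, cache, dh_last) {
  h <- p$h; Tn <- length(cache)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- matrix(0, Tn, p$d)
  dh <- dh_last; dc <- numeric(h)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_prev <- dc * cc$f
    dzi <- di * cc$i * (1 - cc$i)
    dzf <- df * cc$f * (1 - cc$f)
    dzg <- dg * (1 - cc$g^2)
    dzo <- do * cc$o * (1 - cc$o)
    dz <- c(dzi, dzf, dzg, dzo)
    dWx <- dWx + tcrossprod(dz, cc$xt)
    dWh <- dWh + tcrossprod(dz, cc$h_prev)
    db <- db + dz
    dX[t, ] <- drop(crossprod(p$Wx, dz))
    dh <- drop(crossprod(p$Wh, dz))
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}
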