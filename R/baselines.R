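# End-to-end comparison models: a 3D CNN over the full 25-slice volume and
# a CNN-LSTM that embeds each slice with one weight-shared convolutional
# block and reads the slice sequence with an LSTM. Both consume the same
# preprocessed inputs as the two-stage pipeline.

#' 3D-CNN baseline specification
#'
#' Three 3D convolution stages with max-pooling, two batch-normalisation
#' layers, global average pooling and one fully connected softmax layer.
#' Filter counts are configurable (the reference figure's channel sizes are
#' not normative).
#'
#' @param conv_filter_counts exactly three filter counts.
#' @param kernel_size cubic kernel extent (default 3).
#' @return object of class `baseline_3dcnn_spec`.
#' @export
baseline_3dcnn_spec <- function(conv_filter_counts = c(8L, 16L, 32L),
                                kernel_size = 3L) {
  if (length(conv_filter_counts) != 3)
    stop("exactly three 3D convolution stages are required")
  structure(list(conv_filter_counts = as.integer(conv_filter_counts),
                 kernel_size = as.integer(kernel_size)),
            class = "baseline_3dcnn_spec")
}

#' CNN-LSTM baseline specification
#'
#' One 2D convolution block of six convolutional layers with max-pooling,
#' weight-shared across the 25 slices (set `share_weights = FALSE` for the
#' unshared variant), feeding an LSTM with 64 hidden units and a fully
#' connected softmax classifier.
#'
#' @param conv_layers_per_block number of conv layers in the block (6).
#' @param lstm_hidden_units LSTM hidden size (64).
#' @param channels per-conv-layer filter counts (length
#'   `conv_layers_per_block`); the last is the slice embedding size.
#' @param share_weights share the conv block across slices.
#' @return object of class `cnnlstm_spec`.
#' @export
cnnlstm_spec <- function(conv_layers_per_block = 6L,
                         lstm_hidden_units = 64L,
                         channels = c(8L, 8L, 16L, 16L, 32L, 32L),
                         share_weights = TRUE) {
  if (conv_layers_per_block != 6)
    stop("the 2D convolution block uses six convolutional layers")
  if (length(channels) != conv_layers_per_block)
    stop("channels must have one entry per conv layer")
  structure(list(conv_layers_per_block = as.integer(conv_layers_per_block),
                 lstm_hidden_units = as.integer(lstm_hidden_units),
                 channels = as.integer(channels),
                 share_weights = isTRUE(share_weights)),
            class = "cnnlstm_spec")
}

#' Build the 3D-CNN baseline
#'
#' @param spec a [baseline_3dcnn_spec()].
#' @param seed integer controlling weight initialisation.
#' @return object of class `cnn3d_model`. Its `$net` is the ordered layer
#'   list (3 `conv3`, 3 `pool3`, 2 `bn`, 1 `gap`, 1 `dense`).
#' @export
build_3dcnn <- function(spec = baseline_3dcnn_spec(), seed = 1L) {
  f <- spec$conv_filter_counts
  with_seed(seed, {
    net <- list(
      nn_layer_conv3(3L, f[1], k = spec$kernel_size), nn_layer_relu(),
      nn_layer_pool3(), nn_layer_bn(f[1]),
      nn_layer_conv3(f[1], f[2], k = spec$kernel_size), nn_layer_relu(),
      nn_layer_pool3(), nn_layer_bn(f[2]),
      nn_layer_conv3(f[2], f[3], k = spec$kernel_size), nn_layer_relu(),
      nn_layer_pool3(),
      nn_layer_gap(),
      nn_layer_dense(f[3], 3L))
    structure(list(spec = spec, net = net, seed = seed, trained = FALSE),
              class = "cnn3d_model")
  })
}

#' Build the CNN-LSTM baseline
#'
#' @param spec a [cnnlstm_spec()].
#' @param seed integer controlling weight initialisation.
#' @return object of class `cnnlstm_model`: a conv block (`$block`; 25
#'   replicas under `share_weights = FALSE`), LSTM parameters (`$lstm`) and
#'   the final classifier (`$fc`).
#' @export
build_cnn_lstm <- function(spec = cnnlstm_spec(), seed = 1L) {
  ch <- spec$channels
  with_seed(seed, {
    make_block <- function() {
      layers <- list()
      cin <- 3L
      for (i in seq_along(ch)) {
        layers <- c(layers, list(nn_layer_conv2(cin, ch[i]),
                                 nn_layer_relu()))
        if (i %% 2 == 0) layers <- c(layers, list(nn_layer_pool2()))
        cin <- ch[i]
      }
      c(layers, list(nn_layer_gap()))
    }
    block <- if (spec$share_weights) make_block()
             else lapply(1:25, function(i) make_block())
    emb <- ch[length(ch)]
    lstm <- nn_lstm_init(emb, spec$lstm_hidden_units)
    fc <- nn_layer_dense(spec$lstm_hidden_units, 3L)
    structure(list(spec = spec, block = block, lstm = lstm, fc = fc,
                   emb_dim = emb, seed = seed, trained = FALSE),
              class = "cnnlstm_model")
  })
}

## ---- forward passes ---------------------------------------------------

# stack a preprocessed volume into the 4D array (slices, H, W, channels)
volume_stack <- function(pre) {
  d <- dim(pre[[1]]$pixels)
  x <- array(0, c(length(pre), d))
  for (i in seq_along(pre)) x[i, , , ] <- pre[[i]]$pixels / 255
  x
}

cnn3d_forward <- function(model, x, training = FALSE) {
  nn_forward(model$net, x, training)
}

cnnlstm_forward <- function(model, pre, training = FALSE) {
  Tn <- length(pre)
  E <- matrix(0, Tn, model$emb_dim)
  bcaches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    blk <- if (model$spec$share_weights) model$block else model$block[[t]]
    fw <- nn_forward(blk, pre[[t]]$pixels / 255, training)
    E[t, ] <- fw$out
    bcaches[[t]] <- fw$caches
  }
  lf <- nn_lstm_forward(model$lstm, E)
  fz <- nn_fwd_layer(model$fc, lf$h, training)
  list(out = fz$out, E = E, bcaches = bcaches, lstm_cache = lf$cache,
       fc_cache = fz$cache)
}

#' Predict a case label with a baseline model
#'
#' @param object a `cnn3d_model`.
#' @param case an `oct_case`.
#' @param p preprocessing parameters (same stack as the proposed model).
#' @param ... unused.
#' @return list with `label` and named `probabilities` (softmax, sums
#'   to 1).
#' @export
predict.cnn3d_model <- function(object, case, p = preprocess_params(), ...) {
  pre <- preprocess_volume(case, p, training = FALSE)
  z <- cnn3d_forward(object, volume_stack(pre))$out
  prob <- nn_softmax(z)
  names(prob) <- CSC_LABELS
  list(label = CSC_LABELS[which.max(prob)], probabilities = prob)
}

#' @rdname predict.cnn3d_model
#' @export
predict.cnnlstm_model <- function(object, case, p = preprocess_params(),
                                  ...) {
  pre <- preprocess_volume(case, p, training = FALSE)
  z <- cnnlstm_forward(object, pre)$out
  prob <- nn_softmax(z)
  names(prob) <- CSC_LABELS
  list(label = CSC_LABELS[which.max(prob)], probabilities = prob)
}

#' @export
print.cnn3d_model <- function(x, ...) {
  types <- vapply(x$net, `[[`, character(1), "type")
  cat(sprintf("<cnn3d_model> filters %s; layers: %s\n",
              paste(x$spec$conv_filter_counts, collapse = "/"),
              paste(types, collapse = "-")))
  invisible(x)
}

#' @export
print.cnnlstm_model <- function(x, ...) {
  cat(sprintf(paste0("<cnnlstm_model> 6-conv block (%s, %s), LSTM %d ",
                     "hidden units\n"),
              paste(x$spec$channels, collapse = "/"),
              if (x$spec$share_weights) "shared" else "unshared",
              x$spec$lstm_hidden_units))
  invisible(x)
}

## ---- end-to-end training ----------------------------------------------

#' Train a baseline model end-to-end
#'
#' Case-level cross-entropy training with Adam, using the same
#' preprocessing and augmentation stack as the two-stage pipeline.
#'
#' @param model a `cnn3d_model` or `cnnlstm_model`.
#' @param cases training `oct_case` list (at least 2 labels).
#' @param hyper a [train_hyper()]; `batch_size` counts cases.
#' @param p,a preprocessing and augmentation parameters.
#' @return the trained model with a per-epoch loss log in `$log`.
#' @export
train_end_to_end <- function(model, cases, hyper = train_hyper(),
                             p = preprocess_params(),
                             a = augment_params()) {
  if (length(unique(case_labels(cases))) < 2)
    stop("training cases must contain at least 2 distinct labels")
  y <- match(case_labels(cases), CSC_LABELS)
  base <- lapply(cases, function(cs)
    preprocess_volume(cs, p, training = FALSE))
  with_seed(hyper$seed, {
    if (inherits(model, "cnn3d_model"))
      model <- train_cnn3d_loop(model, base, y, hyper, a)
    else if (inherits(model, "cnnlstm_model"))
      model <- train_cnnlstm_loop(model, base, y, hyper, a)
    else stop("unsupported model class")
  })
  model$trained <- TRUE
  model
}

maybe_augment_volume <- function(pre, a) {
  if (!a$enabled) return(pre)
  lapply(pre, augment_slice, a = a)
}

train_cnn3d_loop <- function(model, base, y, hyper, a) {
  n <- length(base)
  state <- nn_adam_init()
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1, n, by = hyper$batch_size)) {
      idx <- ord[b0:min(n, b0 + hyper$batch_size - 1)]
      acc <- NULL
      for (i in idx) {
        x <- volume_stack(maybe_augment_volume(base[[i]], a))
        fw <- nn_forward(model$net, x, training = TRUE)
        model$net <- nn_update_bn(model$net, fw$caches)
        sc <- nn_softmax_ce(fw$out, y[i])
        ep_loss <- ep_loss + sc$loss
        bw <- nn_backward(model$net, fw$caches, sc$dz)
        acc <- nn_acc_grads(acc, bw$grads)
      }
      r <- nn_apply_grads(model$net, nn_scale_grads(acc, 1 / length(idx)),
                          state, hyper$learning_rate)
      model$net <- r$net; state <- r$state
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n))
  }
  model$log <- log
  model
}

train_cnnlstm_loop <- function(model, base, y, hyper, a) {
  n <- length(base)
  state <- nn_adam_init()
  shared <- model$spec$share_weights
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1, n, by = hyper$batch_size)) {
      idx <- ord[b0:min(n, b0 + hyper$batch_size - 1)]
      acc_blk <- NULL; acc_lstm <- NULL; acc_fc <- NULL
      acc_blk_list <- NULL
      for (i in idx) {
        pre <- maybe_augment_volume(base[[i]], a)
        fw <- cnnlstm_forward(model, pre, training = TRUE)
        sc <- nn_softmax_ce(fw$out, y[i])
        ep_loss <- ep_loss + sc$loss
        bfc <- nn_bwd_layer(model$fc, fw$fc_cache, sc$dz)
        acc_fc <- if (is.null(acc_fc)) bfc$grads
                  else Map(`+`, acc_fc, bfc$grads)
        bl <- nn_lstm_backward(model$lstm, fw$lstm_cache, bfc$dx)
        gl <- bl[c("Wx", "Wh", "b")]
        acc_lstm <- if (is.null(acc_lstm)) gl else Map(`+`, acc_lstm, gl)
        for (t in seq_len(nrow(bl$dX))) {
          blk <- if (shared) model$block else model$block[[t]]
          bb <- nn_backward(blk, fw$bcaches[[t]], bl$dX[t, ])
          if (shared) acc_blk <- nn_acc_grads(acc_blk, bb$grads)
          else {
            if (is.null(acc_blk_list))
              acc_blk_list <- vector("list", length(model$block))
            acc_blk_list[[t]] <- nn_acc_grads(acc_blk_list[[t]], bb$grads)
          }
        }
      }
      s <- 1 / length(idx)
      state$t <- state$t + 1
      r <- nn_apply_grads_flat(model$fc, lapply(acc_fc, `*`, s), state,
                               hyper$learning_rate, "fc")
      model$fc <- r$layer; state <- r$state
      for (pn in c("Wx", "Wh", "b")) {
        ru <- nn_adam_step(model$lstm[[pn]], acc_lstm[[pn]] * s, state,
                           paste0("lstm.", pn), hyper$learning_rate)
        model$lstm[[pn]] <- ru$value; state <- ru$state
      }
      if (shared) {
        state$t <- state$t - 1     # one logical step for all param groups
        r <- nn_apply_grads(model$block, nn_scale_grads(acc_blk, s), state,
                            hyper$learning_rate)
        model$block <- r$net; state <- r$state
      } else {
        for (t in seq_along(model$block)) {
          if (is.null(acc_blk_list[[t]])) next
          st0 <- state$t
          r <- nn_apply_grads(model$block[[t]],
                              nn_scale_grads(acc_blk_list[[t]], s), state,
                              hyper$learning_rate,
                              prefix = paste0("B", t, "L"))
          model$block[[t]] <- r$net; state <- r$state
          state$t <- st0
        }
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n))
  }
  model$log <- log
  model
}

# Adam update of a single standalone layer (the CNN-LSTM classifier head).
nn_apply_grads_flat <- function(layer, grads, state, lr, tag) {
  for (pn in names(grads)) {
    r <- nn_adam_step(layer[[pn]], grads[[pn]], state,
                      paste0(tag, ".", pn), lr)
    layer[[pn]] <- r$value; state <- r$state
  }
  list(layer = layer, state = state)
}
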