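# Single-image prediction (SIP) model: a pluggable convolutional backbone
# (frozen by default) with a four-layer fully connected head ending in a
# 3-way softmax. Trained on lesion cuts only; at test time all 25 slices of
# a volume are scored and stacked into a 25 x 3 softmax matrix.

#' SIP model specification
#'
#' @param backbone `"small-cnn"` (a 4-block CNN, the desk-scale default) or
#'   `"resnet50"` (optional; requires an external pretrained weight archive,
#'   not bundled).
#' @param freeze_backbone keep backbone weights fixed and train only the
#'   head (default `TRUE`, the transfer-learning configuration).
#' @param head_widths four positive layer widths ending in 3 (the class
#'   count); default `c(512, 256, 64, 3)`.
#' @param dropout_rate dropout probability after each hidden head layer.
#' @param pretrained initialise the backbone from published weights
#'   (`resnet50` only); otherwise random initialisation from the build seed.
#' @param channels per-block filter counts of the small CNN backbone.
#' @param gap_grid `(rows, cols)` of the adaptive average-pooling grid that
#'   turns the last feature map into the head input (preserves coarse
#'   lesion position).
#' @return object of class `sip_spec`.
#' @export
sip_spec <- function(backbone = c("small-cnn", "resnet50"),
                     freeze_backbone = TRUE,
                     head_widths = c(512L, 256L, 64L, 3L),
                     dropout_rate = 0.5, pretrained = FALSE,
                     channels = c(8L, 16L, 32L, 32L),
                     gap_grid = c(2L, 3L)) {
  if (is.character(backbone)) backbone <- backbone[1]
  if (!backbone %in% c("small-cnn", "resnet50"))
    stop("unknown backbone: ", backbone)
  if (length(head_widths) != 4)
    stop("exactly four head layers are required (four linear layers with ",
         "dropouts)")
  if (head_widths[4] != 3)
    stop("final head width must equal the number of classes (3)")
  if (any(head_widths <= 0)) stop("head widths must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(backbone = backbone, freeze_backbone = isTRUE(freeze_backbone),
                 head_widths = as.integer(head_widths),
                 dropout_rate = dropout_rate, pretrained = isTRUE(pretrained),
                 channels = as.integer(channels),
                 gap_grid = as.integer(gap_grid)),
            class = "sip_spec")
}

#' Training hyper-parameters
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed controlling initialisation order, shuffling,
#'   dropout and augmentation.
#' @param early_stop_patience stop after this many epochs without a training
#'   loss improvement (`NULL` disables).
#' @return object of class `train_hyper`.
#' @export
train_hyper <- function(epochs = 20L, batch_size = 32L,
                        learning_rate = 1e-3, optimizer = "adam",
                        seed = 1L, early_stop_patience = NULL) {
  if (epochs < 1 || batch_size < 1) stop("counts must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (!identical(optimizer, "adam"))
    stop("unknown optimizer: ", optimizer)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "train_hyper")
}

# Pooling stages are only inserted while the running feature map stays at
# least as large as the adaptive pooling grid, so small inputs keep the
# coarse spatial layout the head relies on.
sip_backbone_layers <- function(spec, input_shape) {
  ch <- spec$channels
  cin <- 3L
  h <- input_shape[1]; w <- input_shape[2]
  layers <- list()
  for (i in seq_along(ch)) {
    layers <- c(layers, list(
      nn_layer_conv2(cin, ch[i], trainable = !spec$freeze_backbone),
      nn_layer_relu()))
    if (h %/% 2L >= spec$gap_grid[1] && w %/% 2L >= spec$gap_grid[2]) {
      layers <- c(layers, list(nn_layer_pool2()))
      h <- h %/% 2L; w <- w %/% 2L
    }
    cin <- ch[i]
  }
  c(layers, list(nn_layer_gapgrid(spec$gap_grid[1], spec$gap_grid[2])))
}

sip_head_layers <- function(spec, feat_dim) {
  w <- spec$head_widths
  dims <- c(feat_dim, w)
  layers <- list()
  for (i in 1:4) {
    layers <- c(layers, list(nn_layer_dense(dims[i], dims[i + 1])))
    if (i < 4) layers <- c(layers, list(
      nn_layer_relu(), nn_layer_dropout(spec$dropout_rate)))
  }
  layers
}

#' Build an (untrained) SIP model
#'
#' @param spec a [sip_spec()].
#' @param input_shape `(height, width)` the model expects after
#'   preprocessing; default `c(163, 254)`.
#' @param seed integer controlling weight initialisation.
#' @return object of class `sip_model`. With `freeze_backbone = TRUE` only
#'   head parameters are marked trainable.
#' @export
build_sip <- function(spec = sip_spec(), input_shape = c(163L, 254L),
                      seed = 1L) {
  if (spec$backbone == "resnet50")
    stop("backbone 'resnet50' requires an ImageNet-pretrained weight ",
         "archive, which is not bundled; use backbone = 'small-cnn'")
  with_seed(seed, {
    backbone <- sip_backbone_layers(spec, as.integer(input_shape))
    feat_dim <- prod(spec$gap_grid) * spec$channels[length(spec$channels)]
    head <- sip_head_layers(spec, feat_dim)
    structure(list(spec = spec, backbone = backbone, head = head,
                   feat_dim = feat_dim,
                   input_shape = as.integer(input_shape), seed = seed,
                   trained = FALSE, log = NULL),
              class = "sip_model")
  })
}

#' @export
print.sip_model <- function(x, ...) {
  cat(sprintf(paste0("<sip_model> backbone=%s (%s), head %s, ",
                     "%d trainable / %d total parameters, %s\n"),
              x$spec$backbone,
              if (x$spec$freeze_backbone) "frozen" else "trainable",
              paste(x$spec$head_widths, collapse = "-"),
              sip_n_params(x, trainable_only = TRUE), sip_n_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Count SIP parameters
#' @param model a `sip_model`.
#' @param trainable_only count only parameters updated during training.
#' @export
sip_n_params <- function(model, trainable_only = FALSE) {
  nn_count_params(c(model$backbone, model$head), trainable_only)
}

#' Select the SIP training slice pool
#'
#' CSC cases contribute only their lesion cuts, labelled with the case
#' label; training the per-slice model on non-lesion cuts would force it to
#' separate normal images from visually normal CSC cuts, which is the
#' failure mode the lesion-cut restriction avoids. Normal cases contribute
#' all 25 slices.
#'
#' @param cases list of `oct_case` (training cases only).
#' @param lesion_cuts_only if `FALSE`, CSC cases contribute all slices
#'   (ablation configuration).
#' @return list with `slices` (raw `slice_image`s), `labels`, `case_ids`.
#' @export
select_sip_training_slices <- function(cases, lesion_cuts_only = TRUE) {
  slices <- list(); labels <- character(0); ids <- character(0)
  for (cs in cases) {
    mask <- lesion_mask(cs)
    if (cs$label != "normal" && !any(mask))
      stop("CSC case ", cs$case_id, " has zero lesion cuts")
    keep <- if (cs$label == "normal" || !lesion_cuts_only)
      seq_along(cs$slices) else which(mask)
    slices <- c(slices, cs$slices[keep])
    labels <- c(labels, rep(cs$label, length(keep)))
    ids <- c(ids, rep(cs$case_id, length(keep)))
  }
  list(slices = slices, labels = labels, case_ids = ids)
}

## ---- batched MLP head -------------------------------------------------

mlp_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(x = X)
      X <- sweep(X %*% t(l$W), 2, l$b, "+")
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = X > 0)
      X <- pmax(X, 0)
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix((stats::runif(length(X)) >= l$rate) / (1 - l$rate),
                       nrow(X), ncol(X))
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else caches[[i]] <- list(mask = NULL)
    } else stop("unsupported head layer: ", l$type)
  }
  list(out = X, caches = caches)
}

mlp_backward <- function(layers, caches, dZ) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(dZ, caches[[i]]$x), b = colSums(dZ))
      dZ <- dZ %*% l$W
    } else if (l$type == "relu") {
      dZ <- dZ * caches[[i]]$mask
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) dZ <- dZ * caches[[i]]$mask
    }
  }
  grads
}

mlp_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

sip_backbone_features <- function(model, pixel_list) {
  t(vapply(pixel_list, function(px)
    nn_forward(model$backbone, px / 255)$out, numeric(model$feat_dim)))
}

#' Train the SIP model
#'
#' Minimises cross-entropy over the slice pool with Adam. With the default
#' frozen backbone only the four head layers are updated; frozen parameters
#' are bit-unchanged after training. Augmentation (when enabled) is redrawn
#' every epoch.
#'
#' @param model a `sip_model` from [build_sip()].
#' @param pool slice pool from [select_sip_training_slices()].
#' @param hyper a [train_hyper()].
#' @param p,a preprocessing and augmentation parameters.
#' @return the trained `sip_model`, with a per-epoch training log in
#'   `$log`.
#' @export
train_sip <- function(model, pool, hyper = train_hyper(),
                      p = preprocess_params(), a = augment_params()) {
  n <- length(pool$slices)
  if (n == 0) stop("empty training pool")
  if (length(unique(pool$labels)) < 2)
    stop("training pool must contain at least 2 distinct labels")
  y <- match(pool$labels, CSC_LABELS)
  base <- lapply(pool$slices, function(s)
    downsample_slice(crop_slice(s, p), p))
  with_seed(hyper$seed, {
    if (model$spec$freeze_backbone) {
      model <- sip_train_head(model, base, y, hyper, a)
    } else {
      model <- sip_train_full(model, base, y, hyper, a)
    }
  })
  model$trained <- TRUE
  model
}

sip_train_head <- function(model, base, y, hyper, a) {
  n <- length(base)
  static <- !a$enabled
  if (static)
    X0 <- sip_backbone_features(model, lapply(base, `[[`, "pixels"))
  state <- nn_adam_init()
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  best <- Inf; stall <- 0L
  for (ep in seq_len(hyper$epochs)) {
    X <- if (static) X0 else
      sip_backbone_features(model, lapply(base, function(s)
        augment_slice(s, a)$pixels))
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq(1, n, by = hyper$batch_size)) {
      idx <- ord[b0:min(n, b0 + hyper$batch_size - 1)]
      fb <- mlp_forward(model$head, X[idx, , drop = FALSE], training = TRUE)
      P <- mlp_softmax(fb$out)
      yi <- y[idx]
      ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_along(idx), yi)], 1e-12)))
      ep_correct <- ep_correct + sum(max.col(P, "first") == yi)
      dZ <- P
      dZ[cbind(seq_along(idx), yi)] <- dZ[cbind(seq_along(idx), yi)] - 1
      dZ <- dZ / length(idx)
      grads <- mlp_backward(model$head, fb$caches, dZ)
      r <- nn_apply_grads(model$head, grads, state, hyper$learning_rate)
      model$head <- r$net; state <- r$state
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 accuracy = ep_correct / n))
    if (!is.null(hyper$early_stop_patience)) {
      if (ep_loss / n < best - 1e-6) { best <- ep_loss / n; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= hyper$early_stop_patience) break
    }
  }
  model$log <- log
  model
}

sip_train_full <- function(model, base, y, hyper, a) {
  net <- c(model$backbone, model$head)
  nb <- length(model$backbone)
  state <- nn_adam_init()
  n <- length(base)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq(1, n, by = hyper$batch_size)) {
      idx <- ord[b0:min(n, b0 + hyper$batch_size - 1)]
      acc <- NULL
      for (i in idx) {
        s <- if (a$enabled) augment_slice(base[[i]], a) else base[[i]]
        fw <- nn_forward(net, s$pixels / 255, training = TRUE)
        sc <- nn_softmax_ce(fw$out, y[i])
        ep_loss <- ep_loss + sc$loss
        ep_correct <- ep_correct + (which.max(sc$p) == y[i])
        bw <- nn_backward(net, fw$caches, sc$dz)
        acc <- nn_acc_grads(acc, bw$grads)
      }
      r <- nn_apply_grads(net, nn_scale_grads(acc, 1 / length(idx)), state,
                          hyper$learning_rate)
      net <- r$net; state <- r$state
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 accuracy = ep_correct / n))
  }
  model$backbone <- net[seq_len(nb)]
  model$head <- net[(nb + 1):length(net)]
  model$log <- log
  model
}

#' Per-slice class probabilities
#'
#' @param model a `sip_model`.
#' @param image a preprocessed `slice_image` (or bare H x W x 3 array) at
#'   the model's input size.
#' @return named softmax vector `(acute, chronic, normal)` summing to 1.
#' @export
predict_slice <- function(model, image) {
  px <- if (inherits(image, "slice_image")) image$pixels else image
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an H x W x 3 image")
  if (!is.null(model$input_shape) &&
      !all(d[1:2] == model$input_shape))
    stop("input dimensions ", d[1], "x", d[2], " do not match the model's ",
         "expected ", model$input_shape[1], "x", model$input_shape[2])
  feat <- nn_forward(model$backbone, px / 255)$out
  z <- mlp_forward(model$head, matrix(feat, 1))$out
  p <- drop(mlp_softmax(z))
  names(p) <- CSC_LABELS
  p
}

#' Score a whole volume: the 25 x 3 softmax matrix
#'
#' Applies evaluation-path preprocessing (no augmentation, lesion flags
#' ignored) to every slice and stacks the per-slice softmax vectors in
#' slice order.
#'
#' @param model a trained `sip_model`.
#' @param case an `oct_case`.
#' @param p a [preprocess_params()] object.
#' @return `softmax_matrix`: n_slices x 3 matrix with columns
#'   `acute, chronic, normal`, rows summing to 1, and attribute `case_id`.
#' @export
predict_volume <- function(model, case, p = preprocess_params()) {
  pre <- preprocess_volume(case, p, training = FALSE)
  X <- sip_backbone_features(model, lapply(pre, `[[`, "pixels"))
  P <- mlp_softmax(mlp_forward(model$head, X)$out)
  colnames(P) <- CSC_LABELS
  structure(P, case_id = case$case_id, class = c("softmax_matrix", "matrix",
                                                 "array"))
}
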