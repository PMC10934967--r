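#' Configuration of the Conv1D classifier
#'
#' Four temporal convolutions (no padding, ReLU) followed by flattening and
#' three dense layers; dropout after the first two dense layers; softmax
#' output.  The reference geometry (input 740 x 30, kernels 32/64/128/256
#' of size 5 with stride 2, dense 800/200/52, dropout 0.7) propagates to
#' temporal lengths 368, 182, 89, 43 and a flatten dimension of 11008.
#'
#' @param input_len window length W.
#' @param n_channels input channels C.
#' @param conv_channels kernel counts of the four (or more) conv layers.
#' @param kernel_size,stride shared temporal kernel size and stride.
#' @param dense_units dense layer widths; the last entry is the number of
#'   classes.
#' @param dropout_p dropout probability on the first two dense layers,
#'   in `[0, 1)`.
#' @return a `conv1d_config` with computed `conv_lens` and `flatten_dim`.
#' @export
conv1d_config <- function(input_len = 740, n_channels = 30,
                          conv_channels = c(32, 64, 128, 256),
                          kernel_size = 5, stride = 2,
                          dense_units = c(800, 200, 52),
                          dropout_p = 0.7) {
  stopifnot(length(conv_channels) >= 1, length(dense_units) >= 1,
            dropout_p >= 0, dropout_p < 1, kernel_size >= 1, stride >= 1)
  lens <- integer(length(conv_channels))
  L <- input_len
  min_len <- 1L
  for (i in rev(seq_along(conv_channels))) {
    min_len <- (min_len - 1L) * stride + kernel_size
  }
  for (i in seq_along(conv_channels)) {
    if (L < kernel_size) {
      stop("input_len too short for the conv stack; need at least ", min_len)
    }
    L <- (L - kernel_size) %/% stride + 1L
    lens[i] <- L
  }
  structure(list(input_len = input_len, n_channels = n_channels,
                 conv_channels = conv_channels, kernel_size = kernel_size,
                 stride = stride, dense_units = dense_units,
                 dropout_p = dropout_p, conv_lens = lens,
                 flatten_dim = L * conv_channels[length(conv_channels)],
                 n_classes = dense_units[length(dense_units)]),
            class = "conv1d_config")
}

#' Configuration of the InceptionTime classifier
#'
#' A stack of Inception modules: a size-1 bottleneck convolution feeds
#' three parallel same-padded convolutions with kernels of different sizes;
#' a parallel max-pool branch is projected by a size-1 convolution; the
#' four branches are concatenated (4 x `n_filters` channels), batch
#' normalized and passed through ReLU.  Residual shortcuts (a size-1
#' convolution + batch norm on the block input) are added every
#' `residual_every` modules.  The head is global average pooling over time
#' followed by a dense softmax layer.
#'
#' @param input_len,n_channels input geometry.
#' @param n_modules number of Inception modules (default 6).
#' @param n_filters filters per branch (default 32).
#' @param kernel_sizes branch kernel sizes (default 10, 20, 40).
#' @param bottleneck_channels bottleneck width (default 32).
#' @param use_residual add residual shortcuts (default TRUE).
#' @param residual_every shortcut spacing in modules (default 3).
#' @param n_classes output classes (default 52).
#' @export
inception_config <- function(input_len = 740, n_channels = 30,
                             n_modules = 6, n_filters = 32,
                             kernel_sizes = c(10, 20, 40),
                             bottleneck_channels = 32,
                             use_residual = TRUE, residual_every = 3,
                             n_classes = 52) {
  stopifnot(n_modules >= 1, n_filters >= 1, length(kernel_sizes) >= 1,
            bottleneck_channels >= 1, n_classes >= 1, residual_every >= 1)
  structure(list(input_len = input_len, n_channels = n_channels,
                 n_modules = n_modules, n_filters = n_filters,
                 kernel_sizes = kernel_sizes,
                 bottleneck_channels = bottleneck_channels,
                 use_residual = use_residual,
                 residual_every = residual_every,
                 module_channels = n_filters * (length(kernel_sizes) + 1L),
                 n_classes = n_classes),
            class = "inception_config")
}

new_handle <- function(arch, config, params, decay_mask, seed) {
  structure(list(arch = arch, config = config, params = params,
                 decay_mask = decay_mask, bn_state = list(), seed = seed),
            class = "classifier_handle")
}

#' @export
print.classifier_handle <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<classifier_handle> %s, %d parameter tensors (%d values)\n",
              x$arch, length(x$params), n_par))
  invisible(x)
}

#' Build a Conv1D classifier
#'
#' @param config a [conv1d_config()].
#' @param seed integer seed for weight initialization (He fan-in normal).
#' @return a `classifier_handle`.
#' @export
build_conv1d <- function(config, seed = 1) {
  stopifnot(inherits(config, "conv1d_config"))
  params <- list()
  mask <- list()
  C_in <- config$n_channels
  for (l in seq_along(config$conv_channels)) {
    init <- conv1d_init(C_in, config$conv_channels[l], config$kernel_size,
                        mix_seed(seed, 10, l))
    params[[paste0("conv", l, ".W")]] <- init$W
    params[[paste0("conv", l, ".b")]] <- init$b
    mask[[paste0("conv", l, ".W")]] <- TRUE
    mask[[paste0("conv", l, ".b")]] <- FALSE
    C_in <- config$conv_channels[l]
  }
  D <- config$flatten_dim
  for (l in seq_along(config$dense_units)) {
    init <- dense_init(D, config$dense_units[l], mix_seed(seed, 20, l))
    params[[paste0("dense", l, ".W")]] <- init$W
    params[[paste0("dense", l, ".b")]] <- init$b
    mask[[paste0("dense", l, ".W")]] <- TRUE
    mask[[paste0("dense", l, ".b")]] <- FALSE
    D <- config$dense_units[l]
  }
  new_handle("conv1d", config, params, mask, seed)
}

forward_conv1d <- function(handle, x, train = FALSE, keep_cache = FALSE) {
  cf <- handle$config
  p <- handle$params
  caches <- list()
  h <- x
  for (l in seq_along(cf$conv_channels)) {
    cv <- conv1d_fwd(h, p[[paste0("conv", l, ".W")]],
                     p[[paste0("conv", l, ".b")]], stride = cf$stride)
    r <- relu_fwd(cv$out)
    h <- r$out
    if (keep_cache) caches[[paste0("conv", l)]] <- list(conv = cv,
                                                        mask = r$mask)
  }
  N <- dim(h)[3]
  hf <- matrix(h, cf$flatten_dim, N)
  penult <- hf
  n_dense <- length(cf$dense_units)
  for (l in seq_len(n_dense)) {
    z <- dense_fwd(hf, p[[paste0("dense", l, ".W")]],
                   p[[paste0("dense", l, ".b")]])
    if (l < n_dense) {
      r <- relu_fwd(z)
      if (l == n_dense - 1L) penult <- r$out
      dr <- dropout_fwd(r$out, cf$dropout_p, train)
      if (keep_cache) caches[[paste0("dense", l)]] <-
          list(x = hf, mask = r$mask, drop = dr$mask)
      hf <- dr$out
    } else {
      if (keep_cache) caches[[paste0("dense", l)]] <- list(x = hf)
      hf <- z
    }
  }
  list(logits = hf, penult = penult, caches = caches)
}

backward_conv1d <- function(handle, caches, dlogits) {
  cf <- handle$config
  p <- handle$params
  grads <- list()
  n_dense <- length(cf$dense_units)
  dh <- dlogits
  for (l in rev(seq_len(n_dense))) {
    cc <- caches[[paste0("dense", l)]]
    if (l < n_dense) {
      dh <- dropout_bwd(dh, cc$drop)
      dh <- relu_bwd(dh, cc$mask)
    }
    bw <- dense_bwd(dh, p[[paste0("dense", l, ".W")]], cc$x)
    grads[[paste0("dense", l, ".W")]] <- bw$dW
    grads[[paste0("dense", l, ".b")]] <- bw$db
    dh <- bw$dx
  }
  n_conv <- length(cf$conv_channels)
  Llast <- cf$conv_lens[n_conv]
  dh <- array(dh, c(Llast, cf$conv_channels[n_conv], ncol(dh)))
  for (l in rev(seq_len(n_conv))) {
    cc <- caches[[paste0("conv", l)]]
    dh <- relu_bwd(dh, cc$mask)
    bw <- conv1d_bwd(dh, p[[paste0("conv", l, ".W")]], cc$conv)
    grads[[paste0("conv", l, ".W")]] <- bw$dW
    grads[[paste0("conv", l, ".b")]] <- bw$db
    dh <- bw$dx
  }
  grads
}

#' Build an InceptionTime classifier
#'
#' @param config an [inception_config()].
#' @param seed integer seed for weight initialization.
#' @return a `classifier_handle`.
#' @export
build_inceptiontime <- function(config, seed = 1) {
  stopifnot(inherits(config, "inception_config"))
  params <- list()
  mask <- list()
  # convolutions feeding straight into a batch norm carry no bias (it would
  # be cancelled by the normalization and receive zero gradient)
  add <- function(name, init, w_decay = TRUE, bias = TRUE) {
    params[[paste0(name, ".W")]] <<- init$W
    mask[[paste0(name, ".W")]] <<- w_decay
    if (bias) {
      params[[paste0(name, ".b")]] <<- init$b
      mask[[paste0(name, ".b")]] <<- FALSE
    }
  }
  add_bn <- function(name, n_ch) {
    init <- bn_init(n_ch)
    params[[paste0(name, ".gamma")]] <<- init$gamma
    params[[paste0(name, ".beta")]] <<- init$beta
    mask[[paste0(name, ".gamma")]] <<- FALSE
    mask[[paste0(name, ".beta")]] <<- FALSE
  }
  C_in <- config$n_channels
  res_in_ch <- C_in
  for (i in seq_len(config$n_modules)) {
    add(paste0("m", i, ".bottleneck"),
        conv1d_init(C_in, config$bottleneck_channels, 1,
                    mix_seed(seed, 30, i)))
    for (j in seq_along(config$kernel_sizes)) {
      add(paste0("m", i, ".branch", j),
          conv1d_init(config$bottleneck_channels, config$n_filters,
                      config$kernel_sizes[j], mix_seed(seed, 31, i, j)),
          bias = FALSE)
    }
    add(paste0("m", i, ".pool"),
        conv1d_init(C_in, config$n_filters, 1, mix_seed(seed, 32, i)),
        bias = FALSE)
    add_bn(paste0("m", i, ".bn"), config$module_channels)
    C_in <- config$module_channels
    if (config$use_residual && i %% config$residual_every == 0L) {
      add(paste0("m", i, ".shortcut"),
          conv1d_init(res_in_ch, config$module_channels, 1,
                      mix_seed(seed, 33, i)), bias = FALSE)
      add_bn(paste0("m", i, ".shortcut_bn"), config$module_channels)
      res_in_ch <- config$module_channels
    }
  }
  add("head", dense_init(config$module_channels, config$n_classes,
                         mix_seed(seed, 34)))
  new_handle("inceptiontime", config, params, mask, seed)
}

zero_bias <- function(p, name, W) p[[name]] %||% numeric(nrow(W))

forward_inception <- function(handle, x, train = FALSE, keep_cache = FALSE) {
  cf <- handle$config
  p <- handle$params
  bn_state <- handle$bn_state
  caches <- list()
  h <- x
  res_in <- x
  res_marks <- integer(0)
  for (i in seq_len(cf$n_modules)) {
    mc <- list()
    bt <- conv1d_fwd(h, p[[paste0("m", i, ".bottleneck.W")]],
                     p[[paste0("m", i, ".bottleneck.b")]])
    mc$bottleneck <- bt
    branches <- vector("list", length(cf$kernel_sizes))
    for (j in seq_along(cf$kernel_sizes)) {
      Wj <- p[[paste0("m", i, ".branch", j, ".W")]]
      branches[[j]] <- conv1d_fwd(
        bt$out, Wj, zero_bias(p, paste0("m", i, ".branch", j, ".b"), Wj),
        pad = same_pad(cf$kernel_sizes[j]))
    }
    mc$branches <- branches
    mp <- maxpool3_fwd(h)
    Wp <- p[[paste0("m", i, ".pool.W")]]
    pl <- conv1d_fwd(mp$out, Wp, zero_bias(p, paste0("m", i, ".pool.b"), Wp))
    mc$maxpool <- mp
    mc$pool <- pl
    d <- dim(bt$out)
    cat_out <- array(0, c(d[1], cf$module_channels, d[3]))
    at <- 0L
    for (j in seq_along(branches)) {
      cat_out[, at + seq_len(cf$n_filters), ] <- branches[[j]]$out
      at <- at + cf$n_filters
    }
    cat_out[, at + seq_len(cf$n_filters), ] <- pl$out
    bn_name <- paste0("m", i, ".bn")
    bn <- bn_fwd(cat_out, p[[paste0(bn_name, ".gamma")]],
                 p[[paste0(bn_name, ".beta")]],
                 bn_state[[bn_name]] %||% list(), train)
    bn_state[[bn_name]] <- bn$state
    mc$bn <- bn
    a <- bn$out
    if (cf$use_residual && i %% cf$residual_every == 0L) {
      Ws <- p[[paste0("m", i, ".shortcut.W")]]
      sc <- conv1d_fwd(res_in, Ws,
                       zero_bias(p, paste0("m", i, ".shortcut.b"), Ws))
      sbn_name <- paste0("m", i, ".shortcut_bn")
      sbn <- bn_fwd(sc$out, p[[paste0(sbn_name, ".gamma")]],
                    p[[paste0(sbn_name, ".beta")]],
                    bn_state[[sbn_name]] %||% list(), train)
      bn_state[[sbn_name]] <- sbn$state
      mc$shortcut <- sc
      mc$shortcut_bn <- sbn
      a <- a + sbn$out
      r <- relu_fwd(a)
      h <- r$out
      res_in <- h
      res_marks <- c(res_marks, i)
    } else {
      r <- relu_fwd(a)
      h <- r$out
    }
    mc$mask <- r$mask
    if (keep_cache) caches[[paste0("m", i)]] <- mc
  }
  gp <- gap_fwd(h)
  penult <- gp$out
  logits <- dense_fwd(penult, p[["head.W"]], p[["head.b"]])
  if (keep_cache) {
    caches$gap <- gp
    caches$res_marks <- res_marks
  }
  list(logits = logits, penult = penult, caches = caches,
       bn_state = bn_state)
}

backward_inception <- function(handle, caches, dlogits) {
  cf <- handle$config
  p <- handle$params
  grads <- list()
  bw <- dense_bwd(dlogits, p[["head.W"]], caches$gap$out)
  grads[["head.W"]] <- bw$dW
  grads[["head.b"]] <- bw$db
  dh <- gap_bwd(bw$dx, caches$gap)
  res_marks <- caches$res_marks
  # pending[[as.character(i)]]: gradient to add to the output of module i
  # (0 = network input) coming from residual shortcuts consumed later.
  pending <- list()
  for (i in rev(seq_len(cf$n_modules))) {
    mc <- caches[[paste0("m", i)]]
    key <- as.character(i)
    if (!is.null(pending[[key]])) {
      dh <- dh + pending[[key]]
      pending[[key]] <- NULL
    }
    da <- relu_bwd(dh, mc$mask)
    if (!is.null(mc$shortcut)) {
      sbn_name <- paste0("m", i, ".shortcut_bn")
      sb <- bn_bwd(da, p[[paste0(sbn_name, ".gamma")]], mc$shortcut_bn)
      grads[[paste0(sbn_name, ".gamma")]] <- sb$dgamma
      grads[[paste0(sbn_name, ".beta")]] <- sb$dbeta
      sc <- conv1d_bwd(sb$dx, p[[paste0("m", i, ".shortcut.W")]],
                       mc$shortcut)
      grads[[paste0("m", i, ".shortcut.W")]] <- sc$dW
      prev_mark <- res_marks[res_marks < i]
      src <- if (length(prev_mark)) max(prev_mark) else 0L
      skey <- as.character(src)
      pending[[skey]] <- if (is.null(pending[[skey]])) sc$dx else
        pending[[skey]] + sc$dx
    }
    bn_name <- paste0("m", i, ".bn")
    bb <- bn_bwd(da, p[[paste0(bn_name, ".gamma")]], mc$bn)
    grads[[paste0(bn_name, ".gamma")]] <- bb$dgamma
    grads[[paste0(bn_name, ".beta")]] <- bb$dbeta
    dcat <- bb$dx
    at <- 0L
    dz <- NULL
    for (j in seq_along(cf$kernel_sizes)) {
      dbr <- dcat[, at + seq_len(cf$n_filters), , drop = FALSE]
      at <- at + cf$n_filters
      cb <- conv1d_bwd(dbr, p[[paste0("m", i, ".branch", j, ".W")]],
                       mc$branches[[j]])
      grads[[paste0("m", i, ".branch", j, ".W")]] <- cb$dW
      dz <- if (is.null(dz)) cb$dx else dz + cb$dx
    }
    dpool_out <- dcat[, at + seq_len(cf$n_filters), , drop = FALSE]
    pb <- conv1d_bwd(dpool_out, p[[paste0("m", i, ".pool.W")]], mc$pool)
    grads[[paste0("m", i, ".pool.W")]] <- pb$dW
    dh_pool <- maxpool3_bwd(pb$dx, mc$maxpool)
    btb <- conv1d_bwd(dz, p[[paste0("m", i, ".bottleneck.W")]],
                      mc$bottleneck)
    grads[[paste0("m", i, ".bottleneck.W")]] <- btb$dW
    grads[[paste0("m", i, ".bottleneck.b")]] <- btb$db
    dh <- btb$dx + dh_pool
  }
  if (!is.null(pending[["0"]])) dh <- dh + pending[["0"]]
  grads
}

model_forward <- function(handle, x, train = FALSE, keep_cache = FALSE) {
  if (handle$arch == "conv1d") {
    forward_conv1d(handle, x, train, keep_cache)
  } else {
    forward_inception(handle, x, train, keep_cache)
  }
}

model_backward <- function(handle, caches, dlogits) {
  if (handle$arch == "conv1d") {
    backward_conv1d(handle, caches, dlogits)
  } else {
    backward_inception(handle, caches, dlogits)
  }
}

#' Class probabilities for a batch of windows
#'
#' Inference mode (dropout off, batch-norm running statistics); processed
#' in chunks to bound memory.
#'
#' @param handle a trained `classifier_handle`.
#' @param x `W x C x N` array (or a `window_set`).
#' @param chunk chunk size.
#' @return `n_classes x N` matrix of softmax probabilities.
#' @export
predict_proba <- function(handle, x, chunk = 512L) {
  if (inherits(x, "window_set")) x <- x$x
  N <- dim(x)[3]
  out <- matrix(0, handle$config$n_classes, N)
  for (at in seq(1L, N, by = chunk)) {
    idx <- at:min(at + chunk - 1L, N)
    fw <- model_forward(handle, x[, , idx, drop = FALSE])
    out[, idx] <- softmax_probs(fw$logits)
  }
  out
}

#' Predicted class labels
#' @inheritParams predict_proba
#' @export
predict_classes <- function(handle, x, chunk = 512L) {
  apply(predict_proba(handle, x, chunk), 2, which.max)
}

#' Penultimate-layer features
#'
#' The activation of the last dense layer before the softmax (Conv1D:
#' dimension `dense_units[2]`, 200 in the reference geometry) or the
#' global-average-pooled features (InceptionTime), in inference mode.
#'
#' @inheritParams predict_proba
#' @return `D x N` matrix of features.
#' @export
penultimate_features <- function(handle, x, chunk = 512L) {
  if (inherits(x, "window_set")) x <- x$x
  N <- dim(x)[3]
  parts <- lapply(seq(1L, N, by = chunk), function(at) {
    idx <- at:min(at + chunk - 1L, N)
    model_forward(handle, x[, , idx, drop = FALSE])$penult
  })
  do.call(cbind, parts)
}

#' Re-instantiate the final dense layer
#'
#' Freshly initializes the last pre-softmax dense layer while keeping every
#' other parameter bit-exact; all layers remain trainable.  Used by the
#' transfer-learning protocol after pretraining on ND data.
#'
#' @param handle a `classifier_handle`.
#' @param seed seed for the re-initialization.
#' @export
reinit_final_dense <- function(handle, seed = 1) {
  if (handle$arch == "conv1d") {
    l <- length(handle$config$dense_units)
    D <- if (l == 1) handle$config$flatten_dim else
      handle$config$dense_units[l - 1]
    init <- dense_init(D, handle$config$dense_units[l], mix_seed(seed, 99))
    handle$params[[paste0("dense", l, ".W")]] <- init$W
    handle$params[[paste0("dense", l, ".b")]] <- init$b
  } else {
    init <- dense_init(handle$config$module_channels,
                       handle$config$n_classes, mix_seed(seed, 99))
    handle$params[["head.W"]] <- init$W
    handle$params[["head.b"]] <- init$b
  }
  handle
}

#' Save / load a classifier
#'
#' Standard R serialization of the handle (parameters, config, batch-norm
#' state).
#' @param handle a `classifier_handle`.
#' @param path file path.
#' @export
save_classifier <- function(handle, path) {
  saveRDS(handle, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)
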