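# Minimal neural-network engine used by the classifier builders.
#
# Batches of windows travel as (L, C, N) arrays: time x channels x batch.
# Convolutions are computed as a single matrix product on an im2col-unrolled
# view of the batch (compiled, see src/conv1d.cpp); the remaining primitives
# stay in R as plain BLAS calls.  Every primitive returns the quantities its
# backward pass needs; backward passes are verified against finite
# differences in the test suite.

#' @useDynLib strokehar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

conv1d_init <- function(n_in, n_out, k, seed) {
  with_seed(seed, {
    list(W = matrix(stats::rnorm(n_out * k * n_in, 0,
                                 sqrt(2 / (k * n_in))), n_out, k * n_in),
         b = numeric(n_out))
  })
}

conv1d_fwd <- function(x, W, b, stride = 1L, pad = c(0L, 0L)) {
  d <- dim(x)
  res <- conv1d_fwd_cpp(x, W, b, as.integer(stride),
                        as.integer(pad[1]), as.integer(pad[2]))
  list(out = res$out, xc = res$xc,
       dims = list(L = d[1], C = d[2], stride = as.integer(stride),
                   pad_l = as.integer(pad[1])))
}

conv1d_bwd <- function(dout, W, cache) {
  dm <- cache$dims
  res <- conv1d_bwd_cpp(dout, W, cache$xc, dm$L, dm$C, dm$stride, dm$pad_l)
  list(dx = res$dx, dW = res$dW, db = as.vector(res$db))
}

same_pad <- function(k) {
  p <- k - 1L
  c(p %/% 2L, p - p %/% 2L)
}

dense_init <- function(n_in, n_out, seed) {
  with_seed(seed, {
    list(W = matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)),
                    n_out, n_in),
         b = numeric(n_out))
  })
}

dense_fwd <- function(x, W, b) W %*% x + b                          # x: D x N

dense_bwd <- function(dout, W, x) {
  list(dx = crossprod(W, dout), dW = dout %*% t(x), db = rowSums(dout))
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_bwd <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

bn_init <- function(n_ch) {
  list(gamma = rep(1, n_ch), beta = numeric(n_ch))
}

# Batch normalization over (time, batch) per channel; x is (L, C, N).
bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 3, 2)), ncol = d[2])                  # LN x C
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu^2
    state$mean <- (1 - momentum) * (state$mean %||% mu) + momentum * mu
    state$var <- (1 - momentum) * (state$var %||% v) + momentum * v
  } else {
    mu <- state$mean %||% numeric(d[2])
    v <- state$var %||% rep(1, d[2])
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  out <- aperm(array(y, c(d[1], d[3], d[2])), c(1, 3, 2))
  list(out = out, xhat = xhat, inv = inv, dims = d, state = state)
}

bn_bwd <- function(dout, gamma, cache) {
  d <- cache$dims
  dy <- matrix(aperm(dout, c(1, 3, 2)), ncol = d[2])               # LN x C
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  m <- nrow(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- sweep(dxhat -
                matrix(colMeans(dxhat), m, d[2], byrow = TRUE) -
                cache$xhat *
                matrix(colMeans(dxhat * cache$xhat), m, d[2], byrow = TRUE),
              2, cache$inv, "*")
  list(dx = aperm(array(dx, c(d[1], d[3], d[2])), c(1, 3, 2)),
       dgamma = dgamma, dbeta = dbeta)
}

# Max pooling, kernel 3, stride 1, same padding; x is (L, C, N).
maxpool3_fwd <- function(x) {
  d <- dim(x)
  xp <- array(-Inf, c(d[1] + 2L, d[2], d[3]))
  xp[1 + seq_len(d[1]), , ] <- x
  cur <- xp[seq_len(d[1]), , , drop = FALSE]
  best <- array(1L, d)
  for (s in 2:3) {
    cand <- xp[(s - 1L) + seq_len(d[1]), , , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    best[upd] <- s
  }
  list(out = cur, best = best, dims = d)
}

maxpool3_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  for (s in 1:3) {
    sel <- (cache$best == s) * dout
    # output position t drew from input position t + s - 2
    t_out <- seq_len(d[1])
    t_in <- t_out + s - 2L
    ok <- t_in >= 1L & t_in <= d[1]
    dx[t_in[ok], , ] <- dx[t_in[ok], , , drop = FALSE] +
      sel[t_out[ok], , , drop = FALSE]
  }
  dx
}

gap_fwd <- function(x) {
  d <- dim(x)
  list(out = matrix(colMeans(matrix(x, d[1])), d[2], d[3]), dims = d)
}

gap_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  g <- dout / d[1]
  for (t in seq_len(d[1])) dx[t, , ] <- g
  dx
}

# Softmax cross-entropy; logits K x N, labels in 1..K.
softmax_probs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

xent_loss_grad <- function(logits, labels) {
  p <- softmax_probs(logits)
  N <- ncol(logits)
  ii <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[ii], 1e-12)))
  dlogits <- p
  dlogits[ii] <- dlogits[ii] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Decoupled weight decay: applied to weight matrices, not biases or
# normalization parameters.
adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0.01,
                       decay_mask = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    wd <- if (is.null(decay_mask) || isTRUE(decay_mask[[nm]])) {
      weight_decay
    } else 0
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(params = params, state = state)
}
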