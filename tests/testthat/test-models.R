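# Shape-propagation oracle for valid convolutions: L' = floor((L - k)/s) + 1.
propagate_lengths <- function(L, k, s, n_layers) {
  out <- integer(n_layers)
  for (i in seq_len(n_layers)) {
    L <- (L - k) %/% s + 1L
    out[i] <- L
  }
  out
}

test_that("Conv1D geometry matches the shape-propagation oracle", {
  cf <- conv1d_config()
  expect_equal(cf$conv_lens, propagate_lengths(740, 5, 2, 4))
  expect_equal(cf$conv_lens, c(368, 182, 89, 43))
  expect_equal(cf$flatten_dim, 43 * 256)
  expect_equal(cf$flatten_dim, 11008)
  expect_error(conv1d_config(input_len = 30), "at least")
  # randomized sweep against the oracle
  withr::with_seed(2, {
    for (i in 1:10) {
      L <- sample(100:800, 1); k <- sample(2:7, 1); s <- sample(1:3, 1)
      cfg <- try(conv1d_config(input_len = L, kernel_size = k, stride = s,
                               conv_channels = c(4, 4, 4)), silent = TRUE)
      if (!inherits(cfg, "try-error")) {
        expect_equal(cfg$conv_lens, propagate_lengths(L, k, s, 3))
      }
    }
  })
})

test_that("forward pass yields softmax probabilities and 200-d features", {
  h <- build_conv1d(conv1d_config(), seed = 1)
  x <- withr::with_seed(3, array(stats::rnorm(740 * 30 * 2), c(740, 30, 2)))
  pr <- predict_proba(h, x)
  expect_equal(dim(pr), c(52, 2))
  expect_true(all(pr >= 0))
  expect_equal(colSums(pr), c(1, 1), tolerance = 1e-5)
  feat <- penultimate_features(h, x)
  expect_equal(nrow(feat), 200)
  # inference is deterministic: same window twice, same output
  expect_identical(feat[, 1], penultimate_features(h, x[, , c(1, 1)])[, 2])
})

test_that("Inception modules concatenate to 4 x filters and keep length", {
  cf <- inception_config(input_len = 60, n_channels = 6, n_modules = 2,
                         n_classes = 5)
  expect_equal(cf$module_channels, 4 * 32)
  h <- build_inceptiontime(cf, seed = 2)
  x <- withr::with_seed(4, array(stats::rnorm(60 * 6 * 3), c(60, 6, 3)))
  fw <- strokehar:::model_forward(h, x, keep_cache = TRUE)
  # temporal length preserved through every module (same padding)
  expect_equal(dim(fw$caches$m1$bn$out), c(60, 128, 3))
  expect_equal(dim(fw$caches$m2$bn$out), c(60, 128, 3))
  expect_equal(dim(fw$logits), c(5, 3))
  expect_equal(colSums(strokehar:::softmax_probs(fw$logits)), rep(1, 3),
               tolerance = 1e-5)
  # repeat forward is bit-identical in inference mode
  fw2 <- strokehar:::model_forward(h, x)
  expect_identical(fw$logits, fw2$logits)
})

test_that("both backward passes match finite differences", {
  withr::with_seed(5, {
    x <- array(stats::rnorm(24 * 4 * 5), c(24, 4, 5))
    y <- sample(1:3, 5, replace = TRUE)
  })
  check_grads <- function(h, train) {
    fw <- strokehar:::model_forward(h, x, train = train, keep_cache = TRUE)
    if (!is.null(fw$bn_state)) h$bn_state <- fw$bn_state
    lg <- strokehar:::xent_loss_grad(fw$logits, y)
    gr <- strokehar:::model_backward(h, fw$caches, lg$dlogits)
    eps <- 1e-6
    withr::with_seed(6, {
      for (nm in names(h$params)) {
        n_probe <- min(3, length(h$params[[nm]]))
        for (i in sample(seq_along(h$params[[nm]]), n_probe)) {
          h2 <- h
          h2$params[[nm]][i] <- h2$params[[nm]][i] + eps
          l1 <- strokehar:::xent_loss_grad(
            strokehar:::model_forward(h2, x, train = train)$logits, y)$loss
          h2$params[[nm]][i] <- h2$params[[nm]][i] - 2 * eps
          l0 <- strokehar:::xent_loss_grad(
            strokehar:::model_forward(h2, x, train = train)$logits, y)$loss
          expect_equal(gr[[nm]][i], (l1 - l0) / (2 * eps), tolerance = 1e-4)
        }
      }
    })
    gr
  }
  hc <- build_conv1d(conv1d_config(input_len = 24, n_channels = 4,
                                   conv_channels = c(3, 4), kernel_size = 3,
                                   dense_units = c(6, 5, 3), dropout_p = 0),
                     seed = 7)
  gr_c <- check_grads(hc, train = FALSE)
  expect_setequal(names(gr_c), names(hc$params))

  hi <- build_inceptiontime(
    inception_config(input_len = 24, n_channels = 4, n_modules = 3,
                     n_filters = 3, kernel_sizes = c(3, 5, 8),
                     bottleneck_channels = 3, residual_every = 2,
                     n_classes = 3), seed = 8)
  gr_i <- check_grads(hi, train = TRUE)
  expect_setequal(names(gr_i), names(hi$params))
})

test_that("one optimization step moves every trainable tensor", {
  for (arch in c("conv1d", "inceptiontime")) {
    h <- if (arch == "conv1d") {
      build_conv1d(conv1d_config(input_len = 24, n_channels = 6,
                                 conv_channels = c(4, 4), kernel_size = 3,
                                 dense_units = c(8, 6, 3), dropout_p = 0),
                   seed = 3)
    } else {
      build_inceptiontime(
        inception_config(input_len = 24, n_channels = 6, n_modules = 2,
                         n_filters = 3, kernel_sizes = c(3, 5),
                         bottleneck_channels = 3, residual_every = 2,
                         n_classes = 3), seed = 3)
    }
    ws <- make_test_ws(n_stroke = 1, n_classes = 3, windows_per_class = 8,
                       W = 24, C = 6)
    before <- h$params
    fit <- train_model(h, ws, NULL,
                       train_config(batch_size = 8, total_iterations = 1,
                                    eval_window = c(1, 1), seed = 4))
    moved <- vapply(names(before), function(nm) {
      !isTRUE(all.equal(before[[nm]], fit$handle$params[[nm]],
                        tolerance = 1e-12))
    }, logical(1))
    expect_true(all(moved), info = arch)
  }
})

test_that("Conv1D memorizes a tiny training set (capacity check)", {
  ws <- make_test_ws(n_stroke = 1, n_classes = 3, windows_per_class = 5,
                     W = 32, C = 6, class_signal = 1, seed = 10)
  h <- build_conv1d(conv1d_config(input_len = 32, n_channels = 6,
                                  conv_channels = c(8, 12), kernel_size = 3,
                                  dense_units = c(32, 16, 3), dropout_p = 0),
                    seed = 11)
  cfg <- train_config(batch_size = 15, total_iterations = 300,
                      eval_window = c(250, 259), eval_every = 25, seed = 12)
  fit <- train_model(h, ws, ws, cfg)
  expect_equal(max(fit$trajectory$f1), 1.0)
})

test_that("re-instantiating the final dense layer keeps the trunk intact", {
  cf <- conv1d_config(input_len = 32, n_channels = 6,
                      conv_channels = c(4, 6), kernel_size = 3,
                      dense_units = c(16, 8, 4), dropout_p = 0)
  h <- build_conv1d(cf, seed = 1)
  h2 <- reinit_final_dense(h, seed = 99)
  trunk <- setdiff(names(h$params), c("dense3.W", "dense3.b"))
  for (nm in trunk) expect_identical(h$params[[nm]], h2$params[[nm]])
  expect_false(identical(h$params[["dense3.W"]], h2$params[["dense3.W"]]))
  x <- withr::with_seed(2, array(stats::rnorm(32 * 6 * 3), c(32, 6, 3)))
  expect_false(identical(predict_proba(h, x), predict_proba(h2, x)))
})

test_that("classifiers survive a save/load round trip", {
  h <- build_conv1d(conv1d_config(input_len = 24, n_channels = 6,
                                  conv_channels = c(4, 4), kernel_size = 3,
                                  dense_units = c(8, 6, 2), dropout_p = 0),
                    seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(h, path)
  h2 <- load_classifier(path)
  x <- withr::with_seed(3, array(stats::rnorm(24 * 6 * 2), c(24, 6, 2)))
  expect_identical(predict_proba(h, x), predict_proba(h2, x))
})
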