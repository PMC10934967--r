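# Fixtures are built in code: small window sets with controllable group /
# class structure, and independent oracles for the geometric transforms.

# A small window set with labelled random windows (class structure optional).
make_test_ws <- function(n_nd = 0, n_stroke = 2, n_classes = 2,
                         windows_per_class = 3, W = 16, C = 6,
                         class_signal = 0, seed = 1) {
  withr::with_seed(seed, {
    meta <- list(); slabs <- list()
    subj <- 0
    groups <- c(rep("ND", n_nd),
                rep(c("StrokeRH", "StrokeLH"), length.out = n_stroke))
    class_means <- array(rnorm(W * C * n_classes), c(W, C, n_classes))
    for (g in groups) {
      subj <- subj + 1
      for (cl in seq_len(n_classes)) {
        for (w in seq_len(windows_per_class)) {
          slabs[[length(slabs) + 1L]] <-
            class_signal * class_means[, , cl] + matrix(rnorm(W * C), W, C)
          meta[[length(meta) + 1L]] <- data.frame(
            subject_id = subj, group = g, class_id = cl, rep_idx = 1L,
            severity = if (g == "ND") 66 else 40 + subj,
            window_idx = w - 1L, provenance = "original",
            transform_seed = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
    x <- array(0, c(W, C, length(slabs)))
    for (i in seq_along(slabs)) x[, , i] <- slabs[[i]]
    ws <- strokehar:::new_window_set(x, do.call(rbind, meta))
    attr(ws, "layout") <- sensor_layout(C %/% 6)
    ws
  })
}

# Tiny model / training configs used by protocol structure tests.
tiny_model_config <- function(n_classes = 2, W = 16, C = 6) {
  conv1d_config(input_len = W, n_channels = C, conv_channels = c(4, 6),
                kernel_size = 3, stride = 2, dense_units = c(16, 8, n_classes),
                dropout_p = 0)
}

tiny_train_config <- function(iters = 12, seed = 1) {
  train_config(batch_size = 16, total_iterations = iters,
               eval_window = c(iters - 2, iters), seed = seed)
}

# Independent Rodrigues oracle: v cos(t) + (k x v) sin(t) + k (k.v)(1-cos(t)).
rodrigues_oracle <- function(v, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  cross <- c(k[2] * v[3] - k[3] * v[2],
             k[3] * v[1] - k[1] * v[3],
             k[1] * v[2] - k[2] * v[1])
  v * cos(th) + cross * sin(th) + k * sum(k * v) * (1 - cos(th))
}
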