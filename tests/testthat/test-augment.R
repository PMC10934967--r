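test_that("rotation sampling honours its distributions and determinism", {
  expect_identical(sample_rotation(42), sample_rotation(42))
  draws <- lapply(1:4000, function(i) sample_rotation(mix_seed(3, i)))
  angles <- vapply(draws, `[[`, numeric(1), "angle")
  norms <- vapply(draws, function(d) sqrt(sum(d$axis^2)), numeric(1))
  expect_true(all(abs(angles) <= 90))
  expect_equal(norms, rep(1, 4000), tolerance = 1e-12)
  se <- (90 / sqrt(3)) / sqrt(4000)
  expect_lt(abs(mean(angles)), 3 * se)
})

test_that("window rotation is a per-triad isometry", {
  lay <- sensor_layout()
  w <- withr::with_seed(5, matrix(stats::rnorm(64 * 30), 64, 30))

  no_turn <- rotate_window(w, lay, list(axis = c(0, 0, 1), angle = 0))
  expect_equal(no_turn, w, tolerance = 1e-12)

  # right-handed convention: +90 degrees about z sends x to y
  v <- matrix(0, 1, 30); v[1, 1] <- 1
  out <- rotate_window(v, lay, list(axis = c(0, 0, 1), angle = 90))
  expect_equal(out[1, 1:3], c(0, 1, 0), tolerance = 1e-12)

  params <- sample_rotation_set(lay, seed = 8)
  rot <- rotate_window(w, lay, params)
  tri <- strokehar:::layout_triads(lay)
  for (i in seq_len(nrow(tri))) {
    chs <- tri$channels[[i]]
    expect_equal(sqrt(rowSums(rot[, chs]^2)), sqrt(rowSums(w[, chs]^2)),
                 tolerance = 1e-9)
  }
  expect_error(rotate_window(w[, 1:7], sensor_layout(1), params))
})

test_that("rotation matches the vector-form Rodrigues oracle", {
  withr::with_seed(12, {
    for (i in 1:100) {
      ax <- stats::rnorm(3)
      ang <- stats::runif(1, -180, 180)
      v <- stats::rnorm(3)
      expect_equal(as.vector(rotation_matrix(ax, ang) %*% v),
                   rodrigues_oracle(v, ax, ang), tolerance = 1e-10)
    }
  })
})

test_that("permutation rearranges sub-segments exactly", {
  w8 <- matrix(1:8, 8, 1)
  ident <- list(lengths = c(2, 2, 2, 2), order = 1:4)
  expect_identical(permute_window(w8, ident), w8)

  perm <- list(lengths = c(2, 2, 2, 2), order = c(3, 1, 2, 4))
  expect_equal(permute_window(w8, perm)[, 1], c(5, 6, 1, 2, 3, 4, 7, 8))

  w <- withr::with_seed(3, matrix(stats::rnorm(60 * 4), 60, 4))
  p <- sample_permutation(60, seed = 9)
  out <- permute_window(w, p)
  expect_equal(dim(out), dim(w))
  expect_equal(out[order(out[, 1]), ], w[order(w[, 1]), ])
  expect_true(all(p$lengths >= max(2, 60 %/% 20)))
  expect_error(permute_window(w8, list(lengths = c(3, 3), order = 1:2)))
  expect_error(permute_window(w8, list(lengths = c(4, 4), order = c(1, 1))))
})

test_that("time warping fixes endpoints and preserves monotone structure", {
  w <- withr::with_seed(7, matrix(stats::rnorm(50 * 3), 50, 3))
  ident <- sample_time_warp(50, seed = 1, sigma = 0)
  expect_equal(time_warp_window(w, ident), w, tolerance = 1e-12)

  const <- matrix(2, 50, 1)
  p <- sample_time_warp(50, seed = 4, sigma = 0.3)
  expect_identical(sample_time_warp(50, seed = 4, sigma = 0.3), p)
  expect_equal(time_warp_window(const, p), const, tolerance = 1e-12)

  ramp <- matrix(seq_len(50), 50, 1)
  warped <- time_warp_window(ramp, p)
  expect_true(all(diff(warped[, 1]) > 0))
  expect_equal(warped[c(1, 50), 1], c(1, 50))

  expect_error(time_warp_window(w, list(warp = rev(seq_len(50)))))
})

test_that("warp displacement grows with sigma", {
  disp <- function(sigma) {
    mean(vapply(1:300, function(i) {
      mean(abs(sample_time_warp(100, mix_seed(6, i), sigma = sigma)$warp -
                 seq_len(100)))
    }, numeric(1)))
  }
  expect_gt(disp(0.4), disp(0.1))
})

test_that("dataset augmentation counts, labels and determinism hold", {
  ws <- make_test_ws(n_nd = 2, n_stroke = 2, n_classes = 2,
                     windows_per_class = 5, W = 20, C = 6)
  n_stroke_w <- sum(grepl("Stroke", ws$meta$group))
  n_nd_w <- sum(ws$meta$group == "ND")

  single <- augment_dataset(ws, augment_plan("rotation", 1, base_seed = 2))
  expect_equal(dim(single$x)[3], n_nd_w + 2 * n_stroke_w)
  expect_equal(sum(single$meta$provenance == "rotation"), n_stroke_w)
  # ND windows pass through untouched
  expect_identical(single$x[, , single$meta$group == "ND"],
                   ws$x[, , ws$meta$group == "ND"])

  dbl <- augment_dataset(ws, augment_plan("timewarp", 2, base_seed = 2))
  expect_equal(dim(dbl$x)[3], n_nd_w + 3 * n_stroke_w)
  copies <- dbl$x[, , dbl$meta$provenance == "timewarp"]
  expect_false(identical(copies[, , 1], copies[, , n_stroke_w + 1]))

  # labels of transformed windows equal their sources'
  src <- ws$meta[grepl("Stroke", ws$meta$group), ]
  cp <- single$meta[single$meta$provenance == "rotation", ]
  expect_equal(cp$class_id, src$class_id)
  expect_equal(cp$subject_id, src$subject_id)

  again <- augment_dataset(ws, augment_plan("rotation", 1, base_seed = 2))
  expect_identical(single$x, again$x)

  nd_only <- ws_subset(ws, ws$meta$group == "ND")
  expect_error(augment_dataset(nd_only, augment_plan("rotation", 1)),
               "target group")
})

test_that("class balancing tops up only under-sized classes", {
  ws <- make_test_ws(n_nd = 0, n_stroke = 2, n_classes = 3,
                     windows_per_class = 5, W = 20, C = 6)
  # class sizes: 10 each; drop windows to unbalance: 10 / 4 / 12-like mix
  keep <- c(which(ws$meta$class_id == 1),
            which(ws$meta$class_id == 2)[1:4],
            which(ws$meta$class_id == 3))
  ws <- ws_subset(ws, keep)
  attr(ws, "layout") <- sensor_layout(1)

  out <- balance_by_augmentation(ws, target_count = 10, method = "rotation",
                                 seed = 21)
  tab <- table(out$meta$class_id)
  expect_equal(unname(tab[["2"]]), 10)
  expect_equal(unname(tab[["1"]]), 10)   # already at target: unchanged
  expect_equal(sum(out$meta$provenance == "rotation"), 6)
  # a class above target stays put
  out2 <- balance_by_augmentation(ws, target_count = 4, method = "rotation",
                                  seed = 21)
  expect_identical(dim(out2$x), dim(ws$x))
})
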