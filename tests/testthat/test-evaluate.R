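test_that("macro F1 matches hand-computed confusion matrices", {
  expect_equal(macro_f1(c(1, 2, 3), c(1, 2, 3), 3), 1.0)
  expect_equal(macro_f1(c(2, 3, 1), c(1, 2, 3), 3), 0.0)
  # confusion [[2,1],[1,2]]: per-class F1 = 2/3 each
  truths <- c(1, 1, 1, 2, 2, 2)
  preds <- c(1, 1, 2, 1, 2, 2)
  expect_equal(macro_f1(preds, truths, 2), 2 / 3, tolerance = 1e-12)
  # classes absent from both sides are excluded from the mean
  expect_equal(macro_f1(preds, truths, 5), 2 / 3, tolerance = 1e-12)
  # a class predicted but never true contributes F1 = 0 to the mean
  expect_equal(macro_f1(c(1, 2), c(1, 1), 2), mean(c(2 / 3, 0)),
               tolerance = 1e-12)
  expect_error(macro_f1(integer(0), integer(0), 2), "nonempty")
  expect_error(macro_f1(c(1, 4), c(1, 2), 3), "out of range")
})

test_that("median window scoring summarises the recorded span", {
  traj <- data.frame(iteration = 1:10, f1 = seq(0, 0.9, by = 0.1))
  expect_equal(median_window_f1(traj, c(1, 10)), 0.45)
  expect_equal(median_window_f1(data.frame(iteration = 5, f1 = 0.7),
                                c(5, 5)), 0.7)
  traj$f1 <- 0.5
  expect_equal(median_window_f1(traj, c(3, 8)), 0.5)
  expect_error(median_window_f1(traj[-4, ], c(1, 10)), "missing")
})

test_that("training is seed-deterministic and records the full window", {
  ws <- make_test_ws(n_stroke = 2, n_classes = 3, windows_per_class = 6,
                     W = 16, C = 6, class_signal = 0.8)
  h <- build_conv1d(tiny_model_config(3), seed = 2)
  cfg <- train_config(batch_size = 12, total_iterations = 59,
                      eval_window = c(50, 59), seed = 5)
  fit1 <- train_model(h, ws, ws, cfg)
  fit2 <- train_model(h, ws, ws, cfg)
  expect_identical(fit1$trajectory, fit2$trajectory)
  expect_identical(fit1$handle$params, fit2$handle$params)
  expect_equal(nrow(fit1$trajectory), 10)
  expect_equal(fit1$trajectory$iteration, 50:59)
  # optimization makes progress on the toy problem
  expect_lt(fit1$loss[59], fit1$loss[1])
})

test_that("LOSOCV builds one leak-free fold per stroke subject", {
  ws <- make_test_ws(n_nd = 2, n_stroke = 4, n_classes = 2,
                     windows_per_class = 4, W = 16, C = 6)
  cfg <- tiny_train_config()
  res <- run_losocv(ws, condition("stroke", "Stroke"), cfg,
                    tiny_model_config(2))
  expect_s3_class(res, "condition_result")
  expect_equal(nrow(res$per_subject), 4)
  for (f in res$fold_info) {
    expect_length(f$train_subjects, 3)
    expect_false(f$test_subject %in% f$train_subjects)
  }
  expect_equal(res$mean_f1, mean(res$per_subject$f1))
  expect_true(all(res$per_subject$f1 >= 0 & res$per_subject$f1 <= 1))

  joint <- run_losocv(ws, condition("ndstroke", c("ND", "Stroke")), cfg,
                      tiny_model_config(2))
  for (f in joint$fold_info) {
    expect_length(f$train_subjects, 2 + 3)  # all ND + the other stroke
    expect_false(f$test_subject %in% f$train_subjects)
  }
  # group means aggregate the right subjects
  rh <- joint$per_subject$group == "StrokeRH"
  expect_equal(unname(joint$group_means["StrokeRH"]),
               mean(joint$per_subject$f1[rh]))
})

test_that("augmented LOSOCV transforms only stroke training data", {
  ws <- make_test_ws(n_nd = 1, n_stroke = 3, n_classes = 2,
                     windows_per_class = 3, W = 20, C = 6)
  cfg <- tiny_train_config()
  plan <- augment_plan("rotation", 2, base_seed = 3)
  res <- run_losocv(ws, condition("aug", c("ND", "Stroke"), plan), cfg,
                    tiny_model_config(2, W = 20))
  for (f in res$fold_info) {
    pv <- f$train_provenance
    n_stroke_train <- 2 * 2 * 3          # 2 subjects x 2 classes x 3 windows
    expect_equal(unname(pv[["rotation"]]), 2 * n_stroke_train)
    expect_equal(unname(pv[["original"]]), n_stroke_train + 2 * 3)
  }
})

test_that("TSTR trains on transformed copies only and reduces to the baseline under an identity transform", {
  ws <- make_test_ws(n_nd = 0, n_stroke = 3, n_classes = 2,
                     windows_per_class = 4, W = 16, C = 6,
                     class_signal = 0.8)
  cfg <- tiny_train_config(iters = 20)
  mdl <- tiny_model_config(2)
  tstr <- run_tstr(ws, "rotation", cfg, mdl, base_seed = 5)
  expect_equal(nrow(tstr$per_subject), 3)
  for (f in tstr$fold_info) {
    expect_false("original" %in% names(f$train_provenance))
    expect_false(f$test_subject %in% f$train_subjects)
  }
  # identity rotation makes TSTR reproduce the baseline exactly
  ident <- run_tstr(ws, "rotation", cfg, mdl, base_seed = 5,
                    params = list(angle_range = c(0, 0)))
  base <- run_losocv(ws, condition("stroke", "Stroke"), cfg, mdl)
  expect_equal(ident$per_subject$f1, base$per_subject$f1, tolerance = 1e-12)
})

test_that("transfer learning pretrains once on ND and fine-tunes per fold", {
  ws <- make_test_ws(n_nd = 2, n_stroke = 2, n_classes = 2,
                     windows_per_class = 4, W = 16, C = 6)
  cfg <- tiny_train_config(iters = 15)
  res <- run_transfer(ws, NULL, cfg, tiny_model_config(2))
  expect_equal(nrow(res$per_subject), 2)
  expect_s3_class(res$pretrained, "classifier_handle")
  for (f in res$fold_info) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_false(any(f$train_subjects %in%
                       ws$meta$subject_id[ws$meta$group == "ND"]))
  }
  # an untrained re-instantiated head scores near chance on many classes
  many <- tiny_model_config(26)
  h <- reinit_final_dense(build_conv1d(many, seed = 1), seed = 2)
  x <- withr::with_seed(3, array(stats::rnorm(16 * 6 * 100), c(16, 6, 100)))
  preds <- predict_classes(h, x)
  truths <- withr::with_seed(4, sample(1:26, 100, replace = TRUE))
  expect_lt(macro_f1(preds, truths, 26), 0.12)
})

test_that("subset sweeps evaluate all excluded subjects and report gains", {
  ws <- make_test_ws(n_nd = 0, n_stroke = 4, n_classes = 2,
                     windows_per_class = 3, W = 16, C = 6)
  cfg <- tiny_train_config(iters = 10)
  out <- run_subsets(ws, n_list = 2, draws_per_n = c("2" = 2),
                     augment_plans = list(rot = augment_plan("rotation", 1)),
                     tr_config = cfg, model_config = tiny_model_config(2))
  expect_equal(nrow(out$runs), 2 * 2)          # 2 draws x (original, rot)
  for (f in out$fold_info) {
    expect_length(f$train_subjects, 2)
    expect_length(f$test_subjects, 2)
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
  }
  # draws are reproducible from the seed
  out2 <- run_subsets(ws, n_list = 2, draws_per_n = c("2" = 2),
                      augment_plans = list(rot = augment_plan("rotation", 1)),
                      tr_config = cfg, model_config = tiny_model_config(2))
  expect_identical(out$runs, out2$runs)
  expect_error(run_subsets(ws, n_list = 4, tr_config = cfg,
                           model_config = tiny_model_config(2)),
               "smaller")
})

test_that("percentage-increase bookkeeping follows the definition", {
  base <- data.frame(subject_id = 1:3, f1 = c(0.50, 0.40, 0.60))
  aug <- data.frame(subject_id = 1:3, f1 = c(0.55, 0.48, 0.60))
  g <- relative_gain(base, aug)
  expect_equal(g$gains$gain_pct, c(10, 20, 0), tolerance = 1e-12)
})
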