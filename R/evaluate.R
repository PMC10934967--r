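#' Training configuration
#'
#' The reference optimization recipe: AdamW (learning rate 0.001, betas
#' (0.9, 0.999), eps 1e-8, weight decay 0.01) on cross-entropy loss, batch
#' size 256, about 5200 batch iterations, with each condition's final score
#' taken as the median validation F1 over iterations 5000--5009.  The
#' iteration budget is fixed in iterations, not epochs, so augmented
#' (larger) training sets see the same number of updates.
#'
#' @param lr,beta1,beta2,eps,weight_decay AdamW hyperparameters.
#' @param batch_size minibatch size.
#' @param total_iterations number of batch updates.
#' @param eval_window `(first, last)` iterations over which validation F1
#'   is recorded and summarised by its median; must lie within
#'   `total_iterations`.
#' @param eval_every additionally record validation F1 every this many
#'   iterations (0 = only in the window).
#' @param seed master seed: batch shuffling, dropout and fold-level model
#'   initialization all derive from it.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, weight_decay = 0.01,
                         batch_size = 256, total_iterations = 5200,
                         eval_window = c(5000, 5009), eval_every = 0,
                         seed = 1) {
  stopifnot(batch_size >= 1, total_iterations >= 1,
            length(eval_window) == 2, eval_window[1] <= eval_window[2],
            eval_window[2] <= total_iterations, eval_window[1] >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Experimental condition
#'
#' @param name label of the condition.
#' @param train_groups subset of `c("ND", "Stroke")` used for training.
#' @param augment_plan an [augment_plan()] or `NULL`.
#' @param model `"conv1d"` or `"inceptiontime"`.
#' @param tstr train on transformed stroke windows only, evaluate on
#'   originals (requires an augment plan).
#' @export
condition <- function(name, train_groups = c("ND", "Stroke"),
                      augment_plan = NULL,
                      model = c("conv1d", "inceptiontime"),
                      tstr = FALSE) {
  model <- match.arg(model)
  stopifnot(all(train_groups %in% c("ND", "Stroke")))
  if (tstr && is.null(augment_plan)) {
    stop("a TSTR condition needs an augment plan (training uses ",
         "transformed stroke data only)")
  }
  structure(list(name = name, train_groups = train_groups,
                 augment_plan = augment_plan, model = model, tstr = tstr),
            class = "har_condition")
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of per-class F1; classes absent from both
#' the predictions and the truths are excluded.
#'
#' @param predictions,truths integer class labels in `1..n_classes`.
#' @param n_classes number of classes.
#' @return F1 in `[0, 1]`.
#' @export
macro_f1 <- function(predictions, truths, n_classes) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop("predictions and truths must be nonempty and of equal length")
  }
  if (any(predictions < 1 | predictions > n_classes |
          truths < 1 | truths > n_classes)) {
    stop("labels out of range")
  }
  f1s <- vapply(seq_len(n_classes), function(cl) {
    tp <- sum(predictions == cl & truths == cl)
    fp <- sum(predictions == cl & truths != cl)
    fn <- sum(predictions != cl & truths == cl)
    if (tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Median F1 over the scoring window
#'
#' @param trajectory data frame with columns `iteration` and `f1`.
#' @param eval_window `(first, last)` iterations; every iteration in the
#'   window must be present.
#' @export
median_window_f1 <- function(trajectory, eval_window) {
  want <- seq(eval_window[1], eval_window[2])
  got <- trajectory$f1[match(want, trajectory$iteration)]
  if (any(is.na(got))) stop("trajectory is missing iterations in the window")
  stats::median(got)
}

#' Train a classifier on a window set
#'
#' Uniformly shuffled minibatches (reshuffled each epoch), AdamW updates,
#' cross-entropy loss.  Validation macro-F1 is recorded at every iteration
#' inside `config$eval_window` (and every `eval_every` elsewhere), both
#' pooled and per validation subject.  Deterministic given the config seed.
#'
#' @param handle a `classifier_handle`.
#' @param train_ws training `window_set`.
#' @param valid_ws validation `window_set`, or `NULL`.
#' @param config a [train_config()].
#' @return list with the trained `handle`, `trajectory` (iteration, pooled
#'   f1), `subject_trajectory` (iteration, subject_id, f1) and the mean
#'   training `loss` per recorded span.
#' @export
train_model <- function(handle, train_ws, valid_ws = NULL, config) {
  n_train <- dim(train_ws$x)[3]
  if (n_train == 0) stop("empty training set")
  n_classes <- handle$config$n_classes
  labels <- train_ws$meta$class_id
  eval_iters <- seq(config$eval_window[1], config$eval_window[2])
  if (config$eval_every > 0) {
    eval_iters <- sort(union(eval_iters,
                             seq(config$eval_every, config$total_iterations,
                                 by = config$eval_every)))
  }
  record <- !is.null(valid_ws)
  traj <- list()
  subj_traj <- list()
  losses <- numeric(config$total_iterations)
  opt <- adamw_init(handle$params)
  with_seed(config$seed, {
    order_pool <- integer(0)
    for (it in seq_len(config$total_iterations)) {
      if (length(order_pool) < config$batch_size) {
        order_pool <- c(order_pool, sample.int(n_train))
      }
      idx <- order_pool[seq_len(min(config$batch_size, n_train))]
      order_pool <- order_pool[-seq_along(idx)]
      xb <- train_ws$x[, , idx, drop = FALSE]
      fw <- model_forward(handle, xb, train = TRUE, keep_cache = TRUE)
      if (!is.null(fw$bn_state)) handle$bn_state <- fw$bn_state
      lg <- xent_loss_grad(fw$logits, labels[idx])
      if (!is.finite(lg$loss)) {
        stop("training diverged: non-finite loss at iteration ", it)
      }
      losses[it] <- lg$loss
      grads <- model_backward(handle, fw$caches, lg$dlogits)
      step <- adamw_step(handle$params, grads, opt, lr = config$lr,
                         beta1 = config$beta1, beta2 = config$beta2,
                         eps = config$eps,
                         weight_decay = config$weight_decay,
                         decay_mask = handle$decay_mask)
      handle$params <- step$params
      opt <- step$state
      if (record && it %in% eval_iters) {
        preds <- predict_classes(handle, valid_ws$x)
        truths <- valid_ws$meta$class_id
        traj[[length(traj) + 1L]] <-
          data.frame(iteration = it,
                     f1 = macro_f1(preds, truths, n_classes))
        per_subj <- lapply(unique(valid_ws$meta$subject_id), function(sj) {
          sel <- valid_ws$meta$subject_id == sj
          data.frame(iteration = it, subject_id = sj,
                     f1 = macro_f1(preds[sel], truths[sel], n_classes))
        })
        subj_traj[[length(subj_traj) + 1L]] <- do.call(rbind, per_subj)
      }
    }
  })
  list(handle = handle,
       trajectory = if (length(traj)) do.call(rbind, traj) else
         data.frame(iteration = integer(0), f1 = numeric(0)),
       subject_trajectory = if (length(subj_traj))
         do.call(rbind, subj_traj) else
           data.frame(iteration = integer(0), subject_id = numeric(0),
                      f1 = numeric(0)),
       loss = losses)
}

# ---- protocol helpers -------------------------------------------------------

stroke_subjects <- function(ws) {
  sort(unique(ws$meta$subject_id[grepl("^Stroke", ws$meta$group)]))
}

build_model <- function(arch, model_config, seed) {
  if (arch == "conv1d") build_conv1d(model_config, seed)
  else build_inceptiontime(model_config, seed)
}

assert_no_leakage <- function(train_meta, held_subject) {
  if (any(train_meta$subject_id %in% held_subject)) {
    stop("leakage: held-out subject present in a training set")
  }
  invisible(TRUE)
}

fold_train_set <- function(ws, condition, held) {
  keep_groups <- logical(nrow(ws$meta))
  if ("ND" %in% condition$train_groups) {
    keep_groups <- keep_groups | ws$meta$group == "ND"
  }
  if ("Stroke" %in% condition$train_groups) {
    keep_groups <- keep_groups | grepl("^Stroke", ws$meta$group)
  }
  keep <- keep_groups & !(ws$meta$subject_id %in% held) &
    ws$meta$provenance == "original"
  base <- ws_subset(ws, keep)
  attr(base, "layout") <- attr(ws, "layout")
  plan <- condition$augment_plan
  if (is.null(plan)) return(base)
  if (condition$tstr) {
    out <- transformed_copies(base, plan)
  } else {
    out <- augment_dataset(base, plan)
  }
  attr(out, "layout") <- attr(ws, "layout")
  out
}

summarise_result <- function(name, per_subject, fold_info, seed) {
  gm <- function(g) {
    sel <- if (g == "Stroke") grepl("^Stroke", per_subject$group) else
      per_subject$group == g
    if (!any(sel)) NA_real_ else mean(per_subject$f1[sel])
  }
  structure(list(condition = name, per_subject = per_subject,
                 fold_info = fold_info,
                 mean_f1 = mean(per_subject$f1),
                 group_means = c(Stroke = gm("Stroke"),
                                 StrokeRH = gm("StrokeRH"),
                                 StrokeLH = gm("StrokeLH")),
                 seed = seed),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %s: mean F1 %.3f over %d subjects\n",
              x$condition, x$mean_f1, nrow(x$per_subject)))
  invisible(x)
}

#' Leave-one-subject-out cross-validation over stroke subjects
#'
#' One fold per stroke subject.  The fold's training set contains every
#' other stroke subject's original windows, all ND windows when the
#' condition includes ND, and — when the condition carries an augment plan
#' — transformed copies of the stroke training windows (ND data are never
#' transformed).  For a TSTR condition the training set consists of the
#' transformed copies only.  The fold's test set is every original window
#' of the held-out subject; a structural assertion guarantees the held-out
#' subject never appears in the training set.
#'
#' @param ws a `window_set` of original windows.
#' @param condition a [condition()].
#' @param tr_config a [train_config()].
#' @param model_config a [conv1d_config()] or [inception_config()]
#'   matching `condition$model`.
#' @return a `condition_result` with per-subject median-window F1 scores,
#'   group means, per-fold training/test subject bookkeeping and per-fold
#'   trajectories.
#' @export
run_losocv <- function(ws, condition, tr_config, model_config) {
  subs <- stroke_subjects(ws)
  if (length(subs) < 2) stop("need at least 2 stroke subjects")
  per <- list()
  folds <- list()
  trajs <- list()
  for (f in seq_along(subs)) {
    held <- subs[f]
    train_ws <- fold_train_set(ws, condition, held)
    if (dim(train_ws$x)[3] == 0) stop("empty training set in fold ", f)
    assert_no_leakage(train_ws$meta, held)
    test_sel <- ws$meta$subject_id == held & ws$meta$provenance == "original"
    if (!any(test_sel)) stop("held-out subject ", held, " has no windows")
    test_ws <- ws_subset(ws, test_sel)
    handle <- build_model(condition$model, model_config,
                          mix_seed(tr_config$seed, 101, f))
    fit_cfg <- tr_config
    fit_cfg$seed <- mix_seed(tr_config$seed, 102, f)
    fit <- train_model(handle, train_ws, test_ws, fit_cfg)
    meta1 <- test_ws$meta[1, ]
    per[[f]] <- data.frame(
      subject_id = held, group = meta1$group,
      severity = meta1$severity,
      f1 = median_window_f1(fit$trajectory, tr_config$eval_window))
    folds[[f]] <- list(train_subjects = unique(train_ws$meta$subject_id),
                       test_subject = held,
                       train_provenance = table(train_ws$meta$provenance))
    trajs[[f]] <- fit$trajectory
  }
  res <- summarise_result(condition$name, do.call(rbind, per), folds,
                          tr_config$seed)
  res$trajectories <- trajs
  res
}

#' Train-on-synthetic-test-on-real evaluation
#'
#' LOSOCV in which each fold trains exclusively on transformed copies of
#' the other stroke subjects' windows and evaluates on the held-out
#' subject's original windows.
#'
#' @inheritParams run_losocv
#' @param method transform method (see [augment_plan()]).
#' @param base_seed seed of the transform stream.
#' @param params transform parameters.
#' @export
run_tstr <- function(ws, method, tr_config, model_config,
                     base_seed = 1, params = list()) {
  cond <- condition(paste0("tstr_", method), train_groups = "Stroke",
                    augment_plan = augment_plan(method, n_copies = 1,
                                                base_seed = base_seed,
                                                params = params),
                    tstr = TRUE)
  run_losocv(ws, cond, tr_config, model_config)
}

#' Transfer learning from ND-pretrained weights
#'
#' Stage 1 trains the model once on all ND windows.  Stage 2, per LOSOCV
#' fold, re-instantiates the final dense layer with random parameters and
#' continues training (all layers trainable) on the stroke training
#' windows, optionally augmented.
#'
#' @inheritParams run_losocv
#' @param augment_plan an [augment_plan()] applied to the stroke training
#'   data, or `NULL`.
#' @export
run_transfer <- function(ws, augment_plan = NULL, tr_config, model_config) {
  nd_sel <- ws$meta$group == "ND" & ws$meta$provenance == "original"
  if (!any(nd_sel)) stop("transfer learning requires ND windows")
  nd_ws <- ws_subset(ws, nd_sel)
  pre_handle <- build_model("conv1d", model_config,
                            mix_seed(tr_config$seed, 201))
  pre_cfg <- tr_config
  pre_cfg$seed <- mix_seed(tr_config$seed, 202)
  pretrained <- train_model(pre_handle, nd_ws, NULL, pre_cfg)$handle

  cond <- condition("transfer", train_groups = "Stroke",
                    augment_plan = augment_plan)
  subs <- stroke_subjects(ws)
  if (length(subs) < 2) stop("need at least 2 stroke subjects")
  per <- list(); folds <- list(); trajs <- list()
  for (f in seq_along(subs)) {
    held <- subs[f]
    train_ws <- fold_train_set(ws, cond, held)
    assert_no_leakage(train_ws$meta, held)
    test_ws <- ws_subset(ws, ws$meta$subject_id == held &
                           ws$meta$provenance == "original")
    handle <- reinit_final_dense(pretrained,
                                 mix_seed(tr_config$seed, 203, f))
    fit_cfg <- tr_config
    fit_cfg$seed <- mix_seed(tr_config$seed, 204, f)
    fit <- train_model(handle, train_ws, test_ws, fit_cfg)
    meta1 <- test_ws$meta[1, ]
    per[[f]] <- data.frame(
      subject_id = held, group = meta1$group, severity = meta1$severity,
      f1 = median_window_f1(fit$trajectory, tr_config$eval_window))
    folds[[f]] <- list(train_subjects = unique(train_ws$meta$subject_id),
                       test_subject = held)
    trajs[[f]] <- fit$trajectory
  }
  res <- summarise_result("transfer", do.call(rbind, per), folds,
                          tr_config$seed)
  res$trajectories <- trajs
  res$pretrained = pretrained
  res
}

#' Stroke-subset sweeps
#'
#' For each subset size `n` and each random draw, trains on the chosen `n`
#' stroke subjects' windows (optionally augmented) and evaluates every
#' excluded stroke subject, reporting the mean of per-subject median F1
#' scores per run, mean and sd across draws, and the percentage increase of
#' each augmented plan over the unaugmented subsets.
#'
#' @inheritParams run_losocv
#' @param n_list subset sizes, each `<` the number of stroke subjects.
#' @param draws_per_n named vector mapping subset size to number of draws
#'   (default 1 each; smaller subsets deserve more draws).
#' @param augment_plans named list of [augment_plan()]s to compare against
#'   the unaugmented baseline (`NULL` entries allowed).
#' @return list with `runs` (one row per n / draw / plan), `summary`
#'   (mean and sd across draws plus percent increase over baseline) and
#'   `fold_info`.
#' @export
run_subsets <- function(ws, n_list, draws_per_n = NULL,
                        augment_plans = list(), tr_config, model_config) {
  subs <- stroke_subjects(ws)
  if (any(n_list >= length(subs))) {
    stop("every subset size must be smaller than the number of stroke ",
         "subjects")
  }
  plans <- c(list(original = NULL), augment_plans)
  runs <- list(); fold_info <- list()
  for (n in n_list) {
    n_draws <- if (is.null(draws_per_n)) 1L else
      as.integer(draws_per_n[[as.character(n)]] %||% 1L)
    for (d in seq_len(n_draws)) {
      train_subs <- with_seed(mix_seed(tr_config$seed, 301, n, d),
                              sample(subs, n))
      test_subs <- setdiff(subs, train_subs)
      for (pn in names(plans)) {
        cond <- condition(pn, train_groups = "Stroke",
                          augment_plan = plans[[pn]])
        train_ws <- fold_train_set(ws, cond, test_subs)
        assert_no_leakage(train_ws$meta, test_subs)
        test_ws <- ws_subset(ws, ws$meta$subject_id %in% test_subs &
                               ws$meta$provenance == "original")
        handle <- build_model(cond$model, model_config,
                              mix_seed(tr_config$seed, 302, n, d))
        fit_cfg <- tr_config
        fit_cfg$seed <- mix_seed(tr_config$seed, 303, n, d)
        fit <- train_model(handle, train_ws, test_ws, fit_cfg)
        st <- fit$subject_trajectory
        per_subj <- vapply(test_subs, function(sj) {
          median_window_f1(st[st$subject_id == sj, ], tr_config$eval_window)
        }, numeric(1))
        runs[[length(runs) + 1L]] <- data.frame(
          n = n, draw = d, plan = pn, mean_f1 = mean(per_subj))
        fold_info[[length(fold_info) + 1L]] <-
          list(n = n, draw = d, plan = pn,
               train_subjects = unique(train_ws$meta$subject_id),
               test_subjects = test_subs)
      }
    }
  }
  runs <- do.call(rbind, runs)
  agg <- stats::aggregate(mean_f1 ~ n + plan, data = runs,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(n = agg$n, plan = agg$plan,
                        mean_f1 = agg$mean_f1[, "mean"],
                        sd_f1 = agg$mean_f1[, "sd"])
  base <- summary[summary$plan == "original", c("n", "mean_f1")]
  names(base)[2] <- "base_f1"
  summary <- merge(summary, base, by = "n")
  summary$pct_increase <- ifelse(
    summary$plan == "original", 0,
    100 * (summary$mean_f1 - summary$base_f1) / summary$base_f1)
  list(runs = runs, summary = summary, fold_info = fold_info)
}
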