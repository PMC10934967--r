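#' Desk-scale experiment profile
#'
#' A scaled-down but structurally faithful version of the full study
#' pipeline, sized so that a complete LOSOCV comparison runs on a single
#' CPU in minutes: 6 ND + 6 stroke synthetic subjects, 8 movement classes,
#' 5 repetitions (the full-scale count), raw segments around 640 samples
#' resampled to 640,
#' windows of 128 with stride 128 (5 windows per segment), a narrower
#' Conv1D (12/24/48/48 kernels, dense 96/64/8, dropout 0.3 — the lighter
#' regularization matches the smaller capacity), batch size 48, 600
#' iterations with the scoring window at iterations 550--559.  Modality
#' divisors are estimated from the cohort.  Every statistical dial of the
#' generator (coherence targets, amplitude ratio, severity coupling) keeps
#' its full-scale default.
#'
#' @param n_nd,n_stroke,n_classes,n_reps cohort counts.
#' @param seed master seed.
#' @return list with `cohort` ([cohort_spec()]), `preprocess`
#'   ([preprocess_config()]), `model` ([conv1d_config()]),
#'   `inception_model` ([inception_config()]) and `train`
#'   ([train_config()]).
#' @export
desk_profile <- function(n_nd = 6, n_stroke = 6, n_classes = 8,
                         n_reps = 5, seed = 1) {
  list(
    cohort = cohort_spec(n_nd = n_nd, n_stroke = n_stroke,
                         n_classes = n_classes, n_reps = n_reps,
                         segment_len = 640, seed = seed),
    preprocess = preprocess_config(target_len = 640, window_len = 128,
                                   stride = 128, smooth_len = 3,
                                   divisor_mode = "estimate"),
    model = conv1d_config(input_len = 128, n_channels = 30,
                          conv_channels = c(12, 24, 48, 48),
                          dense_units = c(96, 64, n_classes),
                          dropout_p = 0.3),
    inception_model = inception_config(input_len = 128, n_channels = 30,
                                       n_modules = 3, n_filters = 12,
                                       bottleneck_channels = 12,
                                       n_classes = n_classes),
    train = train_config(batch_size = 48, total_iterations = 600,
                         eval_window = c(550, 559), seed = seed)
  )
}

#' Generate and preprocess a desk-scale cohort in one call
#'
#' @param profile as from [desk_profile()].
#' @return a `window_set` with layout attribute.
#' @export
desk_windows <- function(profile = desk_profile()) {
  preprocess_cohort(generate_cohort(profile$cohort), profile$preprocess)
}
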