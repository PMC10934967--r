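#' Correlation between severity and per-subject F1
#'
#' Pearson correlation (two-sided p-value from the exact t transform with
#' n - 2 degrees of freedom, via [stats::cor.test()]) between stroke
#' subjects' severity scores and their per-subject F1 scores from a
#' condition result.  In the source cohorts this correlation is strongly
#' positive: subjects with better motor function move more like the
#' non-disabled population and are easier to classify.
#'
#' @param profiles list of [subject_profile()]s or a data frame with
#'   `subject_id` and `severity`.
#' @param condition_result a `condition_result` (or any data frame with
#'   `subject_id`, `group`, `f1`).
#' @return a `correlation_report`: list with `pearson_r`, `p_value`, `n`
#'   and the paired `data`.
#' @export
correlate_severity_f1 <- function(profiles, condition_result) {
  if (inherits(condition_result, "condition_result")) {
    per <- condition_result$per_subject
  } else per <- condition_result
  prof <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  per <- per[grepl("^Stroke", per$group), ]
  d <- merge(per[, c("subject_id", "f1")],
             prof[, c("subject_id", "severity")], by = "subject_id")
  if (nrow(d) < 3) stop("need at least 3 stroke subjects with severity and F1")
  if (stats::sd(d$severity) < 1e-12 || stats::sd(d$f1) < 1e-12) {
    stop("zero variance in severity or F1")
  }
  ct <- stats::cor.test(d$severity, d$f1, method = "pearson")
  structure(list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(d), data = d),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> r = %.3f (p = %.4g, n = %d)\n",
              x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Per-subject relative F1 gain and its relation to the baseline
#'
#' Computes `100 * (augmented - baseline) / baseline` per matched subject
#' and the Pearson correlation of the gains with the baseline F1 scores.
#' In the source cohorts this correlation is negative: augmentation helps
#' most where the baseline is weakest.  Subjects with a zero baseline are
#' excluded with a warning; when the gains are constant the correlation is
#' reported as `NA`.
#'
#' @param baseline,augmented `condition_result`s or data frames with
#'   `subject_id` and `f1`.
#' @return list with `gains` (data frame), `pearson_r`, `p_value`, `n`.
#' @export
relative_gain <- function(baseline, augmented) {
  get_per <- function(x) {
    if (inherits(x, "condition_result")) x$per_subject else x
  }
  b <- get_per(baseline); a <- get_per(augmented)
  d <- merge(b[, c("subject_id", "f1")], a[, c("subject_id", "f1")],
             by = "subject_id", suffixes = c("_base", "_aug"))
  zero <- d$f1_base == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " subject(s) with zero baseline F1")
    d <- d[!zero, ]
  }
  d$gain_pct <- 100 * (d$f1_aug - d$f1_base) / d$f1_base
  r <- NA_real_; p <- NA_real_
  if (nrow(d) >= 3 && stats::sd(d$gain_pct) > 1e-12 &&
      stats::sd(d$f1_base) > 1e-12) {
    ct <- stats::cor.test(d$gain_pct, d$f1_base, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(gains = d, pearson_r = r, p_value = p, n = nrow(d))
}

#' Export penultimate-layer features for embedding
#'
#' One feature row per window (inference mode, dropout off), labelled with
#' class and provenance, ready for a 2-D embedding tool (e.g. UMAP) or for
#' [embed_features()].
#'
#' @param handle a trained `classifier_handle`.
#' @param ws a `window_set`.
#' @return a `feature_matrix`: list with `features` (N x D matrix) and
#'   `meta` (the window metadata).
#' @export
export_penultimate <- function(handle, ws) {
  feat <- t(penultimate_features(handle, ws$x))
  if (nrow(feat) != nrow(ws$meta)) stop("feature/metadata row mismatch")
  structure(list(features = feat, meta = ws$meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Write a feature matrix as CSV
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_features <- function(fm, path) {
  df <- cbind(fm$meta[, c("subject_id", "group", "class_id", "provenance")],
              as.data.frame(fm$features))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Project features to two dimensions
#'
#' Principal-component projection of the exported features (centered,
#' unscaled); a fast linear stand-alone embedding.  The exported CSV from
#' [write_features()] can equally be fed to a nonlinear embedding tool
#' such as UMAP.
#'
#' @param fm a `feature_matrix` (or plain matrix).
#' @param dims output dimensionality (default 2).
#' @return N x `dims` matrix of coordinates.
#' @export
embed_features <- function(fm, dims = 2) {
  x <- if (inherits(fm, "feature_matrix")) fm$features else fm
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = dims)
  pc$x[, seq_len(dims), drop = FALSE]
}
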