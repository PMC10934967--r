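#' Preprocessing configuration
#'
#' The reference chain for segmented IMU recordings: linear resampling of
#' every segment to `target_len` samples, per-segment channel centering,
#' modality scaling (all accelerometer channels divided by one constant,
#' all gyroscope channels by another, so the two modalities share a scale),
#' a trailing moving average of the last `smooth_len` points, and sliding
#' windows of `window_len` with stride `stride`.  The reference constants
#' are 3700 / 740 / 150 / 10 with divisors 2.537 (accelerometer) and 0.478
#' (gyroscope) — the pooled standard deviations of the corresponding
#' channels in the source recordings.  `divisor_mode = "estimate"` instead
#' re-derives the divisors from the data at hand.
#'
#' @param target_len L, resampled segment length.
#' @param window_len W, sliding-window length (`W <= L`).
#' @param stride S, window stride (>= 1).
#' @param smooth_len m, trailing moving-average length (>= 1).
#' @param accel_divisor,gyro_divisor fixed modality divisors (> 0).
#' @param divisor_mode `"fixed"` or `"estimate"`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_len = 3700, window_len = 740,
                              stride = 150, smooth_len = 10,
                              accel_divisor = 2.537, gyro_divisor = 0.478,
                              divisor_mode = c("fixed", "estimate")) {
  divisor_mode <- match.arg(divisor_mode)
  stopifnot(window_len <= target_len, stride >= 1, smooth_len >= 1,
            accel_divisor > 0, gyro_divisor > 0)
  structure(list(target_len = target_len, window_len = window_len,
                 stride = stride, smooth_len = smooth_len,
                 accel_divisor = accel_divisor, gyro_divisor = gyro_divisor,
                 divisor_mode = divisor_mode),
            class = "preprocess_config")
}

#' Linearly resample a multichannel signal to a fixed length
#'
#' Each channel is interpolated onto `L` equispaced points spanning the
#' original time range; the first and last samples are preserved exactly.
#'
#' @param signal `T x C` numeric matrix, `T >= 2`.
#' @param L output length.
#' @return `L x C` matrix.
#' @export
interpolate_to_length <- function(signal, L) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2) stop("signal must have at least 2 time points")
  if (nrow(signal) == L) return(signal)
  x0 <- seq(0, 1, length.out = nrow(signal))
  x1 <- seq(0, 1, length.out = L)
  apply(signal, 2, function(v) stats::approx(x0, v, xout = x1)$y)
}

#' Subtract each channel's mean
#' @param signal `T x C` matrix with finite values.
#' @return matrix with zero column means.
#' @export
center_channels <- function(signal) {
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  sweep(signal, 2, colMeans(signal))
}

#' Pooled modality divisors from a set of segments
#'
#' The accelerometer (gyroscope) divisor is the standard deviation of all
#' accelerometer (gyroscope) values pooled over channels, time points and
#' segments — population form, i.e. the root mean squared deviation from
#' the pooled mean.
#'
#' @param segments list of `segment_record`s or of plain signal matrices.
#' @param layout a [sensor_layout()] identifying each channel's modality.
#' @return named numeric `c(accel = ..., gyro = ...)`.
#' @export
compute_divisors <- function(segments, layout) {
  if (length(segments) < 1) stop("need at least one segment")
  sig <- function(s) if (is.list(s)) s$signal else s
  pooled_sd <- function(modality) {
    chs <- layout$channel[layout$modality == modality]
    v <- unlist(lapply(segments, function(s) as.vector(sig(s)[, chs])))
    sqrt(mean((v - mean(v))^2))
  }
  out <- c(accel = pooled_sd("accel"), gyro = pooled_sd("gyro"))
  if (any(out <= 1e-12)) stop("degenerate input: zero variance in a modality")
  out
}

#' Divide channels by their modality divisor
#' @param signal `T x C` matrix.
#' @param layout a [sensor_layout()].
#' @param accel_divisor,gyro_divisor positive scalars.
#' @export
apply_scaling <- function(signal, layout, accel_divisor, gyro_divisor) {
  if (accel_divisor <= 0 || gyro_divisor <= 0) {
    stop("divisors must be positive")
  }
  div <- ifelse(layout$modality == "accel", accel_divisor, gyro_divisor)
  sweep(signal, 2, div, "/")
}

#' Trailing moving average
#'
#' Causal smoothing: `out[t]` is the mean of the last `m` samples ending at
#' `t`.  The first `m - 1` samples average over the shorter available
#' prefix (no padding), so a constant signal is unchanged everywhere.
#'
#' @param signal `T x C` matrix.
#' @param m window length (>= 1).
#' @export
smooth_trailing_mean <- function(signal, m) {
  if (m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  if (m == 1L) return(signal)
  n <- nrow(signal)
  apply(signal, 2, function(v) {
    cs <- cumsum(v)
    out <- cs / pmin(seq_len(n), m)
    if (n > m) {
      t <- (m + 1):n
      out[t] <- (cs[t] - cs[t - m]) / m
    }
    out
  })
}

#' Slide fixed-length windows over a segment
#'
#' Windows start at offsets `0, S, 2S, ...` while `offset + W <= L`; the
#' count is `floor((L - W) / S) + 1` (20 for the reference 3700 / 740 /
#' 150 geometry).
#'
#' @param signal `L x C` matrix.
#' @param W window length (`W <= L`).
#' @param S stride (>= 1).
#' @return list of `W x C` matrices.
#' @export
slide_windows <- function(signal, W, S) {
  L <- nrow(signal)
  if (W > L) stop("window length exceeds signal length")
  if (S < 1) stop("stride must be >= 1")
  offsets <- seq(0L, L - W, by = as.integer(S))
  lapply(offsets, function(o) signal[(o + 1):(o + W), , drop = FALSE])
}

#' Number of sliding windows for a given geometry
#' @inheritParams slide_windows
#' @param L segment length.
#' @export
n_windows <- function(L, W, S) {
  if (W > L) stop("window length exceeds signal length")
  as.integer((L - W) %/% S) + 1L
}

# ---- window sets ------------------------------------------------------------

new_window_set <- function(x, meta) {
  stopifnot(dim(x)[3] == nrow(meta))
  structure(list(x = x, meta = meta), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<window_set> %d windows of %d x %d (%d subjects, %d classes)\n",
              d[3], d[1], d[2], length(unique(x$meta$subject_id)),
              length(unique(x$meta$class_id))))
  invisible(x)
}

#' Subset a window set
#' @param ws a `window_set`.
#' @param idx integer or logical index over windows.
#' @export
ws_subset <- function(ws, idx) {
  new_window_set(ws$x[, , idx, drop = FALSE], ws$meta[idx, , drop = FALSE])
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical window geometry.
#' @export
ws_bind <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "window_set")) parts <- parts[[1]]
  parts <- Filter(function(p) !is.null(p) && dim(p$x)[3] > 0, parts)
  if (length(parts) == 1) return(parts[[1]])
  d1 <- dim(parts[[1]]$x)[1:2]
  x <- array(0, c(d1, sum(vapply(parts, function(p) dim(p$x)[3], 1L))))
  at <- 0L
  for (p in parts) {
    n <- dim(p$x)[3]
    if (any(dim(p$x)[1:2] != d1)) stop("window geometries differ")
    x[, , at + seq_len(n)] <- p$x
    at <- at + n
  }
  meta <- do.call(rbind, lapply(parts, function(p) p$meta))
  rownames(meta) <- NULL
  new_window_set(x, meta)
}

#' Preprocess a cohort of segments into training windows
#'
#' Runs the full chain — resample, center, scale, smooth, window — on every
#' segment.  In `"estimate"` divisor mode the modality divisors are pooled
#' over the resampled, centered segments before scaling (the derivation
#' used for the reference constants).
#'
#' @param cohort an `imu_cohort`, or a list of `segment_record`s.
#' @param config a [preprocess_config()].
#' @param layout a [sensor_layout()]; taken from the cohort when available.
#' @return a `window_set`: `x` is a `W x C x N` array, `meta` a data frame
#'   with `subject_id`, `group`, `class_id`, `rep_idx`, `severity`,
#'   `window_idx` (0-based) and `provenance = "original"`.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config(),
                              layout = NULL) {
  if (inherits(cohort, "imu_cohort")) {
    segments <- cohort$segments
    layout <- layout %||% cohort$layout
  } else {
    segments <- cohort
    layout <- layout %||% sensor_layout(ncol(segments[[1]]$signal) %/% 6)
  }
  stage1 <- lapply(segments, function(s) {
    center_channels(interpolate_to_length(s$signal, config$target_len))
  })
  if (config$divisor_mode == "estimate") {
    div <- compute_divisors(stage1, layout)
    accel_div <- div[["accel"]]; gyro_div <- div[["gyro"]]
  } else {
    accel_div <- config$accel_divisor; gyro_div <- config$gyro_divisor
  }
  per_seg <- n_windows(config$target_len, config$window_len, config$stride)
  C <- nrow(layout)
  N <- length(segments) * per_seg
  x <- array(0, c(config$window_len, C, N))
  meta <- vector("list", length(segments))
  at <- 0L
  for (i in seq_along(segments)) {
    sm <- smooth_trailing_mean(
      apply_scaling(stage1[[i]], layout, accel_div, gyro_div),
      config$smooth_len)
    wins <- slide_windows(sm, config$window_len, config$stride)
    for (w in seq_along(wins)) x[, , at + w] <- wins[[w]]
    at <- at + per_seg
    s <- segments[[i]]
    meta[[i]] <- data.frame(
      subject_id = s$subject_id, group = s$group, class_id = s$class_id,
      rep_idx = s$rep_idx, severity = s$severity %||% NA_real_,
      window_idx = seq_len(per_seg) - 1L, provenance = "original",
      transform_seed = NA_integer_, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  out <- new_window_set(x, meta)
  attr(out, "divisors") <- c(accel = accel_div, gyro = gyro_div)
  attr(out, "layout") <- layout
  out
}
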