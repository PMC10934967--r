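#' Sample random rotation parameters
#'
#' Axis components are drawn uniformly over `[-1, +1]` and normalized to a
#' unit vector (a degenerate all-zero draw is redrawn); the angle is drawn
#' uniformly over `[-90, +90]` degrees by default.
#'
#' @param seed integer seed.
#' @param angle_range degrees, `(lo, hi)`.
#' @return list with unit `axis` (3-vector) and `angle` (degrees).
#' @export
sample_rotation <- function(seed, angle_range = c(-90, 90)) {
  with_seed(seed, {
    repeat {
      ax <- stats::runif(3, -1, 1)
      if (sqrt(sum(ax^2)) > 1e-9) break
    }
    list(axis = ax / sqrt(sum(ax^2)),
         angle = stats::runif(1, angle_range[1], angle_range[2]))
  })
}

#' Rotate the sensor triads of a window
#'
#' Each (sensor, modality) triad of channels forms a 3-vector at every time
#' point; that vector is rotated by the triad's rotation (right-handed
#' Rodrigues rotation), consistently over all time points, so per-time-point
#' Euclidean norms are preserved to machine precision.
#'
#' @param window `W x C` matrix.
#' @param layout a [sensor_layout()] partitioning all channels into triads.
#' @param params list of rotation parameter lists (as from
#'   [sample_rotation()]), one per triad in [layout_triads()] order, or a
#'   single parameter list applied to every triad.
#' @return rotated `W x C` matrix.
#' @export
rotate_window <- function(window, layout, params) {
  tri <- layout_triads(layout)
  if (nrow(layout) != ncol(window)) {
    stop("layout does not cover the window's channels")
  }
  if (!is.null(params$axis)) params <- rep(list(params), nrow(tri))
  if (length(params) != nrow(tri)) {
    stop("need one rotation per (sensor, modality) triad")
  }
  out <- window
  for (i in seq_len(nrow(tri))) {
    R <- rotation_matrix(params[[i]]$axis, params[[i]]$angle)
    chs <- tri$channels[[i]]
    out[, chs] <- window[, chs] %*% t(R)
  }
  out
}

#' Sample rotations for every triad of a layout
#'
#' `mode = "sensor"` (default) draws one rotation per sensor, applied to
#' both its accelerometer and gyroscope triads — the physically consistent
#' model of sensor re-orientation, which keeps the two modalities of one
#' device coherent.  `mode = "independent"` draws one rotation per
#' (sensor, modality) triad (maximal orientation diversity);
#' `mode = "shared"` draws a single rotation per modality, shared across
#' sensors.
#'
#' @inheritParams rotate_window
#' @param seed integer seed.
#' @param mode `"sensor"`, `"independent"` or `"shared"`.
#' @param angle_range degrees.
#' @export
sample_rotation_set <- function(layout, seed,
                                mode = c("sensor", "independent", "shared"),
                                angle_range = c(-90, 90)) {
  mode <- match.arg(mode)
  tri <- layout_triads(layout)
  switch(mode,
    sensor = {
      sensors <- unique(tri$sensor)
      per_sensor <- lapply(sensors, function(s) {
        sample_rotation(mix_seed(seed, s), angle_range)
      })
      names(per_sensor) <- as.character(sensors)
      lapply(as.character(tri$sensor), function(s) per_sensor[[s]])
    },
    independent = lapply(seq_len(nrow(tri)), function(i) {
      sample_rotation(mix_seed(seed, i), angle_range)
    }),
    shared = {
      per_mod <- list(accel = sample_rotation(mix_seed(seed, 1), angle_range),
                      gyro = sample_rotation(mix_seed(seed, 2), angle_range))
      lapply(tri$modality, function(m) per_mod[[m]])
    })
}

#' Sample a window permutation
#'
#' Cuts the window into `n_subsegments` pieces of different random lengths
#' (each at least `min_len`) and draws a random order.
#'
#' @param W window length.
#' @param seed integer seed.
#' @param n_subsegments number of pieces (reference: 4).
#' @param min_len minimum piece length; default `max(2, floor(W / 20))`.
#' @return list with `lengths` (piece lengths in original order) and
#'   `order` (permutation).
#' @export
sample_permutation <- function(W, seed, n_subsegments = 4,
                               min_len = max(2, W %/% 20)) {
  if (n_subsegments * min_len > W) stop("window too short for the cuts")
  with_seed(seed, {
    repeat {
      cuts <- sort(sample(seq_len(W - 1), n_subsegments - 1))
      lens <- diff(c(0, cuts, W))
      if (all(lens >= min_len)) break
    }
    list(lengths = lens, order = sample(n_subsegments))
  })
}

#' Permute the sub-segments of a window
#'
#' @param window `W x C` matrix.
#' @param params as from [sample_permutation()].
#' @return `W x C` matrix; the multiset of rows is preserved exactly.
#' @export
permute_window <- function(window, params) {
  lens <- params$lengths
  if (sum(lens) != nrow(window) || any(lens < 1)) {
    stop("cut lengths do not partition the window")
  }
  if (!setequal(params$order, seq_along(lens))) {
    stop("order is not a valid permutation")
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  idx <- unlist(lapply(params$order, function(p) starts[p]:ends[p]))
  window[idx, , drop = FALSE]
}

#' Sample a random time warp
#'
#' Knot speed multipliers are drawn from a normal with mean 1 and sd
#' `sigma` (clipped below at 0.1), interpolated to a smooth positive speed
#' curve by a cubic spline, accumulated, and renormalized so the warp fixes
#' both endpoints.  `sigma = 0` yields the identity warp.
#'
#' @param W window length.
#' @param seed integer seed.
#' @param n_knots number of speed knots (>= 2).
#' @param sigma spread of the speed multipliers (>= 0).
#' @return list with `warp`, a strictly increasing length-`W` map of
#'   (1-based) output positions to input positions with `warp[1] = 1`,
#'   `warp[W] = W`.
#' @export
sample_time_warp <- function(W, seed, n_knots = 4, sigma = 0.2) {
  stopifnot(n_knots >= 2, sigma >= 0)
  if (sigma == 0) return(list(warp = as.numeric(seq_len(W))))
  speed <- with_seed(seed, {
    mult <- pmax(stats::rnorm(n_knots, 1, sigma), 0.1)
    kx <- seq(1, W, length.out = n_knots)
    pmax(stats::spline(kx, mult, xout = seq_len(W))$y, 0.05)
  })
  cum <- cumsum(speed)
  warp <- 1 + (W - 1) * (cum - cum[1]) / (cum[W] - cum[1])
  list(warp = warp)
}

#' Apply a time warp to a window
#'
#' `out[t] = window` linearly interpolated at `warp[t]`.  Endpoints are
#' fixed, so the first and last rows are unchanged; a monotone warp of a
#' monotone channel stays monotone.
#'
#' @param window `W x C` matrix.
#' @param params as from [sample_time_warp()].
#' @export
time_warp_window <- function(window, params) {
  warp <- params$warp
  W <- nrow(window)
  if (length(warp) != W) stop("warp length must match the window")
  if (any(diff(warp) <= 0)) stop("warp must be strictly increasing")
  if (abs(warp[1] - 1) > 1e-8 || abs(warp[W] - W) > 1e-8) {
    stop("warp must fix both endpoints")
  }
  apply(window, 2, function(v) stats::approx(seq_len(W), v, xout = warp)$y)
}

# ---- dataset-level augmentation --------------------------------------------

#' Plan a dataset augmentation
#'
#' Single augmentation (`n_copies = 1`) adds one transformed copy of the
#' target group's training windows; double augmentation (`n_copies = 2`)
#' adds two copies generated from disjoint seed streams.
#'
#' @param method `"rotation"`, `"permutation"` or `"timewarp"`.
#' @param n_copies 1 or 2.
#' @param base_seed integer; copy `k` uses `base_seed + (k - 1) * 7919`.
#' @param target_group group whose windows are transformed (default
#'   `"Stroke"`, matching both hemiparesis subgroups; ND data are left
#'   unchanged).
#' @param params method parameters: for rotation `angle_range` and `mode`;
#'   for permutation `n_subsegments` / `min_len`; for timewarp `n_knots` /
#'   `sigma`.
#' @return an `augment_plan`.
#' @export
augment_plan <- function(method = c("rotation", "permutation", "timewarp"),
                         n_copies = 1, base_seed = 1,
                         target_group = "Stroke", params = list()) {
  method <- match.arg(method)
  stopifnot(n_copies %in% 1:2)
  structure(list(method = method, n_copies = n_copies,
                 seed_set = base_seed + (seq_len(n_copies) - 1L) * 7919L,
                 target_group = target_group, params = params),
            class = "augment_plan")
}

group_matches <- function(groups, target) {
  if (target == "Stroke") grepl("^Stroke", groups) else groups == target
}

transform_one <- function(window, method, seed, layout, params) {
  switch(method,
    rotation = rotate_window(window, layout, sample_rotation_set(
      layout, seed, mode = params$mode %||% "sensor",
      angle_range = params$angle_range %||% c(-90, 90))),
    permutation = permute_window(window, sample_permutation(
      nrow(window), seed,
      n_subsegments = params$n_subsegments %||% 4,
      min_len = params$min_len %||% max(2, nrow(window) %/% 20))),
    timewarp = time_warp_window(window, sample_time_warp(
      nrow(window), seed,
      n_knots = params$n_knots %||% 4,
      sigma = params$sigma %||% 0.2)))
}

#' Transformed copies of the target group's windows
#'
#' @param ws a `window_set`.
#' @param plan an [augment_plan()].
#' @param layout a [sensor_layout()]; taken from the window set when
#'   available.
#' @return a `window_set` holding only the transformed copies (labels
#'   identical to their sources; `provenance` records the method and
#'   `transform_seed` the per-window seed).
#' @export
transformed_copies <- function(ws, plan, layout = NULL) {
  layout <- layout %||% attr(ws, "layout")
  idx <- which(group_matches(ws$meta$group, plan$target_group))
  if (length(idx) == 0) stop("no windows of the target group to transform")
  parts <- lapply(seq_len(plan$n_copies), function(k) {
    seed_k <- plan$seed_set[k]
    x <- array(0, c(dim(ws$x)[1:2], length(idx)))
    seeds <- integer(length(idx))
    for (j in seq_along(idx)) {
      seeds[j] <- mix_seed(seed_k, idx[j])
      x[, , j] <- transform_one(ws$x[, , idx[j]], plan$method, seeds[j],
                                layout, plan$params)
    }
    meta <- ws$meta[idx, , drop = FALSE]
    meta$provenance <- plan$method
    meta$transform_seed <- seeds
    rownames(meta) <- NULL
    new_window_set(x, meta)
  })
  out <- ws_bind(parts)
  attr(out, "layout") <- layout
  out
}

#' Augment a dataset according to a plan
#'
#' Returns the original windows plus `n_copies` transformed copies of the
#' target group's windows; non-target windows pass through untouched, so
#' the output size is `N + n_copies * N_target`.
#'
#' @inheritParams transformed_copies
#' @export
augment_dataset <- function(ws, plan, layout = NULL) {
  copies <- transformed_copies(ws, plan, layout)
  out <- ws_bind(list(ws, copies))
  attr(out, "layout") <- layout %||% attr(ws, "layout")
  out
}

#' Balance class sizes by augmentation
#'
#' Every class with fewer than `target_count` windows gains transformed
#' copies — sources cycled in order, each copy drawn with a fresh seed —
#' until it reaches `target_count`.  Classes at or above the target are
#' left unchanged.
#'
#' @param ws a `window_set`.
#' @param target_count desired per-class window count (>= 1).
#' @param method transform method (see [augment_plan()]).
#' @param seed integer seed.
#' @param layout a [sensor_layout()].
#' @param params method parameters.
#' @export
balance_by_augmentation <- function(ws, target_count, method, seed,
                                    layout = NULL, params = list()) {
  stopifnot(target_count >= 1)
  layout <- layout %||% attr(ws, "layout")
  classes <- sort(unique(ws$meta$class_id))
  extras <- list()
  for (cl in classes) {
    idx <- which(ws$meta$class_id == cl)
    if (length(idx) == 0) stop("empty class ", cl)
    need <- target_count - length(idx)
    if (need <= 0) next
    src <- idx[((seq_len(need) - 1L) %% length(idx)) + 1L]
    x <- array(0, c(dim(ws$x)[1:2], need))
    seeds <- integer(need)
    for (j in seq_len(need)) {
      seeds[j] <- mix_seed(seed, cl, j)
      x[, , j] <- transform_one(ws$x[, , src[j]], method, seeds[j],
                                layout, params)
    }
    meta <- ws$meta[src, , drop = FALSE]
    meta$provenance <- method
    meta$transform_seed <- seeds
    rownames(meta) <- NULL
    extras[[length(extras) + 1L]] <- new_window_set(x, meta)
  }
  out <- ws_bind(c(list(ws), extras))
  attr(out, "layout") <- layout
  out
}
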