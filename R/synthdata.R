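#' Specification of a synthetic IMU cohort
#'
#' Describes a multi-subject, multi-class cohort of segmented IMU recordings
#' with the statistical structure observed in ADL studies contrasting
#' non-disabled (ND) participants with hemiparetic stroke patients:
#' per-class latent movement templates, group-dependent amplitude
#' attenuation, group-dependent inter-subject signal coherence, and a
#' per-subject severity score (FMA-like, higher = better motor function)
#' that modulates how far a stroke subject's movements fall from the
#' template.
#'
#' `coherence_nd` / `coherence_stroke` are *targets* for the mean pairwise
#' Pearson correlation between subjects' repetition-averaged signals (see
#' [measure_coherence()]); the generator converts them analytically into
#' perturbation magnitudes.
#'
#' @param n_nd,n_stroke numbers of non-disabled and stroke subjects.
#' @param n_classes number of movement classes (reference cohort: 52).
#' @param n_reps repetitions of each movement per subject (reference: 5).
#' @param segment_len nominal raw segment length in samples before any
#'   resampling; actual lengths vary by `len_jitter` and subject tempo.
#' @param n_sensors number of IMU sensors; each carries 6 channels.
#' @param coherence_nd,coherence_stroke target mean pairwise inter-subject
#'   correlations (reference values 0.226 and 0.048).
#' @param amplitude_ratio_stroke affected-side amplitude scale at worst
#'   severity, in (0, 1].
#' @param severity_range numeric `(min, max)` of the severity score for
#'   stroke subjects (reference: 33--66 of a 66-point scale).  ND subjects
#'   carry the maximum.
#' @param stroke_rh_fraction fraction of stroke subjects with right
#'   hemiparesis (the rest are left).
#' @param orientation_sd_nd,orientation_sd_stroke standard deviation, in
#'   degrees, of per-sensor mounting/posture orientation offsets.
#' @param tempo_jitter half-width of the uniform per-subject tempo
#'   multiplier around 1.
#' @param stroke_tempo_slope extra tempo stretch at worst severity
#'   (movements slow down as severity worsens).
#' @param len_jitter `(lo, hi)` multiplicative range of raw segment lengths
#'   around `segment_len`.
#' @param noise_frac white measurement noise sd, as a fraction of each
#'   channel's template sd.
#' @param rep_jitter_frac repetition-to-repetition perturbation sd, as a
#'   fraction of the subject-level perturbation sd.
#' @param severity_coherence_slope strength of the linear coupling between
#'   severity and a stroke subject's individual coherence (0 = none).
#' @param class_specific_frac fraction of the subject-level perturbation
#'   variance that is class-specific (erodes the class signal) rather than
#'   a subject-wide movement style shared across classes.
#' @param side_weight_unaffected weight of the stroke amplitude attenuation
#'   on unaffected-side and trunk sensors (1 = same as affected side).
#' @param gyro_gain scale applied to template time-derivatives to form
#'   gyroscope channels.
#' @param n_perturb_knots spline knots of the smooth perturbation curves.
#' @param template_bumps integer `(min, max)` number of bumps per template
#'   channel.
#' @param max_template_corr redraw ceiling on pairwise template correlation.
#' @param seed integer master seed; the whole cohort is a pure function of
#'   the spec.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_nd = 28, n_stroke = 14, n_classes = 52,
                        n_reps = 5, segment_len = 3700, n_sensors = 5,
                        coherence_nd = 0.226, coherence_stroke = 0.048,
                        amplitude_ratio_stroke = 0.6,
                        severity_range = c(33, 66),
                        stroke_rh_fraction = 9 / 14,
                        orientation_sd_nd = 5, orientation_sd_stroke = 45,
                        tempo_jitter = 0.1, stroke_tempo_slope = 0.25,
                        len_jitter = c(0.8, 1.2),
                        noise_frac = 0.05, rep_jitter_frac = 0.5,
                        severity_coherence_slope = 1,
                        class_specific_frac = 0.35,
                        side_weight_unaffected = 0.3,
                        gyro_gain = 10, n_perturb_knots = 12,
                        template_bumps = c(3, 6),
                        max_template_corr = 0.9,
                        seed = 1) {
  counts <- c(n_nd = n_nd, n_stroke = n_stroke, n_classes = n_classes,
              n_reps = n_reps, segment_len = segment_len,
              n_sensors = n_sensors)
  if (any(counts < 1)) stop("all counts in a cohort_spec must be >= 1")
  if (coherence_nd < 0 || coherence_nd > 1 ||
      coherence_stroke < 0 || coherence_stroke > 1) {
    stop("coherence targets must lie in [0, 1]")
  }
  if (amplitude_ratio_stroke <= 0 || amplitude_ratio_stroke > 1) {
    stop("amplitude_ratio_stroke must lie in (0, 1]")
  }
  stopifnot(length(severity_range) == 2, severity_range[1] <= severity_range[2],
            length(len_jitter) == 2, len_jitter[1] <= len_jitter[2],
            len_jitter[1] > 0)
  spec <- as.list(environment())
  spec <- spec[setdiff(names(spec), "counts")]
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d ND + %d stroke subjects, %d classes x %d reps\n",
    x$n_nd, x$n_stroke, x$n_classes, x$n_reps))
  cat(sprintf("  segment_len ~%d, %d sensors (%d channels)\n",
              x$segment_len, x$n_sensors, 6 * x$n_sensors))
  cat(sprintf("  coherence targets: ND %.3f, stroke %.3f; amp ratio %.2f\n",
              x$coherence_nd, x$coherence_stroke, x$amplitude_ratio_stroke))
  invisible(x)
}

# ---- class templates --------------------------------------------------------

bump_channel <- function(len, n_bumps) {
  t <- seq_len(len)
  centers <- stats::runif(n_bumps, 0.05, 0.95) * len
  widths <- stats::runif(n_bumps, 0.03, 0.12) * len
  amps <- stats::runif(n_bumps, 0.5, 2) * sample(c(-1, 1), n_bumps, TRUE)
  y <- numeric(len)
  for (b in seq_len(n_bumps)) {
    y <- y + amps[b] * exp(-(t - centers[b])^2 / (2 * widths[b]^2))
  }
  y
}

one_template <- function(template_len, n_channels, gyro_gain, bumps, seed) {
  with_seed(seed, {
    if (n_channels %% 6 == 0) {
      # IMU-structured: per sensor, 3 accel channels of smooth bumps and 3
      # gyro channels as scaled derivatives, so the two modalities live on
      # different scales (which is what modality scaling must correct).
      n_sensors <- n_channels %/% 6
      m <- matrix(0, template_len, n_channels)
      for (s in seq_len(n_sensors)) {
        acc <- sapply(1:3, function(a) {
          bump_channel(template_len, sample(bumps[1]:bumps[2], 1))
        })
        d <- rbind(acc[2, ] - acc[1, ], diff(acc)) # forward difference
        m[, (s - 1) * 6 + 1:3] <- acc
        m[, (s - 1) * 6 + 4:6] <- gyro_gain * d
      }
      m
    } else {
      sapply(seq_len(n_channels), function(ch) {
        bump_channel(template_len, sample(bumps[1]:bumps[2], 1))
      })
    }
  })
}

#' Generate per-class latent movement templates
#'
#' One smooth multichannel template per movement class, built from sums of
#' 3--6 random-amplitude, random-width Gaussian bumps per channel (a
#' band-limited stand-in for real ADL kinematics).  When the channel count
#' is a multiple of 6 the channels are organised as IMU sensors
#' (accelerometer triad + gyroscope triad, gyroscope = scaled derivative).
#' Templates whose flattened correlation with an already-accepted template
#' exceeds `max_corr` are redrawn, so classes stay distinguishable.
#'
#' @param n_classes,template_len,n_channels counts (all >= 1).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param gyro_gain,bumps,max_corr see [cohort_spec()].
#' @return list of `template_len x n_channels` matrices, each carrying a
#'   `class_id` attribute.
#' @export
make_class_templates <- function(n_classes, template_len, n_channels, seed,
                                 gyro_gain = 10, bumps = c(3, 6),
                                 max_corr = 0.9) {
  if (n_classes < 1 || template_len < 2 || n_channels < 1) {
    stop("n_classes and n_channels must be >= 1 and template_len >= 2")
  }
  templates <- vector("list", n_classes)
  flat <- matrix(0, template_len * n_channels, n_classes)
  for (cls in seq_len(n_classes)) {
    for (attempt in 1:50) {
      tm <- one_template(template_len, n_channels, gyro_gain, bumps,
                         mix_seed(seed, cls, attempt))
      v <- as.vector(tm)
      ok <- cls == 1 ||
        max(abs(stats::cor(v, flat[, seq_len(cls - 1), drop = FALSE]))) <= max_corr
      if (ok) break
    }
    if (!ok) stop("could not draw a sufficiently distinct template; ",
                  "raise max_corr or template_len")
    flat[, cls] <- v
    attr(tm, "class_id") <- cls
    templates[[cls]] <- tm
  }
  templates
}

# ---- subject profiles -------------------------------------------------------

#' Construct a synthetic subject profile
#'
#' Usually produced by [generate_cohort()]; exposed directly so single
#' segments can be rendered under controlled conditions.  The perturbation
#' fractions are standard deviations expressed as multiples of each
#' channel's (amplitude-scaled) template sd; `perturb_subject_frac` is
#' shared by all repetitions of a class while `perturb_rep_frac` varies per
#' repetition.
#'
#' @param subject_id integer or character id.
#' @param group one of `"ND"`, `"StrokeRH"`, `"StrokeLH"`.
#' @param severity severity score (FMA-like; ND subjects carry the maximum).
#' @param amplitude_scale scalar or per-channel vector of amplitude scales
#'   (> 0).
#' @param template_weight weight of the template component in the
#'   variance-preserving mix with the perturbations (1 = perturbations add
#'   on top of the full template).
#' @param perturb_subject_frac,perturb_rep_frac,noise_frac perturbation and
#'   noise sds relative to channel template sd (>= 0).
#' @param class_specific_frac fraction of the subject-level perturbation
#'   variance that is class-specific rather than a shared subject style.
#' @param orientation list of per-sensor 3x3 rotation matrices, or `NULL`
#'   for no orientation offset.
#' @param tempo_factor time-scale multiplier (> 0); values > 1 slow the
#'   movement down.
#' @param len_jitter `(lo, hi)` multiplicative raw-length range.
#' @param n_knots spline knots of the smooth perturbation curves.
#' @param perturb_seed seed of the subject-level perturbation stream.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group = "ND",
                            severity = 66,
                            amplitude_scale = 1,
                            template_weight = 1,
                            perturb_subject_frac = 0,
                            perturb_rep_frac = 0,
                            class_specific_frac = 0.35,
                            noise_frac = 0,
                            orientation = NULL,
                            tempo_factor = 1,
                            len_jitter = c(1, 1),
                            n_knots = 12,
                            perturb_seed = 0) {
  stopifnot(all(amplitude_scale > 0), tempo_factor > 0,
            perturb_subject_frac >= 0, perturb_rep_frac >= 0,
            noise_frac >= 0)
  if (!group %in% c("ND", "StrokeRH", "StrokeLH")) {
    stop("group must be one of ND, StrokeRH, StrokeLH")
  }
  structure(as.list(environment()), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s (%s), severity %.1f, amp %.2f-%.2f\n",
              x$subject_id, x$group, x$severity,
              min(x$amplitude_scale), max(x$amplitude_scale)))
  invisible(x)
}

#' @export
as.data.frame.subject_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group,
             severity = x$severity,
             amplitude_scale_mean = mean(x$amplitude_scale),
             perturb_subject_frac = x$perturb_subject_frac,
             perturb_rep_frac = x$perturb_rep_frac,
             tempo_factor = x$tempo_factor,
             stringsAsFactors = FALSE)
}

#' Summarise a list of profiles as a data frame
#' @param profiles list of [subject_profile()] objects.
#' @export
profiles_table <- function(profiles) {
  do.call(rbind, lapply(profiles, as.data.frame))
}

# Coherence target -> perturbation weights.  The rendered signal is a
# variance-preserving mix
#   a * (w_T * template + w_S * subject_curve + w_J * rep_curve)
# with w_T^2 + w_S^2 + w_J^2 = 1, so a subject's total signal energy is set
# by the amplitude scale alone (stroke attenuation stays visible as smaller
# peaks) while the mean pairwise correlation of repetition-averaged signals
# equals the coherence target:
#   r = w_T^2 / (w_T^2 + w_S^2 + w_J^2 / n_reps).
# Returned as sds relative to the template component (the form the renderer
# consumes), plus the template weight.
perturb_frac_for_coherence <- function(coherence, rep_jitter_frac, n_reps) {
  if (coherence >= 1) {
    return(list(template_weight = 1, subject_frac = 0))
  }
  coherence <- max(coherence, 1e-3)
  j2 <- rep_jitter_frac^2
  q <- (1 - coherence) / (coherence * (1 + j2 / n_reps))
  w_t2 <- 1 / (1 + q * (1 + j2))
  list(template_weight = sqrt(w_t2), subject_frac = sqrt(q))
}

# Expected attenuation of per-channel inter-subject correlation caused by
# independent per-subject sensor orientation offsets of the given sd (in
# degrees): the diagonal of the composed random rotation has expectation
# about (1 + 2 exp(-sigma^2)) / 3 with sigma the offset sd in radians.
# Orientation is thus itself a source of measured incoherence, and the
# additive perturbation only needs to account for the remainder.
orientation_attenuation <- function(sd_deg) {
  s2 <- (sd_deg * pi / 180)^2
  (1 + 2 * exp(-s2)) / 3
}

random_orientation <- function(n_sensors, sd_deg, seed) {
  if (sd_deg <= 0) return(NULL)
  with_seed(seed, {
    lapply(seq_len(n_sensors), function(s) {
      ax <- stats::rnorm(3)
      rotation_matrix(ax, stats::rnorm(1, 0, sd_deg))
    })
  })
}

#' Draw the subject profiles of a cohort spec
#'
#' Stroke subjects receive a severity score uniform over
#' `spec$severity_range`; severity then drives (i) affected-side amplitude
#' attenuation, affine in the normalised deficit, (ii) a tempo stretch, and
#' (iii) the subject's individual coherence, scaled around the group target
#' by `severity_coherence_slope` so that more severe subjects sit farther
#' from the class templates.
#'
#' @param spec a [cohort_spec()].
#' @param layout the [sensor_layout()] of the cohort.
#' @return list of [subject_profile()] objects, ND first.
#' @export
generate_profiles <- function(spec, layout = sensor_layout(spec$n_sensors)) {
  n <- spec$n_nd + spec$n_stroke
  sev_min <- spec$severity_range[1]
  sev_max <- spec$severity_range[2]
  sevs <- with_seed(mix_seed(spec$seed, 9001),
                    stats::runif(spec$n_stroke, sev_min, sev_max))
  n_rh <- round(spec$stroke_rh_fraction * spec$n_stroke)
  groups <- c(rep("ND", spec$n_nd),
              rep("StrokeRH", n_rh), rep("StrokeLH", spec$n_stroke - n_rh))
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    nd <- g == "ND"
    sev <- if (nd) sev_max else sevs[i - spec$n_nd]
    deficit <- if (nd || sev_max == sev_min) 0 else
      (sev_max - sev) / (sev_max - sev_min)
    if (nd) {
      amp <- rep(1, nrow(layout))
      kappa <- spec$coherence_nd
      ori_sd <- spec$orientation_sd_nd
      tempo_extra <- 1
    } else {
      affected <- if (g == "StrokeRH") "R" else "L"
      w <- ifelse(layout$side == affected, 1, spec$side_weight_unaffected)
      amp <- 1 - (1 - spec$amplitude_ratio_stroke) * deficit * w
      kappa <- spec$coherence_stroke *
        (1 - spec$severity_coherence_slope * (deficit - 0.5))
      kappa <- min(max(kappa, 0.005), 0.999)
      # compensatory posture deviation grows with impairment: the group
      # orientation sd is modulated affinely in the deficit (mean 1 over a
      # uniform severity draw, so the group-level calibration is unchanged)
      ori_sd <- spec$orientation_sd_stroke * (0.5 + deficit)
      tempo_extra <- 1 + spec$stroke_tempo_slope * deficit
    }
    tempo <- with_seed(mix_seed(spec$seed, 9002, i),
                       stats::runif(1, 1 - spec$tempo_jitter,
                                    1 + spec$tempo_jitter)) * tempo_extra
    kappa_additive <- min(kappa / orientation_attenuation(ori_sd), 1)
    wts <- perturb_frac_for_coherence(kappa_additive, spec$rep_jitter_frac,
                                      spec$n_reps)
    profiles[[i]] <- subject_profile(
      subject_id = i, group = g, severity = sev,
      amplitude_scale = amp,
      template_weight = wts$template_weight,
      perturb_subject_frac = wts$subject_frac,
      perturb_rep_frac = spec$rep_jitter_frac * wts$subject_frac,
      class_specific_frac = spec$class_specific_frac,
      noise_frac = spec$noise_frac,
      orientation = random_orientation(spec$n_sensors, ori_sd,
                                       mix_seed(spec$seed, 9003, i)),
      tempo_factor = tempo,
      len_jitter = spec$len_jitter,
      n_knots = spec$n_perturb_knots,
      perturb_seed = mix_seed(spec$seed, 9004, i)
    )
  }
  profiles
}

# ---- segment rendering ------------------------------------------------------

#' Render one subject's repetition of a class template
#'
#' Applies, in order: time scaling (raw length jitter x subject tempo),
#' per-channel amplitude scaling, addition of a subject-level smooth
#' perturbation (fixed across repetitions of a class) and a
#' repetition-level smooth jitter, per-sensor orientation rotation, and
#' white measurement noise.  With an identity profile (unit amplitude, zero
#' perturbation/noise fractions, no orientation, tempo 1, `len_jitter =
#' c(1, 1)`) the output signal equals the template exactly.
#'
#' @param template `T x C` template matrix carrying a `class_id` attribute.
#' @param profile a [subject_profile()]; its `amplitude_scale` must be a
#'   scalar or have length `C`.
#' @param rep_idx repetition index (recorded in the segment).
#' @param seed integer seed for the repetition-level randomness.
#' @param layout [sensor_layout()] used for the orientation rotation; only
#'   needed when the profile has orientation offsets.
#' @return a `segment_record`: list with `subject_id`, `group`, `class_id`,
#'   `rep_idx`, `severity` and the `T' x C` `signal` matrix.
#' @export
render_subject_segment <- function(template, profile, rep_idx, seed,
                                   layout = NULL) {
  C <- ncol(template)
  amp <- profile$amplitude_scale
  if (length(amp) == 1) amp <- rep(amp, C)
  if (length(amp) != C) stop("amplitude_scale length does not match channels")
  # variance-preserving mix: the template (and, proportionally, the
  # perturbations and noise below) are weighted so total energy tracks the
  # amplitude scale rather than growing with the perturbation magnitude
  amp <- amp * (profile$template_weight %||% 1)
  cls <- attr(template, "class_id") %||% 0L

  len_mult <- with_seed(mix_seed(seed, 1),
                        stats::runif(1, profile$len_jitter[1],
                                     profile$len_jitter[2]))
  T_out <- max(2L, as.integer(round(nrow(template) * len_mult *
                                      profile$tempo_factor)))
  x <- if (T_out == nrow(template)) template else
    interpolate_to_length(template, T_out)
  ch_sd <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  x <- sweep(x, 2, amp, "*")

  if (profile$perturb_subject_frac > 0) {
    # The subject-level deviation has two parts: a movement "style" curve
    # shared by all of the subject's classes (posture, habitual dynamics)
    # and a class-specific idiosyncrasy.  Both differ between subjects, so
    # both lower inter-subject coherence; only the class-specific part
    # erodes the class signal itself.
    csf <- profile$class_specific_frac %||% 0.35
    sd_style <- profile$perturb_subject_frac * sqrt(1 - csf)
    sd_class <- profile$perturb_subject_frac * sqrt(csf)
    p <- sapply(seq_len(C), function(ch) {
      sd_style * smooth_curve(nrow(template), profile$n_knots,
                              mix_seed(profile$perturb_seed, 0, ch)) +
        sd_class * smooth_curve(nrow(template), profile$n_knots,
                                mix_seed(profile$perturb_seed, cls, ch))
    })
    if (T_out != nrow(template)) p <- interpolate_to_length(p, T_out)
    x <- x + sweep(p, 2, amp * ch_sd, "*")
  }
  if (profile$perturb_rep_frac > 0) {
    p <- sapply(seq_len(C), function(ch) {
      smooth_curve(T_out, profile$n_knots, mix_seed(seed, 2, ch))
    })
    x <- x + sweep(p, 2, profile$perturb_rep_frac * amp * ch_sd, "*")
  }
  if (!is.null(profile$orientation)) {
    if (is.null(layout)) layout <- sensor_layout(C %/% 6)
    tri <- layout_triads(layout)
    for (i in seq_len(nrow(tri))) {
      R <- profile$orientation[[tri$sensor[i]]]
      chs <- tri$channels[[i]]
      x[, chs] <- x[, chs] %*% t(R)
    }
  }
  if (profile$noise_frac > 0) {
    eps <- with_seed(mix_seed(seed, 3),
                     matrix(stats::rnorm(T_out * C), T_out, C))
    x <- x + sweep(eps, 2, profile$noise_frac * amp * ch_sd, "*")
  }
  if (any(!is.finite(x))) stop("rendered segment contains non-finite values")
  structure(list(subject_id = profile$subject_id, group = profile$group,
                 class_id = cls, rep_idx = rep_idx,
                 severity = profile$severity, signal = x),
            class = "segment_record")
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return an `imu_cohort`: list with `segments` (list of `segment_record`,
#'   length `(n_nd + n_stroke) * n_classes * n_reps`), `profiles`,
#'   `templates`, `layout` and the `spec`.  Bitwise reproducible from the
#'   spec.
#' @examples
#' co <- generate_cohort(cohort_spec(n_nd = 2, n_stroke = 2, n_classes = 3,
#'                                   n_reps = 2, segment_len = 120,
#'                                   seed = 42))
#' length(co$segments)  # 2 subjects x 2 groups... 4 x 3 x 2 = 24
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  layout <- sensor_layout(spec$n_sensors)
  templates <- make_class_templates(
    spec$n_classes, spec$segment_len, nrow(layout),
    seed = mix_seed(spec$seed, 1000),
    gyro_gain = spec$gyro_gain, bumps = spec$template_bumps,
    max_corr = spec$max_template_corr)
  profiles <- generate_profiles(spec, layout)
  n_subj <- length(profiles)
  segments <- vector("list", n_subj * spec$n_classes * spec$n_reps)
  k <- 0L
  for (i in seq_len(n_subj)) {
    for (cls in seq_len(spec$n_classes)) {
      for (r in seq_len(spec$n_reps)) {
        k <- k + 1L
        segments[[k]] <- render_subject_segment(
          templates[[cls]], profiles[[i]], r,
          seed = mix_seed(spec$seed, 2000, i, cls, r), layout = layout)
      }
    }
  }
  structure(list(segments = segments, profiles = profiles,
                 templates = templates, layout = layout, spec = spec),
            class = "imu_cohort")
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort> %d segments from %d subjects (%d classes)\n",
              length(x$segments), length(x$profiles), x$spec$n_classes))
  invisible(x)
}

# ---- coherence and amplitude measurement ------------------------------------

#' Mean pairwise inter-subject signal coherence
#'
#' For one class and one channel: per subject, repetitions are
#' length-aligned by linear interpolation and averaged; the statistic is
#' the mean Pearson correlation over all subject pairs.  Zero-variance
#' pairs are excluded with a warning.
#'
#' @param segments list of `segment_record`s (any classes; filtered).
#' @param class_id class to measure.
#' @param channel channel index.
#' @return mean pairwise correlation in `[-1, 1]`.
#' @export
measure_coherence <- function(segments, class_id, channel) {
  segs <- Filter(function(s) s$class_id == class_id, segments)
  subs <- unique(vapply(segs, function(s) s$subject_id, numeric(1)))
  if (length(subs) < 2) stop("need segments of >= 2 subjects for class ",
                             class_id)
  L <- max(vapply(segs, function(s) nrow(s$signal), 1L))
  means <- sapply(subs, function(sj) {
    rows <- Filter(function(s) s$subject_id == sj, segs)
    m <- sapply(rows, function(s) {
      v <- s$signal[, channel]
      if (length(v) == L) v else
        stats::approx(seq(0, 1, length.out = length(v)), v,
                      xout = seq(0, 1, length.out = L))$y
    })
    rowMeans(as.matrix(m))
  })
  sds <- apply(means, 2, stats::sd)
  keep <- sds > 1e-12
  if (!all(keep)) warning("excluding zero-variance subject signals")
  if (sum(keep) < 2) stop("fewer than 2 subjects with non-degenerate signals")
  cm <- stats::cor(means[, keep, drop = FALSE])
  mean(cm[upper.tri(cm)])
}

#' Cohort-level coherence summary for a group
#'
#' Averages [measure_coherence()] over classes and channels for the
#' segments of one subject group (pooling `StrokeRH`/`StrokeLH` when
#' `group = "Stroke"`).
#'
#' @param cohort an `imu_cohort`.
#' @param group `"ND"` or `"Stroke"` (or a specific subgroup).
#' @param classes,channels subsets to average over (defaults: all classes,
#'   all channels).
#' @export
cohort_coherence <- function(cohort, group, classes = NULL, channels = NULL) {
  classes <- classes %||% seq_len(cohort$spec$n_classes)
  channels <- channels %||% cohort$layout$channel
  segs <- Filter(function(s) {
    if (group == "Stroke") grepl("^Stroke", s$group) else s$group == group
  }, cohort$segments)
  vals <- outer(classes, channels, Vectorize(function(cl, ch) {
    measure_coherence(segs, cl, ch)
  }))
  mean(vals)
}

#' Mean peak amplitude of a group's segments
#'
#' Mean over segments of the largest absolute value across the selected
#' channels; used to verify the stroke amplitude-attenuation contrast.
#' @inheritParams cohort_coherence
#' @export
cohort_peak_amplitude <- function(cohort, group, channels = NULL) {
  channels <- channels %||% cohort$layout$channel
  segs <- Filter(function(s) {
    if (group == "Stroke") grepl("^Stroke", s$group) else s$group == group
  }, cohort$segments)
  mean(vapply(segs, function(s) max(abs(s$signal[, channels])), numeric(1)))
}
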