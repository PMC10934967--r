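test_that("class templates are deterministic, shaped, and distinct", {
  t1 <- make_class_templates(2, 100, 6, seed = 1)
  t2 <- make_class_templates(2, 100, 6, seed = 1)
  expect_identical(t1, t2)

  t3 <- make_class_templates(1, 50, 30, seed = 7)
  expect_length(t3, 1)
  expect_equal(dim(t3[[1]]), c(50, 30))
  expect_identical(attr(t3[[1]], "class_id"), 1L)

  # 52 classes: mean absolute pairwise correlation of flattened templates
  tm <- make_class_templates(52, 500, 30, seed = 3)
  flat <- sapply(tm, as.vector)
  cm <- abs(stats::cor(flat))
  expect_lt(mean(cm[upper.tri(cm)]), 0.5)

  expect_error(make_class_templates(0, 100, 6, seed = 1))
  expect_error(make_class_templates(2, 100, 0, seed = 1))
})

test_that("rendering respects identity and pure-scaling configurations", {
  tm <- make_class_templates(1, 80, 30, seed = 2)[[1]]
  ident <- subject_profile(1)
  seg <- render_subject_segment(tm, ident, 1, seed = 5)
  expect_equal(seg$signal, tm, ignore_attr = TRUE)
  expect_identical(seg$class_id, 1L)

  half <- subject_profile(1, amplitude_scale = 0.5)
  seg2 <- render_subject_segment(tm, half, 1, seed = 5)
  expect_equal(seg2$signal, 0.5 * tm, ignore_attr = TRUE)

  expect_error(render_subject_segment(
    tm, subject_profile(1, amplitude_scale = rep(1, 4)), 1, seed = 5))
})

test_that("repetitions with perturbation differ but track the template", {
  tm <- make_class_templates(1, 200, 30, seed = 4)[[1]]
  pr <- subject_profile(1, perturb_subject_frac = 0.6,
                        perturb_rep_frac = 0.3, perturb_seed = 9)
  a <- render_subject_segment(tm, pr, 1, seed = 11)
  b <- render_subject_segment(tm, pr, 2, seed = 12)
  expect_false(isTRUE(all.equal(a$signal, b$signal)))
  cors <- sapply(1:10, function(ch) stats::cor(a$signal[, ch], tm[, ch]))
  expect_gt(mean(cors), 0.3)
})

test_that("cohort generation matches counts and is reproducible", {
  spec <- cohort_spec(n_nd = 2, n_stroke = 2, n_classes = 3, n_reps = 5,
                      segment_len = 80, seed = 77)
  co <- generate_cohort(spec)
  expect_length(co$segments, 4 * 3 * 5)
  co2 <- generate_cohort(spec)
  expect_identical(lapply(co$segments, `[[`, "signal"),
                   lapply(co2$segments, `[[`, "signal"))
  # every segment's class indexes the template that rendered it
  expect_true(all(vapply(co$segments, function(s)
    s$class_id %in% 1:3, logical(1))))
})

test_that("full coherence with all nuisances off collapses ND to the template", {
  spec <- cohort_spec(n_nd = 3, n_stroke = 1, n_classes = 2, n_reps = 2,
                      segment_len = 60, coherence_nd = 1, noise_frac = 0,
                      orientation_sd_nd = 0, orientation_sd_stroke = 0,
                      tempo_jitter = 0, len_jitter = c(1, 1), seed = 5)
  co <- generate_cohort(spec)
  nd <- Filter(function(s) s$group == "ND" & s$class_id == 1, co$segments)
  ref <- nd[[1]]$signal
  for (s in nd) expect_equal(s$signal, ref)
})

test_that("coherence measurement recovers degenerate cases", {
  sig <- matrix(stats::rnorm(100 * 2), 100, 2)
  seg <- function(subj, rep, m) {
    structure(list(subject_id = subj, group = "ND", class_id = 1,
                   rep_idx = rep, severity = 66, signal = m),
              class = "segment_record")
  }
  same <- list(seg(1, 1, sig), seg(2, 1, sig), seg(3, 1, sig))
  expect_equal(measure_coherence(same, 1, 1), 1.0)

  withr::with_seed(8, {
    indep <- lapply(1:4, function(i) {
      seg(i, 1, matrix(stats::rnorm(2500 * 2), 2500, 2))
    })
  })
  expect_lt(abs(measure_coherence(indep, 1, 1)), 0.05)

  expect_error(measure_coherence(same[1], 1, 1), "2 subjects")
})

test_that("group contrast: ND more coherent and larger peaks than stroke", {
  co <- generate_cohort(cohort_spec(n_nd = 5, n_stroke = 5, n_classes = 3,
                                    n_reps = 2, segment_len = 250, seed = 21))
  ch <- c(1, 2, 8, 14)
  coh_nd <- cohort_coherence(co, "ND", channels = ch)
  coh_st <- cohort_coherence(co, "Stroke", channels = ch)
  expect_gt(coh_nd, coh_st)
  expect_gt(cohort_peak_amplitude(co, "ND"),
            cohort_peak_amplitude(co, "Stroke"))
})

test_that("severity couples to distance from the template", {
  spec <- cohort_spec(n_nd = 1, n_stroke = 9, n_classes = 3, n_reps = 2,
                      segment_len = 250, seed = 31)
  co <- generate_cohort(spec)
  stroke <- Filter(function(p) p$group != "ND", co$profiles)
  cor_to_template <- vapply(stroke, function(p) {
    segs <- Filter(function(s) s$subject_id == p$subject_id, co$segments)
    mean(vapply(segs, function(s) {
      tm <- co$templates[[s$class_id]]
      sig <- interpolate_to_length(s$signal, nrow(tm))
      mean(vapply(c(1, 7, 13), function(ch) stats::cor(sig[, ch], tm[, ch]),
                  numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  sev <- vapply(stroke, function(p) p$severity, numeric(1))
  expect_gt(stats::cor(sev, cor_to_template, method = "spearman"), 0)
})

test_that("cohort round-trips through the CSV container", {
  co <- generate_cohort(cohort_spec(n_nd = 1, n_stroke = 1, n_classes = 2,
                                    n_reps = 2, segment_len = 50, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_length(back$segments, length(co$segments))
  for (i in seq_along(co$segments)) {
    a <- co$segments[[i]]; b <- back$segments[[i]]
    expect_identical(a$class_id, as.integer(b$class_id))
    rel <- max(abs(a$signal - b$signal)) / max(abs(a$signal))
    expect_lt(rel, 1e-7)
  }
  expect_equal(nrow(back$profiles), 2)
})
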