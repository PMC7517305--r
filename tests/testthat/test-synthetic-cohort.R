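# Synthetic cohort generator: RR model, ECG synthesis, cohort assembly.

test_that("constant-rate RR series is the deterministic limit", {
  p <- rr_model_params(mean_rr = 0.8, lf_amp = 0, hf_amp = 0,
                       jitter_sd = 0, ectopic_rate = 0)
  rr <- generate_rr_series(p, 8)
  expect_equal(rr$beat_times, seq(0, 8, by = 0.8), tolerance = 1e-9)
  expect_equal(rr$rr, rep(0.8, 10), tolerance = 1e-9)
})

test_that("LF-only modulation yields the sinusoid's RR standard deviation", {
  p <- rr_model_params(mean_rr = 0.8, lf_amp = 0.05, hf_amp = 0,
                       jitter_sd = 0, ectopic_rate = 0)
  rr <- generate_rr_series(p, 120)
  # oracle: evaluate the modulation formula directly at the generated times
  oracle <- 0.05 * sin(2 * pi * 0.10 * head(rr$beat_times, -1))
  expect_equal(sd(rr$rr), sd(oracle), tolerance = 1e-6)
  expect_equal(sd(rr$rr), 0.05 / sqrt(2), tolerance = 0.1)
})

test_that("RR generation is reproducible under a fixed seed", {
  p <- rr_model_params()
  a <- generate_rr_series(p, 80, seed = 7)
  b <- generate_rr_series(p, 80, seed = 7)
  expect_identical(a$beat_times, b$beat_times)
  c <- generate_rr_series(p, 80, seed = 8)
  expect_false(identical(a$beat_times, c$beat_times))
})

test_that("RR generation rejects invalid durations and keeps RR above 0.2 s", {
  expect_error(generate_rr_series(rr_model_params(), -5), "positive")
  p <- rr_model_params(mean_rr = 0.3, jitter_sd = 0.08)
  for (s in 1:5) {
    rr <- generate_rr_series(p, 60, seed = s)
    expect_true(all(rr$rr > 0.2))
    expect_true(all(diff(rr$beat_times) > 0))
  }
})

test_that("noiseless synthesis places global maxima at ground-truth peaks", {
  rrs <- generate_rr_series(rr_model_params(ectopic_rate = 0), 30, seed = 3)
  rec <- synthesize_ecg(rrs, morphology_params(qrs_amp = 1000, t_amp = 100,
                                               qrs_width_sd = 0),
                        noise_params(baseline_amp = 0, white_sd = 0,
                                     spike_rate = 0), fs = 250, seed = 4)
  expect_true(all(diff(rec$ground_truth_peaks) > 0))
  # every local neighborhood max coincides with a ground-truth index
  # (+-1 sample: beats falling midway between samples tie at the top)
  for (g in rec$ground_truth_peaks[2:(length(rec$ground_truth_peaks) - 1L)]) {
    win <- max(1, g - 25):min(length(rec$samples), g + 25)
    expect_lte(abs(win[which.max(rec$samples[win])] - g), 1)
  }
})

test_that("beat template integral matches the closed-form Gaussian integral", {
  rr <- rr_series(c(0, 1, 2))
  morph <- morphology_params(qrs_width = 0.08, qrs_amp = 1000, t_amp = 0,
                             qrs_width_sd = 0)
  rec <- synthesize_ecg(rr, morph, noise_params(baseline_amp = 0,
                                                white_sd = 0, spike_rate = 0),
                        fs = 250, seed = 1)
  # one beat window: integral of A*exp(-t^2/(2 s^2)) = A*s*sqrt(2*pi)
  sig <- 0.08 / postrosc:::.QRS_SIGMA_FACTOR
  expected <- 1000 * sig * sqrt(2 * pi)
  i <- rec$ground_truth_peaks[2L]
  win <- (i - 100):(i + 100)
  measured <- sum(rec$samples[win]) / 250
  expect_equal(measured, expected, tolerance = 0.01)
})

test_that("cohort respects the configured prevalence exactly", {
  cfg <- cohort_config(n_patients = 162, prevalence = 0.3395, tw = 1,
                       seed = 2)
  coh <- generate_cohort(cfg)
  labels <- vapply(coh, `[[`, integer(1), "label")
  expect_identical(sum(labels == 1L), 55L)
  expect_identical(sum(labels == 0L), 107L)
  expect_error(cohort_config(n_patients = 10, prevalence = 0.01),
               "each class")
})

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 4, prevalence = 0.5, tw = 1, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("null class effect gives statistically indistinguishable classes", {
  cfg <- cohort_config(n_patients = 12, prevalence = 0.5, tw = 1,
                       class_effect = c(lf_amp = 1, hf_amp = 1,
                                        jitter_sd = 1, qrs_width_sd = 1),
                       seed = 13)
  coh <- generate_cohort(cfg)
  labels <- vapply(coh, `[[`, integer(1), "label")
  sdnn <- vapply(coh, function(r) {
    gt <- r$ground_truth_peaks / r$fs
    sd(diff(gt))
  }, numeric(1))
  p <- wilcox.test(sdnn[labels == 1], sdnn[labels == 0], exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("noise- and jitter-free records reproduce the generator SDNN in v2", {
  rec <- synth_record(5, duration = 132,
                      rr = rr_model_params(jitter_sd = 0, ectopic_rate = 0),
                      morph = morphology_params(qrs_width_sd = 0))
  seg <- bandpass_filter(extract_segment(rec, 2))
  beats <- apply_variance_correction(seg, detect_qrs_primary(seg))
  rr <- build_rr_series(beats, 250)
  gt <- gt_in_segment(rec, 2, margin = 0)
  truth_sd <- sd(diff(gt) / 250)
  expect_lt(abs(compute_time_domain(rr)[["v2"]] - truth_sd), 1 / 250)
})

test_that("cohort CSV writer and reader round-trip", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 3, prevalence = 0.4, tw = 1, seed = 31)
  coh <- generate_cohort(cfg)
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(manifest))
  back <- read_cohort(manifest)
  expect_length(back, 3L)
  expect_equal(back[[1L]]$samples, coh[[1L]]$samples, tolerance = 1e-6)
  expect_identical(back[[1L]]$label, coh[[1L]]$label)
  expect_equal(back[[2L]]$rosc_time, coh[[2L]]$rosc_time)
})
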