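# QRS detection, variance correction, bSQI and RR-series construction.

filtered_segment <- function(rec, tw = 1) {
  bandpass_filter(extract_segment(rec, tw))
}

test_that("primary detector is exact on noiseless records", {
  for (s in c(2, 5, 8)) {
    rec <- synth_record(s, duration = 70)
    seg <- filtered_segment(rec)
    b <- detect_qrs_primary(seg)
    gt_int <- gt_in_segment(rec, 1)
    gt_all <- gt_in_segment(rec, 1, margin = 0)
    st <- beat_stats(b$peak_indices, gt_int, gt_all)
    expect_identical(unname(st["sens"]), 1)
    expect_identical(unname(st["ppv"]), 1)
    offs <- vapply(gt_int, function(t) min(abs(b$peak_indices - t)), numeric(1))
    expect_lte(max(offs), 1)
  }
})

test_that("detectors return no beats on a flatline", {
  seg <- analysis_segment(numeric(15000), 250)
  expect_length(detect_qrs_primary(seg)$peak_indices, 0L)
  expect_length(detect_qrs_secondary(seg)$peak_indices, 0L)
})

test_that("primary detector tolerates white noise at 10% of QRS amplitude", {
  for (s in c(3, 6)) {
    rec <- synth_record(s, duration = 70,
                        noise = noise_params(white_sd = 100,
                                             baseline_amp = 100,
                                             spike_rate = 0))
    seg <- filtered_segment(rec)
    b <- apply_variance_correction(seg, detect_qrs_primary(seg))
    st <- beat_stats(b$peak_indices, gt_in_segment(rec, 1),
                     gt_in_segment(rec, 1, margin = 0))
    expect_gte(st[["sens"]], 0.99)
    expect_gte(st[["ppv"]], 0.99)
  }
})

test_that("secondary detector matches the primary on clean records and is at
           least as sensitive at low SNR", {
  rec <- synth_record(4, duration = 70)
  seg <- filtered_segment(rec)
  b1 <- detect_qrs_primary(seg)
  b2 <- detect_qrs_secondary(seg)
  expect_equal(compute_sqi(b1, b2, 250)$bsqi, 1.0)
  sens <- function(b, rec) {
    beat_stats(b$peak_indices, gt_in_segment(rec, 1),
               gt_in_segment(rec, 1, margin = 0))[["sens"]]
  }
  lo <- vapply(c(7, 9, 12), function(s) {
    rec <- synth_record(s, duration = 70,
                        noise = noise_params(white_sd = 300,
                                             baseline_amp = 100,
                                             spike_rate = 0))
    seg <- filtered_segment(rec)
    sens(detect_qrs_secondary(seg), rec) - sens(detect_qrs_primary(seg), rec)
  }, numeric(1))
  expect_gte(mean(lo), 0)
})

test_that("variance correction is the identity on clean records", {
  for (s in c(2, 5)) {
    rec <- synth_record(s, duration = 70,
                        noise = noise_params(white_sd = 15,
                                             baseline_amp = 100,
                                             spike_rate = 0))
    seg <- filtered_segment(rec)
    b <- detect_qrs_primary(seg)
    expect_identical(apply_variance_correction(seg, b)$peak_indices,
                     b$peak_indices)
  }
})

test_that("variance correction rescues spike-suppressed beats", {
  p <- spiked_pair(31, c(20, 20.4, 20.8, 21.2, 21.6))
  seg_s <- filtered_segment(p$spiked)
  gt_int <- gt_in_segment(p$clean, 1)
  gt_all <- gt_in_segment(p$clean, 1, margin = 0)
  b_raw <- detect_qrs_primary(seg_s)
  b_cor <- apply_variance_correction(seg_s, b_raw)
  missed <- function(b) {
    gt_int[!vapply(gt_int, function(t) any(abs(b$peak_indices - t) <= 12),
                   logical(1))]
  }
  m_raw <- missed(b_raw)
  m_cor <- missed(b_cor)
  expect_gte(length(m_raw), 3L)               # spikes do suppress beats
  recovered <- setdiff(m_raw, m_cor)
  expect_gte(length(recovered), ceiling(2 / 3 * length(m_raw)))
  # never removes a beat present before correction
  expect_true(all(b_raw$peak_indices %in% b_cor$peak_indices))
  # corrected detections stay close to a run on the spike-free twin
  b_clean <- detect_qrs_primary(filtered_segment(p$clean))
  agree <- mean(vapply(b_cor$peak_indices, function(i) {
    any(abs(b_clean$peak_indices - i) <= 12)
  }, logical(1)))
  expect_gte(agree, 0.9)
  # and only a small fraction of samples is ever clipped
  x <- seg_s$samples
  clip <- quantile(abs(x), 0.99, names = FALSE)
  expect_lt(mean(abs(x) > clip), 0.011)
})

test_that("bSQI matches hand-counted examples", {
  fs <- 1
  ann <- function(idx) beat_annotations(idx)
  a <- ann(c(1, 2, 3))
  expect_equal(compute_sqi(a, ann(c(1, 2, 3)), fs)$bsqi, 1.0)
  r <- compute_sqi(a, ann(c(1, 2)), fs)
  expect_identical(r$n_matched, 2L)
  expect_identical(r$n_union, 3L)
  expect_equal(r$bsqi, 2 / 3)
  fs2 <- 10
  r2 <- compute_sqi(beat_annotations(10), beat_annotations(12), fs2)
  expect_equal(r2$bsqi, 0)
  expect_true(is.na(compute_sqi(ann(integer(0)), ann(integer(0)), fs)$bsqi))
})

test_that("bSQI is symmetric and shift-invariant", {
  set.seed(42)
  for (i in 1:10) {
    a <- beat_annotations(sort(sample.int(10000, 30)))
    b <- beat_annotations(sort(sample.int(10000, 25)))
    f <- compute_sqi(a, b, 250)
    r <- compute_sqi(b, a, 250)
    expect_equal(f$bsqi, r$bsqi)
    sh <- 500L
    a2 <- beat_annotations(a$peak_indices + sh)
    b2 <- beat_annotations(b$peak_indices + sh)
    expect_equal(compute_sqi(a2, b2, 250)$bsqi, f$bsqi)
  }
})

test_that("RR construction applies the physiological range rule", {
  b <- beat_annotations(c(250, 500, 750))
  rr <- build_rr_series(b, 250)
  expect_equal(rr$beat_times, c(1, 2, 3))
  expect_equal(rr$rr, c(1, 1))
  # a 5 s artifact gap is excluded, neighbors kept
  b2 <- beat_annotations(round(c(1, 2, 3, 8, 9, 10) * 250))
  rr2 <- build_rr_series(b2, 250)
  expect_equal(rr2$rr, rep(1, 4), tolerance = 1e-9)
  expect_equal(rr2$rr_times, c(2, 3, 9, 10), tolerance = 1e-9)
  expect_null(build_rr_series(beat_annotations(c(100L)), 250))
})

test_that("constant-rate records give near-zero detected RR variability", {
  rec <- synth_record(14, duration = 70,
                      rr = rr_model_params(lf_amp = 0, hf_amp = 0,
                                           jitter_sd = 0, ectopic_rate = 0),
                      morph = morphology_params(qrs_width_sd = 0))
  seg <- filtered_segment(rec)
  rr <- build_rr_series(detect_qrs_primary(seg), 250)
  expect_lt(sd(rr$rr), 1 / 250)
})
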