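# HRV features v1-v17: formula oracles, closed-form identities, spectral
# recovery and sample-entropy brute force.

test_that("time-domain features match direct formulas on random series", {
  for (s in 1:25) {
    rr <- rand_rr(s)
    x <- rr$rr
    f <- compute_time_domain(rr)
    d <- diff(x)
    expect_equal(f[["v1"]], mean(x), tolerance = 1e-12)
    expect_equal(f[["v2"]], sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
    expect_equal(f[["v3"]], sqrt(mean(d^2)), tolerance = 1e-12)
    expect_equal(f[["v4"]], f[["v2"]] / f[["v1"]], tolerance = 1e-12)
    expect_equal(f[["v5"]], sum(abs(d) > 0.05))
    expect_equal(f[["v6"]],
                 unname(quantile(x, 0.75) - quantile(x, 0.25)),
                 tolerance = 1e-12)
  }
})

test_that("time-domain features handle degenerate series", {
  const <- rr_series(seq(0, 8, by = 0.8))
  f <- compute_time_domain(const)
  expect_equal(unname(f[c("v2", "v3", "v4", "v5", "v6")]), rep(0, 5))
  alt <- rr_series(c(0, cumsum(rep(c(0.7, 0.9), 10))))
  f2 <- compute_time_domain(alt)
  expect_equal(f2[["v5"]], length(alt$rr) - 1)
  short <- rr_series(c(0, 0.8))
  expect_true(all(is.na(compute_time_domain(short))))
})

test_that("Lomb-Scargle recovers single tones and conserves power", {
  p <- rr_model_params(mean_rr = 0.8, lf_amp = 0.05, hf_amp = 0,
                       jitter_sd = 0, ectopic_rate = 0)
  rr <- generate_rr_series(p, 120)
  sp <- compute_lomb_psd(rr)
  expect_equal(sp$freqs[which.max(sp$psd)], 0.1, tolerance = 0.005)
  tot <- postrosc:::trapz(sp$freqs, sp$psd)
  expect_equal(tot, var(rr$rr), tolerance = 0.2)
  const <- rr_series(seq(0, 60, by = 0.8))
  sp0 <- compute_lomb_psd(const)
  expect_lt(postrosc:::trapz(sp0$freqs, sp0$psd), 1e-12)
})

test_that("equal LF and HF tones give equal band powers", {
  p <- rr_model_params(mean_rr = 0.8, lf_amp = 0.04, hf_amp = 0.04,
                       jitter_sd = 0, ectopic_rate = 0)
  rr <- generate_rr_series(p, 120)
  sp <- compute_lomb_psd(rr)
  f <- compute_freq_domain(sp)
  # oracle: least-squares sinusoid fit at the two known frequencies
  t <- rr$beat_times[-1L]
  x <- rr$rr - mean(rr$rr)
  fit <- lm(x ~ sin(2 * pi * 0.1 * t) + cos(2 * pi * 0.1 * t) +
              sin(2 * pi * 0.3 * t) + cos(2 * pi * 0.3 * t))
  amps <- coef(fit)[-1L]
  p_lf <- sum(amps[1:2]^2) / 2
  p_hf <- sum(amps[3:4]^2) / 2
  expect_equal(p_lf / p_hf, 1, tolerance = 0.05)
  expect_equal(f[["v11"]], p_lf / p_hf, tolerance = 0.15)
  expect_equal(f[["v12"]], 0.1, tolerance = 0.0051)
  expect_equal(f[["v13"]], 0.3, tolerance = 0.0051)
})

test_that("frequency-domain features handle pure and empty spectra", {
  grid <- seq(0.005, 0.5, by = 0.0025)
  tone <- exp(-(grid - 0.1)^2 / (2 * 0.002^2))
  f <- compute_freq_domain(structure(list(freqs = grid, psd = tone),
                                     class = "psd_spectrum"))
  expect_gt(f[["v8"]], 0.99)
  expect_lt(f[["v10"]], 0.01)
  expect_equal(f[["v12"]], 0.1, tolerance = 1e-9)
  zero <- compute_freq_domain(structure(list(freqs = grid,
                                             psd = numeric(length(grid))),
                                        class = "psd_spectrum"))
  expect_equal(zero[["v7"]], 0)
  expect_equal(zero[["v9"]], 0)
  expect_true(is.na(zero[["v8"]]) && is.na(zero[["v11"]]))
})

test_that("Poincare features satisfy their closed forms", {
  for (s in 1:25) {
    rr <- rand_rr(s, n = 50)
    x <- rr$rr
    f <- compute_poincare(rr)
    expect_equal(f[["v14"]], 0.5 * var(diff(x)), tolerance = 1e-12)
    # population-variance oracle for the SD1^2 + SD2^2 decomposition
    pvar <- function(v) mean((v - mean(v))^2)
    n <- length(x)
    d <- (x[-1] - x[-n]) / sqrt(2)
    s2 <- (x[-1] + x[-n]) / sqrt(2)
    expect_lt(abs(pvar(d) + pvar(s2) -
                  (pvar(x[-1]) + pvar(x[-n]))), 1e-9)
    expect_equal(f[["v16"]], f[["v14"]] / f[["v15"]], tolerance = 1e-12)
  }
  const <- rr_series(0:10)
  fc <- compute_poincare(const)
  expect_equal(fc[["v14"]], 0)
  expect_equal(fc[["v15"]], 0)
  expect_true(is.na(fc[["v16"]]))
})

test_that("sample entropy matches the brute-force template counter", {
  # constant series: every template matches, SampEn = 0
  expect_equal(sampen(rep(1, 50), 1, 0.2), 0)
  for (s in 1:10) {
    set.seed(s)
    y <- rnorm(80 + s)
    r <- 0.2 * sd(y)
    expect_equal(sampen(y, 1, r), brute_sampen(y, 1, r), tolerance = 1e-12)
  }
  # through the RR interface with interpolated length <= 100
  rr <- rand_rr(77, n = 14, mean_rr = 0.8, sd = 0.05)
  v17 <- compute_sample_entropy(rr)
  grid <- seq(rr$beat_times[2L], rr$beat_times[length(rr$beat_times)],
              by = 0.1)
  y <- spline(rr$beat_times[-1L], rr$rr, xout = grid, method = "fmm")$y
  expect_lte(length(y), 110)
  expect_equal(v17, brute_sampen(y, 1, 0.2 * sd(y)), tolerance = 1e-12)
})

test_that("white jitter has higher entropy than a sinusoid of equal SD", {
  p_sin <- rr_model_params(mean_rr = 0.8, lf_amp = 0.05, hf_amp = 0,
                           jitter_sd = 0, ectopic_rate = 0)
  rr_sin <- generate_rr_series(p_sin, 120)
  target_sd <- sd(rr_sin$rr)
  p_wht <- rr_model_params(mean_rr = 0.8, lf_amp = 0, hf_amp = 0,
                           jitter_sd = target_sd, ectopic_rate = 0)
  rr_wht <- generate_rr_series(p_wht, 120, seed = 5)
  expect_gt(compute_sample_entropy(rr_wht), compute_sample_entropy(rr_sin))
})

test_that("feature identities and scalings hold across random series", {
  for (s in 1:10) {
    rr <- rand_rr(s, n = 80)
    td <- compute_time_domain(rr)
    pc <- compute_poincare(rr)
    expect_equal(td[["v4"]], td[["v2"]] / td[["v1"]], tolerance = 1e-12)
    expect_equal(pc[["v16"]], pc[["v14"]] / pc[["v15"]], tolerance = 1e-12)
    sp <- compute_lomb_psd(rr)
    fd <- compute_freq_domain(sp)
    if (!is.na(fd[["v8"]])) {
      expect_equal(fd[["v8"]] + fd[["v10"]], 1, tolerance = 1e-12)
    }
    # scaling rr -> c*rr
    cc <- 1.7
    rr_s <- rr_series(rr$beat_times * cc)
    td_s <- compute_time_domain(rr_s)
    pc_s <- compute_poincare(rr_s)
    expect_equal(td_s[["v2"]], cc * td[["v2"]], tolerance = 1e-9)
    expect_equal(td_s[["v3"]], cc * td[["v3"]], tolerance = 1e-9)
    expect_equal(td_s[["v6"]], cc * td[["v6"]], tolerance = 1e-9)
    expect_equal(pc_s[["v14"]], cc^2 * pc[["v14"]], tolerance = 1e-9)
    expect_equal(pc_s[["v15"]], cc^2 * pc[["v15"]], tolerance = 1e-9)
    # time-shift invariance
    rr_t <- rr_series(rr$beat_times + 100)
    expect_equal(compute_time_domain(rr_t), td, tolerance = 1e-9)
  }
})

test_that("sample entropy is invariant under amplitude scaling of RR", {
  rr <- generate_rr_series(rr_model_params(), 120, seed = 8)
  v <- compute_sample_entropy(rr)
  rr2 <- rr
  rr2$rr <- rr$rr * 3
  expect_equal(compute_sample_entropy(rr2), v, tolerance = 1e-9)
})
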